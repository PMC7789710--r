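# Seeded synthetic donors, candidate pools, and policy-ranked match runs.
# Real match-run data are restricted; the generator emulates their marginal
# structure (pool sizes, LAS and distance ranges, ABO and age mixes) so that
# every downstream stage is testable.

#' Configuration for the synthetic cohort generator
#'
#' Bundles the knobs that determine a synthetic waiting list and its match
#' runs.  Defaults emulate the 2018 U.S. lung setting: a continental-scale
#' planar map, a national list of 450 registrations of which roughly 2% are
#' children and 6% adolescents, a bimodal LAS distribution with a small tail
#' of very ill candidates, approximate U.S. ABO frequencies, and per-run
#' screening that leaves adult-donor runs with ~400 ranked candidates and
#' pediatric-donor runs with ~275.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param n_centers number of transplant centers scattered on the map.
#' @param map_extent_nm width/height of the planar map, NM.
#' @param n_candidates national waiting-list size.
#' @param n_donors number of donors (one match run each).
#' @param abo_frequencies named probabilities for types O/A/B/AB.
#' @param age_mix named proportions for `under12`, `adolescent`, `adult`.
#' @param las_mixture two-component normal mixture for LAS of candidates
#'   aged 12+ (list with `weights`, `means`, `sds`), truncated to \[0, 100\].
#' @param waiting_time gamma parameters (`shape`, `scale`, days) for
#'   waiting-list tenure.
#' @param donor_age_mix named proportions of `adult` (18+) vs `pediatric`
#'   donors.
#' @param screening_drop_fraction fraction of the pool screened off each
#'   adult-donor run (center acceptance criteria are not modelled; screening
#'   is a random per-run subset).
#' @param pediatric_screening_drop_fraction same for pediatric-donor runs;
#'   higher by default because centers screen pediatric organs for far fewer
#'   candidates.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_centers = 64L,
                          map_extent_nm = c(3500, 2000),
                          n_candidates = 450L,
                          n_donors = 350L,
                          abo_frequencies = c(O = 0.44, A = 0.42,
                                              B = 0.10, AB = 0.04),
                          age_mix = c(under12 = 0.02, adolescent = 0.06,
                                      adult = 0.92),
                          las_mixture = list(weights = c(0.85, 0.15),
                                             means = c(38, 75),
                                             sds = c(8, 10)),
                          waiting_time = list(shape = 1.5, scale = 200),
                          donor_age_mix = c(adult = 0.90, pediatric = 0.10),
                          screening_drop_fraction = 0.10,
                          pediatric_screening_drop_fraction = 0.39) {
  config <- list(seed = as.integer(seed), n_centers = as.integer(n_centers),
                 map_extent_nm = map_extent_nm,
                 n_candidates = as.integer(n_candidates),
                 n_donors = as.integer(n_donors),
                 abo_frequencies = abo_frequencies, age_mix = age_mix,
                 las_mixture = las_mixture, waiting_time = waiting_time,
                 donor_age_mix = donor_age_mix,
                 screening_drop_fraction = screening_drop_fraction,
                 pediatric_screening_drop_fraction =
                   pediatric_screening_drop_fraction)
  class(config) <- "cohort_config"
  validate_cohort_config(config)
}

#' @rdname cohort_config
#' @param config a `cohort_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  with(config, {
    if (n_centers < 1L || n_candidates < 1L || n_donors < 1L) {
      stop("all counts in a cohort_config must be positive")
    }
    for (p in list(abo_frequencies, age_mix, donor_age_mix)) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop("probabilities must be non-negative and sum to 1")
      }
    }
    if (!length(abo_frequencies) ||
        !all(names(abo_frequencies) %in% ABO_TYPES) ||
        anyDuplicated(names(abo_frequencies))) {
      stop("abo_frequencies must be named with distinct types among O, A, B, AB")
    }
    if (screening_drop_fraction < 0 || screening_drop_fraction >= 1 ||
        pediatric_screening_drop_fraction < 0 ||
        pediatric_screening_drop_fraction >= 1) {
      stop("screening drop fractions must lie in [0, 1)")
    }
    if (length(map_extent_nm) != 2L || any(map_extent_nm <= 0)) {
      stop("map_extent_nm must be two positive lengths")
    }
  })
  invisible(config)
}

.rtruncmix <- function(n, mixture, lower = 0, upper = 100) {
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  x <- stats::rnorm(n, mixture$means[comp], mixture$sds[comp])
  # resample the few draws outside [lower, upper]
  out <- which(x < lower | x > upper)
  while (length(out)) {
    comp <- sample.int(length(mixture$weights), length(out), replace = TRUE,
                       prob = mixture$weights)
    x[out] <- stats::rnorm(length(out), mixture$means[comp],
                           mixture$sds[comp])
    out <- out[x[out] < lower | x[out] > upper]
  }
  x
}

#' Generate a synthetic candidate pool
#'
#' Draws transplant centers uniformly on the map, assigns candidates to
#' centers with symmetric Dirichlet-multinomial center sizes, and samples
#' ages, blood types, waiting times, and (for candidates aged 12+) LAS from
#' the configured distributions.  Under-12 candidates carry `NA` LAS; their
#' medical priority in policy sorting is waiting time.
#'
#' @param config a [cohort_config()].
#' @param seed seed to apply before sampling; `NULL` continues the current
#'   RNG stream (used internally by [generate_match_runs()]).
#' @return candidate data frame with columns `id`, `age_years`, `las`,
#'   `waiting_time_days`, `abo`, `center_x`, `center_y`.
#' @export
generate_pool <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_candidates
  centers <- data.frame(
    x = stats::runif(config$n_centers, 0, config$map_extent_nm[1]),
    y = stats::runif(config$n_centers, 0, config$map_extent_nm[2]))
  center_w <- stats::rgamma(config$n_centers, shape = 1, rate = 1)
  center_of <- sample.int(config$n_centers, n, replace = TRUE,
                          prob = center_w / sum(center_w))
  bracket <- sample(names(config$age_mix), n, replace = TRUE,
                    prob = config$age_mix)
  age <- numeric(n)
  age[bracket == "under12"] <- stats::runif(sum(bracket == "under12"), 0, 12)
  age[bracket == "adolescent"] <-
    stats::runif(sum(bracket == "adolescent"), 12, 18)
  age[bracket == "adult"] <- stats::runif(sum(bracket == "adult"), 18, 75)
  las <- rep(NA_real_, n)
  las[age >= 12] <- .rtruncmix(sum(age >= 12), config$las_mixture)
  data.frame(
    id = sprintf("C%05d", seq_len(n)),
    age_years = age,
    las = las,
    waiting_time_days = stats::rgamma(n, shape = config$waiting_time$shape,
                                      scale = config$waiting_time$scale),
    abo = sample(names(config$abo_frequencies), n, replace = TRUE,
                 prob = config$abo_frequencies),
    center_x = centers$x[center_of],
    center_y = centers$y[center_of],
    stringsAsFactors = FALSE)
}

#' Generate synthetic donors
#'
#' @inheritParams generate_pool
#' @return donor data frame with columns `id`, `age_years`, `abo`,
#'   `hospital_x`, `hospital_y`.
#' @export
generate_donors <- function(config, seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_donors
  kind <- sample(names(config$donor_age_mix), n, replace = TRUE,
                 prob = config$donor_age_mix)
  age <- ifelse(kind == "adult", stats::runif(n, 18, 70),
                stats::runif(n, 0, 18))
  data.frame(
    id = sprintf("D%04d", seq_len(n)),
    age_years = age,
    abo = sample(names(config$abo_frequencies), n, replace = TRUE,
                 prob = config$abo_frequencies),
    hospital_x = stats::runif(n, 0, config$map_extent_nm[1]),
    hospital_y = stats::runif(n, 0, config$map_extent_nm[2]),
    stringsAsFactors = FALSE)
}

#' Generate policy-ranked synthetic match runs
#'
#' Produces one match run per donor: a per-run random screening subset of
#' the pool is ranked by [run_match()] with the adult or pediatric table
#' according to the donor's age.  Fully reproducible from the config seed.
#'
#' @param config a [cohort_config()].
#' @param table_adult,table_ped policy tables for adult and pediatric
#'   donors.
#' @return list of `match_run` objects, named by match id `M0001`, ...
#' @export
generate_match_runs <- function(config,
                                table_adult = adult_policy_table(),
                                table_ped = pediatric_policy_table()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  pool <- generate_pool(config, seed = NULL)
  donors <- generate_donors(config, seed = NULL)
  runs <- vector("list", nrow(donors))
  for (i in seq_len(nrow(donors))) {
    donor <- as.list(donors[i, ])
    adult_donor <- donor$age_years >= 18
    drop <- if (adult_donor) config$screening_drop_fraction
            else config$pediatric_screening_drop_fraction
    keep <- stats::runif(nrow(pool)) >= drop
    run <- run_match(donor, pool[keep, , drop = FALSE],
                     table = if (adult_donor) table_adult else table_ped)
    runs[[i]] <- run
  }
  names(runs) <- sprintf("M%04d", seq_along(runs))
  runs
}

#' Sample a ranking from the rank-ordered logit model
#'
#' Draws one ranking of the pool from the Plackett-Luce distribution implied
#' by a coefficient set: each candidate's latent priority is its linear
#' score plus an independent standard Gumbel disturbance, and candidates are
#' ranked by descending latent priority.  Used for parameter-recovery
#' simulations; the resulting entries carry no classification index because
#' the ranking is stochastic, not policy-derived.
#'
#' @param beta a `coefficient_set` (see [coefficient_set()]).
#' @param pool candidate data frame (see [generate_pool()]).
#' @param donor a donor list (see [run_match()]).
#' @param seed optional seed; `NULL` continues the current stream.
#' @return a `match_run` whose `policy_rank` is the sampled ranking.
#' @export
sample_from_rol <- function(beta, pool, donor, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(pool)
  dist <- sqrt((pool$center_x - donor$hospital_x)^2 +
               (pool$center_y - donor$hospital_y)^2)
  rel <- abo_relation(pool$abo, donor$abo)
  x <- encode_covariates(data.frame(age_years = pool$age_years,
                                    las = pool$las, distance_nm = dist,
                                    abo_relation = rel,
                                    stringsAsFactors = FALSE),
                         beta$model_kind)
  v <- drop(x %*% beta$beta[colnames(x)])
  gumbel <- -log(-log(stats::runif(J)))
  ord <- order(-(v + gumbel), pool$id)
  entries <- data.frame(candidate_id = as.character(pool$id[ord]),
                        policy_rank = seq_len(J),
                        age_years = pool$age_years[ord],
                        las = pool$las[ord],
                        waiting_time_days = pool$waiting_time_days[ord],
                        distance_nm = dist[ord],
                        zone = zone_of(dist[ord]),
                        abo_relation = rel[ord],
                        classification_index = NA_integer_,
                        stringsAsFactors = FALSE)
  new_match_run(donor, entries)
}
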