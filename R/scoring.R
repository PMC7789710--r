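# Composite allocation scores and their policy-facing summaries: attribute
# importance (score span between the most and least preferred level of each
# attribute) and nautical-mile "exchange rates" (the distance change with
# the same score effect as a change in another attribute).

.rounded_beta <- function(beta, rounding) {
  b <- if (inherits(beta, "coefficient_set")) beta$beta else beta
  if (!is.null(rounding)) b <- round(b, rounding)
  b
}

#' Composite allocation score
#'
#' The linear points-based score V = sum_k beta_k x_k of a candidate's
#' covariates.  Worked-example mode (`rounding = 3`) first rounds the
#' coefficients to three decimals, matching how the published tables were
#' computed; `rounding = NULL` uses full-precision coefficients.
#'
#' @param beta a `coefficient_set`.
#' @param x named numeric vector, or a matrix/data frame with one column
#'   per model covariate (names as in [encode_covariates()]).
#' @param rounding decimals to round the coefficients to, or `NULL`.
#' @return numeric score(s).
#' @examples
#' b <- reference_coefficients("adult")
#' composite_score(b, c(las = 50, child = 0, distance = 200,
#'                      abo_identical = 1), rounding = 3)
#' @export
composite_score <- function(beta, x, rounding = NULL) {
  b <- .rounded_beta(beta, rounding)
  if (is.null(dim(x))) {
    if (!setequal(names(x), names(b))) {
      stop("covariates must name exactly: ", paste(names(b), collapse = ", "))
    }
    sum(b * x[names(b)])
  } else {
    x <- as.matrix(as.data.frame(x)[, names(b), drop = FALSE])
    drop(x %*% b)
  }
}

#' Default attribute ranges for importance calculations
#'
#' The most and least preferred observed level of each attribute, on the
#' covariate scale, as used in the published importance tables: LAS spans 0
#' to the sample maximum 96.23; age is the child dummy (adults preferred
#' for adult donors, children for pediatric donors); distance spans 0 to the
#' sample maximum (4415.25 NM adult, 4040.68 NM pediatric); blood type spans
#' the effects-coded +1 (identical) to -1 (compatible/incompatible).
#'
#' @param model_kind `"adult"` or `"pediatric"`.
#' @param las_max,distance_max sample maxima to use as extreme levels.
#' @return data frame with columns `attribute`, `coefficient`, `most`,
#'   `least`.
#' @export
default_attribute_ranges <- function(model_kind = c("adult", "pediatric"),
                                     las_max = 96.23,
                                     distance_max = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(distance_max)) {
    distance_max <- if (model_kind == "adult") 4415.25 else 4040.68
  }
  child_most <- if (model_kind == "adult") 0 else 1
  data.frame(
    attribute = c("medical_priority", "candidate_age", "proximity",
                  "blood_type"),
    coefficient = c("las", "child", "distance", "abo_identical"),
    most = c(las_max, child_most, 0, 1),
    least = c(0, 1 - child_most, distance_max, -1),
    stringsAsFactors = FALSE)
}

#' Rank attributes by importance
#'
#' For each attribute, the score at its most preferred level, the score at
#' its least preferred level, their difference, and the resulting importance
#' rank (rank 1 = largest difference).
#'
#' @param beta a `coefficient_set`.
#' @param ranges attribute ranges (see [default_attribute_ranges()]).
#' @param rounding decimals for the coefficients and the reported scores
#'   (3 reproduces the published tables); `NULL` for full precision.
#' @return data frame with columns `attribute`, `score_most_preferred`,
#'   `score_least_preferred`, `difference`, `importance_rank`.
#' @export
attribute_importance <- function(beta,
                                 ranges = default_attribute_ranges(
                                   beta$model_kind),
                                 rounding = 3) {
  b <- .rounded_beta(beta, rounding)
  missing <- setdiff(ranges$coefficient, names(b))
  if (length(missing)) {
    stop("no coefficient for attribute range(s): ",
         paste(missing, collapse = ", "))
  }
  most <- b[ranges$coefficient] * ranges$most
  least <- b[ranges$coefficient] * ranges$least
  diff <- most - least
  if (!is.null(rounding)) {
    most <- round(most, rounding)
    least <- round(least, rounding)
    diff <- round(diff, rounding)
  }
  out <- data.frame(attribute = ranges$attribute,
                    score_most_preferred = unname(most),
                    score_least_preferred = unname(least),
                    difference = unname(diff),
                    importance_rank = rank(-diff, ties.method = "min"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Distance exchange rate of a score change
#'
#' Converts a composite-score change into the equivalent change in distance
#' (NM): `delta_score / beta_distance`.  A score-increasing change yields a
#' negative NM value (the candidate could be that much farther away for the
#' same score).
#'
#' @param beta a `coefficient_set` with a nonzero distance coefficient.
#' @param delta_score score change(s) to convert.
#' @param rounding decimals for the coefficients; 3 reproduces the published
#'   rates.
#' @return NM equivalent(s) of `delta_score`.
#' @examples
#' exchange_rate(reference_coefficients("adult"), -1)   # 142.857 NM
#' @export
exchange_rate <- function(beta, delta_score, rounding = 3) {
  b <- .rounded_beta(beta, rounding)
  if (b[["distance"]] == 0) {
    stop("distance coefficient is zero; exchange rate undefined")
  }
  delta_score / b[["distance"]]
}

#' Standard exchange-rate table
#'
#' The three canonical conversions: a 25-point LAS reduction, the age change
#' between the 12-plus and under-12 brackets, and a blood-type change from
#' identical to compatible (an effects-coded swing of -2).
#'
#' @inheritParams exchange_rate
#' @return data frame with columns `change`, `delta_score`,
#'   `equivalent_nm`.
#' @export
exchange_rate_table <- function(beta, rounding = 3) {
  b <- .rounded_beta(beta, rounding)
  deltas <- c(las_minus_25 = unname(b[["las"]] * -25),
              adult_to_child = unname(b[["child"]]),
              identical_to_compatible = unname(b[["abo_identical"]] * -2))
  out <- data.frame(change = names(deltas),
                    delta_score = unname(deltas),
                    equivalent_nm = unname(deltas / b[["distance"]]),
                    stringsAsFactors = FALSE)
  if (!is.null(rounding)) {
    out$delta_score <- round(out$delta_score, rounding)
    out$equivalent_nm <- round(out$equivalent_nm, rounding)
  }
  out
}

#' Score and re-rank a match run with a composite score
#'
#' Computes each ranked candidate's composite score and the rank it would
#' have received under a points-based policy (rank 1 = highest score, ties
#' broken by candidate id ascending).
#'
#' @param run a `match_run`.
#' @param beta a `coefficient_set`.
#' @param rounding optional coefficient rounding (see [composite_score()]).
#' @return data frame with columns `candidate_id`, `composite_score`,
#'   `score_rank`, `policy_rank`.
#' @export
score_match_run <- function(run, beta, rounding = NULL) {
  e <- run$entries
  x <- encode_covariates(e, beta$model_kind)
  score <- composite_score(beta, x, rounding = rounding)
  ord <- order(-score, e$candidate_id)
  rank <- integer(nrow(e))
  rank[ord] <- seq_len(nrow(e))
  data.frame(candidate_id = e$candidate_id,
             composite_score = score,
             score_rank = rank,
             policy_rank = e$policy_rank,
             stringsAsFactors = FALSE)
}
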