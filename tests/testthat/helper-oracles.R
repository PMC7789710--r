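# Independent oracles used across tests.  Everything here is deliberately
# naive (pairwise enumeration, closed forms, selection sort) and shares no
# code with the package implementation.

# --- rank statistics ---------------------------------------------------

# tau-b by O(n^2) concordant/discordant pair counting
brute_kendall <- function(a, b) {
  n <- length(a)
  C <- D <- ta <- tb <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      da <- a[i] - a[j]
      db <- b[i] - b[j]
      if (da * db > 0) C <- C + 1
      if (da * db < 0) D <- D + 1
      if (da == 0) ta <- ta + 1
      if (db == 0) tb <- tb + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - ta) * (n0 - tb))
}

# Pearson correlation of midranks, computed from first principles
brute_spearman <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  num / sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# closed form for strict (tie-free) rankings
spearman_closed_form <- function(a, b) {
  n <- length(a)
  1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
}

# --- policy engine -----------------------------------------------------

# Independent re-derivation of the allocation ordering: zone by if-chains,
# ABO relation by an explicit matrix, classification by scanning the table
# rows, and a pairwise-comparator selection sort.
oracle_zone <- function(d) {
  if (d <= 250) "A"
  else if (d <= 500) "B"
  else if (d <= 1000) "C"
  else if (d <= 1500) "D"
  else if (d <= 2500) "E"
  else "F"
}

oracle_abo <- function(cand, donor) {
  if (cand == donor) return("identical")
  ok <- switch(donor,
               O = c("A", "B", "AB"),
               A = "AB",
               B = "AB",
               AB = character())
  if (cand %in% ok) "compatible" else "incompatible"
}

oracle_classification <- function(age, zone, rel, table) {
  bracket <- if (age < 12) "under12" else if (age < 18) "adolescent"
             else "adult"
  for (i in seq_len(nrow(table))) {
    cell_brackets <- switch(table$age_bracket[i],
                            "12plus" = c("adolescent", "adult"),
                            table$age_bracket[i])
    if (table$zone[i] == zone && bracket %in% cell_brackets &&
        table$abo[i] == rel) {
      return(i)
    }
  }
  stop("uncovered triple in oracle")
}

# TRUE if candidate i strictly precedes candidate k under the lexicographic
# rule (classification, then LAS / waiting-time priority, then waiting time,
# then id)
oracle_precedes <- function(pool, i, k, ci) {
  if (ci[i] != ci[k]) return(ci[i] < ci[k])
  key <- function(j) {
    if (pool$age_years[j] >= 12) pool$las[j] else pool$waiting_time_days[j]
  }
  if (key(i) != key(k)) return(key(i) > key(k))
  if (pool$waiting_time_days[i] != pool$waiting_time_days[k]) {
    return(pool$waiting_time_days[i] > pool$waiting_time_days[k])
  }
  pool$id[i] < pool$id[k]
}

# selection sort of the pool by oracle_precedes; returns candidate ids in
# priority order
oracle_ranking <- function(pool, donor, table) {
  n <- nrow(pool)
  d <- sqrt((pool$center_x - donor$hospital_x)^2 +
            (pool$center_y - donor$hospital_y)^2)
  ci <- vapply(seq_len(n), function(j) {
    oracle_classification(pool$age_years[j], oracle_zone(d[j]),
                          oracle_abo(pool$abo[j], donor$abo), table)
  }, numeric(1))
  remaining <- seq_len(n)
  out <- integer(0)
  while (length(remaining)) {
    best <- remaining[1]
    for (j in remaining[-1]) {
      if (oracle_precedes(pool, j, best, ci)) best <- j
    }
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  pool$id[out]
}

# --- fixtures ----------------------------------------------------------

# a match_run built directly from an entries data frame
make_run <- function(entries, donor = list(id = "D1", age_years = 50,
                                           abo = "O")) {
  if (is.null(entries$policy_rank)) {
    entries$policy_rank <- seq_len(nrow(entries))
  }
  if (is.null(entries$candidate_id)) {
    entries$candidate_id <- sprintf("C%03d", seq_len(nrow(entries)))
  }
  structure(list(donor = donor, entries = entries), class = "match_run")
}

# a random ranked run with the covariates the models use
random_run <- function(J, model_kind = "adult", child_prob = 0.1) {
  age <- ifelse(runif(J) < child_prob, runif(J, 0, 12), runif(J, 12, 75))
  make_run(data.frame(
    age_years = age,
    las = ifelse(age < 12, NA_real_, runif(J, 0, 96)),
    waiting_time_days = runif(J, 0, 2000),
    distance_nm = runif(J, 0, 3000),
    abo_relation = sample(c("identical", "compatible", "incompatible"), J,
                          replace = TRUE),
    stringsAsFactors = FALSE))
}

# a random small candidate pool exercising zone boundaries and age brackets
random_pool <- function(n, zone_edges = TRUE) {
  age <- sample(c(runif(n, 0, 12), runif(n, 12, 18), runif(n, 18, 75)), n)
  x <- runif(n, 0, 3000)
  if (zone_edges && n >= 3) {
    x[1:3] <- sample(c(250, 500, 1000, 1500, 2500, 251, 2600), 3)
  }
  data.frame(
    id = sprintf("C%03d", sample.int(999, n)),
    age_years = age,
    las = ifelse(age < 12, NA_real_, round(runif(n, 0, 96), 1)),
    waiting_time_days = sample(c(100, 100, round(runif(n, 0, 2000))), n),
    abo = sample(c("O", "A", "B", "AB"), n, replace = TRUE),
    center_x = x,
    center_y = runif(n, 0, 1500),
    stringsAsFactors = FALSE)
}

random_donor <- function() {
  list(id = "D1", age_years = runif(1, 18, 60),
       abo = sample(c("O", "A", "B", "AB"), 1),
       hospital_x = runif(1, 0, 500), hospital_y = runif(1, 0, 500))
}
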