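# Deterministic match-run ranking under the classification-based U.S. lung
# allocation policy: candidates are stratified into ordered cells of a
# (proximity zone x age bracket x ABO relation) grid and sorted within each
# cell by medical priority.

ABO_TYPES <- c("O", "A", "B", "AB")
ABO_RELATIONS <- c("identical", "compatible", "incompatible")
ZONE_LABELS <- c("A", "B", "C", "D", "E", "F")
# Zone radii around the donor hospital, NM.  Zone A is closed at 250;
# bands above are half-open (250, 500], (500, 1000], ...
ZONE_BREAKS <- c(0, 250, 500, 1000, 1500, 2500, Inf)

#' Blood-type relation between candidate and donor
#'
#' Classifies each candidate/donor ABO pair as `identical` (equal types),
#' `compatible` (donor can give to the candidate under standard transfusion
#' rules, but the types differ: O to A/B/AB, A to AB, B to AB), or
#' `incompatible` otherwise.
#'
#' @param candidate_abo character vector of candidate blood types
#'   (`"O"`, `"A"`, `"B"`, `"AB"`).
#' @param donor_abo donor blood type(s), recycled against `candidate_abo`.
#' @return character vector in `c("identical", "compatible", "incompatible")`.
#' @examples
#' abo_relation(c("A", "AB", "O"), "A")
#' @export
abo_relation <- function(candidate_abo, donor_abo) {
  bad <- !(candidate_abo %in% ABO_TYPES) | !(donor_abo %in% ABO_TYPES)
  if (any(bad)) {
    stop("unknown blood-type token: ",
         paste(unique(c(candidate_abo, donor_abo)[
           !(c(candidate_abo, donor_abo) %in% ABO_TYPES)]), collapse = ", "))
  }
  n <- max(length(candidate_abo), length(donor_abo))
  candidate_abo <- rep_len(candidate_abo, n)
  donor_abo <- rep_len(donor_abo, n)
  can_receive <- (donor_abo == "O") |
    (donor_abo == "A" & candidate_abo == "AB") |
    (donor_abo == "B" & candidate_abo == "AB") |
    (donor_abo == candidate_abo)
  ifelse(candidate_abo == donor_abo, "identical",
         ifelse(can_receive, "compatible", "incompatible"))
}

#' Proximity zone of a donor-candidate distance
#'
#' Maps distance from the donor hospital to the concentric allocation zones:
#' A for 0--250 NM (inclusive), B for (250, 500], C for (500, 1000],
#' D for (1000, 1500], E for (1500, 2500], F beyond 2500 NM.
#'
#' @param distance_nm non-negative numeric vector, nautical miles.
#' @return character vector of zone labels `"A"`--`"F"`.
#' @examples
#' zone_of(c(0, 250, 251, 2600))
#' @export
zone_of <- function(distance_nm) {
  if (any(!is.finite(distance_nm) | distance_nm < 0)) {
    stop("distance_nm must be finite and non-negative")
  }
  as.character(cut(distance_nm, breaks = ZONE_BREAKS, labels = ZONE_LABELS,
                   include.lowest = TRUE, right = TRUE))
}

new_policy_table <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("zone", "age_bracket", "abo") %in% names(cells)))
  cells <- cells[, c("zone", "age_bracket", "abo")]
  rownames(cells) <- NULL
  class(cells) <- c("policy_table", "data.frame")
  cells
}

#' Default adult-donor policy table
#'
#' The 36-cell classification grid used to allocate lungs from donors aged
#' 18 or older: zones A through F in order, and within each zone the age
#' bracket / ABO cells (12-plus identical, 12-plus compatible, 12-plus
#' incompatible, under-12 identical, under-12 compatible, under-12
#' incompatible).  Candidates in a later cell never outrank candidates in an
#' earlier cell.
#'
#' @return a `policy_table`: a data frame with columns `zone`, `age_bracket`,
#'   `abo`, one row per classification cell in priority order.
#' @seealso [pediatric_policy_table()], [run_match()]
#' @export
adult_policy_table <- function() {
  cells <- expand.grid(abo = ABO_RELATIONS,
                       age_bracket = c("12plus", "under12"),
                       zone = ZONE_LABELS,
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  new_policy_table(cells)
}

#' Default pediatric-donor policy table
#'
#' Classification grid for donors younger than 18.  It satisfies the two
#' stated pediatric-policy properties: children (under 12) registered within
#' 1000 NM (zones A--C) are prioritized over all older candidates, and
#' adolescents (12--17) are prioritized ahead of adults within each zone
#' block.  Children beyond 1000 NM occupy the under-12 positions of zones
#' D--F after that zone's adolescents and adults.  Because the age axis has
#' three brackets here, the covering grid has 54 cells; the cell order is a
#' documented default and the engine accepts any table with the same schema.
#'
#' @return a `policy_table` (see [adult_policy_table()]).
#' @export
pediatric_policy_table <- function() {
  abo <- ABO_RELATIONS
  block <- function(zone, bracket) {
    data.frame(zone = zone, age_bracket = bracket, abo = abo,
               stringsAsFactors = FALSE)
  }
  head_cells <- do.call(rbind, lapply(c("A", "B", "C"), block,
                                      bracket = "under12"))
  zone_cells <- do.call(rbind, lapply(ZONE_LABELS, function(z) {
    cells <- rbind(block(z, "adolescent"), block(z, "adult"))
    if (z %in% c("D", "E", "F")) cells <- rbind(cells, block(z, "under12"))
    cells
  }))
  new_policy_table(rbind(head_cells, zone_cells))
}

# Concrete age brackets a table cell covers.
.bracket_expansion <- function(age_bracket) {
  switch(age_bracket,
         under12 = "under12",
         adolescent = "adolescent",
         adult = "adult",
         "12plus" = c("adolescent", "adult"),
         stop("unknown age bracket token: ", age_bracket))
}

.age_bracket_of <- function(age_years) {
  ifelse(age_years < 12, "under12",
         ifelse(age_years < 18, "adolescent", "adult"))
}

# (zone, concrete bracket, abo) -> classification index lookup.
.policy_lookup <- function(table) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    data.frame(zone = table$zone[i],
               bracket = .bracket_expansion(table$age_bracket[i]),
               abo = table$abo[i],
               index = i,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$zone, out$bracket, out$abo, sep = "|")
  if (anyDuplicated(key)) {
    stop("policy table maps some (zone, age bracket, ABO) triple to ",
         "more than one cell: ", paste(unique(key[duplicated(key)]),
                                       collapse = ", "))
  }
  stats::setNames(out$index, key)
}

#' Validate a policy table
#'
#' Checks that the cells are unique, use known tokens, and that every
#' (zone, age bracket, ABO relation) triple that can occur maps to exactly
#' one cell.
#'
#' @param table a `policy_table`.
#' @return `table`, invisibly; errors describe any violation.
#' @export
validate_policy_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(table$zone %in% ZONE_LABELS)) stop("unknown zone label in table")
  if (!all(table$abo %in% ABO_RELATIONS)) stop("unknown ABO relation in table")
  if (anyDuplicated(table[, c("zone", "age_bracket", "abo")])) {
    stop("duplicated policy table cells")
  }
  lookup <- .policy_lookup(table)
  combos <- expand.grid(zone = ZONE_LABELS,
                        bracket = c("under12", "adolescent", "adult"),
                        abo = ABO_RELATIONS, stringsAsFactors = FALSE)
  key <- paste(combos$zone, combos$bracket, combos$abo, sep = "|")
  missing <- key[!(key %in% names(lookup))]
  if (length(missing)) {
    stop("policy table does not cover: ", paste(missing, collapse = ", "))
  }
  invisible(table)
}

#' Classification index of candidates for a donor
#'
#' Returns the 1-based position, in the policy table's priority order, of the
#' cell each candidate falls into.
#'
#' @param age_years candidate ages in years.
#' @param zone proximity zone labels (see [zone_of()]).
#' @param abo_rel ABO relations (see [abo_relation()]).
#' @param table a `policy_table`.
#' @return integer vector of classification indices.
#' @export
classify <- function(age_years, zone, abo_rel, table) {
  lookup <- .policy_lookup(table)
  key <- paste(zone, .age_bracket_of(age_years), abo_rel, sep = "|")
  idx <- lookup[key]
  if (anyNA(idx)) {
    stop("policy table does not cover triple(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  unname(idx)
}

new_match_run <- function(donor, entries) {
  structure(list(donor = donor, entries = entries), class = "match_run")
}

#' @export
print.match_run <- function(x, ...) {
  cat(sprintf("<match_run> donor %s (age %.1f, %s): %d ranked candidates\n",
              x$donor$id, x$donor$age_years, x$donor$abo, nrow(x$entries)))
  if (nrow(x$entries)) print(utils::head(x$entries, 5L))
  invisible(x)
}

#' Rank a candidate pool for a donor under classification-based policy
#'
#' Implements the deterministic match-system ordering: candidates are sorted
#' by classification cell (see [classify()]); within a cell, candidates aged
#' 12 or older are sorted by descending lung allocation score (LAS) and
#' younger candidates by descending waiting time; remaining ties are broken
#' by descending waiting time and then candidate id (ascending), so the
#' ordering is a strict total order and the run is reproducible
#' byte-for-byte.
#'
#' @param donor a donor: list with `id`, `age_years`, `abo`, `hospital_x`,
#'   `hospital_y` (planar NM coordinates).
#' @param pool candidate data frame with columns `id`, `age_years`, `las`
#'   (may be `NA` for under-12 candidates), `waiting_time_days`, `abo`,
#'   `center_x`, `center_y`.
#' @param table a `policy_table`; defaults to the adult or pediatric table
#'   according to `donor$age_years`.
#' @return a `match_run`: list with the `donor` and an `entries` data frame
#'   (`candidate_id`, `policy_rank`, `age_years`, `las`, `waiting_time_days`,
#'   `distance_nm`, `zone`, `abo_relation`, `classification_index`) ordered
#'   by `policy_rank`.
#' @examples
#' pool <- data.frame(id = c("A", "B"), age_years = 45, las = c(50, 90),
#'                    waiting_time_days = 100, abo = "O",
#'                    center_x = c(200, 251), center_y = 0)
#' donor <- list(id = "D1", age_years = 50, abo = "O",
#'               hospital_x = 0, hospital_y = 0)
#' run_match(donor, pool)$entries[, c("candidate_id", "policy_rank")]
#' @export
run_match <- function(donor, pool,
                      table = if (donor$age_years >= 18) adult_policy_table()
                              else pediatric_policy_table()) {
  if (nrow(pool) == 0L) {
    entries <- data.frame(candidate_id = character(), policy_rank = integer(),
                          age_years = numeric(), las = numeric(),
                          waiting_time_days = numeric(),
                          distance_nm = numeric(), zone = character(),
                          abo_relation = character(),
                          classification_index = integer(),
                          stringsAsFactors = FALSE)
    return(new_match_run(donor, entries))
  }
  dist <- sqrt((pool$center_x - donor$hospital_x)^2 +
               (pool$center_y - donor$hospital_y)^2)
  zone <- zone_of(dist)
  rel <- abo_relation(pool$abo, donor$abo)
  ci <- classify(pool$age_years, zone, rel, table)
  # within-cell medical priority: LAS for >= 12, waiting time for children
  key <- ifelse(pool$age_years >= 12, pool$las, pool$waiting_time_days)
  ord <- order(ci, -key, -pool$waiting_time_days, pool$id)
  entries <- data.frame(candidate_id = as.character(pool$id[ord]),
                        policy_rank = seq_along(ord),
                        age_years = pool$age_years[ord],
                        las = pool$las[ord],
                        waiting_time_days = pool$waiting_time_days[ord],
                        distance_nm = dist[ord],
                        zone = zone[ord],
                        abo_relation = rel[ord],
                        classification_index = ci[ord],
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new_match_run(donor, entries)
}

#' Validate match-run invariants
#'
#' Checks rank contiguity (ranks 1..J without gaps or ties), consistency of
#' the recorded zone with the recorded distance, known ABO relation tokens,
#' and (when classification indices are present) that the classification
#' index is non-decreasing with rank.
#'
#' @param run a `match_run`.
#' @param id label used in error messages.
#' @return `run`, invisibly.
#' @export
validate_match_run <- function(run, id = run$donor$id) {
  e <- run$entries
  J <- nrow(e)
  if (J == 0L) return(invisible(run))
  if (!identical(sort(as.integer(e$policy_rank)), seq_len(J))) {
    stop("match run ", id, ": policy ranks are not a gap- and tie-free 1..J")
  }
  if (!all(e$abo_relation %in% ABO_RELATIONS)) {
    stop("match run ", id, ": unknown ABO relation token")
  }
  if (!identical(zone_of(e$distance_nm), as.character(e$zone))) {
    stop("match run ", id, ": zone labels inconsistent with distances")
  }
  e <- e[order(e$policy_rank), ]
  ci <- e$classification_index
  if (!anyNA(ci) && is.unsorted(ci)) {
    stop("match run ", id, ": classification index decreases along the run")
  }
  invisible(run)
}
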