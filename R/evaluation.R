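# Agreement between policy ranks and composite-score ranks: per-run rank
# correlations and their distribution across runs.

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two rankings; equal to the
#' classical tau-a when both rankings are strict.
#'
#' @param ranks_a,ranks_b equal-length numeric rank vectors (length >= 2;
#'   ties allowed).
#' @return tau-b in \[-1, 1\] (`NA` if either vector is constant).
#' @export
kendall_tau <- function(ranks_a, ranks_b) {
  .check_rank_pair(ranks_a, ranks_b)
  stats::cor(ranks_a, ranks_b, method = "kendall")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; for strict rankings this equals the
#' classical 1 - 6 sum(d^2) / (n (n^2 - 1)).
#'
#' @inheritParams kendall_tau
#' @return rho in \[-1, 1\] (`NA` if either vector is constant).
#' @export
spearman_rho <- function(ranks_a, ranks_b) {
  .check_rank_pair(ranks_a, ranks_b)
  stats::cor(ranks_a, ranks_b, method = "spearman")
}

.check_rank_pair <- function(a, b) {
  if (length(a) != length(b)) stop("rank vectors must have equal length")
  if (length(a) < 2L) stop("rank correlation needs at least 2 items")
  if (anyNA(a) || anyNA(b)) stop("rank vectors must not contain NA")
  invisible(NULL)
}

#' Summarize score-vs-policy rank agreement across match runs
#'
#' Scores each run with [score_match_run()], computes Kendall's tau-b and
#' Spearman's rho between policy ranks and score ranks, and summarizes both
#' metrics across runs (mean, minimum, 25th/50th/75th percentile, maximum;
#' percentiles by linear interpolation between order statistics).  Runs with
#' fewer than `min_candidates` ranked candidates are excluded, mirroring the
#' published evaluation's >= 10-candidate filter.
#'
#' @param runs list of `match_run` objects.
#' @param beta a `coefficient_set`.
#' @param min_candidates minimum run length to evaluate (default 10).
#' @param rounding optional coefficient rounding for scoring.
#' @return a `performance_summary`: list with `model_kind`,
#'   `n_runs_evaluated`, a `metrics` data frame (one row per metric with the
#'   six summary statistics) and a `per_run` data frame
#'   (`match_id`, `n_candidates`, `kendall`, `spearman`).
#' @export
summarize_performance <- function(runs, beta, min_candidates = 10L,
                                  rounding = NULL) {
  if (inherits(runs, "match_run")) runs <- list(runs)
  sizes <- vapply(runs, function(r) nrow(r$entries), integer(1))
  keep <- sizes >= min_candidates
  if (!any(keep)) {
    stop("no match runs with at least ", min_candidates, " candidates")
  }
  ids <- names(runs)
  if (is.null(ids)) ids <- sprintf("run%04d", seq_along(runs))
  per_run <- do.call(rbind, lapply(which(keep), function(i) {
    s <- score_match_run(runs[[i]], beta, rounding = rounding)
    data.frame(match_id = ids[i], n_candidates = sizes[i],
               kendall = kendall_tau(s$policy_rank, s$score_rank),
               spearman = spearman_rho(s$policy_rank, s$score_rank),
               stringsAsFactors = FALSE)
  }))
  rownames(per_run) <- NULL
  summarize_metric <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(mean = mean(x), minimum = min(x), p25 = q[1], p50 = q[2], p75 = q[3],
      maximum = max(x))
  }
  metrics <- rbind(kendall = summarize_metric(per_run$kendall),
                   spearman = summarize_metric(per_run$spearman))
  metrics <- data.frame(metric = rownames(metrics), metrics,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model_kind = beta$model_kind,
                 n_runs_evaluated = sum(keep),
                 metrics = metrics, per_run = per_run),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> %s-donor model, %d runs evaluated\n",
              x$model_kind, x$n_runs_evaluated))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-candidate policy-vs-score comparison table
#'
#' One row per ranked candidate, sorted by policy rank, with the rank the
#' candidate would have received under the composite score; the
#' (`policy_rank`, `score_rank`) pairs are directly plottable as a
#' rank-vs-rank scatter.
#'
#' @param run a `match_run`.
#' @param scored output of [score_match_run()] for the same run; computed if
#'   omitted.
#' @param beta coefficient set used when `scored` is omitted.
#' @return data frame with columns `policy_rank`, `score_rank`,
#'   `composite_score`, `las`, `distance_nm`, `abo_relation`, `age_bracket`.
#' @export
export_comparison <- function(run, scored = NULL, beta = NULL) {
  if (is.null(scored)) {
    if (is.null(beta)) stop("supply either a scored table or a beta")
    scored <- score_match_run(run, beta)
  }
  e <- run$entries
  if (!identical(as.character(scored$candidate_id),
                 as.character(e$candidate_id))) {
    stop("scored table does not match the run's candidates")
  }
  out <- data.frame(policy_rank = e$policy_rank,
                    score_rank = scored$score_rank,
                    composite_score = scored$composite_score,
                    las = e$las,
                    distance_nm = e$distance_nm,
                    abo_relation = e$abo_relation,
                    age_bracket = .age_bracket_of(e$age_years),
                    stringsAsFactors = FALSE)
  out <- out[order(out$policy_rank), ]
  rownames(out) <- NULL
  out
}
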