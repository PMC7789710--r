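# Readers and writers (CSV match runs, JSON coefficient sets and policy
# tables) and the end-to-end pipeline driver.

MATCH_RUN_COLUMNS <- c("match_id", "donor_id", "candidate_id", "policy_rank",
                       "age_years", "las", "waiting_time_days",
                       "distance_nm", "zone", "abo_relation",
                       "classification_index")

#' Write match runs to CSV
#'
#' Flattens a list of match runs into one UTF-8, comma-separated file with
#' header `match_id,donor_id,candidate_id,policy_rank,age_years,las,`
#' `waiting_time_days,distance_nm,zone,abo_relation,classification_index`.
#' Reals are written with full double precision so the file round-trips.
#'
#' @param runs named list of `match_run` objects (names become `match_id`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_match_runs <- function(runs, path) {
  if (inherits(runs, "match_run")) runs <- list(runs)
  ids <- names(runs)
  if (is.null(ids)) ids <- sprintf("M%04d", seq_along(runs))
  rows <- do.call(rbind, lapply(seq_along(runs), function(i) {
    e <- runs[[i]]$entries
    if (nrow(e) == 0L) return(NULL)
    cbind(data.frame(match_id = ids[i], donor_id = runs[[i]]$donor$id,
                     stringsAsFactors = FALSE),
          e)
  }))
  rows <- rows[, MATCH_RUN_COLUMNS]
  num <- vapply(rows, is.double, logical(1))
  rows[num] <- lapply(rows[num], format, digits = 17, trim = TRUE)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate match runs from CSV
#'
#' Reads a file written by [write_match_runs()] (or any file with that
#' schema), reconstructs one `match_run` per `match_id`, and validates the
#' invariants: contiguous tie-free ranks, zone labels consistent with
#' distances, known ABO tokens, and non-decreasing classification indices.
#' Donor attributes beyond the id are not part of the schema and are not
#' reconstructed.
#'
#' @param path CSV file path.
#' @return named list of `match_run` objects.
#' @export
read_match_runs <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MATCH_RUN_COLUMNS, names(raw))
  if (length(missing)) {
    stop("match-run file lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("match_id", "donor_id", "candidate_id", "zone")) {
    raw[[col]] <- as.character(raw[[col]])
  }
  raw$policy_rank <- as.integer(raw$policy_rank)
  runs <- lapply(split(raw, raw$match_id), function(block) {
    block <- block[order(block$policy_rank), ]
    entries <- block[, setdiff(MATCH_RUN_COLUMNS, c("match_id", "donor_id"))]
    rownames(entries) <- NULL
    run <- new_match_run(list(id = block$donor_id[1]), entries)
    validate_match_run(run, id = block$match_id[1])
    run
  })
  runs[unique(raw$match_id)]
}

#' Write a coefficient set to JSON
#'
#' @param coefs a `coefficient_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coefs, path) {
  payload <- list(model_kind = coefs$model_kind,
                  beta = as.list(coefs$beta),
                  se = if (!is.null(coefs$se)) as.list(coefs$se),
                  log_likelihood = coefs$log_likelihood,
                  converged = coefs$converged,
                  n_match_runs = coefs$n_match_runs,
                  n_rows = coefs$n_rows)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a coefficient set from JSON
#'
#' @param path file written by [write_coefficients()].
#' @return a `coefficient_set`.
#' @export
read_coefficients <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefficient_set(payload$model_kind, unlist(payload$beta),
                  se = if (!is.null(payload$se)) unlist(payload$se),
                  log_likelihood = payload$log_likelihood %||% NA_real_,
                  converged = payload$converged %||% NA,
                  n_match_runs = payload$n_match_runs %||% NA_integer_,
                  n_rows = payload$n_rows %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write a policy table as JSON
#'
#' The file is an ordered JSON array of objects with fields `zone`
#' (`"A"`--`"F"`), `age_bracket` (`"under12"`, `"12plus"`, `"adolescent"`,
#' `"adult"`), and `abo` (`"identical"`, `"compatible"`, `"incompatible"`);
#' array order is priority order.
#'
#' @param table a `policy_table`.
#' @param path file path.
#' @return `write_policy_table`: `path` invisibly; `read_policy_table`: a
#'   validated `policy_table`.
#' @export
write_policy_table <- function(table, path) {
  jsonlite::write_json(as.data.frame(table), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_policy_table
#' @export
read_policy_table <- function(path) {
  cells <- jsonlite::read_json(path, simplifyVector = TRUE)
  table <- new_policy_table(as.data.frame(cells, stringsAsFactors = FALSE))
  validate_policy_table(table)
  table
}

#' Run the full analysis pipeline
#'
#' simulate -> fit (adult, pediatric) -> score -> evaluate -> report, all
#' deterministic given the config.  Writes, under `out_dir`: the match runs
#' (`match_runs_adult.csv`, `match_runs_pediatric.csv`), fitted coefficient
#' sets (`coefficients_<kind>.json`), per-candidate scores
#' (`scores_<kind>.csv`), agreement summaries (`performance_<kind>.json`
#' plus `per_run_<kind>.csv`), importance and exchange-rate reports
#' (`importance_<kind>.csv`, `exchange_rates_<kind>.csv`, computed from the
#' fitted coefficients at the generated sample's observed LAS/distance
#' maxima), and a `manifest.json` with the config echo, seed, and MD5
#' digests of every output.  A donor mix without pediatric donors skips the
#' pediatric stages with a message.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param min_candidates evaluation filter (see [summarize_performance()]).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, min_candidates = 10L) {
  validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- generate_match_runs(config)
  is_adult <- vapply(runs, function(r) r$donor$age_years >= 18, logical(1))
  outputs <- character()
  emit <- function(name) {
    outputs[[length(outputs) + 1L]] <<- file.path(out_dir, name)
    file.path(out_dir, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (kind in c("adult", "pediatric")) {
    sub <- runs[if (kind == "adult") is_adult else !is_adult]
    if (!length(sub)) {
      message("no ", kind, " donors in this cohort; skipping ", kind,
              " stages")
      next
    }
    stage(paste0("simulate/", kind),
          write_match_runs(sub, emit(sprintf("match_runs_%s.csv", kind))))
    fit <- stage(paste0("fit/", kind), rol_fit(sub, kind))
    stage(paste0("fit/", kind),
          write_coefficients(fit, emit(sprintf("coefficients_%s.json",
                                               kind))))
    scored <- stage(paste0("score/", kind), do.call(rbind, lapply(
      names(sub), function(id) {
        cbind(match_id = id, score_match_run(sub[[id]], fit))
      })))
    utils::write.csv(scored, emit(sprintf("scores_%s.csv", kind)),
                     row.names = FALSE)
    perf <- stage(paste0("evaluate/", kind),
                  summarize_performance(sub, fit,
                                        min_candidates = min_candidates))
    jsonlite::write_json(list(model_kind = perf$model_kind,
                              n_runs_evaluated = perf$n_runs_evaluated,
                              metrics = perf$metrics),
                         emit(sprintf("performance_%s.json", kind)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(perf$per_run, emit(sprintf("per_run_%s.csv", kind)),
                     row.names = FALSE)
    entries <- do.call(rbind, lapply(sub, function(r) r$entries))
    ranges <- default_attribute_ranges(
      kind, las_max = max(entries$las, na.rm = TRUE),
      distance_max = max(entries$distance_nm))
    stage(paste0("report/", kind), {
      utils::write.csv(attribute_importance(fit, ranges, rounding = NULL),
                       emit(sprintf("importance_%s.csv", kind)),
                       row.names = FALSE)
      utils::write.csv(exchange_rate_table(fit, rounding = NULL),
                       emit(sprintf("exchange_rates_%s.csv", kind)),
                       row.names = FALSE)
    })
  }
  manifest <- list(
    tool = paste0("lungmatch ",
                  as.character(utils::packageVersion("lungmatch"))),
    seed = config$seed,
    config = unclass(config),
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(f) unname(tools::md5sum(f))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
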