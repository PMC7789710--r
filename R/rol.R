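# Rank-ordered (exploded) logit estimation.  The latent priority of
# candidate j in a run is u_j = v_j + e_j with v_j = x_j' beta and e_j iid
# standard Gumbel; the probability of an observed strict ranking is the
# Plackett-Luce product of sequential softmax choices over the remaining
# candidates.  The log-likelihood for one run of length J is
#   sum_{j=1}^{J-1} [ v_(j) - logsumexp(v_(j), ..., v_(J)) ]
# with (j) indexing candidates in rank order.

MODEL_COVARIATES <- list(
  adult = c("las", "child", "distance", "abo_identical"),
  pediatric = c("las", "child", "adolescent", "distance", "abo_identical"))

#' Encode model covariates for ranked candidates
#'
#' Implements the covariate coding of the adult- and pediatric-donor models:
#' `las` is the candidate's lung allocation score for ages 12+ and 0 for
#' children; `child` is a dummy for age < 12; `adolescent` (pediatric model
#' only) a dummy for ages 12--17; `distance` is the donor-hospital distance
#' in NM; `abo_identical` is effects-coded, +1 for an identical blood type
#' and -1 for a compatible or (intended) incompatible one.
#'
#' @param entries data frame with columns `age_years`, `las`, `distance_nm`,
#'   `abo_relation`.
#' @param model_kind `"adult"` or `"pediatric"`.
#' @return numeric matrix, one row per entry, columns
#'   `r paste(MODEL_COVARIATES$pediatric, collapse = ", ")` as applicable.
#' @export
encode_covariates <- function(entries, model_kind = c("adult", "pediatric")) {
  model_kind <- match.arg(model_kind)
  age <- entries$age_years
  child <- as.numeric(age < 12)
  las <- ifelse(child == 1, 0, entries$las)
  if (anyNA(las)) stop("candidates aged 12+ must carry a LAS")
  if (!all(entries$abo_relation %in% ABO_RELATIONS)) {
    stop("unknown ABO relation token")
  }
  x <- cbind(las = las,
             child = child,
             adolescent = as.numeric(age >= 12 & age < 18),
             distance = entries$distance_nm,
             abo_identical = ifelse(entries$abo_relation == "identical",
                                    1, -1))
  x[, MODEL_COVARIATES[[model_kind]], drop = FALSE]
}

#' Construct a coefficient set
#'
#' @param model_kind `"adult"` or `"pediatric"`.
#' @param beta named numeric vector of coefficients (names as in
#'   [encode_covariates()]).
#' @param se optional named standard errors.
#' @param log_likelihood log-likelihood at `beta`, if known.
#' @param converged logical convergence flag.
#' @param n_match_runs,n_rows data dimensions behind the estimates.
#' @return a `coefficient_set` list.
#' @export
coefficient_set <- function(model_kind, beta, se = NULL,
                            log_likelihood = NA_real_, converged = NA,
                            n_match_runs = NA_integer_,
                            n_rows = NA_integer_) {
  wanted <- MODEL_COVARIATES[[match.arg(model_kind,
                                        names(MODEL_COVARIATES))]]
  if (!setequal(names(beta), wanted)) {
    stop("beta for a ", model_kind, " model must name exactly: ",
         paste(wanted, collapse = ", "))
  }
  structure(list(model_kind = model_kind, beta = beta[wanted],
                 se = if (!is.null(se)) se[wanted],
                 log_likelihood = log_likelihood, converged = converged,
                 n_match_runs = n_match_runs, n_rows = n_rows),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s-donor rank-ordered logit\n",
              x$model_kind))
  tab <- data.frame(coefficient = names(x$beta), estimate = unname(x$beta))
  if (!is.null(x$se)) tab$se <- unname(x$se)
  print(tab, row.names = FALSE)
  if (is.finite(x$log_likelihood)) {
    cat(sprintf("log-likelihood %.4f on %s runs (%s rows); converged: %s\n",
                x$log_likelihood, x$n_match_runs, x$n_rows, x$converged))
  }
  invisible(x)
}

#' Reference composite-score coefficients (2018 revealed-preference fits)
#'
#' Point estimates of the adult- and pediatric-donor rank-ordered logit
#' models reported from the 2018 U.S. lung match-run analysis, rounded to
#' three decimals as printed.  Used for worked examples and as fixed weights
#' in scoring; standard errors are not reproduced.
#'
#' @param model_kind `"adult"` or `"pediatric"`.
#' @return a `coefficient_set`.
#' @examples
#' reference_coefficients("adult")$beta
#' @export
reference_coefficients <- function(model_kind = c("adult", "pediatric")) {
  model_kind <- match.arg(model_kind)
  beta <- switch(model_kind,
    adult = c(las = 0.040, child = -1.601, distance = -0.007,
              abo_identical = 1.008),
    pediatric = c(las = 0.038, child = 1.946, adolescent = 1.928,
                  distance = -0.007, abo_identical = 0.978))
  coefficient_set(model_kind, beta, converged = TRUE)
}

# Per-run design matrices in rank order; runs with J < 2 are dropped with a
# warning (they carry no ranking information).
prepare_rol_data <- function(runs, model_kind) {
  if (inherits(runs, "match_run")) runs <- list(runs)
  xs <- vector("list", length(runs))
  short <- 0L
  for (i in seq_along(runs)) {
    e <- runs[[i]]$entries
    if (nrow(e) < 2L) { short <- short + 1L; next }
    if (anyDuplicated(e$policy_rank)) {
      stop("tied policy ranks in a match run; the exploded logit requires ",
           "strict orders")
    }
    e <- e[order(e$policy_rank), , drop = FALSE]
    xs[[i]] <- encode_covariates(e, model_kind)
  }
  if (short > 0L) {
    warning(short, " run(s) with fewer than 2 candidates contribute no ",
            "likelihood terms and were dropped")
  }
  xs <- xs[!vapply(xs, is.null, logical(1))]
  if (!length(xs)) stop("no match runs with at least 2 candidates")
  list(xs = xs, n_runs = length(xs),
       n_rows = sum(vapply(xs, nrow, integer(1))))
}

# Suffix logsumexp L_j = log sum_{k >= j} exp(v_k).  Fast vectorized path
# under a global shift; exact sequential path when the spread of v is large
# enough that a single shift could underflow intermediate terms.
.suffix_lse <- function(v) {
  m <- max(v)
  if (m - min(v) < 600) {
    m + log(rev(cumsum(rev(exp(v - m)))))
  } else {
    J <- length(v)
    L <- numeric(J)
    L[J] <- v[J]
    for (j in (J - 1L):1L) {
      a <- max(v[j], L[j + 1L])
      L[j] <- a + log(exp(v[j] - a) + exp(L[j + 1L] - a))
    }
    L
  }
}

# log of the running sum S_m = sum_{j <= m} exp(-L_j), m = 1..J-1
.cum_lse_neg <- function(L1) {
  c <- -L1
  m <- max(c)
  if (m - min(c) < 600) {
    m + log(cumsum(exp(c - m)))
  } else {
    out <- numeric(length(c))
    out[1] <- c[1]
    for (j in seq_along(c)[-1]) {
      a <- max(out[j - 1L], c[j])
      out[j] <- a + log(exp(out[j - 1L] - a) + exp(c[j] - a))
    }
    out
  }
}

.rol_loglik_run <- function(x, beta) {
  v <- drop(x %*% beta)
  J <- length(v)
  L <- .suffix_lse(v)
  sum(v[-J] - L[-J])
}

.rol_gradient_run <- function(x, beta) {
  v <- drop(x %*% beta)
  J <- length(v)
  L <- .suffix_lse(v)
  logS <- .cum_lse_neg(L[-J])          # m = 1..J-1
  logS <- c(logS, logS[J - 1L])        # candidate J appears in sets 1..J-1
  a <- exp(v + logS)                   # sum_j p_{m|j} over sets containing m
  colSums(x[-J, , drop = FALSE]) - drop(crossprod(x, a))
}

#' Rank-ordered logit log-likelihood
#'
#' Evaluates the exploded-logit log-likelihood of policy-ranked match runs
#' at a coefficient vector, using one backward suffix-logsumexp pass per run
#' (O(J) per run, numerically stable).  Runs with fewer than two candidates
#' contribute zero.
#'
#' @param beta a `coefficient_set` or a named numeric vector.
#' @param runs a `match_run` or list of them.
#' @param model_kind model whose covariate coding to use; taken from `beta`
#'   when it is a `coefficient_set`.
#' @return the log-likelihood (a non-positive number).
#' @export
rol_loglik <- function(beta, runs, model_kind = NULL) {
  b <- .beta_vector(beta, model_kind)
  data <- prepare_rol_data(runs, attr(b, "model_kind"))
  sum(vapply(data$xs, .rol_loglik_run, numeric(1), beta = b))
}

#' Analytic gradient of the rank-ordered logit log-likelihood
#'
#' @inheritParams rol_loglik
#' @return named numeric gradient vector (same order as the coefficients).
#' @export
rol_gradient <- function(beta, runs, model_kind = NULL) {
  b <- .beta_vector(beta, model_kind)
  data <- prepare_rol_data(runs, attr(b, "model_kind"))
  g <- Reduce(`+`, lapply(data$xs, .rol_gradient_run, beta = b))
  stats::setNames(g, names(b))
}

.beta_vector <- function(beta, model_kind) {
  if (inherits(beta, "coefficient_set")) {
    b <- beta$beta
    model_kind <- beta$model_kind
  } else {
    b <- beta
    if (is.null(model_kind)) {
      model_kind <- if (setequal(names(b), MODEL_COVARIATES$pediatric))
        "pediatric" else "adult"
    }
  }
  wanted <- MODEL_COVARIATES[[model_kind]]
  if (!setequal(names(b), wanted)) {
    stop("coefficient names must be exactly: ", paste(wanted, collapse = ", "))
  }
  structure(b[wanted], model_kind = model_kind)
}

.fd_hessian <- function(beta, grad_fn) {
  p <- length(beta)
  H <- matrix(0, p, p)
  for (k in seq_len(p)) {
    h <- 1e-5 * max(1, abs(beta[k]))
    bp <- beta; bp[k] <- bp[k] + h
    bm <- beta; bm[k] <- bm[k] - h
    H[, k] <- (grad_fn(bp) - grad_fn(bm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a rank-ordered logit model by maximum likelihood
#'
#' Maximizes the exploded-logit likelihood with the analytic gradient from a
#' zero start.  Covariate columns are root-mean-square-scaled internally for
#' conditioning; optimization is BFGS followed by Newton polishing with a
#' central-difference Hessian.  Convergence requires the scaled-gradient
#' infinity norm below `grad_tol` and a relative log-likelihood change below
#' `loglik_reltol`.  Standard errors are the square roots of the diagonal of
#' the inverse observed information (central-difference Hessian of the
#' analytic gradient, step `1e-5 * max(1, |beta_k|)`).
#'
#' @param runs list of `match_run` objects (strict policy ranks; ties are an
#'   error).
#' @param model_kind `"adult"` or `"pediatric"`.
#' @param grad_tol,loglik_reltol convergence tolerances.
#' @param max_iter Newton-polish iteration cap (after BFGS).
#' @param max_abs_beta flag threshold for likelihood drift: any fitted
#'   |beta| above it marks the fit as suspect (separation-like monotone
#'   likelihood), reported via `converged = FALSE` and a warning.
#' @param ridge optional L2 penalty (per-coefficient, on the original
#'   scale) to stabilize drifting fits; 0 disables it.
#' @return a `coefficient_set` (also of class `rol_fit`) with estimates,
#'   standard errors, log-likelihood, convergence flag and data dimensions.
#' @examples
#' \donttest{
#' cfg <- cohort_config(seed = 7, n_candidates = 40, n_donors = 20)
#' runs <- generate_match_runs(cfg)
#' adult <- Filter(function(r) r$donor$age_years >= 18, runs)
#' fit <- rol_fit(adult, "adult")
#' fit$beta
#' }
#' @export
rol_fit <- function(runs, model_kind = c("adult", "pediatric"),
                    grad_tol = 1e-6, loglik_reltol = 1e-10,
                    max_iter = 50L, max_abs_beta = 50, ridge = 0) {
  model_kind <- match.arg(model_kind)
  data <- prepare_rol_data(runs, model_kind)
  pooled <- do.call(rbind, data$xs)
  qrx <- qr(pooled)
  if (qrx$rank < ncol(pooled)) {
    bad <- colnames(pooled)[qrx$pivot[(qrx$rank + 1L):ncol(pooled)]]
    stop("collinear design: covariate(s) ", paste(bad, collapse = ", "),
         " carry no independent variation")
  }
  scale <- pmax(sqrt(colMeans(pooled^2)), 1e-8)
  xs_scaled <- lapply(data$xs, function(x) sweep(x, 2, scale, `/`))
  p <- ncol(pooled)

  ll <- function(b) {
    sum(vapply(xs_scaled, .rol_loglik_run, numeric(1), beta = b)) -
      0.5 * ridge * sum((b / scale)^2)
  }
  gr <- function(b) {
    Reduce(`+`, lapply(xs_scaled, .rol_gradient_run, beta = b)) -
      ridge * b / scale^2
  }

  opt <- stats::optim(rep(0, p), fn = function(b) -ll(b),
                      gr = function(b) -gr(b), method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  b <- opt$par
  value <- ll(b)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- gr(b)
    H <- .fd_hessian(b, gr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    b_new <- b - step
    value_new <- ll(b_new)
    # halve the step if the polish overshoots
    halvings <- 0L
    while (value_new < value && halvings < 20L) {
      step <- step / 2
      b_new <- b - step
      value_new <- ll(b_new)
      halvings <- halvings + 1L
    }
    rel_change <- abs(value_new - value) / max(1, abs(value_new))
    b <- b_new
    value <- value_new
    if (max(abs(gr(b))) < grad_tol && rel_change < loglik_reltol) {
      converged <- TRUE
      break
    }
  }
  beta <- stats::setNames(b / scale, colnames(pooled))
  if (any(abs(beta) > max_abs_beta)) {
    warning("coefficient magnitude exceeds ", max_abs_beta,
            "; monotone-likelihood drift suspected (consider ridge > 0)")
    converged <- FALSE
  }
  se <- rep(NA_real_, p)
  if (converged) {
    grad_unscaled <- function(bu) {
      Reduce(`+`, lapply(data$xs, .rol_gradient_run, beta = bu)) -
        ridge * bu
    }
    H <- .fd_hessian(beta, grad_unscaled)
    info <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(info) && all(diag(info) > 0)) se <- sqrt(diag(info))
  }
  out <- coefficient_set(model_kind, beta,
                         se = stats::setNames(se, names(beta)),
                         log_likelihood =
                           sum(vapply(data$xs, .rol_loglik_run, numeric(1),
                                      beta = beta)),
                         converged = converged,
                         n_match_runs = data$n_runs, n_rows = data$n_rows)
  out$gradient_inf_norm <- max(abs(gr(b)))
  class(out) <- c("rol_fit", class(out))
  out
}
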