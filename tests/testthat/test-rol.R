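adult_zero <- coefficient_set("adult", c(las = 0, child = 0, distance = 0,
                                         abo_identical = 0))

test_that("covariate encoding follows the model coding rules", {
  x <- encode_covariates(data.frame(age_years = 45, las = 50,
                                    distance_nm = 200,
                                    abo_relation = "identical"), "adult")
  expect_equal(drop(x), c(las = 50, child = 0, distance = 200,
                          abo_identical = 1))
  x <- encode_covariates(data.frame(age_years = 7, las = NA,
                                    distance_nm = 300,
                                    abo_relation = "compatible"), "adult")
  expect_equal(drop(x), c(las = 0, child = 1, distance = 300,
                          abo_identical = -1))
  x <- encode_covariates(data.frame(age_years = 15, las = 33,
                                    distance_nm = 100,
                                    abo_relation = "incompatible"),
                         "pediatric")
  expect_equal(drop(x), c(las = 33, child = 0, adolescent = 1,
                          distance = 100, abo_identical = -1))
  # intended-incompatible is coded like compatible: effects code -1
  x <- encode_covariates(data.frame(age_years = 30, las = 10,
                                    distance_nm = 0,
                                    abo_relation = "incompatible"), "adult")
  expect_equal(unname(x[, "abo_identical"]), -1)
  expect_error(encode_covariates(data.frame(age_years = 20, las = NA,
                                            distance_nm = 1,
                                            abo_relation = "identical"),
                                 "adult"), "LAS")
})

test_that("log-likelihood at beta = 0 is -sum log(J!)", {
  set.seed(10)
  for (J in c(2, 4, 17, 50)) {
    run <- random_run(J)
    expect_equal(rol_loglik(adult_zero, run), -lfactorial(J),
                 tolerance = 1e-12)
  }
  # J = 4 spelled out: -log(24)
  expect_equal(rol_loglik(adult_zero, random_run(4)), -log(24),
               tolerance = 1e-12)
  # J = 2 with equal scores is a symmetric two-way choice
  run2 <- make_run(data.frame(age_years = c(30, 40), las = c(50, 50),
                              distance_nm = c(10, 10),
                              abo_relation = c("identical", "identical"),
                              stringsAsFactors = FALSE))
  expect_equal(rol_loglik(adult_zero, run2), log(0.5), tolerance = 1e-12)
})

test_that("log-likelihood is invariant to per-run score shifts", {
  set.seed(11)
  runs <- replicate(5, random_run(sample(3:12, 1)), simplify = FALSE)
  beta <- c(las = 0.03, child = -1.2, distance = -0.004, abo_identical = 0.7)
  base <- rol_loglik(beta, runs)
  expect_lte(base, 0)
  # shifting every candidate's distance in a run by the same amount shifts
  # all v_j by a constant; the exploded logit is location invariant
  shifted <- lapply(runs, function(r) {
    r$entries$distance_nm <- r$entries$distance_nm + 500
    r
  })
  expect_equal(rol_loglik(beta, shifted), base, tolerance = 1e-9)
})

test_that("analytic gradient matches hand and finite-difference oracles", {
  # two candidates at beta = 0: gradient is half the covariate difference
  run2 <- make_run(data.frame(age_years = c(30, 44), las = c(60, 20),
                              distance_nm = c(100, 700),
                              abo_relation = c("identical", "compatible"),
                              stringsAsFactors = FALSE))
  x <- encode_covariates(run2$entries, "adult")
  d <- x[1, ] - x[2, ]
  expect_equal(rol_gradient(adult_zero, run2), d / 2, tolerance = 1e-12)
  # symmetric pool: all covariates equal, gradient vanishes
  sym <- make_run(data.frame(age_years = rep(30, 4), las = rep(50, 4),
                             distance_nm = rep(100, 4),
                             abo_relation = rep("identical", 4),
                             stringsAsFactors = FALSE))
  expect_equal(max(abs(rol_gradient(adult_zero, sym))), 0)
  # central finite differences on random instances; distances are held in
  # thousands of NM so every coordinate has comparable curvature and the
  # difference quotient is itself accurate to ~1e-9
  set.seed(12)
  for (rep in 1:5) {
    runs <- replicate(3, random_run(sample(3:20, 1)), simplify = FALSE)
    runs <- lapply(runs, function(r) {
      r$entries$distance_nm <- r$entries$distance_nm / 1000
      r
    })
    beta <- c(las = rnorm(1, 0, 0.05), child = rnorm(1),
              distance = rnorm(1, 0, 1), abo_identical = rnorm(1))
    g <- rol_gradient(beta, runs)
    h <- 1e-6 * pmax(1, abs(beta))
    fd <- vapply(seq_along(beta), function(k) {
      bp <- beta; bp[k] <- bp[k] + h[k]
      bm <- beta; bm[k] <- bm[k] - h[k]
      (rol_loglik(bp, runs, "adult") - rol_loglik(bm, runs, "adult")) /
        (2 * h[k])
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-2)), 1e-6)
  }
})

test_that("first-place terms reduce to a conditional-logit softmax", {
  set.seed(13)
  run <- random_run(5)
  beta <- c(las = 0.05, child = -1, distance = -0.002, abo_identical = 0.4)
  x <- encode_covariates(run$entries[order(run$entries$policy_rank), ],
                         "adult")
  v <- drop(x %*% beta)
  # direct product of sequential softmax choices
  direct <- sum(vapply(1:4, function(j) {
    v[j] - log(sum(exp(v[j:5])))
  }, numeric(1)))
  expect_equal(rol_loglik(beta, run, "adult"), direct, tolerance = 1e-10)
})

test_that("degenerate runs are handled: J < 2 warns, ties are rejected", {
  single <- make_run(data.frame(age_years = 30, las = 50, distance_nm = 10,
                                abo_relation = "identical",
                                stringsAsFactors = FALSE))
  ok <- random_run(4)
  expect_warning(ll <- rol_loglik(adult_zero, list(single, ok)),
                 "fewer than 2")
  expect_equal(ll, suppressWarnings(rol_loglik(adult_zero, ok)))
  tied <- random_run(3)
  tied$entries$policy_rank <- c(1L, 1L, 2L)
  expect_error(rol_loglik(adult_zero, tied), "tie")
})

test_that("fitting recovers the generating coefficients", {
  true <- coefficient_set("adult", c(las = 0.04, child = -1.6,
                                     distance = -0.007,
                                     abo_identical = 1.0))
  set.seed(14)
  cfg <- cohort_config(seed = 14, n_candidates = 50, n_donors = 1)
  runs <- lapply(1:200, function(i) {
    pool <- generate_pool(cfg, seed = NULL)
    donor <- as.list(generate_donors(cfg, seed = NULL)[1, ])
    sample_from_rol(true, pool, donor)
  })
  fit <- rol_fit(runs, "adult")
  expect_true(fit$converged)
  expect_lte(fit$log_likelihood, 0)
  expect_true(all(abs(fit$beta - true$beta) < 3 * fit$se))
  # doubling the data leaves estimates put and shrinks SEs by ~1/sqrt(2)
  fit2 <- rol_fit(c(runs, runs), "adult")
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-4)
  expect_equal(unname(fit2$se / fit$se), rep(1 / sqrt(2), 4),
               tolerance = 0.02)
  expect_identical(fit2$n_match_runs, 400L)
})

test_that("rescaling distance rescales its coefficient, not the ranking", {
  set.seed(15)
  true <- coefficient_set("adult", c(las = 0.04, child = -1.6,
                                     distance = -0.007,
                                     abo_identical = 1.0))
  cfg <- cohort_config(seed = 15, n_candidates = 30, n_donors = 1)
  runs <- lapply(1:60, function(i) {
    pool <- generate_pool(cfg, seed = NULL)
    donor <- as.list(generate_donors(cfg, seed = NULL)[1, ])
    sample_from_rol(true, pool, donor)
  })
  fit_nm <- rol_fit(runs, "adult")
  runs_h <- lapply(runs, function(r) {
    r$entries$distance_nm <- r$entries$distance_nm / 100
    r
  })
  fit_h <- rol_fit(runs_h, "adult")
  expect_equal(fit_h$beta[["distance"]], 100 * fit_nm$beta[["distance"]],
               tolerance = 1e-4)
  expect_equal(fit_h$beta[c("las", "child", "abo_identical")],
               fit_nm$beta[c("las", "child", "abo_identical")],
               tolerance = 1e-4)
  s1 <- score_match_run(runs[[1]], fit_nm)
  r1h <- runs_h[[1]]
  s2 <- score_match_run(r1h, fit_h)
  expect_identical(s1$score_rank, s2$score_rank)
})

test_that("a collinear design is rejected by name", {
  set.seed(16)
  runs <- replicate(4, random_run(6, child_prob = 1), simplify = FALSE)
  # every candidate a child: the LAS covariate is identically zero
  expect_error(rol_fit(runs, "adult"), "las")
})
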