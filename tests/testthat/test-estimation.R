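test_that("the 1-state model recovers the pooled Bernoulli proportion", {
  coll <- list(obs_series(c(1, 1, 0, 1, 0), "a"),
               obs_series(c(1, 0, 1, 0, 1), "b"))
  fit <- fit_hmm(coll, model_spec(1), fit_options(n_restarts = 2, seed = 1))
  expect_equal(fit$params$pis, 0.6, tolerance = 1e-6)
  expect_equal(fit$p, 1L)
  expect_equal(fit$aic, 2 * fit$nllk + 2, tolerance = 1e-9)
})

test_that("the fitted optimum dominates the generating truth", {
  truth <- printed_baseline()
  coll <- simulate_collection(generator_config(n_sessions = 60, seed = 8))
  spec <- model_spec(2)
  fit <- fit_hmm(coll, spec, fit_options(n_restarts = 4, seed = 5))
  expect_lte(fit$nllk, -joint_log_likelihood(coll, truth, spec) + 1e-8)
  # reported nllk is reproducible from the reported estimates
  expect_equal(fit$nllk, -joint_log_likelihood(coll, fit$params, spec),
               tolerance = 1e-9)
  # label convention: state 1 dominantly affective
  expect_lt(fit$params$pis[1], fit$params$pis[2])
})

test_that("fits are deterministic under a seed and stable to session order", {
  coll <- simulate_collection(generator_config(n_sessions = 80,
                                               lengths = 12, seed = 12))
  opts <- fit_options(n_restarts = 3, seed = 99)
  f1 <- fit_hmm(coll, model_spec(2), opts)
  f2 <- fit_hmm(coll, model_spec(2), opts)
  expect_identical(f1$working, f2$working)
  expect_identical(f1$nllk, f2$nllk)
  f3 <- fit_hmm(rev(coll), model_spec(2), opts)
  expect_equal(f3$nllk, f1$nllk, tolerance = 1e-8)
  expect_equal(f3$params$pis, f1$params$pis, tolerance = 1e-4)
  expect_equal(f3$params$Gamma, f1$params$Gamma, tolerance = 1e-4)
})

test_that("Wald intervals are symmetric for beta and interior for probabilities", {
  spec <- model_spec(2, covariates = "log_dopr")
  coll <- simulate_collection(generator_config(
    n_sessions = 150, lengths = 12, spec = spec,
    params = list(pis = c(0.25, 0.75),
                  beta = matrix(c(-0.5, -0.4, -1, -0.3), 2, byrow = TRUE),
                  delta = c(0.4, 0.6)),
    seed = 4))
  fit <- fit_hmm(coll, spec, fit_options(n_restarts = 3, seed = 7))
  ci <- fit$ci
  b <- ci[ci$type == "identity", ]
  expect_true(all(abs((b$upper - b$estimate) - (b$estimate - b$lower))
                  < 1e-9, na.rm = TRUE))
  pr <- ci[ci$type == "prob", ]
  expect_true(all(pr$lower > 0 & pr$upper < 1))
  expect_true(all(ci$lower <= ci$estimate + 1e-12 &
                  ci$estimate <= ci$upper + 1e-12, na.rm = TRUE))
  # confidence_intervals() reproduces the stored table
  expect_equal(confidence_intervals(fit), fit$ci)
})

test_that("estimation error shrinks with the amount of data", {
  truth <- printed_baseline()
  err <- sapply(c(40, 400), function(ns) {
    coll <- simulate_collection(generator_config(
      n_sessions = ns, lengths = 15, seed = 21))
    fit <- suppressWarnings(
      fit_hmm(coll, model_spec(2), fit_options(n_restarts = 3, seed = 2)))
    max(abs(c(fit$params$pis - truth$pis,
              fit$params$Gamma - truth$Gamma)))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("degenerate all-identical data is flagged as boundary-adjacent", {
  coll <- list(obs_series(rep(1, 12), "a"), obs_series(rep(1, 9), "b"))
  expect_warning(
    fit <- fit_hmm(coll, model_spec(1), fit_options(n_restarts = 2, seed = 3)),
    "boundary|degenerate")
  expect_gt(fit$params$pis, 0.99)
})

test_that("covariate models warm-started from the baseline dominate it", {
  coll <- simulate_collection(generator_config(n_sessions = 44, seed = 31))
  opts <- fit_options(n_restarts = 3, seed = 17)
  base <- fit_hmm(coll, model_spec(2), opts)
  d0 <- stationary_distribution(base$params$Gamma)
  for (covs in list("response_type", "log_dopr",
                    c("response_type", "log_dopr"))) {
    spec_c <- model_spec(2, covariates = covs)
    k <- length(covs)
    warm <- list(
      beta = cbind(qlogis(c(base$params$Gamma[1, 2],
                            base$params$Gamma[2, 1])),
                   matrix(0, 2, k)),
      pis = base$params$pis, delta = d0)
    fc <- fit_hmm(coll, spec_c, opts, starts = list(warm))
    expect_lte(fc$nllk, base$nllk + 1e-6)
  }
})
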