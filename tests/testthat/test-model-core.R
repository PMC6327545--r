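test_that("stationary distribution solves the defining linear system", {
  expect_equal(stationary_distribution(matrix(0.5, 2, 2)), c(0.5, 0.5))

  # published baseline transition estimates, checked against an
  # independent eigenvector computation
  G <- printed_baseline()$Gamma
  d <- stationary_distribution(G)
  ev <- eigen(t(G))
  ref <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  ref <- ref / sum(ref)
  expect_equal(d, ref, tolerance = 1e-12)
  expect_equal(d, c(0.169, 0.265) / 0.434, tolerance = 1e-12)

  # absorbing state
  G2 <- matrix(c(1, 0, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(stationary_distribution(G2), c(1, 0))
})

test_that("reducible chains with two closed classes are rejected by name", {
  expect_error(stationary_distribution(diag(2)), "stationary")
  G <- rbind(c(1, 0, 0), c(0, 0.5, 0.5), c(0, 0.5, 0.5))
  expect_error(stationary_distribution(G), "stationary")
  expect_error(stationary_distribution(matrix(c(0.5, 0.6, 0.6, 0.4), 2)),
               "sum to 1")
})

test_that("stationarity invariants hold on random matrices", {
  set.seed(101)
  for (i in 1:300) {
    N <- sample(2:4, 1)
    G <- rand_tpm(N)
    d <- stationary_distribution(G)
    expect_lt(max(abs(drop(d %*% G) - d)), 1e-10)
    expect_equal(sum(d), 1, tolerance = 1e-10)
    if (N == 2)
      expect_equal(d, c(G[2, 1], G[1, 2]) / (G[1, 2] + G[2, 1]),
                   tolerance = 1e-12)
  }
})

test_that("emission matrix is diagonal with the state-conditional pmfs", {
  expect_equal(emission_matrix(c(0.2, 0.8), 1), diag(c(0.2, 0.8)))
  # complements of the published emission estimates
  expect_equal(emission_matrix(c(0.209, 0.782), 0), diag(c(0.791, 0.218)))
  expect_equal(emission_matrix(c(0.5, 0.5), 0), diag(c(0.5, 0.5)))
  expect_error(emission_matrix(c(0.2, 0.8), 2), "0, 1")
  expect_error(emission_matrix(c(0, 0.8), 1), "inside")
})

test_that("model_spec enforces the family's structural constraints", {
  expect_error(model_spec(2, covariates = "log_dopr",
                          initial = "stationary"), "estimated")
  expect_error(model_spec(2, covariates = "speed"), "unknown")
  expect_error(model_spec(2, mixture = TRUE, fixed_effects = TRUE),
               "mixture")
  expect_error(model_spec(3, covariates = "log_dopr"), "2-state")
  expect_identical(model_spec(2, covariates = "log_dopr")$initial,
                   "estimated")
  expect_identical(model_spec(2)$initial, "stationary")
})

test_that("working transform fixes 0.5 at zero and round-trips the printed point", {
  spec <- model_spec(1)
  expect_equal(unname(pack_parameters(list(pis = 0.5), spec)), 0)
  expect_equal(unpack_parameters(0, spec)$pis, 0.5)

  spec2 <- model_spec(2)
  pars <- baseline_params(0.265, 0.169, c(0.209, 0.782))
  w <- pack_parameters(pars, spec2)
  back <- unpack_parameters(w, spec2)
  expect_equal(back$Gamma, pars$Gamma, tolerance = 1e-10)
  expect_equal(back$pis, pars$pis, tolerance = 1e-10)

  expect_error(pack_parameters(list(pis = 1), model_spec(1)), "boundary")
  expect_error(pack_parameters(baseline_params(0, 0.2, c(0.3, 0.7)), spec2),
               "boundary")
})

test_that("pack/unpack is a bijection across the whole model family", {
  set.seed(42)
  specs <- candidate_model_set()
  for (spec in specs) {
    for (rep in 1:40) {
      pars <- reassureHMM:::.random_start(spec)
      w <- pack_parameters(pars, spec)
      expect_length(w, count_parameters(spec))
      back <- unpack_parameters(w, spec)
      w2 <- pack_parameters(back, spec)
      expect_lt(max(abs(w - w2)), 1e-10)
      expect_lt(max(abs(unlist(back[sort(names(back))]) -
                        unlist(pars[sort(names(back))]))), 1e-10)
    }
  }
})

test_that("session_series validates its parallel fields", {
  expect_error(session_series("a", integer(0)), "at least one")
  expect_error(session_series("a", c(0, 2)), "0 .*1|affective")
  expect_error(session_series("a", c(0, 1), durations = c(1, -2)),
               "positive")
  expect_error(session_series("a", c(0, 1), durations = 1), "length")
  expect_error(session_series("a", c(0, 1), clinician_id = 3), "1 or 2")
  s <- session_series("a", c(0, 1, 1), durations = c(2, 3, 4),
                      response_types = c(1, 0, 1),
                      response_durations = c(0, 1, 2), clinician_id = 2)
  expect_s3_class(s, "session_series")
  expect_length(s, 3L)
})
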