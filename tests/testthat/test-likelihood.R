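test_that("degenerate cases reduce to closed-form likelihoods", {
  spec <- model_spec(2)
  # single observation, indistinguishable states
  p <- baseline_params(0.5, 0.5, c(0.5, 0.5))
  expect_equal(session_log_likelihood(obs_series(1), p, spec), log(0.5))

  # emission independent of state: plain Bernoulli product
  p2 <- baseline_params(0.3, 0.2, c(0.6, 0.6))
  expect_equal(session_log_likelihood(obs_series(c(1, 0, 1)), p2, spec),
               log(0.6 * 0.4 * 0.6), tolerance = 1e-12)
})

test_that("forward product matches exhaustive path enumeration", {
  spec <- model_spec(2)
  p <- baseline_params(0.3, 0.2, c(0.2, 0.8))
  d <- stationary_distribution(p$Gamma)
  obs <- c(1, 0, 1)
  expect_equal(session_log_likelihood(obs_series(obs), p, spec),
               bf_loglik(obs, d, p$pis, Gamma = p$Gamma),
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:60) {
    N <- sample(2:3, 1)
    n <- sample(1:10, 1)
    spec_i <- model_spec(N)
    G <- rand_tpm(N)
    pis <- sort(runif(N, 0.05, 0.95))
    obs <- rbinom(n, 1, 0.5)
    d <- stationary_distribution(G)
    ll <- session_log_likelihood(obs_series(obs),
                                 list(Gamma = G, pis = pis), spec_i)
    ref <- bf_loglik(obs, d, pis, Gamma = G)
    expect_equal(ll, ref, tolerance = 1e-10)
    expect_lte(exp(ll), 1)
    expect_gt(exp(ll), 0)
  }
})

test_that("joint log-likelihood is additive and order-invariant", {
  spec <- model_spec(2)
  p <- baseline_params(0.25, 0.15, c(0.3, 0.7))
  s1 <- obs_series(c(1, 0, 1), "a")
  expect_equal(joint_log_likelihood(list(s1), p, spec),
               session_log_likelihood(s1, p, spec))
  expect_equal(joint_log_likelihood(list(s1, s1), p, spec),
               2 * session_log_likelihood(s1, p, spec))
  set.seed(11)
  coll <- lapply(1:5, function(i)
    obs_series(rbinom(sample(3:8, 1), 1, 0.5), paste0("s", i)))
  ll <- joint_log_likelihood(coll, p, spec)
  ref <- sum(vapply(coll, function(s)
    bf_loglik(s$observations, stationary_distribution(p$Gamma), p$pis,
              Gamma = p$Gamma), numeric(1)))
  expect_equal(ll, ref, tolerance = 1e-10)
  expect_equal(joint_log_likelihood(rev(coll), p, spec), ll)
  expect_error(joint_log_likelihood(list(), p, spec), "empty")
})

test_that("zero covariate slopes recover the homogeneous likelihood", {
  spec_cov <- model_spec(2, covariates = "log_dopr")
  spec_base <- model_spec(2, initial = "estimated")
  g12 <- 0.265; g21 <- 0.169
  delta <- c(0.4, 0.6)
  set.seed(3)
  s <- session_series("x", rbinom(12, 1, 0.5),
                      durations = rlnorm(12, 1.5, 0.6))
  p_cov <- list(beta = matrix(c(qlogis(g12), 0, qlogis(g21), 0), 2,
                              byrow = TRUE),
                pis = c(0.2, 0.8), delta = delta)
  p_base <- c(baseline_params(g12, g21, c(0.2, 0.8)), list(delta = delta))
  expect_equal(session_log_likelihood(s, p_cov, spec_cov),
               session_log_likelihood(s, p_base, spec_base),
               tolerance = 1e-12)
})

test_that("non-homogeneous forward matches enumeration with per-step matrices", {
  set.seed(19)
  spec <- model_spec(2, covariates = c("response_type", "log_dopr"))
  for (i in 1:25) {
    n <- sample(2:8, 1)
    s <- session_series("x", rbinom(n, 1, 0.5),
                        durations = rlnorm(n, 1.2, 0.7),
                        response_types = rbinom(n, 1, 0.5))
    B <- cbind(qlogis(runif(2, 0.1, 0.9)),
               matrix(runif(4, -1, 1), 2))
    pis <- sort(runif(2, 0.05, 0.95))
    delta <- rand_simplex(2)
    params <- list(beta = B, pis = pis, delta = delta)
    Z <- build_covariate_rows(s, spec)
    gammas <- lapply(seq_len(n - 1), function(t)
      transition_matrix_at(B, Z[t, ]))
    expect_equal(session_log_likelihood(s, params, spec),
                 bf_loglik(s$observations, delta, pis, gammas = gammas),
                 tolerance = 1e-10)
  }
})

test_that("clinician fixed effects with identical sets equal the pooled model", {
  set.seed(23)
  coll <- lapply(1:6, function(i)
    session_series(paste0("s", i), rbinom(8, 1, 0.5),
                   durations = rlnorm(8, 1.5, 0.5),
                   clinician_id = 1L + (i %% 2)))
  B <- matrix(c(-0.5, -0.3, -1, 0.2), 2, byrow = TRUE)
  spec_fe <- model_spec(2, covariates = "log_dopr", fixed_effects = TRUE)
  spec_pool <- model_spec(2, covariates = "log_dopr")
  p_fe <- list(beta = list(B, B), pis = c(0.3, 0.7),
               delta = list(c(0.4, 0.6), c(0.4, 0.6)))
  p_pool <- list(beta = B, pis = c(0.3, 0.7), delta = c(0.4, 0.6))
  expect_identical(joint_log_likelihood(coll, p_fe, spec_fe),
                   joint_log_likelihood(coll, p_pool, spec_pool))

  # homogeneous fixed-effects baseline likewise
  G <- baseline_params(0.3, 0.2, c(0.3, 0.7))$Gamma
  expect_identical(
    joint_log_likelihood(coll, list(Gamma = list(G, G), pis = c(0.3, 0.7)),
                         model_spec(2, fixed_effects = TRUE)),
    joint_log_likelihood(coll, list(Gamma = G, pis = c(0.3, 0.7)),
                         model_spec(2)))
})
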