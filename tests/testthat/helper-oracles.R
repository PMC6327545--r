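# Independent oracles used across the suite: exhaustive enumeration over
# all N^n latent state paths (likelihood and decoding), plus small random
# generators for property-style tests.

# log-likelihood by summing the joint probability over every state path;
# gammas: either a single matrix (homogeneous) or a list of n-1 matrices
bf_loglik <- function(obs, delta, pis, Gamma = NULL, gammas = NULL) {
  n <- length(obs)
  N <- length(pis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- delta[s[1]] * (if (obs[1] == 1) pis[s[1]] else 1 - pis[s[1]])
    if (n > 1) for (t in 2:n) {
      G <- if (is.null(gammas)) Gamma else gammas[[t - 1]]
      p <- p * G[s[t - 1], s[t]] *
        (if (obs[t] == 1) pis[s[t]] else 1 - pis[s[t]])
    }
    tot <- tot + p
  }
  log(tot)
}

# exhaustive global decoding: the path(s) attaining the maximal joint
# log-probability
bf_viterbi <- function(obs, delta, pis, Gamma = NULL, gammas = NULL) {
  n <- length(obs)
  N <- length(pis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  lp <- apply(paths, 1, function(s) {
    p <- log(delta[s[1]]) +
      log(if (obs[1] == 1) pis[s[1]] else 1 - pis[s[1]])
    if (n > 1) for (t in 2:n) {
      G <- if (is.null(gammas)) Gamma else gammas[[t - 1]]
      p <- p + log(G[s[t - 1], s[t]]) +
        log(if (obs[t] == 1) pis[s[t]] else 1 - pis[s[t]])
    }
    p
  })
  best <- max(lp)
  list(log_score = best,
       paths = paths[lp > best - 1e-12, , drop = FALSE])
}

rand_tpm <- function(N) {
  G <- matrix(runif(N * N, 0.05, 1), N, N)
  G / rowSums(G)
}

rand_simplex <- function(N) {
  d <- runif(N, 0.05, 1)
  d / sum(d)
}

# bare series with only observations (enough for baseline likelihoods)
obs_series <- function(obs, id = "s1", clinician_id = 1L)
  session_series(id, obs, clinician_id = clinician_id)

baseline_params <- function(g12, g21, pis)
  list(Gamma = matrix(c(1 - g12, g12, g21, 1 - g21), 2, byrow = TRUE),
       pis = pis)

# the published baseline point in parameter space, reused by several suites
printed_baseline <- function()
  list(Gamma = matrix(c(0.735, 0.265, 0.169, 0.831), 2, byrow = TRUE),
       pis = c(0.209, 0.782))
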