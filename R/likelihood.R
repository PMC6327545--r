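# Likelihood engine: forward matrix-product evaluation with per-step
# rescaling, for homogeneous and covariate-driven (non-homogeneous) chains.

# resolve the per-session initial distribution, transition structure and
# emission probabilities from a natural-parameter list
.session_ingredients <- function(series, params, spec) {
  N <- spec$n_states
  cid <- series$clinician_id
  if (spec$mixture) {
    return(list(delta = params$delta,
                Gamma = rbind(params$delta, params$delta),
                pis = params$pis, inhom = FALSE))
  }
  if (N == 1L)
    return(list(delta = 1, Gamma = matrix(1, 1, 1), pis = params$pis,
                inhom = FALSE))
  if (length(spec$covariates) == 0L) {
    G <- if (spec$fixed_effects) params$Gamma[[cid]] else params$Gamma
    delta <- if (spec$initial == "stationary") stationary_distribution(G)
             else if (spec$fixed_effects) params$delta[[cid]]
             else params$delta
    return(list(delta = delta, Gamma = G, pis = params$pis, inhom = FALSE))
  }
  B <- if (spec$fixed_effects) params$beta[[cid]] else params$beta
  delta <- if (spec$fixed_effects) params$delta[[cid]] else params$delta
  list(delta = delta, beta = B, pis = params$pis, inhom = TRUE)
}

.session_ll <- function(obs, Z, ing) {
  if (!ing$inhom)
    return(.forward_homog_cpp(obs, ing$delta, ing$Gamma, ing$pis))
  if (length(obs) == 1L)
    return(.forward_inhom2_cpp(obs, ing$delta, numeric(0), numeric(0),
                               ing$pis))
  eta <- Z %*% t(ing$beta)
  .forward_inhom2_cpp(obs, ing$delta, plogis(eta[, 1]), plogis(eta[, 2]),
                      ing$pis)
}

#' Session log-likelihood of a Bernoulli-emission HMM
#'
#' Evaluates the log of the matrix product
#' \eqn{\delta P(x_1) \Gamma^{(2)} P(x_2) \cdots \Gamma^{(n)} P(x_n) 1}
#' by the scaled forward recursion.  For homogeneous chains
#' \eqn{\Gamma^{(t)} \equiv \Gamma} and, in stationary mode, \eqn{\delta}
#' is the stationary vector of \eqn{\Gamma}; for covariate models
#' \eqn{\Gamma^{(t)}} is built from the lagged covariates of the transition
#' into position t.
#'
#' @param series a [session_series()].
#' @param params natural parameter list (see [pack_parameters()]).
#' @param spec a [model_spec()].
#' @return The session log-likelihood (a finite scalar for valid interior
#'   parameters).
#' @export
session_log_likelihood <- function(series, params, spec) {
  if (!inherits(series, "session_series")) stop("series must be a session_series")
  .validate_params(params, spec)
  ing <- .session_ingredients(series, params, spec)
  Z <- if (ing$inhom) build_covariate_rows(series, spec) else NULL
  .session_ll(series$observations, Z, ing)
}

.validate_params <- function(params, spec) {
  if (any(!is.finite(params$pis)) || any(params$pis <= 0) ||
      any(params$pis >= 1))
    stop("emission probabilities must be finite and strictly inside (0, 1)")
  if (!is.null(params$Gamma)) {
    Gs <- if (is.list(params$Gamma)) params$Gamma else list(params$Gamma)
    lapply(Gs, .check_tpm)
  }
  if (!is.null(params$beta)) {
    Bs <- if (is.list(params$beta)) params$beta else list(params$beta)
    if (any(!vapply(Bs, function(B) all(is.finite(B)), logical(1))))
      stop("beta coefficients must be finite")
  }
  invisible(params)
}

#' Joint log-likelihood over a collection of independent sessions
#'
#' Sessions are assumed independent with common parameters (per-clinician
#' parameters under fixed effects), so the joint log-likelihood is the sum
#' of the per-session log-likelihoods.
#'
#' @param collection list of [session_series()].
#' @inheritParams session_log_likelihood
#' @export
joint_log_likelihood <- function(collection, params, spec) {
  if (!length(collection)) stop("empty session collection")
  sum(vapply(collection, session_log_likelihood, numeric(1),
             params = params, spec = spec))
}

# Precompute everything data-dependent once, returning a fast negative
# log-likelihood over the working scale for the optimizer.
.make_nll <- function(collection, spec) {
  if (!length(collection)) stop("empty session collection")
  obs <- lapply(collection, `[[`, "observations")
  cid <- vapply(collection, `[[`, integer(1), "clinician_id")
  has_cov <- length(spec$covariates) > 0L
  Z <- if (has_cov) lapply(collection, build_covariate_rows, spec = spec)
       else vector("list", length(collection))
  cids <- sort(unique(cid))
  function(w) {
    nll <- tryCatch({
      params <- unpack_parameters(w, spec)
      # ingredients depend on the data only through the clinician id
      ing_by <- lapply(cids, function(cc) .session_ingredients(
        structure(list(clinician_id = cc), class = "session_series"),
        params, spec))
      names(ing_by) <- as.character(cids)
      ll <- 0
      for (s in seq_along(obs))
        ll <- ll + .session_ll(obs[[s]], Z[[s]], ing_by[[as.character(cid[s])]])
      -ll
    }, error = function(e) Inf)
    if (!is.finite(nll)) 1e10 else nll
  }
}
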