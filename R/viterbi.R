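# Viterbi global decoding: the single most probable latent state sequence
# given a whole session, computed in log space.

#' Most probable latent state sequence of a session
#'
#' Dynamic-programming maximisation of the joint probability
#' \eqn{\Pr(S_1 = s_1, ..., S_n = s_n, X_1 = x_1, ..., X_n = x_n)} over all
#' \eqn{N^n} state paths, in log space.  Time-varying transition matrices
#' (covariate models) are supported; ties are broken toward the lower state
#' index at every backtracking step.
#'
#' @param series a [session_series()].
#' @param params natural parameter list (e.g. `fit$params`); after a fit,
#'   states are already ordered so state 1 is the dominantly affective one.
#' @param spec a [model_spec()].
#' @return An object of class `state_path`: `session_id`, `states` (vector
#'   in 1..N) and `log_score`, the joint log-probability of the decoded
#'   path, which never exceeds the session log-likelihood.
#' @export
viterbi <- function(series, params, spec) {
  if (!inherits(series, "session_series")) stop("series must be a session_series")
  .validate_params(params, spec)
  obs <- series$observations
  n <- length(obs)
  N <- spec$n_states
  ing <- .session_ingredients(series, params, spec)
  lp_obs <- function(x) log(if (x == 1) ing$pis else 1 - ing$pis)
  gammas <- NULL
  if (ing$inhom && n > 1L) {
    Z <- build_covariate_rows(series, spec)
    eta <- Z %*% t(ing$beta)
    g12 <- plogis(eta[, 1]); g21 <- plogis(eta[, 2])
    gammas <- lapply(seq_len(n - 1L), function(t)
      matrix(c(1 - g12[t], g12[t], g21[t], 1 - g21[t]), 2, byrow = TRUE))
  }
  lG <- function(t) log(if (is.null(gammas)) ing$Gamma else gammas[[t]])

  v <- log(ing$delta) + lp_obs(obs[1])
  back <- matrix(NA_integer_, nrow = max(n - 1L, 0L), ncol = N)
  if (n > 1L) for (t in 2:n) {
    lg <- lG(t - 1L)
    vt <- numeric(N)
    for (j in seq_len(N)) {
      cand <- v + lg[, j]
      b <- which.max(cand)            # lowest index wins exact ties
      back[t - 1L, j] <- b
      vt[j] <- cand[b]
    }
    v <- vt + lp_obs(obs[t])
  }
  states <- integer(n)
  states[n] <- which.max(v)
  if (n > 1L) for (t in (n - 1L):1L)
    states[t] <- back[t, states[t + 1L]]
  structure(list(session_id = series$session_id, states = states,
                 log_score = max(v)),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path> session %s, log-score %.4f\n  states: %s\n",
              x$session_id, x$log_score, paste(x$states, collapse = "")))
  invisible(x)
}

#' Decode every session of a collection
#'
#' @param collection list of [session_series()].
#' @param fit an [fit_hmm()] result, or a natural parameter list (then
#'   `spec` is required).
#' @param spec a [model_spec()] when `fit` is a raw parameter list.
#' @return data.frame with one row per reassurance: `session_id`,
#'   `position`, `observation`, `decoded_state` — ready for CSV export.
#' @export
decode_collection <- function(collection, fit, spec = NULL) {
  if (inherits(fit, "hmm_fit")) {
    params <- fit$params; spec <- fit$spec
  } else {
    params <- fit
    if (is.null(spec)) stop("spec is required when fit is a parameter list")
  }
  rows <- lapply(collection, function(s) {
    vp <- viterbi(s, params, spec)
    data.frame(session_id = s$session_id,
               position = seq_along(s$observations),
               observation = s$observations,
               decoded_state = vp$states,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
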