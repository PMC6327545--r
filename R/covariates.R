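#' Lagged covariate design rows for a session
#'
#' Builds one design row per transition of the latent chain (positions
#' t = 2..n).  The row for the transition into position t carries an
#' intercept plus the covariates measured at position t-1: the patient
#' response type at t-1 and/or the natural log of the duration of the
#' previous reassurance (log DOPR).  Lagging means every transition has a
#' covariate observation and nothing is needed before the first position.
#'
#' @param series a [session_series()].
#' @param spec a [model_spec()]; its `covariates` select the columns.
#' @return Numeric matrix with `length(series) - 1` rows and `k + 1`
#'   columns, the first column the constant 1.
#' @export
build_covariate_rows <- function(series, spec) {
  if (!inherits(series, "session_series")) stop("series must be a session_series")
  n <- length(series$observations)
  covs <- spec$covariates
  Z <- matrix(1, nrow = max(n - 1L, 0L), ncol = length(covs) + 1L,
              dimnames = list(NULL, c("(Intercept)", covs)))
  if (n < 2L) return(Z)
  lag_idx <- seq_len(n - 1L)
  for (cv in covs) {
    if (cv == "response_type") {
      if (is.null(series$response_types))
        stop(sprintf("session %s: response_types needed for the response_type covariate",
                     series$session_id))
      Z[, cv] <- series$response_types[lag_idx]
    } else if (cv == "log_dopr") {
      if (is.null(series$durations))
        stop(sprintf("session %s: durations needed for the log_dopr covariate",
                     series$session_id))
      bad <- which(series$durations[lag_idx] <= 0)
      if (length(bad))
        stop(sprintf("session %s: nonpositive duration at position %d cannot be log-transformed",
                     series$session_id, bad[1]))
      Z[, cv] <- log(series$durations[lag_idx])
    }
  }
  Z
}

#' Transition matrix at given covariate values
#'
#' Off-diagonal transition probabilities are the inverse logit of the linear
#' predictors \eqn{\beta_1' z} (state 1 to 2) and \eqn{\beta_2' z} (state 2
#' to 1); diagonal entries are the row complements.  The inverse logit is
#' evaluated with [stats::plogis()], which is saturation-safe for linear
#' predictors of any magnitude.
#'
#' @param coeffs 2 x (k+1) coefficient matrix (rows: transitions 1->2 and
#'   2->1; columns: intercept then covariates), or a list of two such
#'   matrices indexed by clinician when fixed effects are in use.
#' @param z covariate row `c(1, z_1, ..., z_k)` (intercept first).
#' @param clinician_id selects the coefficient set when `coeffs` is a list.
#' @return 2 x 2 row-stochastic transition matrix.
#' @export
transition_matrix_at <- function(coeffs, z, clinician_id = NULL) {
  if (is.list(coeffs)) {
    if (is.null(clinician_id) || !clinician_id %in% seq_along(coeffs))
      stop("no coefficient set for clinician_id ",
           if (is.null(clinician_id)) "<missing>" else clinician_id)
    coeffs <- coeffs[[clinician_id]]
  }
  z <- as.numeric(z)
  if (!is.matrix(coeffs) || nrow(coeffs) != 2L || ncol(coeffs) != length(z))
    stop("coefficient matrix must be 2 x length(z)")
  eta <- drop(coeffs %*% z)
  g12 <- plogis(eta[1]); g21 <- plogis(eta[2])
  matrix(c(1 - g12, g12, g21, 1 - g21), nrow = 2, byrow = TRUE)
}

#' Transition-probability and stationary-distribution profiles
#'
#' Fixes the chosen covariate at each grid value in turn (other covariates
#' held at `at`, default 0), treats the resulting chain as homogeneous, and
#' reports the hypothetical transition probabilities \eqn{\gamma_{12}},
#' \eqn{\gamma_{21}} and the stationary distribution of the implied
#' two-state matrix — the curves used to visualise how, e.g., log DOPR
#' moves the persistence of the latent states.
#'
#' @param coeffs as in [transition_matrix_at()].
#' @param grid numeric vector of covariate values.
#' @param clinician_id coefficient set selector under fixed effects.
#' @param covariate index (1-based among the covariates, excluding the
#'   intercept) of the covariate being varied.
#' @param at fixed values for the remaining covariates (default all 0).
#' @return data.frame with columns `value`, `gamma12`, `gamma21`, `delta1`,
#'   `delta2`.
#' @export
covariate_profile <- function(coeffs, grid, clinician_id = NULL,
                              covariate = 1L, at = NULL) {
  B <- if (is.list(coeffs)) {
    if (is.null(clinician_id) || !clinician_id %in% seq_along(coeffs))
      stop("no coefficient set for clinician_id ",
           if (is.null(clinician_id)) "<missing>" else clinician_id)
    coeffs[[clinician_id]]
  } else coeffs
  k <- ncol(B) - 1L
  if (covariate < 1L || covariate > k) stop("covariate index out of range")
  base <- if (is.null(at)) numeric(k) else as.numeric(at)
  if (length(base) != k) stop("`at` must give one value per covariate")
  if (any(!is.finite(grid))) stop("grid values must be finite")
  out <- lapply(grid, function(v) {
    zz <- base; zz[covariate] <- v
    G <- transition_matrix_at(B, c(1, zz))
    d <- stationary_distribution(G)
    c(value = v, gamma12 = G[1, 2], gamma21 = G[2, 1],
      delta1 = d[1], delta2 = d[2])
  })
  as.data.frame(do.call(rbind, out))
}
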