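# Maximum-likelihood fitting over the working scale with random restarts,
# Newton-type optimisation (stats::nlm) and inverse-Hessian Wald intervals.

#' Fitting options
#'
#' @param n_restarts number of random initialisations (>= 1). Short series
#'   give multimodal likelihoods, so several restarts are the default.
#' @param seed optional integer seed making the fit fully reproducible
#'   (restart draws included); the caller's RNG state is left untouched.
#' @param gradtol working-scale gradient tolerance passed to [stats::nlm()].
#' @param iterlim maximum Newton iterations per restart.
#' @export
fit_options <- function(n_restarts = 10L, seed = NULL, gradtol = 1e-8,
                        iterlim = 500L) {
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  list(n_restarts = n_restarts, seed = seed, gradtol = gradtol,
       iterlim = as.integer(iterlim))
}

# random natural parameters for one restart: probabilities uniform on
# (0.1, 0.9); beta intercepts the logit of a uniform (0.1, 0.9) draw,
# slopes uniform on (-1, 1)
.random_start <- function(spec) {
  N <- spec$n_states
  ru <- function(n) runif(n, 0.1, 0.9)
  params <- list(pis = sort(ru(N)))
  if (spec$mixture) {
    params$delta <- .unpack_simplex(qlogis(ru(1)), 2L)
    return(params)
  }
  if (N == 1L) return(params)
  rGamma <- function() {
    G <- matrix(ru(N * N), N, N)
    G / rowSums(G)
  }
  if (length(spec$covariates) == 0L) {
    params$Gamma <- if (spec$fixed_effects) list(rGamma(), rGamma())
                    else rGamma()
    if (spec$initial == "estimated") {
      rdelta <- function() { d <- ru(N); d / sum(d) }
      params$delta <- if (spec$fixed_effects) list(rdelta(), rdelta())
                      else rdelta()
    }
  } else {
    k <- length(spec$covariates)
    rbeta_ <- function()
      cbind(qlogis(ru(2)), matrix(runif(2 * k, -1, 1), nrow = 2))
    params$beta <- if (spec$fixed_effects) list(rbeta_(), rbeta_())
                   else rbeta_()
    rdelta <- function() { d <- ru(2); d / sum(d) }
    params$delta <- if (spec$fixed_effects) list(rdelta(), rdelta())
                    else rdelta()
  }
  params
}

# deterministic moment-based start: emission probabilities straddling the
# pooled cognitive proportion, persistent transition rows, slopes at zero
.moment_start <- function(collection, spec) {
  N <- spec$n_states
  pbar <- mean(unlist(lapply(collection, `[[`, "observations")))
  pbar <- min(max(pbar, 0.05), 0.95)
  pis <- if (N == 1L) pbar
         else plogis(qlogis(pbar) + seq(-1, 1, length.out = N))
  params <- list(pis = pis)
  if (spec$mixture) {
    params$delta <- c(0.5, 0.5)
    return(params)
  }
  if (N == 1L) return(params)
  G <- matrix(0.2 / (N - 1), N, N); diag(G) <- 0.8
  if (length(spec$covariates) == 0L) {
    params$Gamma <- if (spec$fixed_effects) list(G, G) else G
    if (spec$initial == "estimated") {
      d <- rep(1 / N, N)
      params$delta <- if (spec$fixed_effects) list(d, d) else d
    }
  } else {
    k <- length(spec$covariates)
    B <- cbind(rep(qlogis(0.2), 2), matrix(0, 2, k))
    params$beta <- if (spec$fixed_effects) list(B, B) else B
    d <- c(0.5, 0.5)
    params$delta <- if (spec$fixed_effects) list(d, d) else d
  }
  params
}

#' Fit a reassurance HMM by maximum likelihood
#'
#' Maximises the joint log-likelihood over all sessions on the unconstrained
#' working scale with a Newton-type optimiser ([stats::nlm()]), taking the
#' best local optimum over `n_restarts` random initialisations plus a
#' deterministic moment-based start and any user-supplied `starts`.  After
#' fitting, states are relabelled so the emission probabilities are
#' ascending (state 1 dominantly affective, state 2 dominantly cognitive),
#' and 95% Wald intervals are computed from the inverse of the
#' finite-difference Hessian on the working scale (probability-type
#' parameters back-transformed, hence asymmetric; beta bounds reported
#' directly).
#'
#' @param collection list of [session_series()].
#' @param spec a [model_spec()].
#' @param options a [fit_options()] list.
#' @param starts optional list of natural-parameter lists used as extra
#'   initialisations (e.g. a baseline solution with zero slopes, to warm
#'   start a covariate model).
#' @return An object of class `hmm_fit` with elements `params` (natural
#'   scale, states ordered by ascending emission probability), `nllk`, `p`,
#'   `aic`, `ci` (per-parameter estimate and 95% bounds), `convergence`,
#'   `flags`, `hessian`, `n_restarts_used`, `seed` and `spec`.
#' @export
fit_hmm <- function(collection, spec, options = fit_options(),
                    starts = NULL) {
  if (!length(collection)) stop("empty session collection")
  if (!all(vapply(collection, inherits, logical(1), "session_series")))
    stop("collection must be a list of session_series")
  nll <- .make_nll(collection, spec)
  lay <- param_layout(spec)

  start_vecs <- list(pack_parameters(.moment_start(collection, spec), spec))
  if (!is.null(starts))
    start_vecs <- c(start_vecs,
                    lapply(starts, pack_parameters, spec = spec))
  runs <- .with_seed(options$seed, {
    rand <- replicate(options$n_restarts,
                      pack_parameters(.random_start(spec), spec),
                      simplify = FALSE)
    lapply(c(start_vecs, rand), function(w0) {
      tryCatch(suppressWarnings(
        nlm(nll, w0, gradtol = options$gradtol,
            iterlim = options$iterlim)),
        error = function(e) NULL)
    })
  })
  runs <- Filter(Negate(is.null), runs)
  ok <- vapply(runs, function(r) {
    r$code %in% 1:3 && is.finite(r$minimum) && r$minimum < 1e9
  }, logical(1))
  if (!any(ok)) {
    codes <- vapply(runs, function(r) r$code, numeric(1))
    stop("no restart converged (nlm codes: ",
         paste(codes, collapse = ", "), ")")
  }
  runs <- runs[ok]
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "minimum"))]]

  # relabel states by ascending emission probability, then recompute the
  # optimum quantities at the relabelled (equivalent) parameter vector;
  # working values are clamped to +/-35 so that numerically saturated
  # probabilities stay representable on both scales (plogis(35) < 1)
  w_best <- pmin(pmax(best$estimate, -35), 35)
  params <- .relabel_states(unpack_parameters(w_best, spec), spec)
  w_hat <- pack_parameters(params, spec)
  nllk <- nll(w_hat)
  p <- nrow(lay)
  hess <- tryCatch(optimHess(w_hat, nll), error = function(e) NULL)

  flags <- character(0)
  if (any(params$pis < 1e-3) || any(params$pis > 1 - 1e-3)) {
    flags <- c(flags, "boundary_emission")
    warning("emission probability estimate adjacent to the boundary; ",
            "the data may be degenerate for this model")
  }
  betas <- unlist(params$beta)
  if (length(betas) && any(abs(betas) > 50)) {
    flags <- c(flags, "large_beta")
    warning("|beta| > 50: a transition is effectively saturated; ",
            "interpret the coefficient scale with caution")
  }

  fit <- structure(
    list(spec = spec, params = params, nllk = nllk, logLik = -nllk,
         p = p, aic = 2 * nllk + 2 * p, working = w_hat, hessian = hess,
         convergence = list(code = best$code,
                            gradient_norm = max(abs(best$gradient)),
                            converged = TRUE,
                            iterations = best$iterations),
         flags = flags, n_restarts_used = length(runs),
         n_sessions = length(collection),
         n_obs = sum(vapply(collection, length, integer(1))),
         seed = options$seed),
    class = "hmm_fit")
  fit$ci <- confidence_intervals(fit)
  fit
}

#' Inverse-Hessian Wald confidence intervals
#'
#' Standard errors come from the diagonal of the inverse of the
#' finite-difference Hessian of the negative log-likelihood at the optimum,
#' computed on the unconstrained working scale.  Bounds for
#' probability-type parameters are back-transformed through the inverse
#' logit (so they stay inside (0, 1) and are asymmetric about the
#' estimate); regression coefficients are reported on their own scale with
#' symmetric bounds.  A singular Hessian falls back to the Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @param fit an [fit_hmm()] result.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `parameter`, `type`, `estimate`,
#'   `lower`, `upper`, `se_working`.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  lay <- param_layout(fit$spec)
  w <- fit$working
  q <- qnorm(1 - (1 - level) / 2)
  se <- rep(NA_real_, length(w))
  if (!is.null(fit$hessian)) {
    V <- tryCatch(solve(fit$hessian), error = function(e) NULL)
    if (is.null(V)) {
      warning("singular Hessian: using the Moore-Penrose pseudo-inverse")
      V <- MASS::ginv(fit$hessian)
    }
    dv <- diag(V)
    se <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
  }
  lo_w <- w - q * se
  hi_w <- w + q * se
  est <- ifelse(lay$type == "prob", plogis(w), w)
  lo <- ifelse(lay$type == "prob", plogis(lo_w), lo_w)
  hi <- ifelse(lay$type == "prob", plogis(hi_w), hi_w)
  data.frame(parameter = lay$name, type = lay$type, estimate = est,
             lower = lo, upper = hi, se_working = se,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.hmm_fit <- function(x, digits = 3, ...) {
  print(x$spec)
  cat(sprintf("  sessions: %d  observations: %d\n", x$n_sessions, x$n_obs))
  cat(sprintf("  -log-likelihood: %.2f   p: %d   AIC: %.2f\n",
              x$nllk, x$p, x$aic))
  ci <- x$ci
  ci$estimate <- round(ci$estimate, digits)
  ci$lower <- round(ci$lower, digits)
  ci$upper <- round(ci$upper, digits)
  print(ci[, c("parameter", "estimate", "lower", "upper")])
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.hmm_fit <- function(object, ...) {
  structure(object$logLik, df = object$p, nobs = object$n_obs,
            class = "logLik")
}
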