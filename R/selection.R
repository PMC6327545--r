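# Parameter counting, AIC and multi-model comparison.

#' Number of free parameters of a model specification
#'
#' The length of the working parameter vector: an N-state stationary
#' baseline has N(N-1) transition plus N emission parameters; a 2-state
#' covariate model has 2 emission + 2(k+1) regression + 1 initial
#' parameters; clinician fixed effects double the transition/regression and
#' initial blocks; the independent mixture has one mixing weight plus two
#' emission probabilities.
#'
#' @param spec a [model_spec()].
#' @export
count_parameters <- function(spec) nrow(param_layout(spec))

#' Akaike Information Criterion from a negative log-likelihood
#'
#' `AIC = -2 log L + 2 p = 2 * nllk + 2 * p`; lower is preferred.
#'
#' @param nllk negative joint log-likelihood.
#' @param p number of estimated parameters (>= 0).
#' @export
aic <- function(nllk, p) {
  if (p < 0) stop("p must be nonnegative")
  2 * nllk + 2 * p
}

#' The candidate model family for reassurance series
#'
#' The ten specifications compared in the analysis: homogeneous baselines
#' with 1, 2 and 3 states, the independent two-component mixture, 2-state
#' models with the lagged response type and/or log DOPR as transition
#' covariates, and clinician fixed-effects versions of the baseline and
#' one-covariate models.  The fixed-effects baseline estimates a separate
#' initial distribution per clinician.
#'
#' @return Named list of [model_spec()] objects.
#' @export
candidate_model_set <- function() {
  list(
    "Baseline N=1" = model_spec(1),
    "Baseline N=2" = model_spec(2),
    "Baseline N=3" = model_spec(3),
    "Indep. mixt." = model_spec(2, mixture = TRUE),
    "Response Type" = model_spec(2, covariates = "response_type"),
    "Log DOPR" = model_spec(2, covariates = "log_dopr"),
    "Response Type & log DOPR" =
      model_spec(2, covariates = c("response_type", "log_dopr")),
    "FE baseline" = model_spec(2, fixed_effects = TRUE,
                               initial = "estimated"),
    "FE Response" = model_spec(2, covariates = "response_type",
                               fixed_effects = TRUE),
    "FE Log DOPR" = model_spec(2, covariates = "log_dopr",
                               fixed_effects = TRUE))
}

#' Fit and compare several model specifications by AIC
#'
#' Each specification is fitted to the same collection with the same
#' options (the same seed, so the comparison is deterministic and identical
#' specifications receive identical fits), and the models are tabulated by
#' negative log-likelihood, parameter count and AIC with the minimum-AIC
#' row marked.
#'
#' @param collection list of [session_series()].
#' @param specs named list of [model_spec()] objects.
#' @param options a [fit_options()] list shared across fits.
#' @return data.frame of class `hmm_comparison` with columns `model`,
#'   `nllk`, `p`, `AIC`, `best`; the fitted objects are attached as
#'   attribute `"fits"`.
#' @export
compare_models <- function(collection, specs, options = fit_options()) {
  if (!length(specs)) stop("no specifications to compare")
  labels <- names(specs)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- paste("model", seq_along(specs))
  fits <- lapply(seq_along(specs), function(i) {
    tryCatch(fit_hmm(collection, specs[[i]], options = options),
             error = function(e)
               stop(sprintf("fit failed for \"%s\": %s", labels[i],
                            conditionMessage(e)), call. = FALSE))
  })
  tab <- data.frame(
    model = labels,
    nllk = vapply(fits, `[[`, numeric(1), "nllk"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    AIC = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$best <- seq_len(nrow(tab)) == which.min(tab$AIC)
  attr(tab, "fits") <- stats::setNames(fits, labels)
  class(tab) <- c("hmm_comparison", "data.frame")
  tab
}

#' @export
print.hmm_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  y$nllk <- round(y$nllk, 2)
  y$AIC <- round(y$AIC, 2)
  y$best <- ifelse(y$best, "*", "")
  print(y, row.names = FALSE)
  invisible(x)
}
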