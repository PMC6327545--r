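# Session CSV readers/writers and JSON serialization of fit results.

.SESSION_COLS <- c("session_id", "position", "reassurance_type",
                   "duration_s", "response_type", "response_duration_s",
                   "clinician_id")

#' Read a session table CSV into a session collection
#'
#' Expects a UTF-8 comma-separated file with exactly the columns
#' `session_id, position, reassurance_type, duration_s, response_type,
#' response_duration_s, clinician_id`; positions within a session must be
#' consecutive from 1.  Sessions are returned sorted by `session_id` with
#' rows ordered by position, regardless of the input row order.
#'
#' @param path CSV file path.
#' @return List of [session_series()].
#' @export
read_sessions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .SESSION_COLS))
    stop("session CSV must have exactly the columns: ",
         paste(.SESSION_COLS, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("%s (row %s)", what,
                   paste(head(i, 5), collapse = ", ")))
  }
  bad_row(!df$reassurance_type %in% c(0, 1),
          "reassurance_type must be 0 or 1")
  bad_row(!df$response_type %in% c(0, 1), "response_type must be 0 or 1")
  bad_row(!is.finite(df$duration_s) | df$duration_s <= 0,
          "duration_s must be positive")
  bad_row(!is.finite(df$response_duration_s) | df$response_duration_s < 0,
          "response_duration_s must be nonnegative")
  bad_row(!df$clinician_id %in% c(1, 2), "clinician_id must be 1 or 2")
  bad_row(duplicated(df[c("session_id", "position")]),
          "duplicate (session_id, position)")
  ids <- sort(unique(as.character(df$session_id)))
  lapply(ids, function(id) {
    rows <- df[df$session_id == id, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    if (!identical(as.integer(rows$position), seq_len(nrow(rows))))
      stop(sprintf("session %s: positions must be consecutive from 1", id))
    cid <- unique(rows$clinician_id)
    if (length(cid) != 1L)
      stop(sprintf("session %s: inconsistent clinician_id", id))
    session_series(id, rows$reassurance_type,
                   durations = rows$duration_s,
                   response_types = rows$response_type,
                   response_durations = rows$response_duration_s,
                   clinician_id = cid)
  })
}

#' Write a session collection to the session table CSV
#'
#' @param collection list of [session_series()] with all covariate fields
#'   present.
#' @param path output CSV path.
#' @export
write_sessions <- function(collection, path) {
  rows <- lapply(collection, function(s) {
    if (is.null(s$durations) || is.null(s$response_types) ||
        is.null(s$response_durations))
      stop(sprintf("session %s: all covariate fields are required to write",
                   s$session_id))
    data.frame(session_id = s$session_id,
               position = seq_along(s$observations),
               reassurance_type = s$observations,
               duration_s = s$durations,
               response_type = s$response_types,
               response_duration_s = s$response_durations,
               clinician_id = s$clinician_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$session_id, df$position), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# spec <-> plain list (for JSON)
.spec_to_list <- function(spec) {
  list(n_states = spec$n_states, covariates = as.list(spec$covariates),
       fixed_effects = spec$fixed_effects, mixture = spec$mixture,
       initial = spec$initial)
}

.spec_from_list <- function(x) {
  model_spec(n_states = x$n_states,
             covariates = unlist(x$covariates),
             fixed_effects = isTRUE(x$fixed_effects),
             mixture = isTRUE(x$mixture),
             initial = x$initial)
}

#' Serialize a fitted model to JSON
#'
#' The JSON embeds the model specification, the natural-scale estimates,
#' the fit summary (negative log-likelihood, parameter count, AIC,
#' confidence table, convergence diagnostics), the seed and the package
#' version, so any downstream step (decoding, profiles) can be reproduced
#' from the file alone.
#'
#' @param fit an [fit_hmm()] result.
#' @param path output JSON path.
#' @export
write_fit_json <- function(fit, path) {
  p <- fit$params
  pl <- list(pis = p$pis)
  if (!is.null(p$Gamma))
    pl$Gamma <- if (is.list(p$Gamma)) lapply(p$Gamma, unclass) else p$Gamma
  if (!is.null(p$beta)) pl$beta <- p$beta
  if (!is.null(p$delta)) pl$delta <- p$delta
  obj <- list(package = "reassureHMM",
              version = as.character(packageVersion("reassureHMM")),
              spec = .spec_to_list(fit$spec),
              seed = fit$seed,
              params = pl,
              nllk = fit$nllk, p = fit$p, aic = fit$aic,
              ci = fit$ci,
              convergence = fit$convergence,
              flags = as.list(fit$flags),
              n_sessions = fit$n_sessions, n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path JSON file written by [write_fit_json()].
#' @return List with elements `spec` (a [model_spec()]), `params`
#'   (natural-parameter list), `nllk`, `p`, `aic`, `ci`, `seed`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- .spec_from_list(x$spec)
  pr <- list(pis = as.numeric(x$params$pis))
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  if (!is.null(x$params$Gamma)) {
    pr$Gamma <- if (spec$fixed_effects) lapply(x$params$Gamma, as_mat)
                else as_mat(x$params$Gamma)
  }
  if (!is.null(x$params$beta)) {
    pr$beta <- if (spec$fixed_effects) lapply(x$params$beta, as_mat)
               else as_mat(x$params$beta)
    if (spec$fixed_effects)
      pr$beta <- lapply(pr$beta, function(B) {
        dimnames(B) <- list(c("1->2", "2->1"),
                            c("(Intercept)", spec$covariates)); B })
    else dimnames(pr$beta) <- list(c("1->2", "2->1"),
                                   c("(Intercept)", spec$covariates))
  }
  if (!is.null(x$params$delta)) {
    pr$delta <- if (spec$fixed_effects) lapply(x$params$delta, as.numeric)
                else as.numeric(x$params$delta)
  }
  list(spec = spec, params = pr, nllk = x$nllk, p = x$p, aic = x$aic,
       ci = x$ci, seed = x$seed, version = x$version)
}
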