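#' Construct a single-session reassurance series
#'
#' A session is one review consultation, yielding an ordered binary sequence
#' of reassurances (1 = cognitive, 0 = affective) together with per-utterance
#' covariate sources: the reassurance duration in seconds, the patient
#' response type (1 = positive, 0 = neutral), the response duration, and the
#' identifier of the clinician who held the session.
#'
#' @param session_id opaque session label (coerced to character).
#' @param observations integer/numeric vector of 0/1 reassurance types,
#'   length at least 1.
#' @param durations optional strictly positive reassurance durations
#'   (seconds), parallel to `observations`.
#' @param response_types optional 0/1 patient response types, parallel to
#'   `observations`.
#' @param response_durations optional nonnegative response durations
#'   (seconds).
#' @param clinician_id clinician identifier, 1 or 2.
#' @return An object of class `session_series`.
#' @export
session_series <- function(session_id, observations, durations = NULL,
                           response_types = NULL, response_durations = NULL,
                           clinician_id = 1L) {
  observations <- as.integer(observations)
  n <- length(observations)
  if (n < 1L) stop("a session must contain at least one reassurance")
  if (!all(observations %in% c(0L, 1L)))
    stop("observations must be 0 (affective) or 1 (cognitive)")
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != n)
      stop(sprintf("%s must have the same length as observations", what))
  }
  check_len(durations, "durations")
  check_len(response_types, "response_types")
  check_len(response_durations, "response_durations")
  if (!is.null(durations)) {
    durations <- as.numeric(durations)
    if (any(!is.finite(durations)) || any(durations <= 0))
      stop("durations must be strictly positive and finite")
  }
  if (!is.null(response_types)) {
    response_types <- as.integer(response_types)
    if (!all(response_types %in% c(0L, 1L)))
      stop("response_types must be 0 (neutral) or 1 (positive)")
  }
  if (!is.null(response_durations)) {
    response_durations <- as.numeric(response_durations)
    if (any(!is.finite(response_durations)) || any(response_durations < 0))
      stop("response_durations must be nonnegative and finite")
  }
  clinician_id <- as.integer(clinician_id)
  if (length(clinician_id) != 1L || !clinician_id %in% c(1L, 2L))
    stop("clinician_id must be 1 or 2")
  structure(
    list(session_id = as.character(session_id),
         observations = observations,
         durations = durations,
         response_types = response_types,
         response_durations = response_durations,
         clinician_id = clinician_id),
    class = "session_series")
}

#' @export
print.session_series <- function(x, ...) {
  cat(sprintf("<session_series> id=%s, clinician=%d, n=%d obs: %s\n",
              x$session_id, x$clinician_id, length(x$observations),
              paste(x$observations, collapse = "")))
  invisible(x)
}

#' @export
length.session_series <- function(x) length(x$observations)

# validate an N x N transition probability matrix (rows sum to one)
.check_tpm <- function(Gamma, tol = .ROW_TOL) {
  if (!is.matrix(Gamma) || nrow(Gamma) != ncol(Gamma))
    stop("transition matrix must be square")
  if (any(!is.finite(Gamma)) || any(Gamma < -tol) || any(Gamma > 1 + tol))
    stop("transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(Gamma) - 1) > tol))
    stop("transition matrix rows must sum to 1")
  invisible(Gamma)
}

#' Stationary distribution of a homogeneous Markov chain
#'
#' Solves the linear system \eqn{\delta (I_N - \Gamma + U) = 1'} (with
#' \eqn{U} a matrix of ones), which yields the left eigenvector of the
#' transition matrix associated with eigenvalue 1, normalised to sum to one.
#' For a two-state chain this equals
#' \eqn{(\gamma_{21}, \gamma_{12}) / (\gamma_{12} + \gamma_{21})}.
#'
#' @param Gamma N x N row-stochastic transition probability matrix.
#' @return Numeric vector `delta` with `delta %*% Gamma == delta` and
#'   `sum(delta) == 1`.
#' @export
stationary_distribution <- function(Gamma) {
  .check_tpm(Gamma)
  N <- nrow(Gamma)
  A <- diag(N) - Gamma + matrix(1, N, N)
  delta <- tryCatch(solve(t(A), rep(1, N)),
                    error = function(e)
                      stop(sprintf(
                        "no unique stationary distribution for matrix [%s]",
                        paste(apply(Gamma, 1, paste, collapse = " "),
                              collapse = "; ")), call. = FALSE))
  if (any(delta < -1e-8) ||
      max(abs(drop(delta %*% Gamma) - delta)) > 1e-8)
    stop(sprintf(
      "no unique stationary distribution for matrix [%s]",
      paste(apply(Gamma, 1, paste, collapse = " "), collapse = "; ")))
  delta <- pmax(delta, 0)
  delta / sum(delta)
}

#' Diagonal emission matrix of a Bernoulli-emission HMM
#'
#' Returns the N x N diagonal matrix `P(x)` whose i-th diagonal entry is the
#' probability of observing `x` given latent state i: `pis[i]` for a
#' cognitive reassurance (`x = 1`) and `1 - pis[i]` for an affective one
#' (`x = 0`).
#'
#' @param pis per-state success (cognitive) probabilities.
#' @param x a single observation, 0 or 1.
#' @export
emission_matrix <- function(pis, x) {
  if (length(x) != 1L || !x %in% c(0, 1))
    stop("x must be a single value in {0, 1}")
  if (any(pis <= 0) || any(pis >= 1))
    stop("emission probabilities must lie strictly inside (0, 1)")
  d <- if (x == 1) pis else 1 - pis
  diag(d, nrow = length(pis))
}

#' Specify an HMM variant for reassurance series
#'
#' Describes one member of the candidate model family: the number of latent
#' states, which lagged covariates (if any) drive the transition
#' probabilities, whether transition parameters differ per clinician (fixed
#' effects), whether the chain degenerates to an independent mixture, and
#' how the initial state distribution is handled.
#'
#' @param n_states number of latent states (>= 1).
#' @param covariates character vector, subset of
#'   `c("response_type", "log_dopr")`: the lagged patient response and the
#'   log duration of the previous reassurance.
#' @param fixed_effects logical; separate transition parameter sets for the
#'   two clinicians.
#' @param mixture logical; constrain the chain so every row of the
#'   transition matrix equals the initial distribution (an independent
#'   two-component mixture).
#' @param initial `"stationary"` (initial law is the stationary vector of
#'   the homogeneous chain; only valid without covariates) or `"estimated"`
#'   (free initial probability, required for covariate models).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(n_states = 2L, covariates = character(),
                       fixed_effects = FALSE, mixture = FALSE,
                       initial = NULL) {
  n_states <- as.integer(n_states)
  if (n_states < 1L) stop("n_states must be >= 1")
  covariates <- as.character(covariates)
  bad <- setdiff(covariates, c("response_type", "log_dopr"))
  if (length(bad))
    stop("unknown covariates: ", paste(bad, collapse = ", "))
  if (anyDuplicated(covariates)) stop("duplicate covariate names")
  if (is.null(initial))
    initial <- if (length(covariates)) "estimated" else "stationary"
  initial <- match.arg(initial, c("stationary", "estimated"))
  if (length(covariates) && initial == "stationary")
    stop("a covariate-driven chain is not homogeneous; use initial = \"estimated\"")
  if (mixture && (length(covariates) || fixed_effects))
    stop("mixture mode excludes covariates and fixed effects")
  if (mixture && n_states != 2L)
    stop("the independent mixture is implemented with 2 components")
  if ((length(covariates) || fixed_effects) && n_states != 2L)
    stop("covariates and fixed effects are supported for 2-state models")
  structure(
    list(n_states = n_states, covariates = covariates,
         fixed_effects = isTRUE(fixed_effects), mixture = isTRUE(mixture),
         initial = initial),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %d state(s)%s%s%s, initial=%s\n", x$n_states,
    if (x$mixture) ", independent mixture" else "",
    if (length(x$covariates))
      paste0(", covariates: ", paste(x$covariates, collapse = "+")) else "",
    if (x$fixed_effects) ", clinician fixed effects" else "",
    x$initial))
  invisible(x)
}

# Working-parameter layout ---------------------------------------------------
#
# Every model variant maps its natural parameters to an unconstrained working
# vector: probabilities through the logit, transition-matrix rows for N >= 3
# through a multinomial-logit normalisation against the diagonal entry
# (which reduces to the logit for N = 2), and regression coefficients beta
# unchanged.  `type` records the back-transform each entry needs for
# confidence intervals: "prob" (inverse logit) or "identity".

.layout_tpm_names <- function(N, suffix = "") {
  out <- character(0)
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    out <- c(out, sprintf("gamma%d%d%s", i, j, suffix))
  out
}

#' Working-parameter layout of a model specification
#'
#' @param spec a [model_spec()].
#' @return data.frame with columns `name` and `type` (`"prob"` entries are
#'   logit-transformed probabilities; `"identity"` entries pass through).
#' @keywords internal
param_layout <- function(spec) {
  N <- spec$n_states
  nm <- character(0); ty <- character(0)
  add <- function(names, type) {
    nm <<- c(nm, names); ty <<- c(ty, rep(type, length(names)))
  }
  if (spec$mixture) {
    add("delta1", "prob")
    add(c("pi1", "pi2"), "prob")
  } else if (N == 1L) {
    add("pi1", "prob")
  } else if (length(spec$covariates) == 0L) {
    cl <- if (spec$fixed_effects) c("_c1", "_c2") else ""
    for (s in cl)
      add(.layout_tpm_names(N, s), if (N == 2L) "prob" else "identity")
    add(sprintf("pi%d", seq_len(N)), "prob")
    if (spec$initial == "estimated") {
      for (s in cl) {
        if (N == 2L) add(paste0("delta1", s), "prob")
        else add(sprintf("wdelta%d%s", 2:N, s), "identity")
      }
    }
  } else {
    k <- length(spec$covariates)
    cl <- if (spec$fixed_effects) c("_c1", "_c2") else ""
    for (s in cl)
      for (r in 1:2)
        add(sprintf("beta%d_%d%s", r, 0:k, s), "identity")
    add(c("pi1", "pi2"), "prob")
    for (s in cl) add(paste0("delta1", s), "prob")
  }
  data.frame(name = nm, type = ty, stringsAsFactors = FALSE)
}

.check_interior <- function(p, what) {
  if (any(p <= 0) || any(p >= 1))
    stop(sprintf("%s on the boundary (0 or 1) cannot be mapped to the working scale",
                 what))
}

# row of a t.p.m. -> multinomial-logit working values (off-diagonals vs diag)
.pack_tpm <- function(Gamma) {
  N <- nrow(Gamma)
  .check_interior(diag(Gamma), "diagonal transition probabilities")
  .check_interior(Gamma[row(Gamma) != col(Gamma)], "transition probabilities")
  out <- numeric(0)
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    out <- c(out, log(Gamma[i, j] / Gamma[i, i]))
  out
}

.unpack_tpm <- function(w, N) {
  Gamma <- matrix(0, N, N)
  idx <- 1L
  for (i in seq_len(N)) {
    e <- numeric(N); e[i] <- 1
    for (j in seq_len(N)) if (i != j) {
      e[j] <- exp(w[idx]); idx <- idx + 1L
    }
    Gamma[i, ] <- e / sum(e)
  }
  Gamma
}

.pack_simplex <- function(delta) {
  .check_interior(delta, "initial probabilities")
  N <- length(delta)
  if (N == 2L) qlogis(delta[1]) else log(delta[2:N] / delta[1])
}

.unpack_simplex <- function(w, N) {
  if (N == 2L) {
    d1 <- plogis(w)
    c(d1, 1 - d1)
  } else {
    e <- c(1, exp(w))
    e / sum(e)
  }
}

#' Map natural parameters to the unconstrained working scale
#'
#' The natural parameters of a model are held in a list with elements (as
#' applicable) `pis`, `Gamma` (matrix, or list of two matrices under fixed
#' effects), `beta` (rows = transitions 1->2 and 2->1, columns = intercept
#' then covariates; a list of two such matrices under fixed effects), and
#' `delta` (initial distribution, or list of two under fixed effects).
#' Probabilities map through the logit (multinomial logit for transition
#' rows with 3+ states), beta coefficients pass through unchanged.
#'
#' @param params list of natural parameters (see Details).
#' @param spec a [model_spec()].
#' @return Named numeric working vector; `unpack_parameters()` inverts it.
#' @export
pack_parameters <- function(params, spec) {
  lay <- param_layout(spec)
  N <- spec$n_states
  w <- numeric(0)
  if (spec$mixture) {
    .check_interior(params$delta, "mixing probabilities")
    .check_interior(params$pis, "emission probabilities")
    w <- c(qlogis(params$delta[1]), qlogis(params$pis))
  } else if (N == 1L) {
    .check_interior(params$pis, "emission probabilities")
    w <- qlogis(params$pis[1])
  } else if (length(spec$covariates) == 0L) {
    Gl <- if (spec$fixed_effects) params$Gamma else list(params$Gamma)
    for (G in Gl) w <- c(w, .pack_tpm(G))
    .check_interior(params$pis, "emission probabilities")
    w <- c(w, qlogis(params$pis))
    if (spec$initial == "estimated") {
      dl <- if (spec$fixed_effects) params$delta else list(params$delta)
      for (d in dl) w <- c(w, .pack_simplex(d))
    }
  } else {
    bl <- if (spec$fixed_effects) params$beta else list(params$beta)
    for (B in bl) {
      if (!is.matrix(B) || nrow(B) != 2L ||
          ncol(B) != length(spec$covariates) + 1L)
        stop("beta must be a 2 x (k+1) coefficient matrix per clinician set")
      if (any(!is.finite(B))) stop("beta coefficients must be finite")
      w <- c(w, as.vector(t(B)))
    }
    .check_interior(params$pis, "emission probabilities")
    w <- c(w, qlogis(params$pis))
    dl <- if (spec$fixed_effects) params$delta else list(params$delta)
    for (d in dl) w <- c(w, .pack_simplex(d))
  }
  if (length(w) != nrow(lay)) stop("internal error: layout length mismatch")
  stats::setNames(w, lay$name)
}

#' @rdname pack_parameters
#' @param w working vector as produced by `pack_parameters()`.
#' @export
unpack_parameters <- function(w, spec) {
  lay <- param_layout(spec)
  if (length(w) != nrow(lay))
    stop(sprintf("working vector has length %d; spec requires %d",
                 length(w), nrow(lay)))
  if (any(!is.finite(w))) stop("working parameters must be finite")
  N <- spec$n_states
  pos <- 1L
  take <- function(n) {
    out <- unname(w[pos:(pos + n - 1L)]); pos <<- pos + n; out
  }
  params <- list()
  if (spec$mixture) {
    d1 <- plogis(take(1L))
    params$delta <- c(d1, 1 - d1)
    params$pis <- plogis(take(2L))
  } else if (N == 1L) {
    params$pis <- plogis(take(1L))
  } else if (length(spec$covariates) == 0L) {
    nG <- N * (N - 1L)
    if (spec$fixed_effects) {
      params$Gamma <- list(.unpack_tpm(take(nG), N), .unpack_tpm(take(nG), N))
    } else {
      params$Gamma <- .unpack_tpm(take(nG), N)
    }
    params$pis <- plogis(take(N))
    if (spec$initial == "estimated") {
      nd <- N - 1L
      if (spec$fixed_effects)
        params$delta <- list(.unpack_simplex(take(nd), N),
                             .unpack_simplex(take(nd), N))
      else params$delta <- .unpack_simplex(take(nd), N)
    }
  } else {
    k <- length(spec$covariates)
    grab_beta <- function() {
      B <- matrix(take(2L * (k + 1L)), nrow = 2L, byrow = TRUE)
      dimnames(B) <- list(c("1->2", "2->1"), c("(Intercept)", spec$covariates))
      B
    }
    if (spec$fixed_effects) params$beta <- list(grab_beta(), grab_beta())
    else params$beta <- grab_beta()
    params$pis <- plogis(take(2L))
    if (spec$fixed_effects)
      params$delta <- list(.unpack_simplex(take(1L), 2L),
                           .unpack_simplex(take(1L), 2L))
    else params$delta <- .unpack_simplex(take(1L), 2L)
  }
  params
}

# reorder latent states so pi_1 < pi_2 < ... (state 1 "dominantly affective"),
# resolving label switching after a fit
.relabel_states <- function(params, spec) {
  N <- spec$n_states
  if (N == 1L) return(params)
  ord <- order(params$pis)
  if (identical(ord, seq_len(N))) return(params)
  params$pis <- params$pis[ord]
  perm_G <- function(G) G[ord, ord, drop = FALSE]
  perm_d <- function(d) d[ord]
  if (!is.null(params$Gamma)) {
    params$Gamma <- if (is.list(params$Gamma)) lapply(params$Gamma, perm_G)
                    else perm_G(params$Gamma)
  }
  if (!is.null(params$beta)) {
    # swapping the two state labels swaps the 1->2 and 2->1 coefficient rows
    perm_b <- function(B) { B2 <- B[c(2L, 1L), , drop = FALSE]; rownames(B2) <- rownames(B); B2 }
    params$beta <- if (is.list(params$beta)) lapply(params$beta, perm_b)
                   else perm_b(params$beta)
  }
  if (!is.null(params$delta)) {
    params$delta <- if (is.list(params$delta)) lapply(params$delta, perm_d)
                    else perm_d(params$delta)
  }
  params
}
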