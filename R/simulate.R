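# Synthetic session generator emulating the structure of the study's
# review-consultation data: 44 short binary series with empirical length
# frequencies, two clinicians, type-dependent skewed durations.

#' Empirical session-length frequency table
#'
#' The observed frequencies of session lengths (number of reassurances per
#' session) across the 44 recorded first sessions: lengths range from 3 to
#' 37 with mode 13.  Used as the default sampling distribution for
#' synthetic session lengths.  (The listed sizes total 480 reassurances,
#' slightly below the 483 reported for the pooled sample; the table is
#' nevertheless taken as the length distribution.)
#'
#' @return data.frame with columns `size` and `freq` (frequencies summing
#'   to 44).
#' @export
empirical_length_table <- function() {
  data.frame(
    size = c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 12L, 13L, 14L, 15L, 16L,
             18L, 19L, 26L, 37L),
    freq = c(3L, 4L, 2L, 1L, 3L, 3L, 5L, 4L, 4L, 6L, 1L, 1L, 1L, 1L, 3L,
             1L, 1L))
}

#' Draw session lengths from the empirical length distribution
#'
#' @param n number of lengths to draw.
#' @param seed optional seed (caller's RNG state is preserved).
#' @return Integer vector of lengths, each one of the observed sizes.
#' @export
sample_session_lengths <- function(n, seed = NULL) {
  tab <- empirical_length_table()
  .with_seed(seed,
             sample(tab$size, n, replace = TRUE, prob = tab$freq / sum(tab$freq)))
}

#' Configuration for the synthetic session generator
#'
#' Defaults reproduce the study conditions: 44 sessions with lengths drawn
#' from the empirical length table, a homogeneous 2-state generating chain
#' at the published baseline estimates (transition rows (0.735, 0.265) and
#' (0.169, 0.831); emission probabilities 0.209 and 0.782, giving a
#' long-run cognitive share near 56%), log-normal durations whose location
#' is higher for cognitive than affective reassurances (cognitive
#' utterances carry more verbal content), a coin-flip positive-response
#' probability and an even clinician split.
#'
#' @param n_sessions number of sessions to generate.
#' @param lengths `"empirical"` (default: draw from
#'   [empirical_length_table()]) or an explicit integer vector of lengths
#'   (recycled to `n_sessions`).
#' @param spec generating [model_spec()].
#' @param params natural parameters of the generating model (see
#'   [pack_parameters()] for the layout).
#' @param duration_meanlog named numeric `c(affective = , cognitive = )`
#'   log-scale locations of the duration distributions (log seconds).
#' @param duration_sdlog common log-scale spread of durations.
#' @param response_prob probability of a positive patient response; a
#'   length-2 vector makes it depend on the latent state.
#' @param clinician_probs probabilities of assigning a session to
#'   clinicians 1 and 2.
#' @param seed optional integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sessions = 44L,
                             lengths = "empirical",
                             spec = model_spec(2),
                             params = list(
                               Gamma = matrix(c(0.735, 0.265,
                                                0.169, 0.831),
                                              nrow = 2, byrow = TRUE),
                               pis = c(0.209, 0.782)),
                             duration_meanlog = c(affective = 1.2,
                                                  cognitive = 2.0),
                             duration_sdlog = 0.8,
                             response_prob = 0.5,
                             clinician_probs = c(0.5, 0.5),
                             seed = NULL) {
  n_sessions <- as.integer(n_sessions)
  if (n_sessions < 1L) stop("n_sessions must be >= 1")
  if (!identical(lengths, "empirical")) {
    lengths <- as.integer(lengths)
    if (any(lengths < 1L)) stop("session lengths must be >= 1")
  }
  if (duration_sdlog <= 0) stop("duration_sdlog must be positive")
  if (length(duration_meanlog) != 2L)
    stop("duration_meanlog must give affective and cognitive locations")
  if (!length(response_prob) %in% 1:2 ||
      any(response_prob < 0 | response_prob > 1))
    stop("response_prob must be 1 or 2 probabilities")
  if (length(clinician_probs) != 2L || any(clinician_probs < 0) ||
      sum(clinician_probs) <= 0)
    stop("clinician_probs must be 2 nonnegative weights")
  structure(list(n_sessions = n_sessions, lengths = lengths, spec = spec,
                 params = params, duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 response_prob = response_prob,
                 clinician_probs = clinician_probs / sum(clinician_probs),
                 seed = seed),
            class = "generator_config")
}

# simulate one session; covariate-driven generators close the feedback
# loop: the transition into position t is computed from the covariates
# simulated at position t-1 before the new state is drawn
.simulate_session <- function(id, n, config) {
  spec <- config$spec
  params <- config$params
  N <- spec$n_states
  cid <- sample(1:2, 1, prob = config$clinician_probs)
  ing <- .session_ingredients(
    structure(list(clinician_id = cid), class = "session_series"),
    params, spec)
  pis <- ing$pis
  rp <- config$response_prob
  if (length(rp) == 1L) rp <- rep(rp, N)

  states <- integer(n); obs <- integer(n)
  dur <- numeric(n); resp <- integer(n); rdur <- numeric(n)
  draw_step <- function(s) {
    x <- rbinom(1, 1, pis[s])
    ml <- if (x == 1) config$duration_meanlog[["cognitive"]]
          else config$duration_meanlog[["affective"]]
    list(x = x,
         dur = rlnorm(1, ml, config$duration_sdlog),
         resp = rbinom(1, 1, rp[s]),
         rdur = rlnorm(1, 0.8, config$duration_sdlog))
  }
  states[1] <- sample(seq_len(N), 1, prob = ing$delta)
  st <- draw_step(states[1])
  obs[1] <- st$x; dur[1] <- st$dur; resp[1] <- st$resp; rdur[1] <- st$rdur
  if (n > 1L) for (t in 2:n) {
    G <- if (ing$inhom) {
      z <- c(1, vapply(spec$covariates, function(cv)
        switch(cv, response_type = resp[t - 1L],
               log_dopr = log(dur[t - 1L])), numeric(1)))
      transition_matrix_at(ing$beta, z)
    } else ing$Gamma
    states[t] <- sample(seq_len(N), 1, prob = G[states[t - 1L], ])
    st <- draw_step(states[t])
    obs[t] <- st$x; dur[t] <- st$dur; resp[t] <- st$resp; rdur[t] <- st$rdur
  }
  ss <- session_series(id, obs, durations = dur, response_types = resp,
                       response_durations = rdur, clinician_id = cid)
  attr(ss, "states") <- states
  ss
}

#' Simulate a collection of reassurance sessions
#'
#' Draws each session's clinician, length and initial latent state, then
#' alternates state transitions and emissions; durations and patient
#' responses are simulated alongside so lagged covariates exist for every
#' transition.  When the generating model itself has covariates, the
#' transition matrix entering position t is computed from the covariates
#' simulated at t-1 (closed feedback loop).  The generated latent state
#' paths are kept as the `"states"` attribute of each session for oracle
#' testing but are not part of the exported CSV schema.
#'
#' @param config a [generator_config()].
#' @return List of [session_series()] objects (with hidden `"states"`
#'   attributes); deterministic given `config$seed`.
#' @export
simulate_collection <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("config must be a generator_config")
  .with_seed(config$seed, {
    lens <- if (identical(config$lengths, "empirical"))
      sample_session_lengths(config$n_sessions)
    else rep_len(config$lengths, config$n_sessions)
    lapply(seq_len(config$n_sessions), function(i)
      .simulate_session(sprintf("S%03d", i), lens[i], config))
  })
}

#' True latent state paths of a simulated collection
#'
#' @param collection result of [simulate_collection()].
#' @return data.frame `session_id`, `position`, `true_state`.
#' @export
true_states <- function(collection) {
  rows <- lapply(collection, function(s) {
    st <- attr(s, "states")
    if (is.null(st)) stop("collection carries no latent states")
    data.frame(session_id = s$session_id, position = seq_along(st),
               true_state = st, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
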