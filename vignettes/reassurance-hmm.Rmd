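---
title: "Hidden Markov models for clinician reassurance sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden Markov models for clinician reassurance sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reassureHMM)
```

## The problem and the model

During review consultations, clinicians repeatedly reassure their patients,
and each reassurance can be classified as *cognitive* (information-giving,
coded 1) or *affective* (directly addressing the patient's emotion, coded
0). A consultation therefore yields a short binary time series — typically
between 3 and 37 reassurances — and a study yields a collection of such
series, one per session, each held by one of a small number of clinicians.
Bouts of cognitive reassurances tend to be followed by bouts of affective
ones, which motivates a latent-state model rather than independent coin
flips.

`reassureHMM` models each session as a Bernoulli-emission hidden Markov
model. A latent state process $S_t \in \{1, \dots, N\}$ follows a Markov
chain with transition probability matrix (t.p.m.)
$\Gamma = (\gamma_{ij})$, $\gamma_{ij} = \Pr(S_t = j \mid S_{t-1} = i)$,
rows summing to one. Conditional on the state, the observed reassurance
type is Bernoulli:

$$X_t \mid S_t = i \sim \mathrm{Bernoulli}(\pi_i),$$

with a per-state probability $\pi_i$ of a cognitive reassurance. The
session likelihood is the matrix product

$$\mathcal{L}(\theta \mid x_1, \dots, x_n) =
  \delta P(x_1)\, \Gamma P(x_2) \cdots \Gamma P(x_n)\, \mathbf{1},$$

where $P(x)$ is the diagonal matrix of state-conditional probability
masses and $\delta$ the initial state distribution. Sessions are assumed
independent (each involves a different patient), so the joint
log-likelihood is the sum of the per-session log-likelihoods, maximised
jointly.

For a homogeneous chain the initial law is taken to be the stationary
distribution, obtained by solving
$\delta (I_N - \Gamma + U) = \mathbf{1}'$ with $U$ a matrix of ones
(`stationary_distribution()`); for $N = 2$ this is
$(\gamma_{21}, \gamma_{12}) / (\gamma_{12} + \gamma_{21})$.

### Covariates and fixed effects

External variables are allowed to act on the *transitions*, not on the
state-dependent distributions, through an inverse-logit link:

$$\gamma^t_{12} = \mathrm{logit}^{-1}(\beta_1' z_t), \qquad
  \gamma^t_{21} = \mathrm{logit}^{-1}(\beta_2' z_t),$$

with $z_t' = (1, z_{1,t}, \dots, z_{k,t})$. Two covariates are supported,
both *lagged*: the patient response type at the previous reassurance
(`response_type`) and the natural log of the duration of the previous
reassurance (`log_dopr`). The transition into position $t$ uses covariates
measured at $t-1$, so every transition has a covariate observation and
nothing is needed before the first position. Because a covariate-driven
chain is no longer homogeneous, $\delta_1$ becomes a free parameter
(`initial = "estimated"`).

Clinician fixed effects replace the single transition structure with one
full set per clinician — two t.p.m.s for the baseline model, two $\beta$
matrices for covariate models — selected by the session's clinician ID,
with per-clinician initial distributions estimated separately. Emission
probabilities stay shared.

The independent mixture special case (`mixture = TRUE`) constrains every
row of the t.p.m. to equal the initial law, removing the serial
dependence; it serves as the "no memory" reference in model comparison,
with 3 free parameters (one mixing weight, two emission probabilities).

## Estimation

All parameters are transformed to an unconstrained working scale
(`pack_parameters()`): probabilities through the logit, t.p.m. rows for
$N \ge 3$ through a multinomial-logit normalisation against the diagonal
entry (which reduces to the logit at $N = 2$), and $\beta$ unchanged. The
joint negative log-likelihood is minimised with the Newton-type optimiser
`stats::nlm()`. Short series produce multimodal likelihoods, so `fit_hmm()`
takes the best of `n_restarts` (default 10) random initialisations —
probabilities uniform on (0.1, 0.9), $\beta$ intercepts the logit of such
a draw, slopes uniform on (−1, 1) — plus a deterministic moment-based
start and any user-supplied warm starts. A warm start built from a fitted
baseline with zero slopes makes the nested-model dominance
$\mathrm{nllk}_{\text{covariate}} \le \mathrm{nllk}_{\text{baseline}}$
hold by construction.

After optimisation, states are relabelled so $\pi_1 < \pi_2 < \dots$:
state 1 is the "dominantly affective" state and state 2 the "dominantly
cognitive" one. This fixes the label-switching invariance of the HMM
likelihood with a single documented convention.

Model comparison uses $\mathrm{AIC} = -2\log\ell + 2p$ (`aic()`,
`compare_models()`), where $p$ is the length of the working vector
(`count_parameters()`): $N(N-1) + N$ for the stationary $N$-state
baseline, $2 + 2(k+1) + 1$ for a 2-state model with $k$ covariates,
doubled transition/initial blocks under fixed effects. For the
fixed-effects baseline both conventions are available: stationary
per-clinician chains ($p = 6$) or separately estimated per-clinician
initial laws ($p = 8$); `candidate_model_set()` uses the latter,
consistent with estimating initial distributions separately whenever they
are free.

### Confidence intervals

`confidence_intervals()` computes 95% Wald intervals from the inverse of
the finite-difference Hessian of the negative log-likelihood at the
optimum, on the working scale. Probability-type bounds are
back-transformed through the inverse logit — hence asymmetric about the
estimate and always inside (0, 1) — while $\beta$ bounds are symmetric on
their own scale. With few latent switches these intervals can be very
wide, and effectively saturated transitions produce enormous $|\beta|$
with correspondingly enormous intervals; estimates with $|\beta| > 50$ are
flagged rather than truncated. A singular Hessian falls back to the
Moore–Penrose pseudo-inverse with an explicit warning.

## Decoding and profiles

`viterbi()` computes the single most probable state path per session
(global decoding) by dynamic programming in log space, supporting
time-varying transition matrices; exact ties break toward the lower state
index at every backtracking step, a deterministic convention. The decoded
path's log-score never exceeds the session log-likelihood.

`covariate_profile()` fixes a covariate at each grid value, treats the
chain as homogeneous at that level, and reports the hypothetical
$\gamma_{12}$, $\gamma_{21}$ and stationary distribution — the standard
way to visualise, e.g., how a longer previous reassurance makes both
states more persistent (negative slopes push both switching probabilities
down).

## The synthetic generator

The original consultation recordings are not distributable, so
`simulate_collection()` generates collections with the same statistical
skeleton for testing and calibration studies. Defaults encode the study
conditions: 44 sessions; lengths drawn from the observed length
frequencies (`empirical_length_table()`, sizes 3–37; the listed sizes
total 480 reassurances against a stated pooled 483 — the table is used as
the sampling distribution and the mismatch merely noted); a homogeneous
2-state generating chain at the published baseline estimates
$\hat\Gamma = \begin{pmatrix} 0.735 & 0.265 \\ 0.169 & 0.831
\end{pmatrix}$, $\hat\pi = (0.209, 0.782)$, which implies a long-run
cognitive share $\sum_i \delta_i \pi_i \approx 0.559$; an even clinician
split; and a coin-flip positive-response probability.

Durations are log-normal per reassurance type. No distributional form is
observable from the published summaries beyond heavy right skew and
cognitive reassurances lasting longer than affective ones, so the
log-normal with locations 2.0 (cognitive) and 1.2 (affective) log-seconds
and common scale 0.8 was chosen once as a realistic skewed model with the
right ordering; all of this is overridable in `generator_config()`. When
the generating model itself has covariates, the generator closes the
feedback loop: the transition matrix entering position $t$ is computed
from the covariates simulated at $t-1$ before the new state is drawn.
True latent paths are retained as an attribute (and via `true_states()`)
for oracle testing, but are not part of the exported CSV schema, mirroring
real data.

What passing tests on this generator do *not* show: the generator assumes
exact Bernoulli emissions, independent sessions, log-normal durations and
a response process unrelated to anything unmodelled. Real consultations
may violate any of these (session-to-session clinician carry-over,
duration distributions with different tails, coder disagreement), so
recovery and coverage results here validate the *estimator*, not the
substantive model for any particular data set.

## Numerical choices

* Row-stochasticity, simplex and stationarity checks use a tolerance of
  1e-10; the pack/unpack round trip is exact to the same tolerance.
* The forward recursion rescales at every step and accumulates the log
  normalisers, so session length never threatens underflow (even though
  the longest realistic session, 37, would rarely underflow raw products).
* The inverse logit is `stats::plogis()`, which saturates cleanly for
  linear predictors of any magnitude (the fitted $\hat\beta_{1,\cdot}$ can
  be in the hundreds).
* The optimizer's working vector is clamped to ±35 before the
  natural-scale round trip: beyond roughly ±37 the inverse logit rounds to
  exactly 0/1 in double precision, which would make a numerically
  saturated optimum unrepresentable on the natural scale.
* Sessions of length 1 and 2 are accepted (a length-1 session contributes
  $\delta P(x_1) \mathbf{1}$), although observed sessions start at length 3.
* Covariates are not centred or standardised, so fitted $\beta$ magnitudes
  are directly comparable with intercept-scale intuition; only
  monotonicity matters for the link.
* All randomness (restarts, generator) flows through explicit seeds, and
  seeded routines restore the caller's RNG state.

## Test problem sizes

The test suite validates the forward likelihood and Viterbi against
exhaustive enumeration over all $N^n$ paths (200 random instances each,
$n \le 10$), stationarity on 1000 random matrices, parameter recovery at
300 sessions × length 20, AIC model recovery on 20 replicates of 150
sessions × length 15 with strong state contrast ($\pi = (0.1, 0.9)$,
diagonal 0.8), and 95% interval coverage for $\pi_1$ over 200 replicates
of 100 sessions × length 20. These sizes give Monte-Carlo error small
enough for the stated tolerances while keeping the default run fast on a
single core.

## Known limitations

* Covariates and fixed effects are implemented for 2-state chains (the
  model family of interest); baselines support any $N$.
* For $N \ge 3$, multinomial-logit transition coordinates are reported on
  the working scale in the CI table (no scalar back-transform exists per
  coordinate).
* No forward–backward smoothing, EM estimation, bootstrap intervals or
  formal tests on $\beta$; model choice is by AIC only.
* Wald intervals rely on asymptotic normality on the working scale, a
  rough approximation when latent switches are few — exactly the regime
  short sessions produce; the reported widths make this visible.
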