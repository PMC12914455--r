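---
title: "Methods: from coded caregiver signals to FIML regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from coded caregiver signals to FIML regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predyad)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic generators do and
do not emulate, and where the genuinely open decisions were made.

## 1. Caregiver signal entropy

Micro-coded caregiver behavior arrives as on/off intervals of three signal
modalities — auditory, visual, tactile. At any instant the caregiver
occupies a *composite state*: the subset of modalities currently active,
one of 8 states including "no signal". Every change of that subset is a
transition, so the coded session induces a sequence with no
self-transitions by construction.

Predictability is the plug-in conditional Shannon entropy of that
sequence, in bits per transition,
$$H = -\sum_i \hat\pi_i \sum_j \hat P(j\mid i)\log_2 \hat P(j\mid i),$$
with $\hat P$ the row-normalized transition counts and $\hat\pi$ the
empirical *source-state* frequencies. Choices worth stating:

* **Base 2.** Entropies land on a 0–3 bit scale over at most 8 states,
  the range in which session-level values around 0.1–1.7 bits are
  interpretable.
* **The empty set is a state.** Transitions into and out of silence are
  informative; dropping them would understate the structure of pause-heavy
  interactions. A leading no-signal segment of positive length is included
  by default (`include_leading = TRUE`), so session boundaries are handled
  deterministically; both conventions are exposed because coding
  conventions differ between labs.
* **Empirical $\hat\pi$, not the stationary distribution.** Five-minute
  sessions are far from asymptopia; weighting rows by how often they were
  actually the source matches what a plug-in estimator can honestly claim.
* **No smoothing.** Unobserved transitions contribute zero. A
  `pseudocount` argument exists but defaults off: smoothing changes the
  estimand, and the consistency tests document the plug-in behavior.

The estimator satisfies $0 \le H \le \log_2 k$ for $k$ observed states, is
invariant to state relabeling, and converges to the chain's closed-form
entropy rate (computed independently from the stationary distribution by
`markov_entropy_rate()`) as sequences grow — the test suite checks the
error shrinks through $10^2, 10^3, 10^4$ transitions. Sampling error of
the plug-in estimate at $10^4$ transitions is a few hundredths of a bit
for dense transition matrices, and noticeably larger for near-degenerate
rows (probabilities close to 0 or 1 inflate the variance of row
entropies); the acceptance suite therefore checks the 0.02-bit agreement
bound on random dense chains.

Coding reliability uses 1-s bins: per modality, raw agreement is the
percentage of bins on which two coders agree about presence, and Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$ uses chance agreement from the coders'
marginal bin rates. Modalities absent from both logs are excluded from the
averages — they say nothing about the coders — and $\kappa := 1$ when
observed agreement is exactly 1. These conventions make the degenerate
cases (identical logs; one empty log) behave sensibly.

## 2. Baseline heart-rate variability

RMSSD is computed **on the beat-domain IBI sequence**, not on the 100 Hz
interpolated tachogram. A successive-difference statistic is defined over
beats; resampling to a uniform grid first would replace true beat-to-beat
differences with interpolation increments and systematically shrink them.
The uniform-grid signal (`interpolate_to_grid()`, default 100 Hz, linear
with held endpoints) is still produced, because spectral extensions need
it. This is the one place the package deliberately resolves an ambiguity
in common processing descriptions; the grid route remains available to
anyone who wants the alternative.

Artifact handling is rule-based and conservative: IBIs outside
configurable physiologic bounds (default 250–1000 ms) and successive jumps
above 200 ms are flagged and, on request, replaced by linear interpolation
(`clean_ibi()`). Manual beat editing is out of scope. Winsorization of
RMSSD at the 5th/95th percentiles is a **cohort-level** operation (it
exists to tame between-infant outliers), uses type-7 linear interpolation
between order statistics for reproducibility, and is exactly idempotent
only when the cut points land on order statistics — a property the tests
exercise at n = 101 rather than overclaim in general. Recordings shorter
than 60 s are flagged unusable rather than silently scored.

## 3. Heart-rate-defined sustained attention

The detector follows the 5-beat run rule: outside SA it keeps a rolling
baseline of the 5 most recent IBIs; a run of 5 consecutive IBIs each
**strictly** above the baseline median, whose first beat falls inside a
looking interval, opens a phase at that first beat; inside SA, a run of 5
consecutive IBIs each strictly below the median of the 5 immediately
preceding closes the phase at the run's first beat. Decisions the rule
text leaves open, and how they are fixed here:

* **Ties break toward not changing state** (strict inequalities): the
  conservative reading, so flat stretches never trigger phantom
  transitions.
* **Phase timestamps at the run's first beat**, for both onset and
  offset, so the triggering runs are inside the phase and every emitted
  phase can be *replayed*: each phase records its trigger beat index and
  baseline median, and `replay_sa_onsets()` re-evaluates the rule against
  the stored values. The acceptance suite replays 100 constructed
  fixtures.
* **Looking is required only at onset.** Termination is governed by the
  heart-rate criterion; `require_looking_throughout = TRUE` closes phases
  at look-aways for labs that prefer the stricter convention.
* **Baseline re-seeding** after termination uses the 5 beats immediately
  following the phase offset, the simplest reading of "reset".

Total SA duration and the deceleration score — mean IBI across beats in SA
phases minus mean IBI in the 5 s before stimulus onset, positive = slower
heart — follow directly. An infant with no SA phase gets a **missing**
deceleration, propagated to the statistics stage, never a zero. SA and
inattention phases tile the task window exactly, which is what lets the
EEG stage label every segment.

One behavior of the rule is worth knowing: on stationary noise it still
spends time in "SA", because symmetric fluctuations eventually produce
qualifying runs; the run-length rule is scale-free. Detection is specific
in practice because the looking conjunction gates onsets — which is also
how the synthetic pipeline couples gaze to its planted decelerations.

## 4. Relative frontal theta

Each 1-s segment is Hann-windowed per channel and decomposed by FFT into
1 Hz bins; one-sided power is normalized so the bins sum to the windowed
time-domain energy (Parseval, tested to 1e-6). Relative theta divides
summed 4–6 Hz power by summed 1–50 Hz power — inclusive bin conventions at
both edges, configurable, because no denominator convention is universal —
per segment per frontal channel, averaged across channels then segments.
The per-segment-ratio ordering is the default because it is robust to
segment-count imbalance between conditions; the ratio-of-averaged-spectra
alternative sits behind `method = "average_spectra"`. Log10 band powers
are kept as auxiliary outputs. The change score is attention minus
inattention; it is antisymmetric under label swap and invariant to channel
rescaling, both tested.

Segment rejection summarizes each segment by its maximum absolute
amplitude over frontal channels and drops segments more than 3 SD from the
median summary; infants retaining fewer than 20 segments yield missing
theta values. Both boundaries (exactly 19 vs 20; a planted 100× outlier)
are tested exactly. Upstream cleaning (filtering, ICA) is assumed done by
the usual preprocessing pipelines and is out of scope here.

## 5. Synthetic dyads: what is emulated

The generators produce data with the statistical structure the analysis
assumes — they are the package's test bed, not a physiological simulator.

* **Caregiver sequences** are continuous-time Markov chains over the 8
  composite states with exponential dwell times (mean 2 s, giving ~150
  transitions in a 5-min session — a plausible coded-event density;
  entropy depends only on transition order, so dwell timing is a free
  parameter). `entropy_matched_matrix()` interpolates between a
  deterministic cycle and the uniform matrix to hit any target entropy
  rate exactly, which is how the pipeline plants per-dyad entropy values
  with mean 0.79 and SD 0.32 bits.
* **IBI series** are baseline + AR(1) jitter ($\phi = 0.3$) + a 0.6 Hz
  respiratory sinusoid, the minimal model with both short-range
  autocorrelation and a vagal-like oscillation. A closed-form mapping sets
  the innovation SD and sinusoid amplitude so the expected sample RMSSD
  equals the target (AR(1): $E[\Delta^2] = 2\sigma^2/(1+\phi)$; sinusoid:
  $E[\Delta^2] = A^2(1 - \cos 2\pi f \bar T)$), recovered within a few
  percent in simulation. Decelerations are step increases in IBI over
  planted epochs. Defaults: 400 ms baseline (~150 bpm), RMSSD target mean
  11.23 / SD 4.65 ms.
* **EEG** is 1/f (pink) noise synthesized per 1-s segment in the frequency
  domain, with 4–6 Hz power multiplied by a gain during attention
  segments — the simplest spectrum against which band-power modulation is
  detectable. Channels are normalized to a fixed RMS; relative power is
  scale-invariant, so this only stabilizes rejection statistics.
* **Cohorts** follow a linear structural model on standardized scales with
  planted standardized effects (defaults −0.24 to −0.26 for the entropy
  paths, +0.25 for HRV→deceleration, 0.1 for each covariate), rescaled
  affinely to familiar units so standardized coefficients are unchanged,
  with independent per-variable MCAR masks at rates drawn from 11–23%.
  Covariates stay complete, as demographics typically are. Configurations
  implying non-positive residual variance error out rather than silently
  truncate.

What the generators do **not** emulate — and hence what passing tests do
not establish about real data: ECG waveform morphology and beat-detection
error; gaze annotation noise (looking is exact by construction); EEG
artifacts with realistic topographies; MAR/MNAR missingness; infant
dropout and fussiness; nonlinear or threshold dose-response shapes. Tests
passing on these generators certify the *measurement and inference chain*,
not any empirical claim about infants.

## 6. FIML and the statistics stage

The FIML estimator maximizes the observed-data multivariate-normal
log-likelihood of (outcome, predictors) over missingness patterns via EM
on the saturated mean/covariance, converging at relative log-likelihood
change 1e-8 (configurable). Regression coefficients come from the fitted
covariance; **standardization uses the FIML-estimated full-sample
variances**, not complete-case SDs, for consistency under missingness.
Standard errors are delta-method transforms of the observed information
(numeric central-difference Hessian of the observed-data log-likelihood in
the saturated parameterization); `fit_robust()` substitutes a sandwich
built from per-case scores. With no missing data the estimator reduces
exactly to OLS, which the tests assert to 1e-6 — and the EM solution is
cross-checked against an independent quasi-Newton maximization of the same
likelihood on a Cholesky parameterization.

Sensitivity checks mirror standard practice: `fit_mice()` uses
normal-linear chained equations (25 imputations, Bayesian draws of
coefficients and residual variance) pooled by the usual combining rules —
normal conditionals rather than predictive-mean matching, so the procedure
is fully determined by its seed; `fit_listwise()` is complete-case OLS.
Little's MCAR test compares pattern-wise means to EM-estimated grand
parameters with $df = \sum_j k_j - p$; under the package's MCAR generator
its rejection rate is at the nominal 5%. Covariate screening applies a
fixed mapping by variable type — Pearson correlation for
continuous-continuous, t test when exactly one variable is binary,
chi-square for categorical pairs — at p < .10. Mean baseline heart rate is
added automatically as a covariate to every pipeline model involving
RMSSD; this lives in the config schema so callers cannot forget it.
p-values are two-sided Wald tests with no multiplicity correction, stated
here deliberately.

The sensitivity analysis inverts the noncentral-F power function of the
single-coefficient test: standardized effect $\beta$ maps to
$f^2 = \beta^2/(1-\beta^2)$, noncentrality $\lambda = n f^2$ on
$F(1, n-k-2)$, assuming the focal predictor and $k$ covariates are
mutually uncorrelated. The Monte-Carlo cross-check simulates exactly that
design (orthogonalized Gaussian predictors of unit variance) so the two
routes estimate the same quantity; at n = 104, α = .05, power .80 and 3
covariates the minimal detectable standardized beta is ≈ 0.267.

## 7. Pipeline, problem sizes, and determinism

`run_pipeline()` draws per-dyad latent effects, simulates each dyad's
inputs, runs the enabled measurement stages, assembles records by outer
join on `dyad_id` (order-invariant, duplicate-rejecting), applies MCAR
masks and cohort-level winsorization, and fits the configured models. All
randomness descends from one root seed through recorded per-stage derived
seeds; written outputs are byte-identical across runs with the same
config. Every missing cell the pipeline creates carries a machine-readable
exclusion reason (no SA phase, too few EEG segments, MCAR mask, short
recording), so input dyads always equal analyzed-plus-excluded.

Validation problem sizes, chosen to exercise the asymptotics the claims
rely on while keeping the default suite fast: entropy consistency at
$10^2$–$10^4$ transitions and 20 dense chains at $10^4$; RMSSD recovery
over 50 seeds of 300-s recordings; deceleration recovery (+20 ms planted,
±5 ms tolerance) over 50 seeds; FIML bias/coverage and Little's-test
calibration over 200 cohorts of n = 104 with 11–23% MCAR; end-to-end
recovery of a planted entropy→HRV effect of −0.25 over 100 seeded runs of
n = 500 dyads with the entropy, HRV and stats stages enabled (the planted
effect flows through exactly those stages; the EEG stage is validated
separately at smaller scale because synthesizing 64-channel task-length
EEG per dyad dominates runtime without adding information about this
effect). Measured-variable attenuation — estimation noise in entropy and
RMSSD — shrinks the planted −0.25 to about −0.17 at the measured level,
which n = 500 detects with high power.

## 8. Known limitations

* The FIML engine assumes joint normality; binary sex enters as a numeric
  regressor, standard in this literature but still an approximation, and
  heavy-tailed outcomes are only partially protected by winsorization and
  robust SEs.
* The SA detector's behavior on stationary noise (Section 3) means SA
  *duration* on noise-only data is not zero; duration comparisons are
  meaningful relative to a looking-gated baseline, which is how the
  pipeline uses them.
* Numeric-Hessian standard errors cost $O(d^2)$ likelihood evaluations
  ($d = p + p(p+1)/2$); fits stay sub-second for the model sizes here but
  grow quickly with many predictors.
* Entropy at 5-min session lengths (~150 transitions) is estimated with
  visible downward bias for 8-state spaces; the pipeline treats it as a
  measured variable (attenuation, not bias in the planted direction), and
  k > 1 Markov orders are out of scope.
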