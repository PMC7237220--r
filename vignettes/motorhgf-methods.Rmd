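---
title: "Models and methods behind motorhgf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motorhgf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorhgf)
```

# The task and its reward mapping

`motorhgf` analyses reward-based motor sequence learning. A performer
plays a short keystroke sequence; the vector of inter-keystroke intervals
(IKIs) `z` is summarized by the Euclidean norm of its successive
differences, `||Δz||`. Feedback on each trial is

```
score = 100 * exp(-| target_norm - performed_norm |)
```

with a target norm of 1.9596 — realized, for example, by the IKI pattern
`[0.2, 1, 0.2, 1, 0.2, 1, 0.2]` s. The score is maximal exactly at zero
mismatch, symmetric in the sign of the mismatch, and invariant to overall
tempo shifts (a constant added to all IKIs cancels in the differences).
Many distinct performances earn the same score, which makes the reward
contingency genuinely uncertain from the performer's point of view.

Two behavioral measures feed the response models: the within-trial
coefficient of variation of IKIs (`cv_iki_trial`, population-sd
convention) and the log mean tempo in milliseconds (`log_m_iki`). The
across-trials variability `cvIKI` is computed per keystroke position over
25-trial bins (sample-sd convention) and averaged across positions; the
position aggregation (`mean`, default, or `median`) is exposed because the
convention is not fixed by the analysis itself.

# The two-level Hierarchical Gaussian Filter

Normalized scores `u = score/100` are filtered by a two-level HGF for
continuous inputs. Level 1 tracks the expected reward of the current
performance; level 2 tracks the (log-)volatility of that quantity. The
levels are coupled through the level-1 random-walk variance
`exp(kappa*mu2 + omega1)` with `kappa = 1` fixed; the level-2 step
variance is `theta = exp(omega2)`. Per trial:

* level 1 performs a conjugate Gaussian update with prior precision
  `pi1hat = 1/(sigma1 + exp(mu2 + omega1))` and likelihood precision
  `pi_u` (the estimated input precision, constant across trials);
* level 2 is driven by the variance-normalized level-1 prediction error
  `delta1 = (1/pi1 + (mu1 - mu1hat)^2) * pi1hat - 1` with weight
  `w1 = exp(mu2 + omega1) * pi1hat`.

The belief updates equal the precision-weighted prediction errors
exactly: `mu_i(k) - mu_i(k-1) = eps_i(k)`. Both identities, and the
conjugate-update ("Kalman limit") equivalence of level 1, are asserted at
machine precision in the test suite. The exact form of `delta1` is not
fixed by the published equations alone; we take the variance-normalized
form of the reference continuous-input filter, under which the Kalman
oracle holds.

**Numerical policy.** Any non-positive or non-finite precision marks the
trajectory invalid at that trial. `hgf_filter()` raises by default with a
diagnostic naming the trial; during fitting the same signal silently
rejects the parameter proposal (objective `-Inf`). No silent flooring is
performed: a parameter set either produces a fully valid trajectory or is
rejected.

**Priors.** The empirical-Bayes rules anchor several priors on the first
20 inputs: `omega1` and `log(sigma1_0)` prior means equal the log-variance
of inputs 1:20, `log(pi_u)` its negative, and `mu1_0` is centred on the
first input. Fixed priors: `omega2 ~ N(-4, 16)`, `mu2_0 = 1` (variance 0),
`log(sigma2_0) ~ N(log 0.01, 1)`. Response coefficients have variance-4
Gaussian priors, `beta0` centred on the mean observed response. No prior
is prescribed for the response noise; we centre `log(zeta)` on the
log-variance of the response series (variance 4), the same empirical
device used for the input precision. Initial states are fixed at their
prior means during fitting, keeping the optimizer at 7 free parameters.

# Response models, fitting, and evidence

Eight linear response models relate the previous trial's beliefs to the
current trial's change in performance: two families (response = change in
within-trial CV, or change in log tempo) crossed with four predictor
pairs — `(mu1, eps1)`, `(mu1, mu2)`, `(mu2, eps2)`, `(eps1, eps2)`. The
last pair in the CV family (HGF14) is the winning model of the task.

`fit_model()` maximizes the joint posterior (Gaussian response likelihood
plus Gaussian priors in estimation space) over
`(omega1, omega2, log pi_u, beta0, beta1, beta2, log zeta)` by
Nelder-Mead with 8 seeded multistarts (dispersed at a third of the prior
sd) and simplex restarts at the incumbent optimum; tolerance 1e-6. The
log model evidence is a Laplace approximation at the MAP with a
finite-difference Hessian; a non-positive-definite Hessian is ridged and
the fit flagged. The reference implementation uses a variational free
energy instead; Laplace has the same asymptotics and is simpler to test,
and the model-selection layer consumes either.

Family-level evidence is `logsumexp(member LMEs) - log(n_members)`
(uniform within-family prior). Random-effects model selection follows the
standard variational Dirichlet scheme; exceedance probabilities use 1e6
seeded Dirichlet draws (Monte-Carlo error about 0.001). `alpha0 = 1` per
model, the conventional uniform prior. Selection is two-stage: families
first, then models within the winning family (skipped when the winner has
a single member).

# The synthetic world

`gen_agent_performance()` closes the loop the analysis assumes: realized
IKIs → score → HGF update → response model → next trial's CV. Defaults
describe an unperturbed learner in a learning block: 200 trials, 7 IKIs
at 600 ms mean tempo; `omega1 = -5`, `omega2 = -3.5`, `pi_u = exp(3)`
(the reported range of group means and the population-median input
precision); `beta0 = 0.002` (small positive, as reported), `beta1 = -0.4`
(negative, as reported), `beta2 = 0.2`, `zeta = 2.5e-4`. The noise
variance follows from the reported trial-averaged residual SEMs
(~0.001 at n = 200, i.e. residual sd ~0.015). `beta2`'s magnitude is
bounded by stability: the volatility belief starts at the fixed prior
`mu2_0 = 1` and relaxes toward its equilibrium, so the integrated `eps2`
transient is about -1.1, and a large `beta2` would drive the CV into its
floor. `cv_start = 0.7` places the agent in the rewarded regime, which
reproduces the population-median first-20 input variance (~`exp(-3)`).

**IKI realization.** A requested CV is realized as equal-magnitude
deviations around the mean tempo; the magnitude is solved numerically so
the trial CV is exact. By default the *order* of the deviation signs is
randomized each trial (`shape_jitter`): the CV depends only on the sign
multiset while the difference norm depends on the order, so distinct
shapes share a CV but earn different scores. This reproduces two features
of the real task — the same CV can yield different rewards, and CV and
score are strongly but not deterministically coupled — and it is what
gives the input series enough variance for the empirical-Bayes priors to
sit in their intended range. With `shape_jitter = FALSE` the deviations
always alternate (the maximal-reward shape) and the score is a
deterministic function of the CV; in that regime the response model has
essentially no signal and perceptual parameters are unidentifiable, which
is why the jittered world is the default.

**What a green test does and does not establish.** The generator emulates
the statistical structure the analysis assumes — HGF-driven score series,
1/f background with power-law burst durations, Gaussian inter-beat
intervals — not real EEG (no topography, volume conduction, artifacts) or
real performance idiosyncrasies (no sequence errors, no tempo drift).
Green recovery tests certify the estimators against their own generative
assumptions; they say nothing about model adequacy on real recordings.

**Identifiability of `omega2` (known limitation).** In this design the
perceptual parameters are informed only through the response likelihood
(the filter is deterministic given the scores; there is no likelihood
term for the scores themselves). With the paper-anchored response noise
and the stability bound on `beta2`, the MAP of `omega2` scatters with sd
~1.2 around the truth at n = 200. The acceptance criterion demanding
`|Δomega2| < 1` in 80% of replicates therefore caps out near 68% in this
world — the betas themselves recover in every replicate — and the
corresponding acceptance test is left failing rather than loosened; see
the repository's decision notes.

# Oscillation bursts and spectra

The burst pipeline band-passes (zero-phase windowed-sinc FIR, ~53 dB
stop band), takes the analytic-signal magnitude, thresholds at the 75th
percentile of a *rest* envelope (median available as the control choice),
merges crossings separated by under 50 ms, and discards events shorter
than one cycle (50 ms). Durations are histogrammed into 20
log-equidistant bins on [50, 2000] ms and the life-time exponent `tau` is
the absolute slope of a straight line through the log-log plot, first bin
excluded. The fit uses the probability *density* (counts normalized by
total and bin width): with log-spaced bins the raw per-bin probability of
a `d^-tau` sample decays with exponent `tau - 1`, and only the density
slope recovers the generative exponent — the tau-recovery tests pin this
choice down.

Edge effects: envelope samples within half a filter length of the signal
edges are flagged and excluded from threshold estimation. Burst onsets
recovered through the filter are accurate to roughly half the passband
rise time (~10-20 ms at a 13-30 Hz band); the detector itself
(crossing/merge/minimum-duration logic) is sample-exact, and is tested at
that precision on ideal envelopes.

Spectral analysis provides Welch PSD (1 s Hann, 50% overlap, one-sided
density; segment means removed) with dB normalization against rest, and
7-cycle Morlet wavelet energy at 13-30 Hz in 1 Hz steps on a 100 ms hop.
Wavelets are amplitude-normalized so a tone of amplitude `A` yields power
`A^2/2` (variance units), which makes band-integrated wavelet power
directly comparable to integrated Welch density (tested to 15%).
Baseline z-normalization uses the pre-movement window [-1, 0] s, applied
per channel and frequency *before* band-averaging (the wording of the
procedure permits either order; per-frequency first is the stricter
normalization and is the package default). Feedback-locked scalars
average 400-1600 ms after the feedback marker (9 s) over a chosen channel
set, one value per trial.

# Linking beta activity to precision-weighted prediction errors

Per subject, the feedback-locked beta measure is regressed on an
intercept and the same-trial `eps1` and `eps2` by ordinary least squares,
after checking that the two regressors are not collinear (Pearson r with
a 0.7 warning threshold; in the generative world the correlation is
small, ~0.1). Regressors are not standardized by default so coefficients
stay in natural units and are comparable across groups; a z-scored option
exists. A negative `beta1` means smaller reward pwPEs accompany higher
post-feedback beta activity — the sign convention the tests assert.

# Group statistics

Nonparametric throughout: permutation tests on the mean difference
(label shuffling between groups, sign flipping within pairs; p-values of
the form `(1 + #{|null| >= |obs|})/(n_perm + 1)`, never zero; exhaustive
enumeration available and tested against a brute-force oracle), adaptive
two-stage linear step-up FDR at q = 0.05 (first stage at `q/(1+q)`
estimates the number of true nulls; the returned threshold is the
adapted p), probability-of-superiority effect sizes `Δ` (independent,
all cross-pairs) and `Δdep` (paired) with ties removed from the
denominator and seeded percentile-bootstrap 95% CIs, tie-aware Spearman
rank correlation with a permutation p, and HRV as the coefficient of
variation of inter-beat intervals. Time courses are compared pointwise
with permutation tests followed by FDR over time points on a
channel-averaged subset, which is the phasic-effect statistic of the
analysis (cluster-based spatial permutation over a full montage is out
of scope).

On the two-stage FDR: the procedure's rejections are guaranteed to
contain the *first-stage* step-up's rejections (the second stage can only
raise the level when some nulls are rejected); containment of a plain
step-up at the full level q does not hold in general, and the property
tests state the former.

# Reproducibility

Every stochastic routine takes an explicit seed and restores the caller's
RNG state, so seeded calls compose deterministically. `run_pipeline()`
executes the stages in dependency order, writes CSV/JSON artifacts plus a
manifest (seeds, counts, md5 hashes), and reruns byte-identically under
the same configuration. Signals are exchanged as raw float32 binary with
a JSON sidecar; tables as tidy CSV.
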