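# motorhgf

Analysis tools for reward-based motor sequence learning experiments, for
researchers studying how trial-wise reward feedback shapes motor
variability and how feedback-locked beta-band (13–30 Hz) activity relates
to belief updating.

In the task this package models, a performer plays a short keystroke
sequence on each trial and receives a score rewarding a *target pattern of
timing differences*: with inter-keystroke intervals `z` and difference
vector `Δz = (z2−z1, …, zn−zn−1)`,

    score = 100 · exp( − | ‖Δz_target‖ − ‖Δz_performed‖ | ),

with target norm 1.9596 (realized e.g. by the IKI pattern
`[0.2, 1, 0.2, 1, 0.2, 1, 0.2]` s). The package implements, end to end:

* **task_scoring** — IKI differences, norms, the reward mapping, within-
  and across-trial coefficients of variation;
* **hgf_perceptual** — a two-level Hierarchical Gaussian Filter for
  continuous inputs (`hgf_filter`), with the empirical-Bayes priors
  anchored on the first 20 scores (`default_priors`) and exact
  precision-weighted prediction-error (pwPE) trajectories;
* **response_models** — the eight linear response models HGF11–HGF24
  mapping previous-trial beliefs (μ1, μ2) and pwPEs (ε1, ε2) to per-trial
  changes in timing variability or tempo; joint MAP fitting with Laplace
  log model evidence (`fit_model`);
* **model_selection** — log family evidence and random-effects Bayesian
  model selection with Dirichlet exceedance probabilities (`rfx_bms`,
  `select_model`);
* **burst_dynamics** — beta-burst detection on the amplitude envelope
  (75th-percentile rest threshold, one-cycle minimum, 50 ms merge gap),
  log-binned duration distributions and the life-time exponent τ;
* **spectral_power** — Welch PSD with dB normalization to rest, 7-cycle
  Morlet time–frequency power with pre-movement baseline z-normalization,
  feedback-locked (400–1600 ms) per-trial measures;
* **neural_linking** — per-subject OLS of feedback-locked beta measures on
  ε1 and ε2;
* **group_stats** — permutation tests (Monte-Carlo and exhaustive),
  adaptive two-stage FDR, probability-of-superiority effect sizes Δ/Δdep
  with bootstrap CIs, Spearman ρ, HRV, pointwise time-course tests;
* **synthetic_data** — closed-loop HGF-driven performers
  (`gen_agent_performance`), 1/f signals with power-law burst injections
  (`gen_burst_signal`), R-peak trains (`gen_rpeaks`) and multi-subject
  group datasets (`gen_group_dataset`), all with exact ground truth;
* **pipeline** — `run_pipeline()` / `validate_inputs()` plus a CLI front
  end in `inst/cli/pipeline.R`.

## Worked example

```r
library(motorhgf)

# a maximally rewarded performance
p <- trial_performance(c(0.2, 1, 0.2, 1, 0.2, 1, 0.2))
cat("norm:", round(performance_norm(p), 4),
    " score:", compute_score(p, 1.9596), "\n")
#> norm: 1.9596  score: 99.99918

# simulate a learner and fit the winning response model
# (Δcv ~ β0 + β1·ε1 + β2·ε2; generative values −0.4 and 0.2)
ap  <- gen_agent_performance(agent_config(n_trials = 200, seed = 42))
fit <- fit_model(ap$u, ap$cv, enumerate_models()$HGF14,
                 options = list(seed = 42))
round(fit$map_params, 4)
#>  omega1  omega2    pi_u   beta0   beta1   beta2    zeta
#> -5.1577 -1.9371 17.1768  0.0037 -0.6023  0.2269  0.0003
cat("log model evidence:", round(fit$lme, 1), "\n")
#> log model evidence: 519.1

# burst life-time exponent of a synthetic beta-band signal
bs  <- gen_burst_signal(burst_signal_config(tau_true = 1.5,
                                            duration_s = 600,
                                            burst_rate_per_s = 0.5,
                                            seed = 7))
env <- band_envelope(bs$signal, bs$fs)
thr <- threshold_from_rest(env, 75)
ev  <- detect_bursts(env, bs$fs, thr)
cat("true tau:", round(duration_distribution(bs$annotations$duration_ms)$tau, 2),
    " detected bursts:", nrow(ev),
    " detected tau:", round(duration_distribution(ev)$tau, 2), "\n")
#> true tau: 1.54  detected bursts: 903  detected tau: 2.26
```

Reading the output: the fitted response coefficients land near their
generative values (β1 −0.60 vs −0.40, β2 0.23 vs 0.20) while ω2 is only
weakly identified from behavior — exactly the pattern quantified in the
acceptance suite. The detected τ exceeds the generative exponent of the
*injected* bursts because a 75th-percentile threshold also harvests brief
noise-driven envelope excursions; the detected distribution, not the
injected one, is the analysis-level quantity (fitting the annotated
ground-truth durations recovers 1.54, close to the generative 1.5).

## Pipeline CLI

```sh
Rscript inst/cli/pipeline.R report --seed 1 --subjects 4 --trials 100 \
        --out /tmp/run1
```

runs simulate → score → fit → select → burst → link → stats on a
synthetic two-group dataset and prints the between-group statistics with
effect sizes; every stage output (tidy CSVs, JSON results, manifest with
seeds and md5 hashes) lands in `--out`.
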