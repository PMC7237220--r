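#' Configuration of a synthetic burst-bearing signal
#'
#' A 1/f background with band-limited oscillation bursts injected at
#' Poisson onsets. Burst durations follow a truncated power law on
#' \[50, 2000\] ms with exponent `tau_true`, the regime observed for
#' beta-band burst life-times.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Signal duration in seconds.
#' @param band Two-element numeric, burst carrier band in Hz (default
#'   13-30, the beta band).
#' @param tau_true Power-law exponent of burst durations, > 1.
#' @param burst_rate_per_s Mean burst onsets per second (>= 0).
#' @param burst_amplitude Burst peak amplitude (a.u.).
#' @param noise_exponent 1/f slope of the background (power ~ f^-exponent).
#' @param noise_amplitude Background sd (a.u.); 0 gives a noiseless signal.
#' @param burst_taper `"hann"` (default) shapes each burst with a Hann
#'   window; `"rect"` keeps full amplitude throughout the burst, which
#'   makes half-amplitude threshold crossings align with the true edges.
#' @param seed Integer seed.
#' @return A `burst_signal_config` list.
#' @export
burst_signal_config <- function(fs = 256, duration_s = 180, band = c(13, 30),
                                tau_true = 1.5, burst_rate_per_s = 2,
                                burst_amplitude = 2, noise_exponent = 1,
                                noise_amplitude = 1,
                                burst_taper = c("hann", "rect"), seed = 1) {
  burst_taper <- match.arg(burst_taper)
  stopifnot(fs > 0, duration_s > 0, length(band) == 2,
            band[1] > 0, band[1] < band[2], band[2] < fs / 2,
            tau_true > 1, burst_rate_per_s >= 0, burst_amplitude >= 0,
            noise_amplitude >= 0)
  structure(list(fs = fs, duration_s = duration_s, band = band,
                 tau_true = tau_true, burst_rate_per_s = burst_rate_per_s,
                 burst_amplitude = burst_amplitude,
                 noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude,
                 burst_taper = burst_taper, seed = as.integer(seed)),
            class = "burst_signal_config")
}

#' Sample burst durations from a truncated power law
#'
#' Inverse-CDF sampling of a truncated Pareto density proportional to
#' `d^-tau` on `[lo, hi]` (milliseconds).
#'
#' @param n Number of samples.
#' @param tau Exponent, > 1.
#' @param lo,hi Truncation bounds in ms (defaults 50 and 2000).
#' @return Numeric vector of durations in ms.
#' @export
rtrunc_powerlaw <- function(n, tau, lo = 50, hi = 2000) {
  stopifnot(tau > 1, lo > 0, hi > lo)
  u <- runif(n)
  e <- 1 - tau
  (lo^e + u * (hi^e - lo^e))^(1 / e)
}

# spectrally shaped Gaussian noise: power ~ f^-exponent, output sd = 1
onef_noise <- function(n, fs, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  X <- fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror to two-sided frequencies
  shape <- c(0, f[-1]^(-exponent / 2))  # kill DC
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a burst-bearing synthetic signal with ground truth
#'
#' @param cfg A [burst_signal_config()].
#' @return A list of class `burst_signal`: `signal` (numeric), `fs`,
#'   `annotations` (data.frame `onset_s`, `duration_ms`, `freq_hz`,
#'   `merged`; merged overlapping bursts are flagged), and `config`.
#' @export
gen_burst_signal <- function(cfg) {
  stopifnot(inherits(cfg, "burst_signal_config"))
  n <- round(cfg$fs * cfg$duration_s)
  with_seed(cfg$seed, {
    x <- if (cfg$noise_amplitude > 0) {
      cfg$noise_amplitude * onef_noise(n, cfg$fs, cfg$noise_exponent)
    } else numeric(n)
    n_burst <- rpois(1, cfg$burst_rate_per_s * cfg$duration_s)
    ann <- data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                      freq_hz = numeric(0), merged = logical(0))
    if (n_burst > 0) {
      onset <- sort(runif(n_burst, 0, cfg$duration_s))
      dur_ms <- rtrunc_powerlaw(n_burst, cfg$tau_true)
      freq <- runif(n_burst, cfg$band[1], cfg$band[2])
      phase <- runif(n_burst, 0, 2 * pi)
      keep <- onset + dur_ms / 1000 <= cfg$duration_s
      onset <- onset[keep]; dur_ms <- dur_ms[keep]
      freq <- freq[keep]; phase <- phase[keep]
      for (b in seq_along(onset)) {
        i0 <- floor(onset[b] * cfg$fs) + 1
        len <- max(2L, round(dur_ms[b] / 1000 * cfg$fs))
        idx <- i0:min(i0 + len - 1, n)
        tt <- (idx - i0) / cfg$fs
        taper <- if (cfg$burst_taper == "hann") {
          0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(idx)))
        } else rep(1, length(idx))
        x[idx] <- x[idx] + cfg$burst_amplitude * taper *
          sin(2 * pi * freq[b] * tt + phase[b])
      }
      ann <- merge_annotations(data.frame(onset_s = onset,
                                          duration_ms = dur_ms,
                                          freq_hz = freq))
    }
    structure(list(signal = x, fs = cfg$fs, annotations = ann, config = cfg),
              class = "burst_signal")
  })
}

# merge overlapping [onset, onset + dur) annotation intervals; merged rows
# flagged; frequency of the first member kept
merge_annotations <- function(ann) {
  if (nrow(ann) < 2) {
    ann$merged <- rep(FALSE, nrow(ann))
    return(ann)
  }
  ann <- ann[order(ann$onset_s), ]
  out <- ann[1, , drop = FALSE]
  out$merged <- FALSE
  for (i in 2:nrow(ann)) {
    last <- nrow(out)
    end_prev <- out$onset_s[last] + out$duration_ms[last] / 1000
    if (ann$onset_s[i] < end_prev) {
      new_end <- max(end_prev, ann$onset_s[i] + ann$duration_ms[i] / 1000)
      out$duration_ms[last] <- (new_end - out$onset_s[last]) * 1000
      out$merged[last] <- TRUE
    } else {
      row <- ann[i, , drop = FALSE]
      row$merged <- FALSE
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

#' Generate a multi-subject group dataset with known ground truth
#'
#' Each group is described by overrides of the agent defaults plus a
#' burst-duration exponent (`tau_true`), heart-rate parameters
#' (`mean_hr_bpm`, `ibi_cv`) and trial-wise feedback-locked link
#' coefficients (`link_beta0`, `link_beta1`, `link_beta2`,
#' `link_noise_sd`). Group differences are injected simply by giving groups
#' different values. Per subject the dataset holds the performance table
#' with scores, the ground-truth HGF trajectory, a sample of burst
#' durations drawn from the group's power law, an R-peak train, and a
#' synthetic feedback-locked beta measure generated from the subject's own
#' pwPE series.
#'
#' @param group_configs Named list (>= 2 groups) of per-group override
#'   lists.
#' @param n_subjects Subjects per group (>= 2), recycled across groups.
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @param n_burst_samples Ground-truth burst durations drawn per subject.
#' @param target_norm Target norm of the reward mapping.
#' @param include_signals If `TRUE`, also synthesize a continuous burst
#'   signal per subject (slower; off by default).
#' @return A `group_dataset` list: `subjects` (data.frame subject, group,
#'   seed), `performance` (long data.frame subject, group, trial, position,
#'   iki_ms, kvel, score), `ground_truth` (per-subject list), `rpeaks`,
#'   `signals` (or `NULL`), `config`.
#' @export
gen_group_dataset <- function(group_configs, n_subjects, seed = 1,
                              n_burst_samples = 1000, target_norm = 1.9596,
                              include_signals = FALSE) {
  if (length(group_configs) < 2) stop("need at least 2 groups")
  if (is.null(names(group_configs)) || any(names(group_configs) == "")) {
    stop("group_configs must be a named list")
  }
  n_subjects <- rep_len(as.integer(n_subjects), length(group_configs))
  if (any(n_subjects < 2)) stop("need at least 2 subjects per group")

  agent_fields <- names(formals(agent_config))
  subj_rows <- list(); perf_rows <- list(); gt <- list()
  rpeaks <- list(); signals <- if (include_signals) list() else NULL
  sid <- 0L
  for (gi in seq_along(group_configs)) {
    gname <- names(group_configs)[gi]
    gcfg <- group_configs[[gi]]
    defaults <- list(tau_true = 1.7, mean_hr_bpm = 70, ibi_cv = 0.05,
                     link_beta0 = 1, link_beta1 = -3, link_beta2 = 0,
                     link_noise_sd = 0.5)
    extra <- modify_defaults(defaults,
                             gcfg[setdiff(names(gcfg), agent_fields)])
    for (si in seq_len(n_subjects[gi])) {
      sid <- sid + 1L
      sseed <- (seed + 7919L * sid) %% .Machine$integer.max
      acfg_args <- gcfg[intersect(names(gcfg), agent_fields)]
      acfg_args$seed <- sseed
      acfg <- do.call(agent_config, acfg_args)
      ap <- gen_agent_performance(acfg, target_norm)
      subject <- sprintf("s%03d", sid)
      perf <- ap$performance
      perf$subject <- subject
      perf$group <- gname
      perf$score <- ap$scores[perf$trial]
      perf_rows[[sid]] <- perf[, c("subject", "group", "trial", "position",
                                   "iki_ms", "kvel", "score")]
      durations <- with_seed(sseed + 1L,
                             rtrunc_powerlaw(n_burst_samples, extra$tau_true))
      beta_measure <- with_seed(sseed + 2L, {
        extra$link_beta0 + extra$link_beta1 * ap$traj$eps1 +
          extra$link_beta2 * ap$traj$eps2 +
          rnorm(length(ap$scores), 0, extra$link_noise_sd)
      })
      gt[[subject]] <- list(group = gname, config = acfg, extra = extra,
                            cv = ap$cv, u = ap$u, traj = ap$traj,
                            clipped = ap$clipped,
                            burst_durations_ms = durations,
                            beta_measure = beta_measure)
      rpeaks[[subject]] <- gen_rpeaks(extra$mean_hr_bpm, extra$ibi_cv,
                                      duration_s = 180, seed = sseed + 3L)
      if (include_signals) {
        scfg <- burst_signal_config(tau_true = extra$tau_true,
                                    seed = sseed + 4L)
        signals[[subject]] <- gen_burst_signal(scfg)
      }
      subj_rows[[sid]] <- data.frame(subject = subject, group = gname,
                                     seed = sseed)
    }
  }
  structure(list(subjects = do.call(rbind, subj_rows),
                 performance = do.call(rbind, perf_rows),
                 ground_truth = gt, rpeaks = rpeaks, signals = signals,
                 config = list(group_configs = group_configs,
                               n_subjects = n_subjects, seed = seed,
                               target_norm = target_norm,
                               n_burst_samples = n_burst_samples)),
            class = "group_dataset")
}
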