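#' Configuration of a simulated HGF-driven performer
#'
#' Describes an agent that performs a short keystroke sequence over many
#' trials, receives a feedback score after each trial, filters the score
#' series with the two-level HGF, and adjusts its within-trial timing
#' variability on the next trial according to the winning response model:
#' `delta cv(k) ~ Normal(beta0 + beta1*eps1(k-1) + beta2*eps2(k-1), zeta)`.
#'
#' Defaults reflect the task's learning blocks (200 trials of an 8-note
#' sequence, i.e. 7 IKIs, mean tempo 600 ms) and perceptual parameters in
#' the range reported for unperturbed performers (omega1 near -5, omega2
#' near -3.5, input precision near exp(3)). The response coefficients are
#' chosen so each regressor's contribution is comparable to the response
#' noise sd (see the methods vignette).
#'
#' @param omega1,omega2 Perceptual parameters (level-1 log-volatility
#'   offset; level-2 step parameter).
#' @param pi_u Input precision, > 0.
#' @param beta0,beta1,beta2 Response coefficients.
#' @param zeta Response noise variance, > 0.
#' @param n_trials Number of trials.
#' @param seq_length Number of IKIs per trial (6 or 7 in the task).
#' @param base_tempo_ms Mean IKI in milliseconds.
#' @param cv_start Within-trial CV on the first trial.
#' @param shape_jitter Randomize the order of the IKI deviations each trial
#'   (default TRUE). The within-trial CV is preserved exactly (it depends
#'   only on the deviation magnitudes) while the difference norm — and so
#'   the score — varies with the pattern shape, reproducing the fact that
#'   distinct performances share a CV but earn different rewards. With
#'   FALSE the deviations always alternate (the maximal-reward shape) and
#'   the score is a deterministic function of the CV.
#' @param seed Integer seed.
#' @return An `agent_config` list.
#' @export
agent_config <- function(omega1 = -5, omega2 = -3.5, pi_u = exp(3),
                         beta0 = 0.002, beta1 = -0.4, beta2 = 0.2,
                         zeta = 2.5e-4, n_trials = 200, seq_length = 7,
                         base_tempo_ms = 600, cv_start = 0.7,
                         shape_jitter = TRUE, seed = 1) {
  stopifnot(zeta > 0, pi_u > 0, seq_length >= 2, n_trials >= 1,
            base_tempo_ms > 0, cv_start >= 0)
  structure(list(omega1 = omega1, omega2 = omega2, pi_u = pi_u,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2, zeta = zeta,
                 n_trials = as.integer(n_trials),
                 seq_length = as.integer(seq_length),
                 base_tempo_ms = base_tempo_ms, cv_start = cv_start,
                 shape_jitter = isTRUE(shape_jitter),
                 seed = as.integer(seed)),
            class = "agent_config")
}

# Realize a within-trial CV as an IKI vector (seconds): deviations of equal
# magnitude around the mean tempo with a given sign pattern (the alternating
# low/high pattern of the task's own maximal-reward example by default). The
# magnitude is solved numerically so the population CV of the vector equals
# `cv`; the CV depends only on the sign multiset, not its order, while the
# difference norm (hence the score) depends on the order. Returns the vector
# plus a `clipped` flag when the requested CV is infeasible (an IKI would
# reach 0).
iki_from_cv <- function(cv, seq_length, base_tempo_s,
                        signs = rep_len(c(-1, 1), seq_length)) {
  s <- signs
  pat <- function(a) base_tempo_s + s * a
  cv_of <- function(a) {
    x <- pat(a)
    sd_pop(x) / mean(x)
  }
  a_max <- base_tempo_s * 0.999
  clipped <- FALSE
  if (cv <= 0) {
    a <- 0
    clipped <- cv < 0
  } else if (cv >= cv_of(a_max)) {
    a <- a_max
    clipped <- TRUE
  } else {
    a <- stats::uniroot(function(a) cv_of(a) - cv, c(0, a_max),
                        tol = 1e-12)$root
  }
  list(iki = pat(a), clipped = clipped)
}

# largest realizable within-trial CV for the alternating pattern
max_feasible_cv <- function(seq_length, base_tempo_s) {
  s <- rep_len(c(-1, 1), seq_length)
  x <- base_tempo_s + s * base_tempo_s * 0.999
  sd_pop(x) / mean(x)
}

#' Simulate a closed-loop HGF agent performing the sequence task
#'
#' Per trial: the current within-trial CV is realized as an alternating IKI
#' vector, scored against the target norm, the normalized score is filtered
#' by the agent's HGF, and the next trial's CV change is drawn from the
#' winning response model using the previous trial's precision-weighted
#' prediction errors. Requested CVs that would produce non-positive IKIs
#' are clipped and flagged.
#'
#' @param cfg An [agent_config()].
#' @param target_norm Positive target norm of IKI differences (task default
#'   1.9596).
#' @return A list of class `agent_performance`: `performance` (data.frame
#'   trial, position, iki_ms, kvel), `scores` (0-100), `cv` (per-trial
#'   within-trial CV), `u`, `traj` (ground-truth `hgf_trajectory`),
#'   `clipped` (logical per trial), `config`, `target_norm`.
#' @export
gen_agent_performance <- function(cfg, target_norm = 1.9596) {
  stopifnot(inherits(cfg, "agent_config"), target_norm > 0)
  n <- cfg$n_trials
  m_s <- cfg$base_tempo_ms / 1000
  cv <- numeric(n); scores <- numeric(n); clipped <- logical(n)
  iki <- matrix(NA_real_, n, cfg$seq_length)
  cv[1] <- cfg$cv_start
  cv_hi <- max_feasible_cv(cfg$seq_length, m_s)

  filter_prefix <- function(u) {
    hgf_filter_core(u, 1, cfg$omega1, cfg$omega2, cfg$pi_u,
                    u[1], 0.05, 1, 0.01)
  }

  base_signs <- rep_len(c(-1, 1), cfg$seq_length)
  kvel <- with_seed(cfg$seed, {
    for (k in seq_len(n)) {
      signs <- if (cfg$shape_jitter) sample(base_signs) else base_signs
      real <- iki_from_cv(cv[k], cfg$seq_length, m_s, signs)
      iki[k, ] <- real$iki
      clipped[k] <- clipped[k] || real$clipped
      scores[k] <- compute_score(trial_performance(real$iki), target_norm)
      if (k < n) {
        raw <- filter_prefix(scores[1:k] / 100)
        if (raw$bad > 0) {
          stop("agent's perceptual parameters left the valid region at trial ",
               raw$bad)
        }
        mu_resp <- cfg$beta0 + cfg$beta1 * raw$eps1[k] + cfg$beta2 * raw$eps2[k]
        dcv <- rnorm(1, mu_resp, sqrt(cfg$zeta))
        nxt <- cv[k] + dcv
        if (nxt < 0) { nxt <- 0; clipped[k + 1] <- TRUE }
        if (nxt > cv_hi) { nxt <- cv_hi; clipped[k + 1] <- TRUE }
        cv[k + 1] <- nxt
      }
    }
    matrix(rnorm(n * (cfg$seq_length + 1), 60, 3), n)
  })

  u <- scores / 100
  params <- hgf_params(cfg$omega1, cfg$omega2, cfg$pi_u,
                       mu1_0 = u[1], sigma1_0 = 0.05)
  traj <- hgf_filter(params, u)
  perf <- data.frame(
    trial = rep(seq_len(n), each = cfg$seq_length),
    position = rep(seq_len(cfg$seq_length), n),
    iki_ms = as.vector(t(iki)) * 1000,
    kvel = as.vector(t(kvel[, seq_len(cfg$seq_length), drop = FALSE])))
  structure(list(performance = perf, scores = scores, cv = cv, u = u,
                 traj = traj, clipped = clipped, config = cfg,
                 target_norm = target_norm),
            class = "agent_performance")
}

#' Simulate an R-peak train
#'
#' Inter-beat intervals are Gaussian with the stated mean (60 /
#' `mean_hr_bpm` seconds) and coefficient of variation, cumulated into
#' event times; non-positive draws are resampled with a warning.
#'
#' @param mean_hr_bpm Mean heart rate in beats per minute, > 0.
#' @param ibi_cv Coefficient of variation of the inter-beat interval, >= 0.
#' @param duration_s Recording duration in seconds.
#' @param seed Integer seed.
#' @return Numeric vector of R-peak times in seconds within
#'   `[0, duration_s]`.
#' @export
gen_rpeaks <- function(mean_hr_bpm, ibi_cv, duration_s, seed = 1) {
  stopifnot(mean_hr_bpm > 0, ibi_cv >= 0, duration_s > 0)
  mean_ibi <- 60 / mean_hr_bpm
  n_draw <- ceiling(duration_s / mean_ibi * 1.5) + 20
  with_seed(seed, {
    ibi <- rnorm(n_draw, mean_ibi, ibi_cv * mean_ibi)
    bad <- ibi <= 0
    if (any(bad)) {
      warning(sprintf("resampled %d non-positive inter-beat intervals", sum(bad)))
      while (any(bad)) {
        ibi[bad] <- rnorm(sum(bad), mean_ibi, ibi_cv * mean_ibi)
        bad <- ibi <= 0
      }
    }
    t <- cumsum(ibi)
    t[t <= duration_s]
  })
}
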