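#' Trial performance container
#'
#' Holds one trial's inter-keystroke intervals (IKIs, in seconds) and,
#' optionally, keystroke velocities. For an n-note sequence there are n - 1
#' IKIs; the reward mapping of the task operates on the successive
#' differences of this vector.
#'
#' @param iki Numeric vector of positive IKIs in seconds, length >= 2.
#' @param kvel Optional numeric vector of keystroke velocities (a.u.).
#' @return An object of class `trial_performance`.
#' @export
#' @examples
#' p <- trial_performance(c(0.2, 1, 0.2, 1, 0.2, 1, 0.2))
#' performance_norm(p)
trial_performance <- function(iki, kvel = NULL) {
  iki <- as.numeric(iki)
  if (length(iki) < 2) stop("need at least 2 IKIs per trial")
  if (any(!is.finite(iki)) || any(iki <= 0)) stop("all IKIs must be positive and finite")
  if (!is.null(kvel)) {
    kvel <- as.numeric(kvel)
    if (any(!is.finite(kvel))) stop("keystroke velocities must be finite")
  }
  structure(list(iki = iki, kvel = kvel), class = "trial_performance")
}

as_trial_performance <- function(p) {
  if (inherits(p, "trial_performance")) p else trial_performance(p)
}

#' Successive differences of the IKI vector
#'
#' Element i is `iki[i + 1] - iki[i]`; since IKIs are themselves intervals
#' between keystroke onsets, this is a vector of differences of differences.
#'
#' @param p A [trial_performance()] object or numeric IKI vector.
#' @return Numeric vector of length `length(iki) - 1`.
#' @export
iki_differences <- function(p) {
  p <- as_trial_performance(p)
  diff(p$iki)
}

#' Euclidean norm of the IKI difference pattern
#'
#' @inheritParams iki_differences
#' @return Non-negative scalar; 0 for an isochronous performance.
#' @export
performance_norm <- function(p) {
  sqrt(sum(iki_differences(p)^2))
}

#' Trial reward score
#'
#' Proximity between the performed norm of IKI differences and the target
#' norm: `100 * exp(-|target - performed|)`. The score is 100 exactly when
#' the performed norm matches the target and decays symmetrically with the
#' absolute mismatch.
#'
#' @inheritParams iki_differences
#' @param target_norm Positive target norm (the task default is 1.9596).
#' @return Score in (0, 100].
#' @export
#' @examples
#' compute_score(trial_performance(c(0.2, 1, 0.2, 1, 0.2, 1, 0.2)), 1.9596)
compute_score <- function(p, target_norm) {
  stopifnot(is.numeric(target_norm), length(target_norm) == 1L, target_norm > 0)
  100 * exp(-abs(target_norm - performance_norm(p)))
}

#' Within-trial performance measures
#'
#' Computes the within-trial coefficient of variation of IKIs
#' (`cv_iki_trial`, population sd over mean), the log mean tempo
#' (`log_m_iki`, natural log of the mean IKI in milliseconds), the norm of
#' IKI differences and, when a target norm is given, the trial score.
#'
#' @inheritParams compute_score
#' @param target_norm Optional positive target norm; when `NULL` the score
#'   is `NA`.
#' @return A list of class `performance_measures` with fields
#'   `cv_iki_trial`, `log_m_iki`, `diff_norm`, `score`.
#' @export
trial_measures <- function(p, target_norm = NULL) {
  p <- as_trial_performance(p)
  m <- mean(p$iki)
  cv <- sd_pop(p$iki) / m
  dn <- performance_norm(p)
  score <- if (is.null(target_norm)) NA_real_ else compute_score(p, target_norm)
  structure(list(cv_iki_trial = cv, log_m_iki = log(m * 1000),
                 diff_norm = dn, score = score),
            class = "performance_measures")
}

# population sd (divide by n): the within-trial convention
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' First-difference series across trials
#'
#' `delta_series(x)[k]` stores `x[k + 1] - x[k]`: the change from trial k to
#' trial k + 1, aligned so that regressors from trial k pair with the change
#' observed at trial k + 1.
#'
#' @param x Numeric per-trial series, length >= 2.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
delta_series <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("delta_series needs at least 2 trials")
  diff(x)
}

#' Across-trials coefficient of variation in trial bins
#'
#' For each complete bin of `bin_size` trials, computes the CV (sample sd /
#' mean) across trials separately at each keystroke position and aggregates
#' across positions. This is the across-trials variability measure (cvIKI
#' when applied to IKIs, cvKvel when applied to velocities); 100 trials with
#' the default bin size give four values.
#'
#' @param x Numeric matrix, trials x positions (IKIs or velocities).
#' @param bin_size Number of trials per bin (default 25).
#' @param agg Aggregation across positions: `"mean"` (default) or
#'   `"median"`.
#' @return Numeric vector with one CV per complete bin. An incomplete final
#'   bin is dropped with a warning.
#' @export
across_trials_cv <- function(x, bin_size = 25, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < bin_size) stop("fewer trials than one bin")
  n_bins <- n %/% bin_size
  if (n %% bin_size != 0) {
    warning(sprintf("dropping incomplete final bin of %d trials", n %% bin_size))
  }
  vapply(seq_len(n_bins), function(b) {
    rows <- ((b - 1) * bin_size + 1):(b * bin_size)
    cv_pos <- apply(x[rows, , drop = FALSE], 2,
                    function(col) stats::sd(col) / mean(col))
    if (agg == "mean") mean(cv_pos) else stats::median(cv_pos)
  }, numeric(1))
}
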