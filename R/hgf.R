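#' HGF perceptual-model parameters
#'
#' Parameter set for the two-level Hierarchical Gaussian Filter (HGF) for
#' continuous inputs. Level 1 tracks the reward tendency of the current
#' performance; level 2 tracks its (phasic log-) volatility. The level-1
#' random-walk variance is coupled to level 2 through
#' `exp(kappa * mu2 + omega1)`; the level-2 step variance is
#' `theta = exp(omega2)`. By convention `kappa = 1`, drift `rho = 0` and
#' unit trial spacing are fixed.
#'
#' @param omega1 Log-volatility offset at level 1.
#' @param omega2 Level-2 step parameter; `theta = exp(omega2)`.
#' @param pi_u Input precision (inverse variance of the score noise), > 0.
#' @param mu1_0,sigma1_0 Initial mean and variance of the level-1 belief.
#' @param mu2_0,sigma2_0 Initial mean and variance of the level-2 belief
#'   (defaults 1 and 0.01).
#' @param kappa Coupling gain, fixed at 1 unless explicitly overridden.
#' @return An object of class `hgf_params`.
#' @export
hgf_params <- function(omega1, omega2, pi_u, mu1_0, sigma1_0,
                       mu2_0 = 1, sigma2_0 = 0.01, kappa = 1) {
  stopifnot(is.finite(omega1), is.finite(omega2), pi_u > 0,
            is.finite(mu1_0), sigma1_0 > 0, is.finite(mu2_0), sigma2_0 > 0)
  structure(list(kappa = kappa, omega1 = omega1, omega2 = omega2,
                 pi_u = pi_u, mu1_0 = mu1_0, sigma1_0 = sigma1_0,
                 mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 theta = exp(omega2)),
            class = "hgf_params")
}

#' Normalize feedback scores to HGF inputs
#'
#' Scores on the 0-100 task scale are divided by 100 to give the input
#' series u in \[0, 1\].
#'
#' @param scores Numeric vector of scores in \[0, 100\].
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_scores <- function(scores) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 100)) {
    stop("scores must lie in [0, 100]")
  }
  scores / 100
}

#' Empirical-Bayes priors from the first 20 inputs
#'
#' Builds the Gaussian priors used to fit the HGF, several of which are
#' anchored on the first 20 input values: the prior means of `omega1` and
#' `log(sigma1_0)` equal the log-variance of inputs 1:20, the prior mean of
#' `log(pi_u)` is its negative, and the `mu1_0` prior is centred on the
#' first input with the variance of inputs 1:20. The remaining priors are
#' fixed: `omega2` ~ N(-4, 16), `omega1` variance 16, `log(pi_u)` variance
#' 4, `mu2_0 = 1` (variance 0), `log(sigma2_0)` ~ N(log 0.01, 1), `log
#' kappa` fixed at 0.
#'
#' Response priors: `beta0` is centred on the mean observed response (the
#' "individual mean of the behavioral parameter") and `beta1`, `beta2` on 0,
#' all with variance 4; `log(zeta)` is centred on the log-variance of the
#' response series (variance 4) — the same empirical device used for the
#' input precision, since no fixed prior is prescribed for the noise.
#'
#' @param u Input series in \[0, 1\], length >= 20.
#' @param y Optional observed response series (e.g. the per-trial change in
#'   within-trial CV); required to set the `beta0` and `log(zeta)` prior
#'   means.
#' @return A list of class `hgf_priors`; each element has `mean` and `var`.
#' @export
default_priors <- function(u, y = NULL) {
  u <- as.numeric(u)
  if (length(u) < 20) stop("need at least 20 inputs to set priors")
  v20 <- stats::var(u[1:20])
  if (!is.finite(v20) || v20 <= 0) {
    stop("degenerate prior: first 20 inputs have zero variance")
  }
  lv <- log(v20)
  pr <- list(
    omega1      = list(mean = lv, var = 16),
    omega2      = list(mean = -4, var = 16),
    log_pi_u    = list(mean = -lv, var = 4),
    mu1_0       = list(mean = u[1], var = v20),
    log_sigma1_0 = list(mean = lv, var = 1),
    mu2_0       = list(mean = 1, var = 0),
    log_sigma2_0 = list(mean = log(0.01), var = 1),
    log_kappa   = list(mean = 0, var = 0)
  )
  if (!is.null(y)) {
    y <- as.numeric(y)
    vy <- stats::var(y)
    if (!is.finite(vy) || vy <= 0) stop("degenerate response series")
    pr$beta0 <- list(mean = mean(y), var = 4)
    pr$beta1 <- list(mean = 0, var = 4)
    pr$beta2 <- list(mean = 0, var = 4)
    pr$log_zeta <- list(mean = log(vy), var = 4)
  }
  class(pr) <- "hgf_priors"
  pr
}

#' Run the two-level HGF forward filter
#'
#' Applies the sequential update equations of the continuous-input HGF to
#' the input series and returns every latent trajectory: predictions
#' (`mu1hat`, `mu2hat`), posterior means (`mu1`, `mu2`), precisions (`pi1`,
#' `pi2`, and their predictions), prediction errors (`delta_u`, `delta1`)
#' and the precision-weighted prediction errors `eps1 = mu1 - mu1hat`,
#' `eps2 = mu2 - mu2hat`, which equal the posterior-mean update steps
#' exactly. The level-1 prediction error entering level 2 is the
#' variance-normalized form
#' `delta1 = (1/pi1 + (mu1 - mu1hat)^2) * pi1hat - 1`.
#'
#' @param params An [hgf_params()] object.
#' @param u Input series in \[0, 1\] (normalized scores).
#' @param on_invalid `"error"` (default) aborts with a diagnostic naming
#'   the trial at which a precision became non-positive; `"flag"` returns
#'   the partial trajectory with attribute `bad` set — the signal used to
#'   reject parameter proposals during fitting.
#' @return A data.frame of class `hgf_trajectory`, one row per trial, with
#'   columns `u, mu1hat, mu1, sigma1, pi1, pi1hat, mu2hat, mu2, sigma2,
#'   pi2, pi2hat, delta_u, delta1, eps1, eps2, w1`.
#' @export
hgf_filter <- function(params, u, on_invalid = c("error", "flag")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(inherits(params, "hgf_params"))
  u <- as.numeric(u)
  if (any(!is.finite(u))) stop("inputs must be finite")
  raw <- hgf_filter_core(u, params$kappa, params$omega1, params$omega2,
                         params$pi_u, params$mu1_0, params$sigma1_0,
                         params$mu2_0, params$sigma2_0)
  bad <- raw$bad
  if (bad > 0 && on_invalid == "error") {
    stop(sprintf(paste0("negative or non-finite precision at trial %d ",
                        "(omega1=%.3g, omega2=%.3g, pi_u=%.3g): ",
                        "parameter set outside the valid region"),
                 bad, params$omega1, params$omega2, params$pi_u))
  }
  traj <- data.frame(u = raw$u, mu1hat = raw$mu1hat, mu1 = raw$mu1,
                     sigma1 = 1 / raw$pi1, pi1 = raw$pi1,
                     pi1hat = raw$pi1hat, mu2hat = raw$mu2hat,
                     mu2 = raw$mu2, sigma2 = 1 / raw$pi2, pi2 = raw$pi2,
                     pi2hat = raw$pi2hat, delta_u = raw$delta_u,
                     delta1 = raw$delta1, eps1 = raw$eps1, eps2 = raw$eps2,
                     w1 = raw$w1)
  attr(traj, "params") <- params
  attr(traj, "bad") <- bad
  class(traj) <- c("hgf_trajectory", "data.frame")
  traj
}

#' Extract precision-weighted prediction errors
#'
#' Returns the `eps1` and `eps2` series of a trajectory; each equals the
#' posterior-mean update at its level, `mu_i(k) - mu_i_hat(k)`.
#'
#' @param traj An `hgf_trajectory` from [hgf_filter()].
#' @return A list with numeric vectors `eps1` and `eps2`.
#' @export
unpack_pwpe <- function(traj) {
  stopifnot(inherits(traj, "hgf_trajectory"))
  list(eps1 = traj$eps1, eps2 = traj$eps2)
}

# Fast internal path used inside the fitting objective: returns the raw
# list from the compiled filter (with the `bad` flag) without data.frame
# construction.
hgf_filter_quiet <- function(kappa, omega1, omega2, pi_u, mu1_0, sigma1_0,
                             mu2_0, sigma2_0, u) {
  hgf_filter_core(u, kappa, omega1, omega2, pi_u, mu1_0, sigma1_0,
                  mu2_0, sigma2_0)
}
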