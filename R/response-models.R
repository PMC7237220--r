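#' Enumerate the eight linear response models
#'
#' Two model families — one explaining the per-trial change in within-trial
#' IKI variability (`delta_cv`), one the change in log mean tempo
#' (`delta_log_miki`) — crossed with four predictor pairs taken from the
#' previous trial's belief trajectory: (mu1, eps1), (mu1, mu2), (mu2, eps2)
#' and (eps1, eps2). The winning model of the task (HGF14) regresses the
#' change in within-trial CV on the precision-weighted prediction errors
#' about reward (eps1) and volatility (eps2).
#'
#' @return A named list of 8 `response_model_spec` objects
#'   (HGF11..HGF14, HGF21..HGF24).
#' @export
enumerate_models <- function() {
  pairs <- list(c("mu1", "eps1"), c("mu1", "mu2"),
                c("mu2", "eps2"), c("eps1", "eps2"))
  fams <- list(cv_family = "delta_cv", tempo_family = "delta_log_miki")
  out <- list()
  for (fi in seq_along(fams)) {
    for (pi in seq_along(pairs)) {
      name <- sprintf("HGF%d%d", fi, pi)
      out[[name]] <- structure(
        list(name = name, family = names(fams)[fi],
             response = fams[[fi]], predictors = pairs[[pi]]),
        class = "response_model_spec")
    }
  }
  out
}

#' Predicted response series of a linear response model
#'
#' The response at trial k (k >= 2) is predicted from the trajectory at
#' trial k - 1: `yhat(k) = beta0 + beta1 * q1(k-1) + beta2 * q2(k-1)`, with
#' (q1, q2) the spec's predictor pair.
#'
#' @param spec A `response_model_spec` from [enumerate_models()].
#' @param traj An `hgf_trajectory` covering trials 1..n.
#' @param betas Numeric vector `c(beta0, beta1, beta2)`.
#' @return Numeric vector of length n - 1, aligned with
#'   `delta_series(measure)`.
#' @export
predicted_response <- function(spec, traj, betas) {
  stopifnot(inherits(spec, "response_model_spec"), length(betas) == 3)
  n <- nrow(traj)
  if (n < 2) stop("trajectory must cover at least 2 trials")
  q1 <- traj[[spec$predictors[1]]][seq_len(n - 1)]
  q2 <- traj[[spec$predictors[2]]][seq_len(n - 1)]
  betas[1] + betas[2] * q1 + betas[3] * q2
}

#' Gaussian response log-likelihood
#'
#' Sum of Normal log-densities of the observed responses around their
#' predictions, with noise variance `zeta`.
#'
#' @param y Observed response series.
#' @param yhat Predicted response series (same length).
#' @param zeta Noise variance, > 0.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(y, yhat, zeta) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (!is.numeric(zeta) || length(zeta) != 1L || zeta <= 0) {
    stop("zeta must be a positive variance")
  }
  sum(dnorm(y, mean = yhat, sd = sqrt(zeta), log = TRUE))
}

# free parameters, in estimation space
.est_names <- c("omega1", "omega2", "log_pi_u",
                "beta0", "beta1", "beta2", "log_zeta")

# log-joint (likelihood + Gaussian priors in estimation space); -Inf marks
# an invalid trajectory and rejects the proposal
.log_joint <- function(xi, u, y_resp, spec, pr_mean, pr_sd, fixed) {
  raw <- hgf_filter_core(u, fixed$kappa, xi[1], xi[2], exp(xi[3]),
                         fixed$mu1_0, fixed$sigma1_0, fixed$mu2_0,
                         fixed$sigma2_0)
  if (raw$bad > 0) return(-Inf)
  n <- length(u)
  q1 <- raw[[spec$predictors[1]]][seq_len(n - 1)]
  q2 <- raw[[spec$predictors[2]]][seq_len(n - 1)]
  yhat <- xi[4] + xi[5] * q1 + xi[6] * q2
  zeta <- exp(xi[7])
  ll <- sum(dnorm(y_resp, yhat, sqrt(zeta), log = TRUE))
  lp <- sum(dnorm(xi, pr_mean, pr_sd, log = TRUE))
  val <- ll + lp
  if (!is.finite(val)) return(-Inf)
  val
}

#' Fit a response model jointly with the HGF perceptual parameters
#'
#' Maximum-a-posteriori estimation of the 7 free parameters (omega1,
#' omega2, log pi_u, beta0, beta1, beta2, log zeta) by multi-start
#' Nelder-Mead on the log-joint (response log-likelihood plus Gaussian
#' log-priors in estimation space). Initial belief states are fixed at
#' their prior means. Parameter proposals whose trajectories hit a
#' non-positive precision are rejected. The log model evidence is a
#' Laplace approximation around the MAP with a finite-difference Hessian.
#'
#' @param u Normalized input scores in \[0, 1\], length >= 21 (>= 30 trials
#'   recommended).
#' @param y Per-trial measure series (within-trial CV or log mean tempo in
#'   ms, length = length(u)); the modelled response is `delta_series(y)`.
#' @param spec A `response_model_spec`.
#' @param priors Optional [default_priors()] result (computed from `u` and
#'   `delta_series(y)` when `NULL`).
#' @param options List: `n_starts` (default 8), `seed` (default 1), `tol`
#'   (relative objective tolerance, default 1e-6), `maxit` (default 1500).
#' @return A `fitted_model` list: `map_params` (natural space), `est`
#'   (estimation space), `lme`, `logjoint`, `residuals`, `traj` (at MAP),
#'   `spec`, `convergence` (0 = clean), `n_trials`.
#' @export
fit_model <- function(u, y, spec, priors = NULL, options = list()) {
  stopifnot(inherits(spec, "response_model_spec"))
  u <- as.numeric(u); y <- as.numeric(y)
  if (length(u) != length(y)) stop("u and y must have one value per trial")
  if (length(u) < 21) stop("need at least 21 trials to fit")
  y_resp <- delta_series(y)
  opts <- modify_defaults(list(n_starts = 8, seed = 1, tol = 1e-6,
                               maxit = 1500), options)
  if (is.null(priors)) priors <- default_priors(u, y_resp)
  if (is.null(priors$beta0)) stop("priors lack response-model entries")

  pr_mean <- c(priors$omega1$mean, priors$omega2$mean, priors$log_pi_u$mean,
               priors$beta0$mean, priors$beta1$mean, priors$beta2$mean,
               priors$log_zeta$mean)
  pr_sd <- sqrt(c(priors$omega1$var, priors$omega2$var, priors$log_pi_u$var,
                  priors$beta0$var, priors$beta1$var, priors$beta2$var,
                  priors$log_zeta$var))
  fixed <- list(kappa = 1, mu1_0 = priors$mu1_0$mean,
                sigma1_0 = exp(priors$log_sigma1_0$mean),
                mu2_0 = priors$mu2_0$mean,
                sigma2_0 = exp(priors$log_sigma2_0$mean))
  obj <- function(xi) .log_joint(xi, u, y_resp, spec, pr_mean, pr_sd, fixed)

  run_nm <- function(x0) {
    tryCatch(
      optim(x0, obj, method = "Nelder-Mead",
            control = list(fnscale = -1, maxit = opts$maxit,
                           reltol = opts$tol)),
      error = function(e) NULL)
  }
  best <- NULL
  with_seed(opts$seed, {
    for (s in seq_len(opts$n_starts)) {
      x0 <- pr_mean
      if (s > 1) {
        for (try in 1:25) {
          # dispersed starts: a third of the prior sd explores the ridge
          # between the perceptual parameters without leaving the typical set
          x0 <- pr_mean + rnorm(length(pr_mean)) * pr_sd / 3
          if (is.finite(obj(x0))) break
        }
      }
      if (!is.finite(obj(x0))) next
      fit <- run_nm(x0)
      if (is.null(fit)) next
      if (is.null(best) || fit$value > best$value) best <- fit
    }
    # Nelder-Mead benefits from simplex restarts at the incumbent optimum
    if (!is.null(best)) {
      for (r in 1:5) {
        fit <- run_nm(best$par)
        if (is.null(fit) || fit$value <= best$value + 1e-6) {
          if (!is.null(fit) && fit$value > best$value) best <- fit
          break
        }
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    stop("no valid parameter region found for this model/data combination")
  }

  map <- best$par
  names(map) <- .est_names
  convergence <- best$convergence

  # Laplace evidence around the MAP
  d <- length(map)
  lme <- NA_real_
  hess_ok <- TRUE
  H <- tryCatch(-optimHess(map, obj), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      H <- H + diag(d) * (abs(min(ev)) + 1e-6)
      hess_ok <- FALSE
    }
    lme <- best$value + 0.5 * d * log(2 * pi) -
      0.5 * as.numeric(determinant(H, logarithm = TRUE)$modulus)
  } else {
    hess_ok <- FALSE
  }
  if (!hess_ok) convergence <- max(convergence, 1L)

  params <- hgf_params(omega1 = map[["omega1"]], omega2 = map[["omega2"]],
                       pi_u = exp(map[["log_pi_u"]]), mu1_0 = fixed$mu1_0,
                       sigma1_0 = fixed$sigma1_0, mu2_0 = fixed$mu2_0,
                       sigma2_0 = fixed$sigma2_0)
  traj <- hgf_filter(params, u)
  yhat <- predicted_response(spec, traj,
                             map[c("beta0", "beta1", "beta2")])
  structure(list(
    map_params = c(omega1 = map[["omega1"]], omega2 = map[["omega2"]],
                   pi_u = exp(map[["log_pi_u"]]), beta0 = map[["beta0"]],
                   beta1 = map[["beta1"]], beta2 = map[["beta2"]],
                   zeta = exp(map[["log_zeta"]])),
    est = map, lme = lme, logjoint = best$value,
    residuals = y_resp - yhat, traj = traj, spec = spec,
    convergence = convergence, n_trials = length(y_resp)),
    class = "fitted_model")
}

#' Residual diagnostics of a fitted response model
#'
#' @param fm A `fitted_model` from [fit_model()].
#' @return List with `mean` (trial-averaged residual), `sem`, and `lag1`
#'   autocorrelation.
#' @export
residual_diagnostics <- function(fm) {
  stopifnot(inherits(fm, "fitted_model"))
  r <- fm$residuals
  list(mean = mean(r), sem = stats::sd(r) / sqrt(length(r)),
       lag1 = as.numeric(acf(r, lag.max = 1, plot = FALSE)$acf[2]))
}

# shallow defaults merge
modify_defaults <- function(defaults, x) {
  stopifnot(is.list(x))
  defaults[names(x)] <- x
  defaults
}
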