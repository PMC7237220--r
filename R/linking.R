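#' Linear independence check of the two pwPE regressors
#'
#' Pearson correlation between the eps1 and eps2 series entering the
#' feedback-locked regression, with its test; pairs with `|r|` above the
#' flag threshold are marked as collinear.
#'
#' @param eps1,eps2 Equal-length numeric series.
#' @param flag_threshold Absolute correlation above which the pair is
#'   flagged (default 0.7).
#' @return List with `r`, `p`, `flag`.
#' @export
check_regressor_independence <- function(eps1, eps2, flag_threshold = 0.7) {
  eps1 <- as.numeric(eps1); eps2 <- as.numeric(eps2)
  if (length(eps1) != length(eps2)) stop("regressor lengths differ")
  if (stats::sd(eps1) == 0 || stats::sd(eps2) == 0) stop("constant regressor")
  ct <- stats::cor.test(eps1, eps2, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, flag = abs(r) >= flag_threshold)
}

#' Trial-wise regression of a feedback-locked beta measure on pwPEs
#'
#' Per-subject ordinary least squares of the feedback-locked beta power (or
#' burst rate) on an intercept and the same-trial precision-weighted
#' prediction errors about reward (eps1) and volatility (eps2). A negative
#' eps1 coefficient means that smaller reward pwPEs go with higher
#' post-feedback beta activity.
#'
#' @param y Per-trial feedback-locked measure.
#' @param eps1,eps2 pwPE series aligned with `y`.
#' @param standardize Z-score the regressors first (default FALSE;
#'   coefficients in natural units).
#' @return A `link_regression` list: `coefficients` (beta0, beta1, beta2),
#'   `se`, `n_trials`, `regressor_correlation`, `residuals`,
#'   `standardized`.
#' @export
fit_link_regression <- function(y, eps1, eps2, standardize = FALSE) {
  y <- as.numeric(y); eps1 <- as.numeric(eps1); eps2 <- as.numeric(eps2)
  n <- length(y)
  if (length(eps1) != n || length(eps2) != n) stop("series lengths differ")
  if (n < 10) stop("need at least 10 trials for a reported fit")
  if (standardize) {
    eps1 <- (eps1 - mean(eps1)) / stats::sd(eps1)
    eps2 <- (eps2 - mean(eps2)) / stats::sd(eps2)
  }
  X <- cbind(1, eps1, eps2)
  if (qr(X)$rank < 3) stop("rank-deficient design (collinear regressors)")
  fit <- lm(y ~ eps1 + eps2)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  rc <- if (stats::sd(eps1) > 0 && stats::sd(eps2) > 0) cor(eps1, eps2) else NA_real_
  structure(list(
    coefficients = c(beta0 = unname(cf[1]), beta1 = unname(cf[2]),
                     beta2 = unname(cf[3])),
    se = c(beta0 = unname(se[1]), beta1 = unname(se[2]),
           beta2 = unname(se[3])),
    n_trials = n, regressor_correlation = rc,
    residuals = stats::residuals(fit), standardized = standardize),
    class = "link_regression")
}
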