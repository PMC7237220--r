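#' Nonparametric permutation test
#'
#' Difference-of-means statistic with a permutation null: group-label
#' shuffling for independent samples, sign-flipping of within-pair
#' differences for paired samples. The p-value is
#' `(1 + #\{|null| >= |obs|\}) / (n_perm + 1)` and therefore never 0. With
#' `exact = TRUE` the null is enumerated exhaustively (all label
#' assignments / all sign patterns) and `p = #\{|null| >= |obs|\} / n_total`,
#' which includes the identity permutation.
#'
#' @param a,b Numeric samples (equal length when `paired`).
#' @param paired Paired test via sign-flipping (default FALSE).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed Integer seed.
#' @param statistic `"mean_diff"` (default) or `"t"` (Welch/paired t).
#' @param exact Enumerate the full null (small samples only).
#' @return A `perm_test` list: `statistic`, `p`, `n_permutations`,
#'   `paired`, `seed`, `exact`.
#' @export
permutation_test <- function(a, b, paired = FALSE, n_perm = 10000, seed = 1,
                             statistic = c("mean_diff", "t"),
                             exact = FALSE) {
  statistic <- match.arg(statistic)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty input sample")
  if (paired && length(a) != length(b)) stop("paired samples must have equal length")
  if (!exact && n_perm < 1000) stop("n_perm must be at least 1000")
  tol <- 1e-12

  if (paired) {
    d <- a - b
    stat <- function(x) {
      if (statistic == "mean_diff") mean(x)
      else mean(x) / (stats::sd(x) / sqrt(length(x)))
    }
    obs <- stat(d)
    if (exact) {
      n <- length(d)
      if (n > 20) stop("exact paired enumeration limited to n <= 20")
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      null <- apply(signs, 1, function(s) stat(d * s))
      p <- sum(abs(null) >= abs(obs) - tol) / length(null)
      n_used <- length(null)
    } else {
      null <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          stat(d * sample(c(-1, 1), length(d), replace = TRUE))
        }, numeric(1))
      })
      p <- (1 + sum(abs(null) >= abs(obs) - tol)) / (n_perm + 1)
      n_used <- n_perm
    }
  } else {
    pool <- c(a, b)
    na <- length(a)
    stat2 <- function(x, y) {
      if (statistic == "mean_diff") mean(x) - mean(y)
      else (mean(x) - mean(y)) /
        sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    }
    obs <- stat2(a, b)
    if (exact) {
      combs <- utils::combn(length(pool), na)
      if (ncol(combs) > 5e5) stop("exact enumeration too large")
      null <- apply(combs, 2, function(ix) stat2(pool[ix], pool[-ix]))
      p <- sum(abs(null) >= abs(obs) - tol) / length(null)
      n_used <- length(null)
    } else {
      null <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          ix <- sample(length(pool), na)
          stat2(pool[ix], pool[-ix])
        }, numeric(1))
      })
      p <- (1 + sum(abs(null) >= abs(obs) - tol)) / (n_perm + 1)
      n_used <- n_perm
    }
  }
  structure(list(statistic = obs, p = p, n_permutations = n_used,
                 paired = paired, seed = seed, exact = exact),
            class = "perm_test")
}

# Benjamini-Hochberg linear step-up; returns the rejection mask
bh_mask <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

#' Adaptive FDR control (two-stage linear step-up)
#'
#' The two-stage procedure: a first-stage linear step-up at level
#' `q' = q / (1 + q)` estimates the number of true nulls `m0 = m - r1`; a
#' second stage runs the step-up at level `q' * m / m0`. Returns the
#' adapted threshold p-value (the largest rejected p, 0 when nothing is
#' rejected) and the rejection mask.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `threshold`, `mask`, `m0`, `q`.
#' @export
fdr_adaptive <- function(pvals, q = 0.05) {
  p <- as.numeric(pvals)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  q1 <- q / (1 + q)
  mask1 <- bh_mask(p, q1)
  r1 <- sum(mask1)
  mask <- if (r1 == 0) {
    rep(FALSE, m)
  } else if (r1 == m) {
    rep(TRUE, m)
  } else {
    bh_mask(p, q1 * m / (m - r1))
  }
  thr <- if (any(mask)) max(p[mask]) else 0
  list(threshold = thr, mask = mask, m0 = if (r1 == m) 0 else m - r1, q = q)
}

#' Probability-of-superiority effect size with bootstrap CI
#'
#' Independent samples: `delta = N(A > B) / (Ntot - Nties)` over all
#' `size(A) * size(B)` cross-pairs. Dependent samples: the proportion of
#' paired comparisons with `a > b`, ties removed from the denominator.
#' The 95% CI is a seeded percentile bootstrap.
#'
#' @param a,b Numeric samples (equal length when `dependent`).
#' @param dependent Paired version (default FALSE).
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @return An `effect_size` list: `delta`, `kind`, `ci95`, `n_ties`.
#' @export
effect_size_delta <- function(a, b, dependent = FALSE, n_boot = 5000,
                              seed = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (dependent && length(a) != length(b)) {
    stop("dependent samples must have equal length")
  }
  core <- function(a, b) {
    if (dependent) {
      ties <- sum(a == b)
      denom <- length(a) - ties
      if (denom == 0) return(c(NA_real_, ties))
      c(sum(a > b) / denom, ties)
    } else {
      gt <- sum(vapply(a, function(x) sum(x > b), numeric(1)))
      ties <- sum(vapply(a, function(x) sum(x == b), numeric(1)))
      denom <- length(a) * length(b) - ties
      if (denom == 0) return(c(NA_real_, ties))
      c(gt / denom, ties)
    }
  }
  est <- core(a, b)
  if (is.na(est[1])) stop("undefined effect size: all comparisons tied")
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      if (dependent) {
        ix <- sample(length(a), replace = TRUE)
        core(a[ix], b[ix])[1]
      } else {
        core(sample(a, replace = TRUE), sample(b, replace = TRUE))[1]
      }
    }, numeric(1))
  })
  ci <- as.numeric(quantile(boot, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE))
  structure(list(delta = est[1],
                 kind = if (dependent) "dependent" else "independent",
                 ci95 = ci, n_ties = as.integer(est[2]),
                 n_boot = n_boot, seed = seed),
            class = "effect_size")
}

#' Spearman rank correlation with permutation p-value
#'
#' Tie-aware ranks (mid-ranks), Pearson correlation of the ranks, p-value
#' by permuting one variable.
#'
#' @param x,y Numeric vectors, equal length >= 5.
#' @param n_perm Permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `rho` and `p`.
#' @export
spearman_rho <- function(x, y, n_perm = 10000, seed = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(rho = rho, p = p)
}

#' Heart-rate variability metrics from R-peak times
#'
#' HRV is the coefficient of variation of the inter-beat interval;
#' mean heart rate is 60 / mean IBI.
#'
#' @param rpeaks Strictly increasing R-peak times in seconds, length >= 3.
#' @return List with `cv_ibi` and `mean_hr` (bpm).
#' @export
hrv_metrics <- function(rpeaks) {
  t <- as.numeric(rpeaks)
  if (length(t) < 3) stop("need at least 3 R-peaks")
  ibi <- diff(t)
  if (any(ibi <= 0)) stop("R-peak times must be strictly increasing")
  list(cv_ibi = stats::sd(ibi) / mean(ibi), mean_hr = 60 / mean(ibi))
}

#' Pointwise permutation test over a time course with adaptive FDR
#'
#' Per-subject series (subjects x time; a `subjects x channels x time`
#' array is first averaged over the selected channels) are compared between
#' groups with a permutation test at every time point, followed by adaptive
#' FDR control over time points. The returned mask marks the significant
#' time points (the significance bars under a time-course plot).
#'
#' @param a,b Matrices `subjects x time` or arrays `subjects x channels x
#'   time` on the same grid.
#' @param channels Optional channel indices averaged before testing.
#' @param n_perm Permutations per time point (default 2000).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed (per-timepoint seeds are derived from it).
#' @param paired Paired tests (default FALSE).
#' @return List with `p` (per time point), `mask`, `threshold`.
#' @export
pointwise_timecourse_test <- function(a, b, channels = NULL, n_perm = 2000,
                                      q = 0.05, seed = 1, paired = FALSE) {
  avg_ch <- function(x) {
    if (length(dim(x)) == 3) {
      ch <- if (is.null(channels)) seq_len(dim(x)[2]) else channels
      apply(x[, ch, , drop = FALSE], c(1, 3), mean)
    } else as.matrix(x)
  }
  a <- avg_ch(a); b <- avg_ch(b)
  if (ncol(a) != ncol(b)) stop("time grids differ")
  nt <- ncol(a)
  p <- vapply(seq_len(nt), function(ti) {
    permutation_test(a[, ti], b[, ti], paired = paired, n_perm = n_perm,
                     seed = seed + ti)$p
  }, numeric(1))
  f <- fdr_adaptive(p, q)
  list(p = p, mask = f$mask, threshold = f$threshold)
}
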