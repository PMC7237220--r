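# shared fixtures and independent oracles (kept deliberately naive: loops
# and closed forms, never calls into the code paths they check)

# the task's printed maximal-reward IKI pattern (seconds)
max_reward_iki <- c(0.2, 1, 0.2, 1, 0.2, 1, 0.2)

# element-wise difference loop, the brute-force oracle for iki_differences
oracle_diffs <- function(x) {
  out <- numeric(length(x) - 1)
  for (i in seq_along(out)) out[i] <- x[i + 1] - x[i]
  out
}

# conjugate Gaussian posterior mean: prior N(m, 1/p), likelihood
# precision pu, observation u
oracle_conjugate_mean <- function(m, p, pu, u) {
  (p * m + pu * u) / (p + pu)
}

# double-loop probability of superiority with tie correction
oracle_delta <- function(a, b) {
  gt <- 0L; ties <- 0L
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1L else if (x == y) ties <- ties + 1L
  }
  gt / (length(a) * length(b) - ties)
}

# all-assignments permutation p-value for the mean difference
oracle_exact_perm_p <- function(a, b) {
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  obs <- mean(a) - mean(b)
  null <- apply(idx, 2, function(ix) mean(pool[ix]) - mean(pool[-ix]))
  sum(abs(null) >= abs(obs) - 1e-12) / ncol(idx)
}

# a small deterministic hgf trajectory for response-model arithmetic
fake_traj <- function(mu1, mu2, eps1, eps2) {
  df <- data.frame(mu1 = mu1, mu2 = mu2, eps1 = eps1, eps2 = eps2)
  class(df) <- c("hgf_trajectory", "data.frame")
  df
}

# random valid input series in [0, 1]
random_u <- function(n, seed = 1) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); expr
  }
  withr_seed(seed, pmin(pmax(rnorm(n, 0.5, 0.15), 0.01), 0.99))
}
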