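#' Log family evidence from per-subject log model evidences
#'
#' Aggregates member-model log evidences into a log family evidence per
#' subject under a uniform within-family prior:
#' `LFE = logsumexp(LME_members) - log(n_members)`.
#'
#' @param lme Numeric matrix, subjects x models, with column names.
#' @param partition Named character vector mapping model name -> family.
#' @return Numeric matrix, subjects x families.
#' @export
family_log_evidence <- function(lme, partition) {
  lme <- as.matrix(lme)
  if (is.null(colnames(lme))) stop("lme must have model column names")
  if (!all(colnames(lme) %in% names(partition))) {
    stop("every model must be assigned to a family")
  }
  if (any(!is.finite(lme))) stop("lme contains missing or non-finite entries")
  fams <- unique(partition[colnames(lme)])
  out <- sapply(fams, function(f) {
    members <- colnames(lme)[partition[colnames(lme)] == f]
    if (length(members) == 0) stop("empty family: ", f)
    apply(lme[, members, drop = FALSE], 1,
          function(r) logsumexp(r) - log(length(r)))
  })
  out <- matrix(out, nrow = nrow(lme), dimnames = list(rownames(lme), fams))
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Random-effects Bayesian model selection
#'
#' Variational inference on the Dirichlet posterior over population model
#' frequencies given per-subject log evidences: posterior model assignments
#' are updated as `softmax(lme + digamma(alpha) - digamma(sum alpha))` and
#' the Dirichlet concentrations as `alpha0 + summed assignments`, iterated
#' to convergence. Exceedance probabilities (posterior probability that a
#' model is the most frequent) are estimated by seeded Monte-Carlo sampling
#' from the converged Dirichlet.
#'
#' @param lme Numeric matrix, subjects x models (or families).
#' @param n_samples Dirichlet draws for the exceedance estimate (default
#'   1e6, about +-0.001 Monte-Carlo error).
#' @param seed Seed for the exceedance sampling.
#' @param alpha0 Prior concentration per model (default 1, uniform).
#' @param tol,max_iter Convergence control on the alpha iterates.
#' @return A `bms_result` list: `alpha`, `expected_frequencies`,
#'   `exceedance_probabilities`, `assignments` (subjects x models), and
#'   `n_iter`.
#' @export
rfx_bms <- function(lme, n_samples = 1e6, seed = 1, alpha0 = 1,
                    tol = 1e-9, max_iter = 2000) {
  lme <- as.matrix(lme)
  n <- nrow(lme); k <- ncol(lme)
  if (k < 2) stop("need at least 2 models")
  if (n < 2) stop("need at least 2 subjects")
  if (any(!is.finite(lme))) stop("lme contains missing or non-finite entries")
  a0 <- rep(alpha0, k)
  alpha <- a0
  g <- NULL
  for (it in seq_len(max_iter)) {
    w <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    g <- exp(w)
    g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
    if (it == max_iter) {
      stop("BMS did not converge after ", max_iter,
           " iterations; final alpha: ", paste(signif(alpha, 4), collapse = ", "))
    }
  }
  xp <- with_seed(seed, {
    draws <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    idx <- max.col(draws, ties.method = "first")
    tabulate(idx, nbins = k) / n_samples
  })
  ef <- alpha / sum(alpha)
  names(ef) <- names(xp) <- colnames(lme)
  structure(list(alpha = stats::setNames(alpha, colnames(lme)),
                 expected_frequencies = ef,
                 exceedance_probabilities = xp,
                 assignments = g, n_iter = it),
            class = "bms_result")
}

#' Two-stage model selection: family first, then model within family
#'
#' Runs random-effects BMS on log family evidences, then on the member
#' models of the winning family only.
#'
#' @param lme Numeric matrix, subjects x models, with column names.
#' @param partition Named character vector model -> family.
#' @param ... Passed to [rfx_bms()].
#' @return List with `family_bms`, `winning_family`, `model_bms`,
#'   `winning_model`.
#' @export
select_model <- function(lme, partition, ...) {
  lfe <- family_log_evidence(lme, partition)
  fam_bms <- rfx_bms(lfe, ...)
  win_fam <- names(which.max(fam_bms$exceedance_probabilities))
  members <- colnames(lme)[partition[colnames(lme)] == win_fam]
  if (length(members) > 1) {
    mod_bms <- rfx_bms(lme[, members, drop = FALSE], ...)
    winner <- names(which.max(mod_bms$exceedance_probabilities))
  } else {
    mod_bms <- NULL
    winner <- members
  }
  list(family_bms = fam_bms, winning_family = win_fam,
       model_bms = mod_bms, winning_model = winner)
}

# Evaluate expr with a temporary RNG state seeded at `seed`; restores the
# caller's RNG afterwards so seeded helpers compose predictably.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
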