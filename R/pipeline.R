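#' Pipeline configuration
#'
#' All task and analysis constants default to the values of the task
#' design: target norm 1.9596, trial markers GO 0 s / STOP 7 s / feedback
#' 9 s, 25-trial bins, beta band 13-30 Hz, 75th-percentile burst threshold,
#' feedback-locked window 400-1600 ms, FDR level q = 0.05.
#'
#' @param groups Named list of per-group generator overrides (see
#'   [gen_group_dataset()]); the default defines a control and an
#'   experimental group differing in burst life-time exponent and link
#'   intercept.
#' @param n_subjects Subjects per group.
#' @param n_trials Trials per subject.
#' @param seed Master seed.
#' @param stages Character vector of stages to run, in dependency order
#'   among `c("simulate", "score", "fit", "select", "burst", "link",
#'   "stats")`.
#' @param models Response-model names fitted in the `fit` stage (default
#'   the two family winners, enough for a family-level comparison).
#' @param target_norm,bin_size,band,burst_percentile,q Analysis constants.
#' @param fit_options Options passed to [fit_model()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(groups = list(
                              control = list(),
                              experimental = list(omega2 = -4.5,
                                                  tau_true = 1.4,
                                                  link_beta0 = 2)),
                            n_subjects = 4, n_trials = 100, seed = 1,
                            stages = c("simulate", "score", "fit", "select",
                                       "burst", "link", "stats"),
                            models = c("HGF14", "HGF24"),
                            target_norm = 1.9596, bin_size = 25,
                            band = c(13, 30), burst_percentile = 75,
                            q = 0.05,
                            fit_options = list(n_starts = 2, seed = 1)) {
  structure(list(groups = groups, n_subjects = n_subjects,
                 n_trials = n_trials, seed = seed, stages = stages,
                 models = models, target_norm = target_norm,
                 bin_size = bin_size, band = band,
                 burst_percentile = burst_percentile, q = q,
                 fit_options = fit_options,
                 markers = c(go = 0, stop = 7, feedback = 9)),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on a synthetic group
#' dataset: simulate -> score -> fit (response models) -> select (BMS) ->
#' burst (life-time exponents) -> link (feedback-locked regression) ->
#' stats (between-group permutation tests with effect sizes). Stage outputs
#' are written under `out_dir` (CSV/JSON) and a manifest records seeds,
#' counts and file hashes. Rerunning with the same config reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("motorhgf_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "score", "fit", "select", "burst", "link", "stats")
  stages <- match.arg(config$stages, known, several.ok = TRUE)
  deps <- list(score = "simulate", fit = "simulate", select = "fit",
               burst = "simulate", link = "simulate", stats = "simulate")
  for (s in stages) {
    for (d in deps[[s]]) {
      if (!d %in% stages) stop(sprintf("stage '%s' requires stage '%s'", s, d))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  log <- list()

  if ("simulate" %in% stages) {
    groups <- lapply(config$groups, function(g) {
      if (is.null(g$n_trials)) g$n_trials <- config$n_trials
      g
    })
    ds <- gen_group_dataset(groups, config$n_subjects, seed = config$seed,
                            target_norm = config$target_norm)
    res$dataset <- ds
    write_performance_csv(ds$performance, file.path(out_dir, "performance.csv"))
    log$simulate <- list(n_subjects = nrow(ds$subjects),
                         n_trials = config$n_trials)
  }

  subjects <- res$dataset$subjects$subject
  gt <- res$dataset$ground_truth

  if ("score" %in% stages) {
    perf <- read_performance_csv(file.path(out_dir, "performance.csv"))
    sc <- do.call(rbind, lapply(split(perf, list(perf$subject, perf$trial),
                                      drop = TRUE), function(d) {
      d <- d[order(d$position), ]
      data.frame(subject = d$subject[1], trial = d$trial[1],
                 score = compute_score(trial_performance(d$iki_ms / 1000),
                                       config$target_norm))
    }))
    sc <- sc[order(sc$subject, sc$trial), ]
    rownames(sc) <- NULL
    write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
    res$scores <- sc
    log$score <- list(n_rows = nrow(sc))
  }

  if ("fit" %in% stages) {
    specs <- enumerate_models()[config$models]
    fits <- list()
    lme <- matrix(NA_real_, length(subjects), length(specs),
                  dimnames = list(subjects, names(specs)))
    for (s in subjects) {
      u <- gt[[s]]$u
      fits[[s]] <- lapply(specs, function(sp) {
        y <- if (sp$response == "delta_cv") gt[[s]]$cv else {
          # per-trial log mean IKI in ms
          perf <- res$dataset$performance
          d <- perf[perf$subject == s, ]
          as.numeric(tapply(d$iki_ms, d$trial, function(v) log(mean(v))))
        }
        fit_model(u, y, sp, options = config$fit_options)
      })
      lme[s, ] <- vapply(fits[[s]], function(f) f$lme, numeric(1))
    }
    res$fits <- fits
    res$lme <- lme
    write.csv(data.frame(subject = rep(rownames(lme), ncol(lme)),
                         model = rep(colnames(lme), each = nrow(lme)),
                         lme = as.vector(lme)),
              file.path(out_dir, "evidence.csv"), row.names = FALSE)
    log$fit <- list(n_fits = length(subjects) * length(specs))
  }

  if ("select" %in% stages) {
    specs <- enumerate_models()[config$models]
    partition <- vapply(specs, function(sp) sp$family, character(1))
    res$selection <- select_model(res$lme, partition, seed = config$seed)
    jsonlite::write_json(
      list(winning_family = res$selection$winning_family,
           winning_model = res$selection$winning_model,
           family_xp = res$selection$family_bms$exceedance_probabilities,
           model_xp = res$selection$model_bms$exceedance_probabilities),
      file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
    log$select <- list(winner = res$selection$winning_model)
  }

  if ("burst" %in% stages) {
    tau <- vapply(subjects, function(s) {
      duration_distribution(gt[[s]]$burst_durations_ms)$tau
    }, numeric(1))
    res$tau <- data.frame(subject = subjects,
                          group = res$dataset$subjects$group, tau = tau)
    write.csv(res$tau, file.path(out_dir, "tau.csv"), row.names = FALSE)
    log$burst <- list(n_subjects = length(tau))
  }

  if ("link" %in% stages) {
    links <- lapply(subjects, function(s) {
      fit_link_regression(gt[[s]]$beta_measure, gt[[s]]$traj$eps1,
                          gt[[s]]$traj$eps2)
    })
    names(links) <- subjects
    res$links <- links
    lk <- do.call(rbind, lapply(subjects, function(s) {
      data.frame(subject = s, group = res$dataset$subjects$group[
                   res$dataset$subjects$subject == s],
                 t(links[[s]]$coefficients))
    }))
    write.csv(lk, file.path(out_dir, "link_coefficients.csv"),
              row.names = FALSE)
    res$link_table <- lk
    log$link <- list(n_subjects = length(links))
  }

  if ("stats" %in% stages) {
    groups <- unique(res$dataset$subjects$group)
    g1 <- subjects[res$dataset$subjects$group == groups[1]]
    g2 <- subjects[res$dataset$subjects$group == groups[2]]
    mean_score <- vapply(subjects, function(s) mean(gt[[s]]$u) * 100,
                         numeric(1))
    comparisons <- list(score = mean_score)
    if (!is.null(res$tau)) {
      comparisons$tau <- stats::setNames(res$tau$tau, res$tau$subject)
    }
    if (!is.null(res$link_table)) {
      comparisons$link_beta1 <- stats::setNames(res$link_table$beta1,
                                                res$link_table$subject)
    }
    hrv <- vapply(subjects, function(s) {
      hrv_metrics(res$dataset$rpeaks[[s]])$cv_ibi
    }, numeric(1))
    comparisons$hrv <- hrv
    out <- lapply(names(comparisons), function(nm) {
      v <- comparisons[[nm]]
      pt <- permutation_test(v[g1], v[g2], n_perm = 2000,
                             seed = config$seed)
      es <- effect_size_delta(v[g1], v[g2], n_boot = 1000,
                              seed = config$seed)
      list(measure = nm, p = pt$p, statistic = pt$statistic,
           delta = es$delta, ci95 = es$ci95)
    })
    names(out) <- names(comparisons)
    pv <- vapply(out, function(o) o$p, numeric(1))
    fdr <- fdr_adaptive(pv, config$q)
    res$stats <- list(tests = out, fdr = fdr)
    jsonlite::write_json(list(tests = out, p_fdr = fdr$threshold,
                              significant = names(pv)[fdr$mask]),
                         file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    log$stats <- list(n_tests = length(pv), n_significant = sum(fdr$mask))
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("motorhgf")),
    seed = config$seed, stages = stages, log = log,
    hashes = as.list(tools::md5sum(files[!grepl("manifest", files)])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

#' Validate pipeline input files
#'
#' Schema and invariant checks on a run directory's tables: required
#' columns, positive IKIs, scores within \[0, 100\]. Violations are
#' returned as a report (and raised when `strict`).
#'
#' @param dir Run directory containing `performance.csv` (and optionally
#'   `scores.csv`).
#' @param strict Raise an error on any violation (default FALSE).
#' @return Character vector of violation messages (empty when clean).
#' @export
validate_inputs <- function(dir, strict = FALSE) {
  report <- character(0)
  pf <- file.path(dir, "performance.csv")
  if (!file.exists(pf)) {
    report <- c(report, "performance.csv missing")
  } else {
    perf <- read_performance_csv(pf)
    need <- c("subject", "group", "trial", "position", "iki_ms", "kvel",
              "score")
    miss <- setdiff(need, names(perf))
    if (length(miss)) {
      report <- c(report, paste("performance.csv missing columns:",
                                paste(miss, collapse = ", ")))
    } else {
      bad <- which(!is.finite(perf$iki_ms) | perf$iki_ms <= 0)
      if (length(bad)) {
        report <- c(report, sprintf("non-positive IKI at rows: %s",
                                    paste(head(bad, 5), collapse = ", ")))
      }
      badsc <- which(perf$score < 0 | perf$score > 100)
      if (length(badsc)) {
        report <- c(report, sprintf("score out of [0,100] at rows: %s",
                                    paste(head(badsc, 5), collapse = ", ")))
      }
    }
  }
  if (strict && length(report)) stop(paste(report, collapse = "; "))
  report
}
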