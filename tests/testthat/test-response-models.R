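test_that("enumerate_models yields the 8 unique specifications", {
  specs <- enumerate_models()
  expect_length(specs, 8)
  keys <- vapply(specs, function(s)
    paste(s$family, paste(s$predictors, collapse = "+")), character(1))
  expect_length(unique(keys), 8)
  expect_setequal(names(specs),
                  c(paste0("HGF1", 1:4), paste0("HGF2", 1:4)))
  # the winning model: cv family driven by the two pwPEs
  expect_identical(specs$HGF14$family, "cv_family")
  expect_identical(specs$HGF14$predictors, c("eps1", "eps2"))
  expect_identical(specs$HGF24$response, "delta_log_miki")
})

test_that("predicted_response does the k-1 linear arithmetic", {
  traj <- fake_traj(mu1 = c(0.2, 0.4, 0.6), mu2 = c(1, 0.8, 0.6),
                    eps1 = c(0.05, -0.02, 0.01),
                    eps2 = c(-0.01, 0.02, 0))
  spec14 <- enumerate_models()$HGF14
  # pencil: yhat(k) = b0 + b1*eps1(k-1) + b2*eps2(k-1), k = 2, 3
  got <- predicted_response(spec14, traj, c(0.1, 2, -1))
  expect_equal(got, c(0.1 + 2 * 0.05 - 1 * (-0.01),
                      0.1 + 2 * (-0.02) - 1 * 0.02))
  # beta1 = beta2 = 0 -> constant intercept
  expect_equal(predicted_response(spec14, traj, c(0.3, 0, 0)), rep(0.3, 2))
  # swapping predictor order with swapped betas is identical
  spec11 <- enumerate_models()$HGF11  # (mu1, eps1)
  swapped <- structure(list(name = "x", family = "cv_family",
                            response = "delta_cv",
                            predictors = c("eps1", "mu1")),
                       class = "response_model_spec")
  expect_equal(predicted_response(spec11, traj, c(0, 1.5, -2)),
               predicted_response(swapped, traj, c(0, -2, 1.5)))
})

test_that("log_likelihood obeys the Gaussian closed forms", {
  y <- c(0.1, -0.2, 0.05)
  expect_equal(log_likelihood(y, y, 0.04),
               3 * dnorm(0, 0, 0.2, log = TRUE))
  # doubling zeta with fixed residuals changes LL analytically
  yhat <- y + c(0.1, 0.1, -0.1)
  rss <- sum((y - yhat)^2)
  expect_equal(log_likelihood(y, yhat, 0.08) - log_likelihood(y, yhat, 0.04),
               -3 / 2 * log(2) + rss / (2 * 0.04) - rss / (2 * 0.08))
  # independent-sum property
  expect_equal(log_likelihood(c(y, y), c(yhat, yhat), 0.04),
               2 * log_likelihood(y, yhat, 0.04))
  expect_error(log_likelihood(y, yhat, 0), "positive")
  expect_error(log_likelihood(y, yhat[1:2], 0.1), "lengths")
})

test_that("log-joint decomposes into likelihood plus priors", {
  ap <- gen_agent_performance(agent_config(n_trials = 60, seed = 21))
  spec <- enumerate_models()$HGF14
  y_resp <- delta_series(ap$cv)
  pr <- default_priors(ap$u, y_resp)
  pr_mean <- c(pr$omega1$mean, pr$omega2$mean, pr$log_pi_u$mean,
               pr$beta0$mean, pr$beta1$mean, pr$beta2$mean,
               pr$log_zeta$mean)
  pr_sd <- sqrt(c(16, 16, 4, 4, 4, 4, 4))
  xi <- pr_mean + 0.1
  fixed <- list(kappa = 1, mu1_0 = pr$mu1_0$mean,
                sigma1_0 = exp(pr$log_sigma1_0$mean), mu2_0 = 1,
                sigma2_0 = 0.01)
  lj <- motorhgf:::.log_joint(xi, ap$u, y_resp, spec, pr_mean, pr_sd, fixed)
  # term-by-term reconstruction
  pars <- hgf_params(xi[1], xi[2], exp(xi[3]), fixed$mu1_0, fixed$sigma1_0)
  traj <- hgf_filter(pars, ap$u)
  yhat <- predicted_response(spec, traj, xi[4:6])
  ll <- log_likelihood(y_resp, yhat, exp(xi[7]))
  lp <- sum(dnorm(xi, pr_mean, pr_sd, log = TRUE))
  expect_equal(lj, ll + lp)
})

test_that("fit_model is deterministic and recovers a null effect", {
  ap <- gen_agent_performance(agent_config(beta1 = 0, beta2 = 0,
                                           n_trials = 120, seed = 31))
  spec <- enumerate_models()$HGF14
  opts <- list(n_starts = 2, seed = 5)
  f1 <- fit_model(ap$u, ap$cv, spec, options = opts)
  f2 <- fit_model(ap$u, ap$cv, spec, options = opts)
  expect_identical(f1$est, f2$est)
  expect_identical(f1$lme, f2$lme)
  # true betas are 0: the fitted effects, in response units
  # (coefficient x regressor spread), should be buried in the noise
  noise_sd <- sqrt(f1$map_params[["zeta"]])
  expect_lt(abs(f1$map_params[["beta1"]]) * sd(f1$traj$eps1), noise_sd / 2)
  expect_lt(abs(f1$map_params[["beta2"]]) * sd(f1$traj$eps2), noise_sd / 2)
  expect_true(is.finite(f1$lme))
  expect_length(f1$residuals, 119)
})

test_that("the generating model beats a wrong predictor set in evidence", {
  spec_true <- enumerate_models()$HGF14   # (eps1, eps2)
  spec_wrong <- enumerate_models()$HGF12  # (mu1, mu2)
  wins <- vapply(1:4, function(s) {
    ap <- gen_agent_performance(agent_config(n_trials = 150, seed = 40 + s))
    opts <- list(n_starts = 3, seed = s)
    lme_t <- fit_model(ap$u, ap$cv, spec_true, options = opts)$lme
    lme_w <- fit_model(ap$u, ap$cv, spec_wrong, options = opts)$lme
    lme_t > lme_w
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("residual diagnostics are calibrated for a well-specified fit", {
  fm <- structure(list(residuals = c(0, 0, 0, 0)), class = "fitted_model")
  d0 <- residual_diagnostics(fm)
  expect_identical(d0$mean, 0)
  ap <- gen_agent_performance(agent_config(n_trials = 150, seed = 51))
  fit <- fit_model(ap$u, ap$cv, enumerate_models()$HGF14,
                   options = list(n_starts = 2, seed = 1))
  d <- residual_diagnostics(fit)
  expect_lt(abs(d$mean), 2 * d$sem)
  expect_lt(abs(d$lag1), 0.35)
})
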