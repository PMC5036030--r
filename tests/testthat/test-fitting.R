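test_that("intercept-only conventional fit recovers psi and p", {
  sim <- simulate_dataset(sim_config(
    n_sites = 2000, n_replicates = 6, covariates = "x1",
    beta_psi = c("(Intercept)" = 0), # psi = 0.5
    alpha_p = c("(Intercept)" = logit(0.7)),
    seed = 401
  ))
  d <- occu_data(sim$detections, sim$site_covariates)
  fit <- occu_fit(d, psi = "1", p = "1", restarts = 3, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(inv_logit(fit$par[["psi_(Intercept)"]]) - 0.5), 0.05)
  expect_lt(abs(inv_logit(fit$par[["p_(Intercept)"]]) - 0.7), 0.05)
  # AIC identity on the fitted object
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-10)
  # likelihood at the MLE is at least the likelihood at the truth
  pb <- fit$problem
  expect_lte(negative_loglik(pb, fit$par),
             negative_loglik(pb, c(0, logit(0.7))) + 1e-6)
})

test_that("misclassification fit recovers a small false-positive rate", {
  sim <- simulate_dataset(sim_config(
    n_sites = 3000, n_replicates = 6, covariates = "x1",
    beta_psi = c("(Intercept)" = logit(0.4)),
    alpha_p = c("(Intercept)" = logit(0.8)),
    p10 = 0.05, seed = 402
  ))
  d <- occu_data(sim$detections, sim$site_covariates)
  fit <- occu_fit(d, psi = "1", p = "1", misclassification = TRUE,
                  restarts = 3, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(p10_hat(fit) - 0.05), 0.03)
  expect_lt(abs(inv_logit(fit$par[["psi_(Intercept)"]]) - 0.4), 0.05)
  expect_lt(abs(inv_logit(fit$par[["p_(Intercept)"]]) - 0.8), 0.05)
})

test_that("standard errors shrink like 1/sqrt(M) and ignore site order", {
  ses <- vapply(c(500, 2000, 8000), function(M) {
    sim <- simulate_dataset(sim_config(
      n_sites = M, n_replicates = 4, covariates = "x1",
      beta_psi = c("(Intercept)" = 0.2),
      alpha_p = c("(Intercept)" = 0.6), seed = 403
    ))
    d <- occu_data(sim$detections, sim$site_covariates)
    fit <- occu_fit(d, restarts = 1)
    standard_errors(fit)$std_error[1]
  }, 0)
  expect_lt(abs(ses[1] / ses[2] - 2), 0.4) # 20% of the 1/sqrt(4) ratio
  expect_lt(abs(ses[2] / ses[3] - 2), 0.4)

  # permutation invariance of the SEs
  sim <- small_survey(n_sites = 80)
  d1 <- occu_data(sim$detections, sim$site_covariates)
  perm <- withr::with_seed(5, sample(80))
  d2 <- occu_data(sim$detections[perm, ], sim$site_covariates)
  f1 <- occu_fit(d1, psi = "pop", p = "pop", restarts = 1)
  f2 <- occu_fit(d2, psi = "pop", p = "pop", restarts = 1)
  expect_equal(standard_errors(f1)$std_error, standard_errors(f2)$std_error,
               tolerance = 1e-4)
})

test_that("degenerate curvature is flagged, not silently inverted", {
  # J = 1 leaves only the product psi * p identifiable: a flat ridge
  withr::with_seed(8, {
    det <- tibble::tibble(site_id = 1:200, rep_1 = rbinom(200, 1, 0.35))
    covs <- tibble::tibble(site_id = 1:200, x = rnorm(200))
    d <- occu_data(det, covs)
    fit <- occu_fit(d, psi = "1", p = "1", restarts = 2)
    expect_true(any(grepl("standard errors undefined", fit$warnings)))
    expect_true(all(is.na(standard_errors(fit)$std_error)))
  })

  # p10 driven to its zero boundary on data without false positives
  sim <- simulate_dataset(sim_config(
    n_sites = 225, covariates = "pop",
    beta_psi = c("(Intercept)" = 0.3, pop = -0.6),
    alpha_p = c("(Intercept)" = 0.8), p10 = 0, seed = 1
  ))
  d <- occu_data(sim$detections, sim$site_covariates)
  fit <- occu_fit(d, psi = "pop", p = "1", misclassification = TRUE,
                  restarts = 3)
  expect_lt(p10_hat(fit), 0.01)
  expect_true(any(grepl("boundary", fit$warnings)))
  expect_true(is.na(standard_errors(fit)$std_error[4]))
})

test_that("prediction applies the training standardization and inverse logit", {
  d <- small_data(n_sites = 60)
  fit <- occu_fit(d, psi = "pop + rug", p = "pop", restarts = 2)
  # in-sample predictions reproduce the fitted psi_i exactly
  pred <- predict(fit)
  X <- design_matrix("pop + rug", d$site_covariates)
  expect_equal(pred$psi, unname(inv_logit(drop(X %*% fit$par[1:3]))),
               tolerance = 1e-12)
  # new raw-scale data go through the stored record
  grid <- tibble::tibble(cell_id = 1:3, pop = c(-1, 0, 2), rug = c(0, 1, -1))
  p2 <- predict(fit, grid)
  std <- apply_standardization(grid, fit$standardization)
  Xg <- design_matrix("pop + rug", std)
  expect_equal(p2$psi, unname(inv_logit(drop(Xg %*% fit$par[1:3]))),
               tolerance = 1e-12)
  expect_error(predict(fit, tibble::tibble(pop = 1)), "rug")

  # hand-set coefficients give closed-form probabilities
  fit0 <- fit
  fit0$par[] <- 0
  expect_true(all(predict(fit0)$psi == 0.5))
  fit0$par[1] <- -1.4
  expect_equal(unique(predict(fit0)$psi), 1 / (1 + exp(1.4)),
               tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- small_data(n_sites = 60)
  fit <- occu_fit(d, psi = "pop", p = "1", misclassification = TRUE,
                  restarts = 2)
  td <- tidy(fit)
  expect_equal(td$component, c("psi", "psi", "p", "p10"))
  expect_equal(nrow(td), fit$n_params)
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  expect_equal(gl$p10, p10_hat(fit))
  expect_equal(AIC(fit), fit$aic) # via the logLik method
})
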