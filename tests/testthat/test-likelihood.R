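test_that("site marginal likelihood matches hand-evaluated mixtures", {
  # J = 1, psi = p = 0.5, y = 1: psi * p = 0.25
  pb <- intercept_problem(matrix(1))
  expect_equal(site_loglik(pb, c(0, 0), 1), log(0.25), tolerance = 1e-12)

  # misclassification two-term mixture, J = 2, y = (1, 0):
  # 0.6 * 0.7 * 0.3 + 0.4 * 0.1 * 0.9 = 0.162
  pb2 <- intercept_problem(matrix(c(1, 0), 1, 2), misclassification = TRUE)
  par2 <- c(logit(0.6), logit(0.7), logit(0.1))
  expect_equal(site_loglik(pb2, par2, 1), log(0.162), tolerance = 1e-12)

  # conventional all-zero history: psi * prod(1 - p) + (1 - psi)
  pb3 <- intercept_problem(matrix(0, 1, 3))
  par3 <- c(logit(0.4), logit(0.3))
  expect_equal(site_loglik(pb3, par3, 1), log(0.4 * 0.7^3 + 0.6),
               tolerance = 1e-12)
})

test_that("misclassification model reduces to the conventional model as p10 -> 0", {
  withr::with_seed(42, {
    y <- matrix(rbinom(60, 1, 0.4), 15, 4)
    X <- cbind(`(Intercept)` = 1, x = rnorm(15))
    pb_om <- likelihood_problem(y, X, X, misclassification = FALSE)
    pb_mm <- likelihood_problem(y, X, X, misclassification = TRUE)
    th <- c(0.3, -0.6, 0.5, 0.2)
    expect_equal(
      negative_loglik(pb_mm, c(th, logit(1e-13))),
      negative_loglik(pb_om, th),
      tolerance = 1e-8
    )
  })
})

test_that("the log-likelihood is additive over sites", {
  d <- small_data(n_sites = 30)
  X <- design_matrix("pop", d$site_covariates)
  pb <- likelihood_problem(d$y, X, X, misclassification = TRUE)
  th <- c(0.2, -0.5, 0.6, -0.1, -2.5)
  per_site <- vapply(1:30, function(i) site_loglik(pb, th, i), 0)
  expect_equal(-sum(per_site), negative_loglik(pb, th), tolerance = 1e-10)

  # duplicating every site doubles the value
  pb2 <- likelihood_problem(rbind(d$y, d$y), rbind(X, X), rbind(X, X),
                            misclassification = TRUE)
  expect_equal(negative_loglik(pb2, th), 2 * negative_loglik(pb, th),
               tolerance = 1e-10)
})

test_that("vectorized likelihood agrees with brute-force latent-state enumeration", {
  withr::with_seed(99, {
    for (draw in 1:200) {
      M <- sample(1:6, 1)
      J <- sample(1:6, 1)
      mm <- draw %% 2 == 0
      y <- matrix(rbinom(M * J, 1, 0.5), M, J)
      if (J > 1 && runif(1) < 0.3) {
        y[sample(M, 1), sample(J, 1)] <- NA # keep >=1 observed per site
      }
      X_psi <- cbind(1, matrix(rnorm(M), M, 1))
      X_p <- cbind(1, matrix(rnorm(M), M, 1))
      pb <- likelihood_problem(y, X_psi, X_p, misclassification = mm)
      th <- rnorm(pb$n_params, sd = 2)
      i <- sample(M, 1)
      expect_equal(site_loglik(pb, th, i),
                   brute_force_site_loglik(pb, th, i),
                   tolerance = 1e-10)
    }
  })
})

test_that("history probabilities sum to one for both model classes", {
  withr::with_seed(7, {
    for (J in c(2, 4, 6)) {
      y <- all_histories(J)
      for (mm in c(FALSE, TRUE)) {
        pb <- intercept_problem(y, misclassification = mm)
        th <- c(rnorm(2), if (mm) rnorm(1, -2))
        tot_main <- sum(exp(vapply(
          seq_len(nrow(y)), function(i) site_loglik(pb, th, i), 0
        )))
        tot_brute <- sum(exp(vapply(
          seq_len(nrow(y)), function(i) brute_force_site_loglik(pb, th, i), 0
        )))
        expect_equal(tot_main, 1, tolerance = 1e-10)
        expect_equal(tot_brute, 1, tolerance = 1e-10)
      }
    }
  })
})

test_that("all-detections likelihood increases with detection probability", {
  y <- matrix(1, 1, 4)
  pb <- intercept_problem(y)
  etas <- seq(-2, 3, by = 0.25)
  ll <- vapply(etas, function(e) site_loglik(pb, c(logit(0.9), e), 1), 0)
  expect_true(all(diff(ll) > 0))
})

test_that("missing replicates contribute nothing to the likelihood", {
  y_full <- matrix(c(1, 0, 1), 1, 3)
  y_na <- matrix(c(1, 0, 1, NA), 1, 4)
  th <- c(0.3, 0.7, -2)
  expect_equal(
    site_loglik(intercept_problem(y_na, TRUE), th, 1),
    site_loglik(intercept_problem(y_full, TRUE), th, 1),
    tolerance = 1e-12
  )
  expect_error(intercept_problem(matrix(NA_integer_, 1, 3)), "missing")
})

test_that("analytic gradient matches central finite differences", {
  withr::with_seed(123, {
    d <- small_data(n_sites = 25, p10 = 0.05)
    X_psi <- design_matrix("pop + rug", d$site_covariates)
    X_p <- design_matrix("pop", d$site_covariates)
    for (mm in c(FALSE, TRUE)) {
      pb <- likelihood_problem(d$y, X_psi, X_p, misclassification = mm)
      for (rep in 1:3) {
        th <- rnorm(pb$n_params)
        g <- occumis:::negative_loglik_grad(pb, th)
        gn <- vapply(seq_along(th), function(i) {
          h <- 1e-6
          e <- replace(rep(0, length(th)), i, h)
          (negative_loglik(pb, th + e) - negative_loglik(pb, th - e)) / (2 * h)
        }, 0)
        expect_equal(unname(g), gn, tolerance = 1e-5)
      }
    }
  })
})

test_that("survey-specific detection covariates enter via stacked design rows", {
  withr::with_seed(55, {
    M <- 12
    J <- 3
    y <- matrix(rbinom(M * J, 1, 0.5), M, J)
    effort <- matrix(rnorm(M * J), M, J)
    # stacked replicate-major design
    X_p <- cbind(1, as.numeric(effort))
    X_psi <- matrix(1, M, 1)
    pb <- likelihood_problem(y, X_psi, X_p, misclassification = FALSE)
    th <- c(0.4, 0.2, 0.9)
    for (i in c(1, 5, 12)) {
      expect_equal(site_loglik(pb, th, i),
                   brute_force_site_loglik(pb, th, i),
                   tolerance = 1e-10)
    }
    g <- occumis:::negative_loglik_grad(pb, th)
    gn <- vapply(seq_along(th), function(i) {
      h <- 1e-6
      e <- replace(rep(0, 3), i, h)
      (negative_loglik(pb, th + e) - negative_loglik(pb, th - e)) / (2 * h)
    }, 0)
    expect_equal(unname(g), gn, tolerance = 1e-5)
  })
})
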