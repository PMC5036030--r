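test_that("candidate enumeration counts follow the subset algebra", {
  # 2 covariates, no interactions: 2^2 subsets per component, crossed
  cs <- enumerate_candidates(c("pop", "rug"), interactions = FALSE)
  expect_length(cs, 16)
  expect_identical(attr(cs, "provenance"), "enumerated")

  # 1 covariate: no pairs exist, so interactions change nothing
  expect_length(enumerate_candidates("pop", interactions = TRUE), 4)

  # with one optional interaction per component: 2 covariates give
  # {1, a, b, a+b, a*b} = 5 component formulas, 25 specs
  expect_length(enumerate_candidates(c("a", "b"), interactions = TRUE), 25)

  # labels are unique across the set
  labels <- vapply(enumerate_candidates(c("a", "b", "c")), `[[`, "", "label")
  expect_false(anyDuplicated(labels) > 0)

  # the cap refuses with the would-be count
  expect_error(
    enumerate_candidates(c("a", "b", "c", "d"), max_candidates = 100),
    "1600"
  )

  # explicit lists pass through untouched
  specs <- list(occu_spec("a", "1"), occu_spec("1", "a"), occu_spec("a", "a"))
  cs2 <- candidate_set(specs)
  expect_length(cs2, 3)
  expect_error(candidate_set(list(occu_spec("a", "1"), occu_spec("a", "1"))),
               "duplicate")
})

make_fit_stub <- function(label, loglik, k, mm = FALSE) {
  structure(
    list(
      spec = occu_spec("1", "1", misclassification = mm, label = label),
      loglik = loglik, n_params = k, aic = 2 * k - 2 * loglik,
      converged = TRUE
    ),
    class = "occu_fit"
  )
}

test_that("AIC ranking computes dAIC and Akaike weights", {
  # two models exactly 2 AIC units apart: weights 1/(1+e^-1), e^-1/(1+e^-1)
  fits <- list(make_fit_stub("A", -100, 3), make_fit_stub("B", -100, 4))
  rk <- rank_models(fits)
  expect_equal(rk$dAIC, c(0, 2))
  expect_equal(rk$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-4)
  expect_equal(sum(rk$weight), 1, tolerance = 1e-12)

  # a single model carries all the weight
  rk1 <- rank_models(list(make_fit_stub("solo", -50, 2)))
  expect_equal(rk1$weight, 1)
  expect_equal(rk1$dAIC, 0)

  # exact ties share weight equally with a stable label tie-break
  rkt <- rank_models(list(make_fit_stub("zeta", -60, 3),
                          make_fit_stub("alpha", -60, 3)))
  expect_equal(rkt$label, c("alpha", "zeta"))
  expect_equal(rkt$weight, c(0.5, 0.5))

  # non-converged fits are excluded with a message
  bad <- make_fit_stub("bad", -10, 2)
  bad$converged <- FALSE
  expect_message(rk2 <- rank_models(c(fits, list(bad))), "non-converged")
  expect_false("bad" %in% rk2$label)
  expect_error(suppressMessages(rank_models(list(bad))), "no converged")
})

test_that("two-phase selection pairs top conventional models with their MM twins", {
  sim <- small_survey(n_sites = 120, p10 = 0.04, seed = 207)
  d <- occu_data(sim$detections, sim$site_covariates)

  # single candidate: final joint table is exactly the OM/MM pair
  sel1 <- two_phase_select(
    d, candidate_set(list(occu_spec("pop", "pop"))), restarts = 2
  )
  expect_equal(nrow(sel1$ranking), 2)
  expect_setequal(sel1$ranking$class, c("OM", "MM"))
  expect_equal(sum(sel1$ranking$weight), 1, tolerance = 1e-12)

  # order of the candidate list does not change the outcome
  specs <- list(occu_spec("pop", "1"), occu_spec("1", "pop"),
                occu_spec("pop + rug", "pop"))
  sel_a <- two_phase_select(d, candidate_set(specs), restarts = 2)
  sel_b <- two_phase_select(d, candidate_set(rev(specs)), restarts = 2)
  expect_equal(sel_a$ranking, sel_b$ranking, tolerance = 1e-8)
  # every phase-2 MM label has its OM twin among the phase-1 top set
  mm_labels <- sel_a$ranking$label[sel_a$ranking$class == "MM"]
  om_twins <- sub("^MM", "OM", mm_labels)
  top_om <- sel_a$phase1_ranking$label[sel_a$phase1_ranking$dAIC < 2]
  expect_true(all(om_twins %in% top_om))
})

test_that("model averaging is a weight-renormalized convex combination", {
  sim <- small_survey(n_sites = 120, seed = 208)
  d <- occu_data(sim$detections, sim$site_covariates)
  f1 <- occu_fit(d, psi = "pop", p = "1", restarts = 2)
  f2 <- occu_fit(d, psi = "rug", p = "1", restarts = 2)
  fits <- list(f1, f2)
  rk <- rank_models(fits)

  # single-top-model averaging is the identity
  rk_one <- rk[rk$dAIC == 0, ]
  rk_one$weight <- 1
  avg1 <- model_average(fits, d$site_covariates_raw, ranking = rk_one)
  best_fit <- if (rk$label[1] == f1$spec$label) f1 else f2
  expect_equal(avg1$psi_avg, predict(best_fit)$psi, tolerance = 1e-12)

  # equal weights average the probabilities arithmetically
  rk_eq <- rk
  rk_eq$dAIC <- c(0, 0)
  rk_eq$weight <- c(0.5, 0.5)
  avg2 <- model_average(fits, d$site_covariates_raw, ranking = rk_eq)
  manual <- (predict(f1)$psi + predict(f2)$psi) / 2
  expect_equal(avg2$psi_avg, manual, tolerance = 1e-12)
  expect_equal(sum(attr(avg2, "weights")), 1, tolerance = 1e-12)

  # averages stay inside the envelope of the component predictions
  lo <- pmin(predict(f1)$psi, predict(f2)$psi)
  hi <- pmax(predict(f1)$psi, predict(f2)$psi)
  expect_true(all(avg2$psi_avg >= lo - 1e-12 & avg2$psi_avg <= hi + 1e-12))

  # a strictly dominated model never enters the dAIC < 2 set
  f_bad <- make_fit_stub("OM dominated", min(rk$logLik) - 30, 2)
  rk3 <- rank_models(c(fits, list(f_bad)))
  avg3 <- model_average(c(fits, list(f_bad)), d$site_covariates_raw,
                        ranking = rk3)
  avg_ref <- model_average(fits, d$site_covariates_raw, ranking = rk)
  expect_equal(avg3$psi_avg, avg_ref$psi_avg, tolerance = 1e-12)
})
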