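# fixtures built in code, shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small simulated survey with one occupancy and one detection covariate
small_survey <- function(n_sites = 150, p10 = 0, seed = 101,
                         missing_rate = 0) {
  simulate_dataset(sim_config(
    n_sites = n_sites, n_replicates = 4,
    covariates = c("pop", "rug"),
    beta_psi = c("(Intercept)" = 0.4, pop = -0.9, rug = 0.6),
    alpha_p = c("(Intercept)" = 0.6, pop = -0.4),
    p10 = p10, missing_rate = missing_rate, seed = seed
  ))
}

small_data <- function(...) {
  sim <- small_survey(...)
  occu_data(sim$detections, sim$site_covariates)
}

# a likelihood problem with given history matrix and intercept-only designs
intercept_problem <- function(y, misclassification = FALSE) {
  y <- as.matrix(y)
  likelihood_problem(
    y,
    X_psi = matrix(1, nrow(y), 1, dimnames = list(NULL, "(Intercept)")),
    X_p = matrix(1, nrow(y), 1, dimnames = list(NULL, "(Intercept)")),
    misclassification = misclassification
  )
}

# all 2^J detection histories of length J as a matrix
all_histories <- function(J) {
  as.matrix(expand.grid(rep(list(0:1), J)))
}
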