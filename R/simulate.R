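#' Configuration for a simulated occupancy survey
#'
#' Defaults emulate the interview-survey design the package targets:
#' `M = 225` sites of 5 x 5 km, `J = 6` spatial replicates (hunting zones) per
#' site, and four standardized site covariates (`elev`, `rug`, `for`, `pop`
#' for elevation, ruggedness, forest area and human-settlement density).
#' Occupancy and detection are logit-linear in the covariates; false-positive
#' detections at unoccupied sites occur with constant probability `p10`.
#'
#' @param n_sites Number of sites M (positive integer).
#' @param n_replicates Number of replicates J per site (positive integer).
#' @param covariates Site covariates: either a character vector of names
#'   (each drawn standard normal) or a named list of generator functions
#'   `function(n)` returning `n` numeric draws.
#' @param beta_psi Named numeric vector of occupancy coefficients. Names are
#'   `"(Intercept)"`, covariate names, or interaction terms written `"a*b"`
#'   (or `"a:b"`).
#' @param alpha_p Named numeric vector of detection coefficients (same naming
#'   rules).
#' @param p10 Constant false-positive detection probability, in `[0, 1)`.
#' @param missing_rate Probability that any site-replicate observation is
#'   missing (default 0).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list.
#' @examples
#' sim_config(beta_psi = c("(Intercept)" = 0.5, pop = -1), seed = 1)
#' @export
sim_config <- function(n_sites = 225,
                       n_replicates = 6,
                       covariates = c("elev", "rug", "for", "pop"),
                       beta_psi = c("(Intercept)" = 0),
                       alpha_p = c("(Intercept)" = 0.5),
                       p10 = 0,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(
    length(n_sites) == 1, n_sites >= 1, n_sites == round(n_sites),
    length(n_replicates) == 1, n_replicates >= 1,
    n_replicates == round(n_replicates),
    is.numeric(p10), length(p10) == 1, p10 >= 0, p10 < 1,
    is.numeric(missing_rate), missing_rate >= 0, missing_rate < 1,
    length(seed) == 1
  )
  if (is.character(covariates)) {
    covariates <- stats::setNames(
      replicate(length(covariates), stats::rnorm, simplify = FALSE),
      covariates
    )
  }
  if (!is.list(covariates) || is.null(names(covariates)) ||
      any(names(covariates) == "") ||
      !all(vapply(covariates, is.function, TRUE))) {
    stop("covariates must be a character vector of names or a named list of generator functions")
  }
  check_terms <- function(coefs, what) {
    if (is.null(names(coefs)) || any(names(coefs) == "")) {
      stop(what, " must be a fully named numeric vector")
    }
    for (term in names(coefs)) {
      if (term == "(Intercept)") next
      parts <- strsplit(gsub("[[:space:]]", "", term), "[*:]")[[1]]
      unknown <- setdiff(parts, names(covariates))
      if (length(parts) > 2 || length(unknown) > 0) {
        stop(what, " references unknown or unsupported term: ", term)
      }
    }
  }
  check_terms(beta_psi, "beta_psi")
  check_terms(alpha_p, "alpha_p")
  structure(
    list(
      n_sites = as.integer(n_sites),
      n_replicates = as.integer(n_replicates),
      covariates = covariates,
      beta_psi = beta_psi,
      alpha_p = alpha_p,
      p10 = p10,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# evaluate a named coefficient map against a covariate table
linear_predictor <- function(coefs, data) {
  eta <- rep(0, nrow(data))
  for (term in names(coefs)) {
    if (term == "(Intercept)") {
      eta <- eta + coefs[[term]]
    } else {
      parts <- strsplit(gsub("[[:space:]]", "", term), "[*:]")[[1]]
      x <- data[[parts[1]]]
      if (length(parts) == 2) x <- x * data[[parts[2]]]
      eta <- eta + coefs[[term]] * x
    }
  }
  eta
}

#' Draw site covariates from a simulation configuration
#'
#' @param config A [sim_config()].
#' @return A tibble with `site_id` and one column per declared covariate;
#'   default generators produce standard-normal (pre-standardized) columns.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$covariates) == 0) stop("covariate specification is empty")
  withr::with_seed(config$seed, simulate_covariates_impl(config))
}

simulate_covariates_impl <- function(config) {
  cols <- lapply(config$covariates, function(g) {
    x <- g(config$n_sites)
    if (!is.numeric(x) || length(x) != config$n_sites) {
      stop("covariate generator must return n_sites numeric values")
    }
    x
  })
  tibble::as_tibble(c(list(site_id = seq_len(config$n_sites)), cols))
}

#' Draw latent occupancy states
#'
#' Computes `true_psi = inv_logit(X beta)` from the occupancy coefficient map
#' and draws `true_z[i] ~ Bernoulli(true_psi[i])`.
#'
#' @param config A [sim_config()].
#' @param covariates Site covariate tibble from [simulate_covariates()].
#' @return A list with `true_z` (0/1 integer vector) and `true_psi`.
#' @export
simulate_occupancy <- function(config, covariates) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(
    config$seed + 1L,
    simulate_occupancy_impl(config, covariates)
  )
}

simulate_occupancy_impl <- function(config, covariates) {
  psi <- inv_logit(linear_predictor(config$beta_psi, covariates))
  z <- stats::rbinom(length(psi), 1L, psi)
  list(true_z = z, true_psi = psi)
}

#' Draw detection histories
#'
#' Occupied sites generate `Y_ij ~ Bernoulli(p_ij)` with
#' `p_ij = inv_logit(X alpha)`; unoccupied sites generate false positives
#' `Y_ij ~ Bernoulli(p10)`. A positive `missing_rate` blanks observations at
#' random (missing at random).
#'
#' @param config A [sim_config()].
#' @param covariates Site covariate tibble.
#' @param true_z Latent occupancy vector of length `n_sites`.
#' @return A list with `detections` (M x J integer matrix, `NA` = missing)
#'   and `true_p` (M x J matrix of detection probabilities given presence).
#' @export
simulate_detections <- function(config, covariates, true_z) {
  stopifnot(inherits(config, "sim_config"),
            length(true_z) == config$n_sites)
  withr::with_seed(
    config$seed + 2L,
    simulate_detections_impl(config, covariates, true_z)
  )
}

simulate_detections_impl <- function(config, covariates, true_z) {
  M <- config$n_sites
  J <- config$n_replicates
  p <- inv_logit(linear_predictor(config$alpha_p, covariates))
  true_p <- matrix(p, M, J)
  prob <- ifelse(true_z == 1, p, config$p10)
  y <- matrix(stats::rbinom(M * J, 1L, rep(prob, J)), M, J)
  if (config$missing_rate > 0) {
    y[stats::runif(M * J) < config$missing_rate] <- NA_integer_
  }
  colnames(y) <- paste0("rep_", seq_len(J))
  list(detections = y, true_p = true_p)
}

#' Simulate a full dataset with known truth
#'
#' Runs [simulate_covariates()], [simulate_occupancy()] and
#' [simulate_detections()] under the config's single seed; identical configs
#' yield bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @return An object of class `occu_sim`: a list with `detections` (tibble
#'   `site_id, rep_1, ...`), `site_covariates` (tibble), `truth` (tibble
#'   `site_id, z, psi, p_1, ...` — sidecar never consumed by fitting), and
#'   `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_sites = 20, seed = 7))
#' sim$detections
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  covariates <- withr::with_seed(config$seed, simulate_covariates_impl(config))
  occ <- withr::with_seed(
    config$seed + 1L, simulate_occupancy_impl(config, covariates)
  )
  det <- withr::with_seed(
    config$seed + 2L,
    simulate_detections_impl(config, covariates, occ$true_z)
  )
  J <- config$n_replicates
  detections <- tibble::as_tibble(cbind(
    tibble::tibble(site_id = covariates$site_id),
    tibble::as_tibble(det$detections)
  ))
  pmat <- det$true_p
  colnames(pmat) <- paste0("p_", seq_len(J))
  truth <- tibble::as_tibble(cbind(
    tibble::tibble(
      site_id = covariates$site_id,
      z = occ$true_z,
      psi = occ$true_psi
    ),
    tibble::as_tibble(pmat)
  ))
  structure(
    list(
      detections = detections,
      site_covariates = covariates,
      truth = truth,
      config = config
    ),
    class = "occu_sim"
  )
}

#' @export
print.occu_sim <- function(x, ...) {
  cat(
    "<occu_sim> ", x$config$n_sites, " sites x ", x$config$n_replicates,
    " replicates, p10 = ", x$config$p10, ", seed = ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated dataset to CSV files
#'
#' Detections and covariates are written in the dialect the readers expect
#' (comma-separated, UTF-8, empty string for missing). The truth sidecar
#' (latent states, psi, p, seed) is a separate file so fitting never sees it.
#'
#' @param sim An `occu_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "occu_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    detections = file.path(dir, "detections.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(sim$detections, paths[["detections"]], na = "")
  readr::write_csv(sim$site_covariates, paths[["covariates"]], na = "")
  truth <- sim$truth
  truth$seed <- sim$config$seed
  readr::write_csv(truth, paths[["truth"]], na = "")
  invisible(paths)
}
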