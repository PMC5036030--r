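#' Assemble a likelihood problem
#'
#' Packages the detection matrix with the occupancy and detection design
#' matrices for evaluation of the site-marginal log-likelihood. The site
#' marginal sums over the latent occupancy state z:
#' conventional model
#' `L_i = psi_i * prod_j p_ij^y (1-p_ij)^(1-y) + (1-psi_i) * 1{all y_ij = 0}`;
#' misclassification model
#' `L_i = psi_i * prod_j p_ij^y (1-p_ij)^(1-y) +
#'        (1-psi_i) * prod_j p10^y (1-p10)^(1-y)`.
#' Missing replicates are skipped in both products.
#'
#' @param y M x J matrix of 0/1 detections, `NA` = missing; every row needs
#'   at least one non-missing entry.
#' @param X_psi M x k_psi occupancy design matrix.
#' @param X_p Detection design matrix: M x k_p (site-level covariates) or
#'   (M*J) x k_p stacked replicate-major (survey covariates).
#' @param misclassification Logical; estimate a scalar false-positive rate
#'   `p10` (intercept-only, on the logit scale)?
#' @return A `likelihood_problem` list; `n_params` gives the parameter count.
#' @export
likelihood_problem <- function(y, X_psi, X_p, misclassification = FALSE) {
  y <- as.matrix(y)
  M <- nrow(y)
  stopifnot(
    nrow(X_psi) == M,
    nrow(X_p) == M || nrow(X_p) == M * ncol(y),
    all(y %in% c(0, 1) | is.na(y))
  )
  if (any(rowSums(!is.na(y)) == 0)) {
    stop("site(s) with all replicates missing")
  }
  structure(
    list(
      y = y,
      X_psi = X_psi,
      X_p = X_p,
      misclassification = isTRUE(misclassification),
      n_sites = M,
      n_replicates = ncol(y),
      n_params = ncol(X_psi) + ncol(X_p) + isTRUE(misclassification)
    ),
    class = "likelihood_problem"
  )
}

# split a flat parameter vector into (beta, alpha, logit_p10)
split_params <- function(problem, params) {
  kb <- ncol(problem$X_psi)
  ka <- ncol(problem$X_p)
  stopifnot(length(params) == problem$n_params)
  list(
    beta = params[seq_len(kb)],
    alpha = params[kb + seq_len(ka)],
    logit_p10 = if (problem$misclassification) params[kb + ka + 1] else -Inf
  )
}

# log(p) and log(1-p) of inv_logit(eta), stable over the full double range
log_plogis <- function(eta) stats::plogis(eta, log.p = TRUE)

# per-site pieces shared by value and gradient:
# logA = log P(history | occupied), logB = log P(history | unoccupied)
loglik_pieces <- function(problem, params) {
  pr <- split_params(problem, params)
  y <- problem$y
  M <- problem$n_sites
  J <- problem$n_replicates
  obs <- !is.na(y)
  y0 <- ifelse(obs, y, 0L)

  eta_psi <- drop(problem$X_psi %*% pr$beta)
  eta_p <- matrix(drop(problem$X_p %*% pr$alpha), M, J)

  lp <- log_plogis(eta_p)
  l1mp <- log_plogis(-eta_p)
  logA <- rowSums((y0 * lp + (1 - y0) * l1mp) * obs)

  n_obs <- rowSums(obs)
  n_det <- rowSums(y0)
  if (problem$misclassification) {
    logB <- n_det * log_plogis(pr$logit_p10) +
      (n_obs - n_det) * log_plogis(-pr$logit_p10)
  } else {
    logB <- ifelse(n_det == 0, 0, -Inf)
  }

  l_psi <- log_plogis(eta_psi)
  l_1mpsi <- log_plogis(-eta_psi)
  # stable two-term log-sum-exp
  t1 <- l_psi + logA
  t2 <- l_1mpsi + logB
  m <- pmax(t1, t2)
  m[!is.finite(m)] <- 0 # both -Inf cannot occur: logA is finite
  logL <- m + log(exp(t1 - m) + exp(t2 - m))

  list(
    pr = pr, obs = obs, y0 = y0,
    eta_psi = eta_psi, eta_p = eta_p,
    logA = logA, logB = logB, t1 = t1, t2 = t2, logL = logL,
    n_obs = n_obs, n_det = n_det
  )
}

#' Site-marginal log-likelihood of one site
#'
#' @param problem A [likelihood_problem()].
#' @param params Flat parameter vector: occupancy coefficients, detection
#'   coefficients, then `logit_p10` when the problem is a misclassification
#'   model.
#' @param site_index Site row (1-based).
#' @return The log of the site's marginal likelihood.
#' @examples
#' pb <- likelihood_problem(matrix(1), matrix(1), matrix(1))
#' site_loglik(pb, c(0, 0), 1) # log(0.25): psi = p = 0.5, y = 1
#' @export
site_loglik <- function(problem, params, site_index) {
  stopifnot(site_index >= 1, site_index <= problem$n_sites)
  loglik_pieces(problem, params)$logL[site_index]
}

#' Negative log-likelihood over all sites
#'
#' The objective minimized by [occu_fit()]: `-sum_i site_loglik(i)`.
#'
#' @inheritParams site_loglik
#' @return A single number, finite at interior parameter values.
#' @export
negative_loglik <- function(problem, params) {
  -sum(loglik_pieces(problem, params)$logL)
}

# analytic gradient of negative_loglik (checked against finite differences
# in the test suite):
#   d logL_i / d beta  = (wA_i - psi_i) x_i
#   d logL_i / d alpha = wA_i * sum_j (y_ij - p_ij) x_pij
#   d logL_i / d lp10  = wB_i * sum_j (y_ij - p10)        (observed j only)
# with wA_i = psi_i A_i / L_i the posterior probability of occupancy.
negative_loglik_grad <- function(problem, params) {
  pc <- loglik_pieces(problem, params)
  M <- problem$n_sites
  psi <- stats::plogis(pc$eta_psi)
  wA <- exp(pc$t1 - pc$logL)
  wB <- exp(pc$t2 - pc$logL)

  g_beta <- drop(crossprod(problem$X_psi, wA - psi))

  p <- stats::plogis(pc$eta_p)
  r <- wA * ((pc$y0 - p) * pc$obs) # M x J residual matrix
  if (nrow(problem$X_p) == M) {
    g_alpha <- drop(crossprod(problem$X_p, rowSums(r)))
  } else {
    g_alpha <- drop(crossprod(problem$X_p, as.numeric(r)))
  }

  if (problem$misclassification) {
    p10 <- stats::plogis(pc$pr$logit_p10)
    g_p10 <- sum(wB * (pc$n_det - pc$n_obs * p10))
    -c(g_beta, g_alpha, g_p10)
  } else {
    -c(g_beta, g_alpha)
  }
}

#' Brute-force site log-likelihood by latent-state enumeration
#'
#' Independent oracle for [site_loglik()]: explicitly enumerates the latent
#' occupancy state z in {0, 1} and accumulates
#' `sum_z P(z) prod_j P(y_ij | z)` in plain probability space with
#' [stats::dbinom()], with no shared code with the vectorized path.
#'
#' @inheritParams site_loglik
#' @return The log of the site's marginal likelihood.
#' @export
brute_force_site_loglik <- function(problem, params, site_index) {
  pr <- split_params(problem, params)
  y <- problem$y[site_index, ]
  M <- problem$n_sites
  J <- problem$n_replicates
  psi <- 1 / (1 + exp(-sum(problem$X_psi[site_index, ] * pr$beta)))
  if (nrow(problem$X_p) == M) {
    eta <- rep(sum(problem$X_p[site_index, ] * pr$alpha), J)
  } else {
    eta <- vapply(seq_len(J), function(j) {
      sum(problem$X_p[(j - 1) * M + site_index, ] * pr$alpha)
    }, 0)
  }
  p10 <- if (problem$misclassification) 1 / (1 + exp(-pr$logit_p10)) else 0
  total <- 0
  for (z in 0:1) {
    prob_z <- if (z == 1) psi else 1 - psi
    cond <- 1
    for (j in seq_len(J)) {
      if (is.na(y[j])) next
      pj <- if (z == 1) 1 / (1 + exp(-eta[j])) else p10
      cond <- cond * stats::dbinom(y[j], 1, pj)
    }
    total <- total + prob_z * cond
  }
  log(total)
}
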