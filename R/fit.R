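#' Specify one candidate occupancy model
#'
#' @param psi Occupancy formula (string or [occu_formula()]).
#' @param p Detection formula.
#' @param misclassification Logical; estimate a constant false-positive rate
#'   `p10` in addition to the false-negative structure?
#' @param label Optional label; defaults to a Table-style
#'   `"OM psi(...) p(...)"` / `"MM psi(...) p(...)"` string that uniquely
#'   identifies the spec within a candidate set.
#' @return An `occu_spec` object.
#' @examples
#' occu_spec("pop + rug", "pop * elev + for", misclassification = TRUE)
#' @export
occu_spec <- function(psi = "1", p = "1", misclassification = FALSE,
                      label = NULL) {
  psi <- occu_formula(psi)
  p <- occu_formula(p)
  if (is.null(label)) {
    label <- sprintf(
      "%s psi(%s) p(%s)",
      if (misclassification) "MM" else "OM", format(psi), format(p)
    )
  }
  structure(
    list(
      psi_formula = psi, p_formula = p,
      misclassification = isTRUE(misclassification), label = label
    ),
    class = "occu_spec"
  )
}

#' @export
print.occu_spec <- function(x, ...) {
  cat("<occu_spec> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Minimizes the site-marginal negative log-likelihood (see
#' [likelihood_problem()]) by BFGS with an analytic gradient on the
#' unconstrained (logit/identity) scale, using multiple starts: the first
#' start is deterministic (zero coefficients; for misclassification models
#' the detection intercept starts at +1 and `logit_p10` at -3, i.e.
#' `p10 ~ 0.047`), the remaining `restarts - 1` are standard-normal
#' perturbations of it. The best optimum is kept. For misclassification
#' models a label-swap check guards the `p11 > p10` identifiability
#' convention: if the fitted site-mean detection probability falls below the
#' fitted `p10`, the model is refit from a swapped start and the
#' higher-likelihood solution kept, with a warning recorded either way.
#' Standard errors come from the inverse of a central-finite-difference
#' Hessian (step 1e-5 per coordinate).
#'
#' @param data An [occu_data()] object.
#' @param spec An [occu_spec()]; alternatively give `psi`, `p` and
#'   `misclassification` directly.
#' @param psi,p,misclassification Used only when `spec` is `NULL`.
#' @param restarts Total number of optimizer starts (default 5).
#' @param seed Integer seed for the random restarts.
#' @param control Passed to [stats::optim()] (defaults:
#'   `reltol = 1e-8`, `maxit = 1000`).
#' @return An object of class `occu_fit` with the MLE (`par`), covariance
#'   (`vcov`), `loglik`, `n_params`, `aic`, `converged`, `n_restarts_used`
#'   and accumulated `warnings`. A fit where every start fails is returned
#'   with `converged = FALSE`, not raised as an error.
#' @examples
#' sim <- simulate_dataset(sim_config(
#'   n_sites = 100, covariates = "pop",
#'   beta_psi = c("(Intercept)" = 0.4, pop = -0.8),
#'   alpha_p = c("(Intercept)" = 0.8), seed = 11
#' ))
#' d <- occu_data(sim$detections, sim$site_covariates)
#' occu_fit(d, psi = "pop", p = "1", restarts = 2)
#' @export
occu_fit <- function(data, spec = NULL, psi = "1", p = "1",
                     misclassification = FALSE, restarts = 5, seed = 1L,
                     control = list()) {
  stopifnot(inherits(data, "occu_data"))
  if (is.null(spec)) spec <- occu_spec(psi, p, misclassification)
  stopifnot(inherits(spec, "occu_spec"))

  X_psi <- design_matrix(spec$psi_formula, data$site_covariates)
  X_p <- p_design_matrix(data, spec$p_formula)
  problem <- likelihood_problem(data$y, X_psi, X_p, spec$misclassification)
  k <- problem$n_params

  start0 <- rep(0, k)
  if (spec$misclassification) {
    start0[ncol(X_psi) + 1] <- 1 # detection intercept
    start0[k] <- -3 # logit_p10
  }
  starts <- c(
    list(start0),
    if (restarts > 1) {
      withr::with_seed(seed, lapply(seq_len(restarts - 1), function(i) {
        start0 + stats::rnorm(k)
      }))
    }
  )
  control <- utils::modifyList(list(reltol = 1e-8, maxit = 1000), control)

  run_optim <- function(st) {
    tryCatch(
      stats::optim(
        st, fn = negative_loglik, gr = negative_loglik_grad,
        problem = problem, method = "BFGS", control = control
      ),
      error = function(e) NULL
    )
  }
  results <- lapply(starts, run_optim)
  results <- results[!vapply(results, is.null, TRUE)]
  results <- results[vapply(results, function(r) is.finite(r$value), TRUE)]

  warnings <- character(0)
  if (length(results) == 0) {
    return(new_occu_fit(
      spec, data, problem,
      par = stats::setNames(start0, param_names(problem)),
      vcov = matrix(NA_real_, k, k), loglik = NA_real_, converged = FALSE,
      n_restarts_used = length(starts),
      warnings = "all optimizer starts failed"
    ))
  }
  best <- results[[which.min(vapply(results, `[[`, 0, "value"))]]

  # identifiability guard: enforce p11 > p10 by swap-refit
  if (spec$misclassification) {
    sp <- split_params(problem, best$par)
    p11_mean <- mean(stats::plogis(drop(X_p %*% sp$alpha)))
    p10_hat <- stats::plogis(sp$logit_p10)
    if (p11_mean < p10_hat) {
      warnings <- c(warnings, "label swap detected (p11 < p10); refit from swapped start")
      swapped <- best$par
      swapped[ncol(X_psi) + 1] <- sp$logit_p10
      swapped[ncol(X_psi) + seq_len(ncol(X_p))][-1] <- 0
      swapped[k] <- logit(min(max(p11_mean, 1e-6), 1 - 1e-6))
      res2 <- run_optim(swapped)
      if (!is.null(res2) && is.finite(res2$value) && res2$value < best$value) {
        best <- res2
      }
    }
  }

  converged <- best$convergence == 0
  if (!converged) {
    warnings <- c(warnings, paste0("optim convergence code ", best$convergence))
  }
  par <- stats::setNames(best$par, param_names(problem))

  H <- numeric_hessian(function(v) negative_loglik(problem, v), best$par)
  kap <- tryCatch(kappa(H, exact = FALSE), error = function(e) Inf)
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vcov) || !is.finite(kap) || kap > 1e10 ||
      any(!is.finite(diag(vcov))) || any(diag(vcov) < 0)) {
    warnings <- c(
      warnings,
      "Hessian singular or near-singular; standard errors undefined (parameter at boundary or not identified)"
    )
    vcov <- matrix(NA_real_, k, k)
  }
  dimnames(vcov) <- list(names(par), names(par))
  # a Wald SE above 10 on the logit scale spans essentially (0, 1): the
  # parameter carries no information (flat ridge or boundary), so its SE is
  # reported as undefined rather than as a meaningless large number
  vague <- which(sqrt(diag(vcov)) > 10)
  if (length(vague) > 0) {
    warnings <- c(warnings, paste0(
      "standard errors undefined for ",
      paste(names(par)[vague], collapse = ", "),
      " (flat likelihood: parameter at boundary or not identified)"
    ))
    vcov[vague, ] <- vcov[, vague] <- NA_real_
  }
  if (spec$misclassification && stats::plogis(par[[k]]) < 1e-5) {
    warnings <- c(
      warnings,
      "p10 estimate at the zero boundary; its logit-scale standard error is undefined"
    )
    vcov[k, ] <- vcov[, k] <- NA_real_
  }

  new_occu_fit(
    spec, data, problem, par = par, vcov = vcov, loglik = -best$value,
    converged = converged, n_restarts_used = length(starts),
    warnings = warnings
  )
}

param_names <- function(problem) {
  c(
    paste0("psi_", colnames(problem$X_psi)),
    paste0("p_", colnames(problem$X_p)),
    if (problem$misclassification) "logit_p10"
  )
}

new_occu_fit <- function(spec, data, problem, par, vcov, loglik, converged,
                         n_restarts_used, warnings) {
  k <- problem$n_params
  structure(
    list(
      spec = spec,
      par = par,
      vcov = vcov,
      loglik = loglik,
      n_params = k,
      aic = 2 * k - 2 * loglik,
      converged = converged,
      n_restarts_used = n_restarts_used,
      warnings = warnings,
      n_sites = problem$n_sites,
      n_replicates = problem$n_replicates,
      standardization = data$standardization,
      site_covariates_raw = data$site_covariates_raw,
      problem = problem
    ),
    class = "occu_fit"
  )
}

# central finite-difference Hessian, fixed step per coordinate
numeric_hessian <- function(f, x, h = 1e-5) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  step <- function(i, s) {
    v <- x
    v[i] <- v[i] + s * h
    v
  }
  for (i in seq_len(k)) {
    H[i, i] <- (f(step(i, 1)) - 2 * f0 + f(step(i, -1))) / h^2
    if (i < k) {
      for (j in seq((i + 1), k)) {
        vpp <- x; vpp[c(i, j)] <- vpp[c(i, j)] + h
        vpm <- x; vpm[i] <- vpm[i] + h; vpm[j] <- vpm[j] - h
        vmp <- x; vmp[i] <- vmp[i] - h; vmp[j] <- vmp[j] + h
        vmm <- x; vmm[c(i, j)] <- vmm[c(i, j)] - h
        H[i, j] <- H[j, i] <- (f(vpp) - f(vpm) - f(vmp) + f(vmm)) / (4 * h^2)
      }
    }
  }
  H
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("<occu_fit> ", x$spec$label, "\n", sep = "")
  cat(
    "  logLik ", format(x$loglik, digits = 6),
    ", AIC ", format(x$aic, digits = 6),
    ", k = ", x$n_params,
    ", converged: ", x$converged, "\n",
    sep = ""
  )
  if (length(x$warnings) > 0) {
    cat("  warnings: ", paste(x$warnings, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_sites,
            class = "logLik")
}

#' Standard errors of a fitted model
#'
#' Square roots of the diagonal of the inverse finite-difference Hessian of
#' the negative log-likelihood at the MLE; `NA` with a recorded warning when
#' the curvature is degenerate (e.g. `p10` driven to its boundary on data
#' without false positives).
#'
#' @param fit An `occu_fit`.
#' @return A tibble with `term`, `estimate`, `std_error`.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  tibble::tibble(
    term = names(fit$par),
    estimate = unname(fit$par),
    std_error = sqrt(diag(fit$vcov))
  )
}

#' Estimated false-positive rate
#' @param fit An `occu_fit`.
#' @return `p10` on the probability scale; 0 for conventional models.
#' @export
p10_hat <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  if (fit$spec$misclassification) {
    unname(stats::plogis(fit$par[["logit_p10"]]))
  } else {
    0
  }
}

#' Predict occupancy and detection probabilities
#'
#' Applies the training standardization record to `newdata` (raw covariate
#' scale), builds the design matrices and maps the linear predictors through
#' the inverse logit. For misclassification models the returned `p` is the
#' detection probability given presence (p11).
#'
#' @param object An `occu_fit`.
#' @param newdata Data frame with the covariates the formulas need (raw
#'   scale), e.g. a prediction grid; defaults to the training sites.
#' @param ... Unused.
#' @return A tibble with the key column (`site_id`/`cell_id` when present),
#'   `psi` and `p`.
#' @export
predict.occu_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$site_covariates_raw
  newdata <- tibble::as_tibble(newdata)
  need <- union(
    formula_covariates(object$spec$psi_formula),
    formula_covariates(object$spec$p_formula)
  )
  rep_terms <- setdiff(need, object$standardization$covariate)
  if (length(rep_terms) > 0) {
    stop(
      "prediction with survey-specific covariates is not supported: ",
      paste(rep_terms, collapse = ", ")
    )
  }
  missing <- setdiff(need, names(newdata))
  if (length(missing) > 0) {
    stop(
      "covariate column(s) required for prediction: ",
      paste(missing, collapse = ", ")
    )
  }
  std <- apply_standardization(newdata, object$standardization)
  X_psi <- design_matrix(object$spec$psi_formula, std)
  X_p <- design_matrix(object$spec$p_formula, std)
  kb <- ncol(object$problem$X_psi)
  beta <- object$par[seq_len(kb)]
  alpha <- object$par[kb + seq_len(ncol(object$problem$X_p))]
  out <- tibble::tibble(
    psi = stats::plogis(drop(X_psi %*% beta)),
    p = stats::plogis(drop(X_p %*% alpha))
  )
  keys <- intersect(c("site_id", "cell_id"), names(newdata))
  if (length(keys) > 0) {
    out <- dplyr::bind_cols(newdata[keys[1]], out)
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted occupancy model
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `component` (`psi`, `p` or `p10`),
#'   `estimate`, `std.error`.
#' @export
tidy.occu_fit <- function(x, ...) {
  se <- standard_errors(x)
  tibble::tibble(
    term = se$term,
    component = dplyr::case_when(
      se$term == "logit_p10" ~ "p10",
      startsWith(se$term, "psi_") ~ "psi",
      TRUE ~ "p"
    ),
    estimate = se$estimate,
    std.error = se$std_error
  )
}

#' Glance at a fitted occupancy model
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `label`, `misclassification`, `k`, `logLik`,
#'   `AIC`, `p10`, `converged`, `nobs`.
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(
    label = x$spec$label,
    misclassification = x$spec$misclassification,
    k = x$n_params,
    logLik = x$loglik,
    AIC = x$aic,
    p10 = p10_hat(x),
    converged = x$converged,
    nobs = x$n_sites
  )
}
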