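#' Enumerate a candidate model set
#'
#' Default generator: every subset of main effects for the occupancy
#' component crossed with every subset for the detection component, each
#' subset optionally augmented by a single two-way interaction between
#' covariates present in that component. With `interactions = FALSE` the set
#' is the plain subset cross (e.g. 2 covariates give 4 x 4 = 16 specs). A
#' user-supplied list of [occu_spec()]s bypasses enumeration entirely
#' (`candidate_set()`).
#'
#' @param covariates Character vector of 1–8 covariate names.
#' @param interactions Allow one two-way interaction per component?
#' @param misclassification Logical; enumerate misclassification specs
#'   instead of conventional ones (the two-phase workflow starts
#'   conventional).
#' @param max_candidates Refuse (with the would-be count) above this cap,
#'   prompting an explicit list.
#' @return A `candidate_set`: list of `occu_spec` with a `provenance`
#'   attribute.
#' @examples
#' length(enumerate_candidates(c("pop", "rug"), interactions = FALSE)) # 16
#' @export
enumerate_candidates <- function(covariates, interactions = TRUE,
                                 misclassification = FALSE,
                                 max_candidates = 2000) {
  stopifnot(
    is.character(covariates), length(covariates) >= 1,
    length(covariates) <= 8, !anyDuplicated(covariates)
  )
  subsets <- unlist(
    lapply(0:length(covariates), function(k) {
      utils::combn(covariates, k, simplify = FALSE)
    }),
    recursive = FALSE
  )
  component_formulas <- unlist(lapply(subsets, function(s) {
    base <- if (length(s) == 0) "1" else paste(s, collapse = " + ")
    out <- list(base)
    if (interactions && length(s) >= 2) {
      for (pair in utils::combn(s, 2, simplify = FALSE)) {
        rest <- setdiff(s, pair)
        out <- c(out, paste(
          c(paste(pair, collapse = " * "), rest),
          collapse = " + "
        ))
      }
    }
    out
  }))
  n <- length(component_formulas)^2
  if (n > max_candidates) {
    stop(
      "enumeration would produce ", n, " candidates (cap ", max_candidates,
      "); supply an explicit candidate list instead"
    )
  }
  specs <- list()
  for (f_psi in component_formulas) {
    for (f_p in component_formulas) {
      specs <- c(specs, list(occu_spec(f_psi, f_p, misclassification)))
    }
  }
  candidate_set(specs, provenance = "enumerated")
}

#' Build a candidate set from explicit specs
#'
#' @param specs List of [occu_spec()] objects with unique labels.
#' @param provenance `"user-listed"` or `"enumerated"`.
#' @return A `candidate_set`.
#' @export
candidate_set <- function(specs, provenance = "user-listed") {
  stopifnot(all(vapply(specs, inherits, TRUE, "occu_spec")))
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("duplicate candidate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(specs, class = "candidate_set", provenance = provenance)
}

#' Rank fitted models by AIC
#'
#' Computes `dAIC_m = AIC_m - min(AIC)` and Akaike weights
#' `w_m = exp(-dAIC_m / 2) / sum(exp(-dAIC / 2))`. Non-converged fits are
#' excluded with a message. Ties are broken stably by label order.
#'
#' @param fits List of `occu_fit` objects.
#' @return An `occu_ranking` tibble: `label`, `class` (`"OM"`/`"MM"`), `k`,
#'   `logLik`, `AIC`, `dAIC`, `weight`, sorted ascending by AIC.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, TRUE, "occu_fit")))
  ok <- vapply(fits, `[[`, TRUE, "converged")
  if (any(!ok)) {
    dropped <- vapply(fits[!ok], function(f) f$spec$label, "")
    message("excluding non-converged fit(s): ", paste(dropped, collapse = "; "))
  }
  fits <- fits[ok]
  if (length(fits) == 0) stop("no converged fits to rank")
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      label = f$spec$label,
      class = if (f$spec$misclassification) "MM" else "OM",
      k = f$n_params,
      logLik = f$loglik,
      AIC = f$aic
    )
  })
  tab <- dplyr::arrange(tab, .data$AIC, .data$label)
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rel <- exp(-tab$dAIC / 2)
  tab$weight <- rel / sum(rel)
  class(tab) <- c("occu_ranking", class(tab))
  tab
}

#' Two-phase model selection with misclassification counterparts
#'
#' Phase 1 fits every (conventional) candidate and ranks by AIC. Phase 2
#' refits each phase-1 model with `dAIC < phase2_cut` as its
#' misclassification counterpart (same formulas plus the scalar `p10`). The
#' final ranking covers the union of the phase-1 top models and their
#' phase-2 counterparts, with Akaike weights renormalized over that union so
#' they sum to 1. Per-model fitting failures are collected, not fatal.
#'
#' @param data An [occu_data()].
#' @param candidates A `candidate_set` of conventional specs.
#' @param phase2_cut dAIC threshold for entering phase 2 (default 2).
#' @param restarts,seed,control Passed to [occu_fit()].
#' @return An `occu_selection` list: `ranking` (final joint
#'   `occu_ranking`), `fits` (named by label, the union), `phase1_ranking`,
#'   and `warnings`.
#' @export
two_phase_select <- function(data, candidates, phase2_cut = 2,
                             restarts = 5, seed = 1L, control = list()) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (any(vapply(candidates, `[[`, TRUE, "misclassification"))) {
    stop("phase-1 candidates must be conventional (misclassification = FALSE)")
  }
  fit_one <- function(spec) {
    t0 <- proc.time()[["elapsed"]]
    f <- tryCatch(
      occu_fit(data, spec, restarts = restarts, seed = seed,
               control = control),
      error = function(e) {
        warning("fit failed for ", spec$label, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(f)) f$elapsed <- proc.time()[["elapsed"]] - t0
    f
  }
  phase1 <- purrr::compact(lapply(candidates, fit_one))
  names(phase1) <- vapply(phase1, function(f) f$spec$label, "")
  # stable across candidate order: rank_models sorts by (AIC, label)
  phase1_ranking <- rank_models(phase1)

  top_labels <- phase1_ranking$label[phase1_ranking$dAIC < phase2_cut]
  top_fits <- phase1[top_labels]
  phase2 <- purrr::compact(lapply(top_fits, function(f) {
    fit_one(occu_spec(f$spec$psi_formula, f$spec$p_formula,
                      misclassification = TRUE))
  }))
  names(phase2) <- vapply(phase2, function(f) f$spec$label, "")

  final_fits <- c(top_fits, phase2)
  ranking <- rank_models(final_fits)
  final_fits <- final_fits[ranking$label]

  structure(
    list(
      ranking = ranking,
      fits = final_fits,
      phase1_ranking = phase1_ranking,
      warnings = unlist(lapply(final_fits, `[[`, "warnings"))
    ),
    class = "occu_selection"
  )
}

#' @export
print.occu_selection <- function(x, ...) {
  cat("<occu_selection> ", nrow(x$phase1_ranking), " phase-1 models, ",
      nrow(x$ranking), " in final joint ranking\n", sep = "")
  print(tibble::as_tibble(x$ranking))
  invisible(x)
}

#' Model-averaged occupancy and detection predictions
#'
#' Restricts to models with `dAIC < cut` (the best model always qualifies),
#' renormalizes their Akaike weights to sum to 1, and averages each model's
#' predicted probabilities on the probability scale. For misclassification
#' models the averaged detection probability is p11 (detection given
#' presence); the weighted `p10` is returned as an attribute
#' (conventional models contribute `p10 = 0`).
#'
#' @param selection An `occu_selection` (or a list of fits plus a `ranking`).
#' @param newdata Covariate table (raw scale) to predict on: the surveyed
#'   sites or a prediction grid.
#' @param cut dAIC inclusion threshold (default 2).
#' @param ranking Optional explicit `occu_ranking` when `selection` is a
#'   plain list of fits.
#' @return A tibble with the key column, `psi_avg` and `p_avg`; attributes
#'   `weights` (renormalized, named by label) and `p10_avg`.
#' @export
model_average <- function(selection, newdata, cut = 2, ranking = NULL) {
  if (inherits(selection, "occu_selection")) {
    fits <- selection$fits
    ranking <- selection$ranking
  } else {
    fits <- selection
    if (is.null(ranking)) stop("supply a ranking for a plain list of fits")
    names(fits) <- vapply(fits, function(f) f$spec$label, "")
  }
  top <- ranking[ranking$dAIC < cut, ]
  w <- top$weight / sum(top$weight)
  names(w) <- top$label
  preds <- lapply(top$label, function(lb) predict(fits[[lb]], newdata))
  psi_avg <- Reduce(`+`, purrr::map2(preds, w, ~ .x$psi * .y))
  p_avg <- Reduce(`+`, purrr::map2(preds, w, ~ .x$p * .y))
  out <- tibble::tibble(psi_avg = psi_avg, p_avg = p_avg)
  keys <- intersect(c("site_id", "cell_id"), names(preds[[1]]))
  if (length(keys) > 0) out <- dplyr::bind_cols(preds[[1]][keys[1]], out)
  attr(out, "weights") <- w
  attr(out, "p10_avg") <- sum(w * vapply(fits[top$label], p10_hat, 0))
  attr(out, "any_misclassification") <- any(top$class == "MM")
  out
}
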