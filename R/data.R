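#' Bundle detection histories with covariates
#'
#' Aligns the site covariate table (and optional replicate-level covariate
#' tables) to the detection histories by `site_id` — never by row order —
#' and standardizes every covariate to mean 0, sd 1, keeping the
#' centering/scaling record for later prediction on a grid.
#'
#' @param detections Tibble with columns `site_id, rep_1, ..., rep_J`;
#'   entries 0/1 or `NA` for missing. Every site needs at least one
#'   non-missing replicate.
#' @param site_covariates Tibble with `site_id` plus numeric covariate
#'   columns; no missing values (no imputation is performed).
#' @param rep_covariates Optional named list of survey-specific covariates,
#'   each a tibble `site_id, rep_1, ..., rep_J` giving that covariate's value
#'   per site and replicate.
#' @return An object of class `occu_data`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_sites = 30, seed = 2))
#' occu_data(sim$detections, sim$site_covariates)
#' @export
occu_data <- function(detections, site_covariates, rep_covariates = NULL) {
  detections <- tibble::as_tibble(detections)
  site_covariates <- tibble::as_tibble(site_covariates)
  stopifnot("site_id" %in% names(detections),
            "site_id" %in% names(site_covariates))
  if (anyDuplicated(detections$site_id)) {
    stop("duplicate site_id in detections")
  }
  if (anyDuplicated(site_covariates$site_id)) {
    stop("duplicate site_id in covariates")
  }
  rep_cols <- grep("^rep_[0-9]+$", names(detections), value = TRUE)
  if (length(rep_cols) == 0) stop("detections has no rep_* columns")
  rep_cols <- paste0("rep_", seq_len(length(rep_cols)))
  y <- as.matrix(detections[rep_cols])
  if (!all(y %in% c(0, 1) | is.na(y))) {
    bad <- which(!(y %in% c(0, 1) | is.na(y)), arr.ind = TRUE)[1, ]
    stop(
      "non-binary detection entry at site_id ",
      detections$site_id[bad[1]], ", ", rep_cols[bad[2]]
    )
  }
  if (any(rowSums(!is.na(y)) == 0)) {
    stop("site(s) with all replicates missing: ",
         paste(detections$site_id[rowSums(!is.na(y)) == 0], collapse = ", "))
  }
  unmatched <- setdiff(detections$site_id, site_covariates$site_id)
  if (length(unmatched) > 0) {
    stop("site_id in detections without covariates: ",
         paste(utils::head(unmatched, 10), collapse = ", "))
  }
  site_covariates <- site_covariates[
    match(detections$site_id, site_covariates$site_id),
  ]
  if (anyNA(site_covariates)) {
    stop("missing covariate values are not allowed (no imputation)")
  }
  std <- standardize_covariates(site_covariates)

  rep_std <- NULL
  if (!is.null(rep_covariates)) {
    stopifnot(is.list(rep_covariates), !is.null(names(rep_covariates)))
    rep_std <- lapply(rep_covariates, function(tab) {
      tab <- tibble::as_tibble(tab)
      stopifnot("site_id" %in% names(tab))
      tab <- tab[match(detections$site_id, tab$site_id), ]
      m <- as.matrix(tab[rep_cols])
      if (anyNA(m)) stop("missing replicate-covariate values are not allowed")
      ctr <- mean(m)
      scl <- stats::sd(as.numeric(m))
      if (!is.finite(scl) || scl == 0) stop("zero-variance replicate covariate")
      list(values = (m - ctr) / scl, center = ctr, scale = scl)
    })
  }

  structure(
    list(
      site_id = detections$site_id,
      y = y,
      n_sites = nrow(y),
      n_replicates = ncol(y),
      site_covariates_raw = site_covariates,
      site_covariates = std$data,
      standardization = std$record,
      rep_covariates = rep_std
    ),
    class = "occu_data"
  )
}

#' @export
print.occu_data <- function(x, ...) {
  cat(
    "<occu_data> ", x$n_sites, " sites x ", x$n_replicates, " replicates, ",
    nrow(x$standardization), " site covariate(s)",
    if (!is.null(x$rep_covariates)) {
      paste0(", ", length(x$rep_covariates), " replicate covariate(s)")
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

# Build the detection design matrix for an occu_data object. Site-level-only
# formulas give an M x k matrix; formulas touching replicate covariates give
# an (M*J) x k matrix stacked replicate-major (all sites for rep 1, then
# rep 2, ...) so that matrix(X %*% a, M, J) reshapes correctly.
p_design_matrix <- function(data, formula) {
  f <- occu_formula(formula)
  need <- formula_covariates(f)
  rep_names <- names(data$rep_covariates)
  if (length(intersect(need, rep_names)) == 0) {
    return(design_matrix(f, data$site_covariates))
  }
  M <- data$n_sites
  J <- data$n_replicates
  long <- data$site_covariates[rep(seq_len(M), times = J), ]
  for (v in intersect(need, rep_names)) {
    long[[v]] <- as.numeric(data$rep_covariates[[v]]$values)
  }
  design_matrix(f, long)
}
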