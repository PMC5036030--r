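#' Naïve occupancy estimate
#'
#' The observed proportion of sites with at least one detection, uncorrected
#' for imperfect detection: `x` sites detected out of `M`, naïve
#' `psi = x / M`. A site with any 1 among its non-missing replicates counts
#' as detected.
#'
#' @param detections Detection histories: a tibble with `site_id` and
#'   `rep_*` columns, an [occu_data()], or a plain 0/1/NA matrix.
#' @return A one-row tibble: `x`, `n_sites`, `naive_psi`.
#' @examples
#' y <- rbind(c(1, 0), c(0, 0), c(NA, 1))
#' naive_occupancy(y) # x = 2 of 3
#' @export
naive_occupancy <- function(detections) {
  y <- as_detection_matrix(detections)
  if (nrow(y) == 0) stop("empty detection matrix")
  detected <- apply(y, 1, function(r) any(r == 1, na.rm = TRUE))
  tibble::tibble(
    x = sum(detected),
    n_sites = nrow(y),
    naive_psi = sum(detected) / nrow(y)
  )
}

as_detection_matrix <- function(detections) {
  if (inherits(detections, "occu_data")) {
    return(detections$y)
  }
  if (is.data.frame(detections)) {
    rep_cols <- grep("^rep_[0-9]+$", names(detections), value = TRUE)
    return(as.matrix(detections[rep_cols]))
  }
  as.matrix(detections)
}

#' Region-level occupancy and detection summary
#'
#' The standard summary row for one species: detected-site count `x`, naïve
#' `psi = x/M`, the mean model-averaged occupancy over the surveyed sites
#' (the sum of occupancy probabilities for all surveyed cells divided by the
#' number of sites), and the mean model-averaged occupancy and detection
#' probabilities over all grid cells of the region.
#'
#' @param site_predictions Model-averaged predictions at the surveyed sites
#'   (tibble with `psi_avg`, `p_avg`), e.g. from [model_average()].
#' @param grid_predictions Model-averaged predictions at the regional grid
#'   cells (same columns).
#' @param detections Detection histories for the surveyed sites (any form
#'   accepted by [naive_occupancy()]); row count must match
#'   `site_predictions`.
#' @param p10 Estimated false-positive rate, or `NULL` when the averaged
#'   model set contains no misclassification model (defaults to the
#'   `p10_avg` attribute of `site_predictions` when present).
#' @return A one-row tibble: `x`, `n_sites`, `naive_psi`, `psi_hat_sites`,
#'   `psi_bar_region`, `p_bar_region`, `p10_hat` (`NA` when absent).
#' @export
occupancy_summary <- function(site_predictions, grid_predictions, detections,
                              p10 = NULL) {
  stopifnot(nrow(site_predictions) > 0, nrow(grid_predictions) > 0)
  y <- as_detection_matrix(detections)
  if (nrow(y) != nrow(site_predictions)) {
    stop("detections and site predictions disagree on the number of sites")
  }
  if (is.null(p10) && isTRUE(attr(site_predictions, "any_misclassification"))) {
    p10 <- attr(site_predictions, "p10_avg")
  }
  naive <- naive_occupancy(y)
  tibble::tibble(
    x = naive$x,
    n_sites = naive$n_sites,
    naive_psi = naive$naive_psi,
    psi_hat_sites = mean(site_predictions$psi_avg),
    psi_bar_region = mean(grid_predictions$psi_avg),
    p_bar_region = mean(grid_predictions$p_avg),
    p10_hat = if (is.null(p10)) NA_real_ else p10
  )
}

#' Export a prediction grid to CSV
#'
#' Writes one row per cell, ordered by `cell_id`, probabilities at 6+
#' decimal places. Columns: `cell_id`, coordinates and covariates passed
#' through, then `psi_avg`, `p_avg`.
#'
#' @param grid Tibble with `cell_id`, optional `easting`/`northing`,
#'   covariates, and `psi_avg`/`p_avg` columns.
#' @param path Output file path.
#' @return Invisibly, the exported tibble.
#' @export
export_grid <- function(grid, path) {
  stopifnot("cell_id" %in% names(grid),
            all(c("psi_avg", "p_avg") %in% names(grid)))
  grid <- dplyr::arrange(tibble::as_tibble(grid), .data$cell_id)
  front <- intersect(c("cell_id", "easting", "northing"), names(grid))
  back <- c("psi_avg", "p_avg")
  grid <- grid[c(front, setdiff(names(grid), c(front, back)), back)]
  out <- grid
  out$psi_avg <- sprintf("%.6f", out$psi_avg)
  out$p_avg <- sprintf("%.6f", out$p_avg)
  readr::write_csv(out, path, na = "")
  invisible(grid)
}
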