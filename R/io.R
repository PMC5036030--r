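#' Read detection histories from CSV
#'
#' Expected dialect: comma-separated, UTF-8, header
#' `site_id,rep_1,...,rep_J`; entries 0/1 or empty for missing.
#'
#' @param path CSV file path.
#' @return A tibble with `site_id` and integer `rep_*` columns (`NA` =
#'   missing).
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  tab <- readr::read_csv(path, col_types = readr::cols(), na = "",
                         progress = FALSE)
  rep_cols <- grep("^rep_[0-9]+$", names(tab), value = TRUE)
  if (!"site_id" %in% names(tab) || length(rep_cols) == 0) {
    stop("detections header must be site_id,rep_1,...,rep_J")
  }
  if (anyDuplicated(tab$site_id)) {
    stop("duplicate site_id: ",
         paste(unique(tab$site_id[duplicated(tab$site_id)]), collapse = ", "))
  }
  for (cn in rep_cols) {
    v <- tab[[cn]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad) > 0) {
      stop("non-binary entry '", v[bad[1]], "' at site_id ",
           tab$site_id[bad[1]], ", column ", cn)
    }
    tab[[cn]] <- as.integer(v)
  }
  tab[c("site_id", rep_cols)]
}

#' Read a site covariate table from CSV
#'
#' @param path CSV file path with header `site_id,<covariate>...`.
#' @param site_ids Optional site ids that must all be present (alignment is
#'   always by key downstream, never by row order).
#' @return A tibble.
#' @export
read_covariates <- function(path, site_ids = NULL) {
  if (!file.exists(path)) stop("covariates file not found: ", path)
  tab <- readr::read_csv(path, col_types = readr::cols(), na = "",
                         progress = FALSE)
  if (!"site_id" %in% names(tab)) stop("covariates header must include site_id")
  covs <- setdiff(names(tab), "site_id")
  if (anyNA(tab[covs])) {
    stop("missing covariate value(s); imputation is not performed")
  }
  if (!is.null(site_ids)) {
    unmatched <- setdiff(site_ids, tab$site_id)
    if (length(unmatched) > 0) {
      stop("site_id without covariates: ",
           paste(utils::head(unmatched, 10), collapse = ", "))
    }
  }
  tab
}

#' Read a prediction-grid covariate table from CSV
#'
#' @param path CSV with header `cell_id,...` (covariates plus any extra
#'   columns, which pass through to the exported grid).
#' @return A tibble ordered by `cell_id`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  tab <- readr::read_csv(path, col_types = readr::cols(), na = "",
                         progress = FALSE)
  if (!"cell_id" %in% names(tab)) stop("grid header must include cell_id")
  if (anyDuplicated(tab$cell_id)) stop("duplicate cell_id in grid")
  dplyr::arrange(tab, .data$cell_id)
}

#' Read and validate a run configuration (YAML)
#'
#' Schema (all blocks optional unless noted):
#' \preformatted{
#' paths: {detections: ..., covariates: ..., grid: ..., out_dir: ...}
#' candidates:
#'   covariates: [elev, rug, for, pop]   # enumeration, or
#'   interactions: true
#'   specs: [{psi: "pop + rug", p: "elev"}, ...]  # explicit list
#' selection: {delta_aic: 2.0, phase2_cut: 2.0}
#' optimizer: {restarts: 5, seed: 1}
#' simulate: {n_sites: 225, n_replicates: 6, covariates: [...],
#'            beta_psi: {"(Intercept)": 0.5, pop: -1}, alpha_p: {...},
#'            p10: 0.03, missing_rate: 0, seed: 1}
#' }
#'
#' @param path YAML file path.
#' @return The validated config list, class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  defaults <- list(
    paths = list(),
    candidates = list(interactions = TRUE),
    selection = list(delta_aic = 2.0, phase2_cut = 2.0),
    optimizer = list(restarts = 5, seed = 1L)
  )
  for (block in names(defaults)) {
    cfg[[block]] <- utils::modifyList(defaults[[block]], cfg[[block]] %||% list())
  }
  if (cfg$selection$delta_aic <= 0 || cfg$selection$phase2_cut <= 0) {
    stop("selection thresholds must be positive")
  }
  if (is.null(cfg$paths$detections) && is.null(cfg$simulate)) {
    stop("config needs either paths$detections or a simulate block")
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_sim_config <- function(sim) {
  sim_config(
    n_sites = sim$n_sites %||% 225,
    n_replicates = sim$n_replicates %||% 6,
    covariates = unlist(sim$covariates) %||% c("elev", "rug", "for", "pop"),
    beta_psi = unlist(sim$beta_psi) %||% c("(Intercept)" = 0),
    alpha_p = unlist(sim$alpha_p) %||% c("(Intercept)" = 0.5),
    p10 = sim$p10 %||% 0,
    missing_rate = sim$missing_rate %||% 0,
    seed = sim$seed %||% 1L
  )
}

config_candidates <- function(cand, covariate_names) {
  if (!is.null(cand$specs)) {
    candidate_set(lapply(cand$specs, function(s) {
      occu_spec(s$psi %||% "1", s$p %||% "1")
    }))
  } else {
    enumerate_candidates(
      unlist(cand$covariates) %||% covariate_names,
      interactions = isTRUE(cand$interactions),
      max_candidates = cand$max_candidates %||% 2000
    )
  }
}

#' Run the full occupancy analysis pipeline
#'
#' Simulate-or-read the data, run [two_phase_select()], model-average over
#' the dAIC < 2 set, summarize, and export: writes `ranking.csv`,
#' `summary.csv`, `grid.csv` and `run.log` (seed, package and R versions,
#' per-model timing, convergence and identifiability warnings) under the
#' output directory. When no prediction grid is supplied, the surveyed-site
#' covariate table serves as the grid.
#'
#' @param config A `run_config` list, or a YAML path.
#' @param out_dir Output directory (overrides `paths$out_dir`).
#' @param seed Overrides `optimizer$seed`.
#' @return Invisibly, a list with `data`, `selection`, `site_predictions`,
#'   `grid_predictions`, `summary` and the output `paths`.
#' @export
run_occupancy_analysis <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out_dir <- out_dir %||% config$paths$out_dir %||% stop("no output directory")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed %||% config$optimizer$seed)
  log_lines <- c(
    paste0("occumis ", as.character(utils::packageVersion("occumis")),
           " | ", R.version.string),
    paste0("seed: ", seed),
    paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  )

  if (!is.null(config$paths$detections)) {
    detections <- read_detections(config$paths$detections)
    covariates <- read_covariates(config$paths$covariates,
                                  site_ids = detections$site_id)
    log_lines <- c(log_lines, paste0("data: read from ", config$paths$detections))
  } else {
    sc <- config_sim_config(config$simulate)
    sim <- simulate_dataset(sc)
    write_dataset(sim, file.path(out_dir, "data"))
    detections <- sim$detections
    covariates <- sim$site_covariates
    log_lines <- c(log_lines, paste0(
      "data: simulated (", sc$n_sites, " sites x ", sc$n_replicates,
      " replicates, p10 = ", sc$p10, ", sim seed = ", sc$seed, ")"
    ))
  }
  data <- occu_data(detections, covariates)

  candidates <- config_candidates(
    config$candidates, config$simulate$covariate_names %||%
      setdiff(names(covariates), "site_id")
  )
  selection <- two_phase_select(
    data, candidates,
    phase2_cut = config$selection$phase2_cut,
    restarts = config$optimizer$restarts, seed = seed
  )
  timing <- vapply(selection$fits, function(f) f$elapsed %||% NA_real_, 0)
  log_lines <- c(
    log_lines,
    paste0("phase-1 candidates: ", length(candidates)),
    paste0("final joint ranking: ", nrow(selection$ranking), " models"),
    paste0("timing[s] ", names(timing), ": ", round(timing, 3)),
    if (length(selection$warnings) > 0) {
      paste0("warning: ", selection$warnings)
    } else "no fitting warnings"
  )

  site_pred <- model_average(selection, data$site_covariates_raw,
                             cut = config$selection$delta_aic)
  if (!is.null(config$paths$grid)) {
    grid_tab <- read_grid(config$paths$grid)
  } else {
    grid_tab <- dplyr::rename(data$site_covariates_raw, cell_id = "site_id")
    log_lines <- c(log_lines, "grid: none supplied; using surveyed sites")
  }
  grid_pred <- model_average(selection, grid_tab,
                             cut = config$selection$delta_aic)
  grid_out <- dplyr::bind_cols(
    grid_tab,
    grid_pred[c("psi_avg", "p_avg")]
  )

  summary_tab <- occupancy_summary(site_pred, grid_pred, data)

  paths <- c(
    ranking = file.path(out_dir, "ranking.csv"),
    summary = file.path(out_dir, "summary.csv"),
    grid = file.path(out_dir, "grid.csv"),
    log = file.path(out_dir, "run.log")
  )
  readr::write_csv(tibble::as_tibble(selection$ranking), paths[["ranking"]])
  readr::write_csv(summary_tab, paths[["summary"]])
  export_grid(grid_out, paths[["grid"]])
  if (length(selection$warnings) > 0) {
    message("fitting warnings surfaced in run.log and summary output")
  }
  writeLines(log_lines, paths[["log"]])

  invisible(list(
    data = data, selection = selection, site_predictions = site_pred,
    grid_predictions = grid_pred, summary = summary_tab, paths = paths
  ))
}
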