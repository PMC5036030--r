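#' Parse a covariate formula string
#'
#' Formulas use the compact field notation for occupancy and detection
#' components: main effects joined by `+`, two-way interactions written with
#' `*`, e.g. `"pop * elev + for"`. An interaction `a * b` expands to the main
#' effects `a` and `b` plus their product term, so `"pop * elev + for"` has
#' main effects `pop`, `elev`, `for` and one interaction column `pop:elev`.
#' The intercept is always present. `"1"`, `""` and `NULL` all denote an
#' intercept-only component.
#'
#' @param x A formula string, or an existing `occu_formula` (returned as-is).
#' @return An object of class `occu_formula` with elements `main_terms`
#'   (character vector, declaration order), `interaction_terms` (list of
#'   character pairs) and `label` (canonical string form).
#' @examples
#' occu_formula("rug * pop + for")
#' occu_formula("1")
#' @export
occu_formula <- function(x) {
  if (inherits(x, "occu_formula")) {
    return(x)
  }
  if (is.null(x) || length(x) == 0) x <- "1"
  stopifnot(is.character(x), length(x) == 1)
  txt <- gsub("[[:space:]]+", "", x)
  main <- character(0)
  inter <- list()
  if (!txt %in% c("", "1", "~1")) {
    for (term in strsplit(txt, "+", fixed = TRUE)[[1]]) {
      if (term == "" || term == "1") next
      parts <- strsplit(term, "[*:]")[[1]]
      if (length(parts) == 1) {
        main <- union(main, parts)
      } else if (length(parts) == 2) {
        if (parts[1] == parts[2]) {
          stop("interaction of a covariate with itself is not supported: ", term)
        }
        # conventional expansion: a * b contributes both main effects
        main <- union(main, parts)
        inter <- c(inter, list(parts))
      } else {
        stop("only two-way interactions are supported: ", term)
      }
    }
  }
  # drop duplicate interactions irrespective of member order
  if (length(inter) > 1) {
    keys <- vapply(inter, function(p) paste(sort(p), collapse = ":"), "")
    inter <- inter[!duplicated(keys)]
  }
  out <- structure(
    list(main_terms = main, interaction_terms = inter),
    class = "occu_formula"
  )
  out$label <- format(out)
  out
}

#' @export
format.occu_formula <- function(x, ...) {
  terms <- c(
    x$main_terms,
    vapply(x$interaction_terms, paste, "", collapse = " * ")
  )
  if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
}

#' @export
print.occu_formula <- function(x, ...) {
  cat("<occu_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Covariates referenced by a formula
#' @param formula An `occu_formula` or formula string.
#' @return Character vector of covariate names.
#' @export
formula_covariates <- function(formula) {
  f <- occu_formula(formula)
  union(f$main_terms, unlist(f$interaction_terms))
}

#' Standardize covariate columns
#'
#' Centers and scales every non-key numeric column to mean 0 and sample
#' standard deviation 1 (denominator n - 1). The returned record carries the
#' centering/scaling constants so that the identical transform can later be
#' applied to a prediction grid with [apply_standardization()].
#'
#' @param data A data frame of covariates. Columns named `site_id` or
#'   `cell_id` are treated as keys and passed through untouched.
#' @param record Optional record from a previous call; when supplied, its
#'   constants are applied instead of recomputing them.
#' @return A list with `data` (standardized tibble) and `record` (tibble with
#'   columns `covariate`, `center`, `scale`).
#' @examples
#' standardize_covariates(data.frame(site_id = 1:3, elev = c(1, 2, 3)))
#' @export
standardize_covariates <- function(data, record = NULL) {
  data <- tibble::as_tibble(data)
  keys <- intersect(c("site_id", "cell_id"), names(data))
  covs <- setdiff(names(data), keys)
  if (is.null(record)) {
    bad <- covs[!vapply(data[covs], is.numeric, TRUE)]
    if (length(bad) > 0) {
      stop("non-numeric covariate column(s): ", paste(bad, collapse = ", "))
    }
    center <- vapply(data[covs], mean, 0)
    scale <- vapply(data[covs], stats::sd, 0)
    degenerate <- covs[!is.finite(scale) | scale == 0]
    if (length(degenerate) > 0) {
      stop(
        "zero-variance covariate column(s): ",
        paste(degenerate, collapse = ", ")
      )
    }
    record <- tibble::tibble(covariate = covs, center = center, scale = scale)
  }
  out <- apply_standardization(data, record)
  list(data = out, record = record)
}

#' Apply a stored standardization to new data
#'
#' @param data A data frame holding at least the covariates named in `record`
#'   (extra columns pass through unchanged).
#' @param record A record returned by [standardize_covariates()].
#' @return A tibble with the recorded covariates transformed as
#'   `(x - center) / scale`.
#' @export
apply_standardization <- function(data, record) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(record$covariate, names(data))
  if (length(missing) > 0) {
    stop("covariate column(s) absent: ", paste(missing, collapse = ", "))
  }
  for (k in seq_len(nrow(record))) {
    v <- record$covariate[k]
    data[[v]] <- (data[[v]] - record$center[k]) / record$scale[k]
  }
  data
}

#' Invert a stored standardization
#' @inheritParams apply_standardization
#' @return A tibble with the recorded covariates mapped back to raw scale.
#' @export
invert_standardization <- function(data, record) {
  data <- tibble::as_tibble(data)
  for (k in seq_len(nrow(record))) {
    v <- record$covariate[k]
    data[[v]] <- data[[v]] * record$scale[k] + record$center[k]
  }
  data
}

#' Build a design matrix from a formula and standardized covariates
#'
#' Columns are ordered intercept first, then main effects in declaration
#' order, then interaction columns in declaration order. Each interaction
#' column is the elementwise product of its two (already standardized) main
#' effect columns; products are not re-standardized.
#'
#' @param formula An `occu_formula` or formula string.
#' @param data Standardized covariate data frame (one row per site or cell).
#' @return A numeric matrix with `"(Intercept)"` as the first column and an
#'   attribute `row_ids` carrying `site_id`/`cell_id` when present.
#' @examples
#' d <- data.frame(rug = c(1, -1), pop = c(-1, 0.5))
#' design_matrix("rug * pop", d)
#' @export
design_matrix <- function(formula, data) {
  f <- occu_formula(formula)
  data <- tibble::as_tibble(data)
  need <- formula_covariates(f)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("unknown covariate(s) in formula: ", paste(missing, collapse = ", "))
  }
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in f$main_terms) cols[[v]] <- as.numeric(data[[v]])
  for (p in f$interaction_terms) {
    cols[[paste(p, collapse = ":")]] <-
      as.numeric(data[[p[1]]]) * as.numeric(data[[p[2]]])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  keys <- intersect(c("site_id", "cell_id"), names(data))
  if (length(keys) > 0) attr(X, "row_ids") <- data[[keys[1]]]
  X
}

#' Logit and inverse-logit link functions
#'
#' Thin, domain-checked wrappers around [stats::qlogis()] and
#' [stats::plogis()]; `inv_logit()` is numerically stable over the whole
#' double range.
#'
#' @param p Probabilities strictly inside (0, 1).
#' @param x Real values.
#' @return `logit()` returns log-odds; `inv_logit()` returns probabilities.
#' @examples
#' inv_logit(0)      # 0.5
#' logit(inv_logit(3.7))
#' @export
logit <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("logit is defined only on (0, 1)")
  }
  stats::qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)
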