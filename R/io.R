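#' Read and write growth-series CSV files
#'
#' Growth series are stored as plain CSV with columns `time_days`, `size` and
#' optionally `label`. Reading validates the schema: required columns, a
#' non-empty table, strictly increasing times within each label and
#' non-negative sizes.
#'
#' @param data A growth-series tibble.
#' @param path File path.
#' @return `read_growth_series()` returns a validated tibble;
#'   `write_growth_series()` returns `data` invisibly.
#' @export
write_growth_series <- function(data, path) {
  validate_growth_series_multi(data)
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_growth_series
#' @export
read_growth_series <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_growth_series_multi(data)
  data
}

validate_growth_series_multi <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("a growth series must be a non-empty data frame")
  }
  if (!all(c("time_days", "size") %in% names(data))) {
    abort("a growth series needs columns `time_days` and `size`")
  }
  split_by <- if ("label" %in% names(data)) data$label else
    rep(1L, nrow(data))
  for (part in split(data, split_by)) validate_growth_series(part)
  invisible(data)
}

#' Read and write trajectory CSV files
#'
#' Trajectories (stochastic or expected) are stored as CSV with columns
#' `division_index`, optional `time_hours`, `n_healthy`, `n_cancer`,
#' `n_mutant`. Reading validates monotone division indices and a constant
#' population total.
#'
#' @param data A trajectory tibble (from [simulate_moran()] or
#'   [expected_trajectory()]).
#' @param path File path.
#' @export
write_trajectory <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(data)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("division_index", "n_healthy", "n_cancer", "n_mutant")
  if (!all(need %in% names(data))) {
    abort("a trajectory needs columns division_index, n_healthy, n_cancer, n_mutant")
  }
  if (is.unsorted(data$division_index, strictly = TRUE)) {
    abort("`division_index` must be strictly increasing")
  }
  tot <- data$n_healthy + data$n_cancer + data$n_mutant
  if (length(unique(tot)) != 1L) {
    abort("population total must be constant along a trajectory")
  }
  data
}

#' Write ensemble outputs
#'
#' Writes the per-step summary (`<prefix>_summary.csv`) and the per-replicate
#' final states (`<prefix>_replicates.csv`).
#'
#' @param ensemble A `moran_ensemble`.
#' @param prefix Path prefix for the two CSV files.
#' @return The two file paths, invisibly.
#' @export
write_ensemble <- function(ensemble, prefix) {
  paths <- paste0(prefix, c("_summary.csv", "_replicates.csv"))
  readr::write_csv(ensemble$summary, paths[1])
  readr::write_csv(ensemble$replicates, paths[2])
  invisible(paths)
}

#' Write a fit result
#'
#' Stores the fitted parameters and diagnostics as JSON and the full RMSE
#' surface as CSV alongside (`<path>.csv` when `path` ends in `.json`).
#'
#' @param fit A `moran_fit`.
#' @param path JSON file path.
#' @return The JSON path, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  surface_path <- sub("\\.json$", ".csv", path)
  if (identical(surface_path, path)) surface_path <- paste0(path, ".csv")
  readr::write_csv(fit$grid, surface_path)
  jsonlite::write_json(
    list(stage = fit$stage,
         estimates = as.list(fit$estimates),
         rmse = fit$rmse, N = fit$N, init_prop = fit$init_prop,
         n_grid = nrow(fit$grid),
         eff_m_identifiable = fit$diagnostics$eff_m_identifiable %||% NA,
         rmse_surface = basename(surface_path)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
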