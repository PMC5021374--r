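titration_cols <- c("mutant_fraction", "replicate", "count", "scale")

check_header <- function(path, expected) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(header, expected)) {
    abort(sprintf(
      "%s: expected header `%s`, found `%s` (columns are not guessed).",
      path, paste(expected, collapse = ","), paste(header, collapse = ",")
    ))
  }
}

#' Read and write titration CSV files
#'
#' The titration dialect is a UTF-8, dot-decimal CSV with the exact header
#' `mutant_fraction,replicate,count,scale`; files with any other header are
#' rejected rather than guessed at.
#'
#' @param path File path.
#' @return `read_titration()` returns a validated titration tibble.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  check_header(path, titration_cols)
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      mutant_fraction = readr::col_double(),
      replicate = readr::col_character(),
      count = readr::col_double(),
      scale = readr::col_double()
    )
  )
  validate_titration(data, require_control = FALSE)
}

#' @rdname read_titration
#' @param data A titration tibble.
#' @export
write_titration <- function(data, path) {
  readr::write_csv(data[, titration_cols], path)
  invisible(path)
}

#' Read a gradient profile CSV (`fraction,intensity`)
#'
#' @param path File path.
#' @return A validated gradient profile tibble.
#' @export
read_gradient_profile <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  check_header(path, c("fraction", "intensity"))
  validate_profile(readr::read_csv(
    path,
    col_types = readr::cols(
      fraction = readr::col_integer(), intensity = readr::col_double()
    )
  ))
}

#' Read a marker CSV (`mass_kda,peak_fraction`)
#'
#' @param path File path.
#' @return A marker tibble suitable for [calibrate_gradient()].
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  check_header(path, c("mass_kda", "peak_fraction"))
  readr::read_csv(
    path,
    col_types = readr::cols(
      mass_kda = readr::col_double(), peak_fraction = readr::col_double()
    )
  )
}

fit_to_list <- function(fit) {
  list(
    z_hat = fit$z_hat, K_hat = fit$K_hat, mode_hat = fit$mode_hat,
    A0_hat = fit$A0_hat, loglik = fit$loglik, aic = fit$aic,
    loglik_table = fit$grid,
    package_version = as.character(utils::packageVersion("ringstoich"))
  )
}

#' Fit a titration CSV and write the result as JSON
#'
#' File-level wrapper around [fit_stoichiometry()]: reads the titration
#' dialect, fits, and (optionally) writes a JSON document containing the
#' selected model, the full log-likelihood table and the fitted activity
#' curve for plotting.
#'
#' @param csv Path to a titration CSV.
#' @param out Optional path for the JSON result.
#' @param ... Passed to [fit_stoichiometry()].
#' @return The `ring_fit`, invisibly.
#' @export
run_fit <- function(csv, out = NULL, ...) {
  data <- read_titration(csv)
  fit <- fit_stoichiometry(data, ...)
  if (!is.null(out)) {
    model <- ring_model(fit$z_hat, fit$K_hat, fit$mode_hat)
    payload <- c(fit_to_list(fit), list(
      activity_curve = activity_curve(model, seq(0, 1, by = 0.02),
                                      fit$settings$rule)
    ))
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(fit)
}

#' Analyse a gradient profile CSV against a marker CSV
#'
#' Reads both files, calibrates, detects peaks and assigns oligomer orders;
#' optionally writes the calibration, peaks and assignments as JSON.
#'
#' @param profile_csv Path to a `fraction,intensity` CSV.
#' @param markers_csv Path to a `mass_kda,peak_fraction` CSV.
#' @param subunit_mass Monomer mass in kDa.
#' @param out Optional JSON output path.
#' @param ... Passed to [detect_peaks()].
#' @return The assignment tibble, invisibly.
#' @export
run_gradient <- function(profile_csv, markers_csv, subunit_mass, out = NULL,
                         ...) {
  profile <- read_gradient_profile(profile_csv)
  cal <- calibrate_gradient(read_markers(markers_csv))
  peaks <- detect_peaks(profile, ...)
  assigned <- assign_oligomer_states(peaks, cal, subunit_mass)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(
        calibration = list(slope = cal$slope, intercept = cal$intercept),
        peaks = assigned,
        package_version = as.character(utils::packageVersion("ringstoich"))
      ),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(assigned)
}

#' Simulate a titration dataset to CSV
#'
#' @param out Path for the titration CSV.
#' @param design A [titration_design()].
#' @return The simulated tibble, invisibly; the design is also written as
#'   JSON alongside the CSV (`<out>.design.json`).
#' @export
run_simulate <- function(out, design = titration_design(seed = 1)) {
  data <- simulate_titration(design)
  write_titration(data, out)
  jsonlite::write_json(
    list(
      p_grid = design$p_grid, n_replicates = design$n_replicates,
      control_mean = design$control_mean, scale = design$scale,
      truth = list(z = design$model$z, K = design$model$K,
                   mode = design$model$mode,
                   requires_donor = design$rule$requires_donor),
      seed = design$seed
    ),
    paste0(out, ".design.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(data)
}

#' Simulate a sequential-cycle trajectory to CSV
#'
#' Draws one ring composition at mutant fraction `p` and writes its
#' translocation trajectory (`cycle,engaged_subunit,translocated_bp,stalled`).
#'
#' @param out Path for the trajectory CSV.
#' @param p Mutant fraction of the pool.
#' @param model A [ring_model()] (`K = 1`).
#' @param config A [sim_config()]; its seed governs the composition draw.
#' @return The trajectory tibble, invisibly.
#' @export
run_ringsim <- function(out, p = 0, model = ring_model(6, 1),
                        config = sim_config(seed = 1)) {
  draw <- function() runif(model$z) < p
  comp <- if (is.null(config$seed)) draw() else {
    withr::with_seed(config$seed, draw())
  }
  traj <- simulate_ring(ring_state(comp), config)
  readr::write_csv(traj, out)
  invisible(traj)
}
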