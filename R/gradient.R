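#' Validate a gradient fractionation profile
#'
#' A profile is one rate-zonal (e.g. 15--35% glycerol) gradient read out as
#' fluorescence per fraction. Fractions are numbered 1..n bottom-to-top, the
#' collection order, so heavier species peak at *smaller* fraction indices.
#'
#' @param profile Data frame with columns `fraction` (unique integers,
#'   contiguous from 1) and `intensity` (nonnegative).
#' @return The profile as a tibble, ordered by fraction.
#' @export
validate_profile <- function(profile) {
  if (!all(c("fraction", "intensity") %in% names(profile))) {
    abort("profile needs columns `fraction` and `intensity`.")
  }
  profile <- as_tibble(profile) |> arrange(.data$fraction)
  f <- profile$fraction
  if (anyNA(f) || !identical(as.integer(f), seq_len(nrow(profile)))) {
    abort("`fraction` must be unique integers contiguous from 1.")
  }
  if (anyNA(profile$intensity) || any(profile$intensity < 0)) {
    abort("`intensity` must be nonnegative.")
  }
  profile
}

#' Calibrate a gradient with molecular-mass markers
#'
#' Fits the standard rate-zonal calibration
#' `peak_fraction = a * log10(mass) + b` by least squares to a set of marker
#' proteins of known mass (e.g. BSA 66 kDa, alcohol dehydrogenase 140 kDa,
#' beta-amylase 200 kDa). With exactly two markers the line interpolates them
#' exactly. Under bottom-to-top fraction numbering heavier species sediment
#' deeper, so the slope is expected to be negative; a nonnegative slope
#' triggers a warning.
#'
#' @param markers Data frame with columns `mass_kda` (positive, distinct) and
#'   `peak_fraction` (real-valued fraction indices); at least 2 rows.
#'
#' @return An object of class `gradient_calibration` with elements `slope`,
#'   `intercept`, `residuals`, `markers` and the underlying `lm` fit.
#'   Methods: [tidy()], [glance()], [predict_fraction()], [predict_mass()].
#' @export
#' @examples
#' cal <- calibrate_gradient(data.frame(
#'   mass_kda = c(66, 200), peak_fraction = c(23, 15)
#' ))
#' predict_fraction(cal, 140)
calibrate_gradient <- function(markers) {
  if (!all(c("mass_kda", "peak_fraction") %in% names(markers))) {
    abort("markers need columns `mass_kda` and `peak_fraction`.")
  }
  markers <- as_tibble(markers)
  if (nrow(markers) < 2) {
    abort("calibration needs at least 2 markers.")
  }
  if (anyNA(markers$mass_kda) || any(markers$mass_kda <= 0)) {
    abort("marker masses must be positive.")
  }
  if (anyDuplicated(markers$mass_kda)) {
    abort("marker masses must be distinct (identical masses give a singular fit).")
  }
  fit <- lm(peak_fraction ~ log10(mass_kda), data = markers)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warn(paste(
      "calibration slope is nonnegative; with bottom-to-top numbering,",
      "heavier markers should peak at smaller fraction indices."
    ))
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      residuals = unname(stats::residuals(fit)),
      markers = markers,
      fit = fit
    ),
    class = "gradient_calibration"
  )
}

#' @export
print.gradient_calibration <- function(x, ...) {
  cat(sprintf(
    "<gradient_calibration> fraction = %.4f * log10(mass kDa) + %.4f (%d markers)\n",
    x$slope, x$intercept, nrow(x$markers)
  ))
  invisible(x)
}

#' @rdname calibrate_gradient
#' @param x,object A `gradient_calibration`.
#' @param ... Unused.
#' @method tidy gradient_calibration
#' @export
tidy.gradient_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "log10_mass_kda"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"])
  )
}

#' @rdname calibrate_gradient
#' @method glance gradient_calibration
#' @export
glance.gradient_calibration <- function(x, ...) {
  tibble(
    n_markers = nrow(x$markers),
    sigma = summary(x$fit)$sigma,
    max_abs_residual = if (nrow(x$markers) > 2) max(abs(x$residuals)) else 0
  )
}

#' Predict the peak fraction of a species of known mass
#'
#' @param calibration A [calibrate_gradient()] fit.
#' @param mass_kda Positive mass in kDa (vectorised).
#' @return Real-valued fraction index (not rounded).
#' @export
predict_fraction <- function(calibration, mass_kda) {
  stopifnot(inherits(calibration, "gradient_calibration"))
  if (anyNA(mass_kda) || any(mass_kda <= 0)) {
    abort("`mass_kda` must be positive.")
  }
  calibration$slope * log10(mass_kda) + calibration$intercept
}

#' Invert the calibration: mass at a given fraction
#'
#' Exact inverse of [predict_fraction()]:
#' `predict_mass(cal, predict_fraction(cal, m)) == m`.
#'
#' @param calibration A [calibrate_gradient()] fit.
#' @param fraction Real-valued fraction index (vectorised).
#' @return Mass in kDa.
#' @export
predict_mass <- function(calibration, fraction) {
  stopifnot(inherits(calibration, "gradient_calibration"))
  10^((fraction - calibration$intercept) / calibration$slope)
}

moving_average <- function(x, window) {
  half <- (window - 1) / 2
  vapply(seq_along(x), function(i) {
    j <- max(1, i - half):min(length(x), i + half)
    mean(x[j])
  }, numeric(1))
}

# Topographic prominence of local maxima: for each peak, walk outward on each
# side to the nearest strictly higher point (or the edge), take the minimum
# along each walk; the key saddle is the higher of the two minima.
peak_prominences <- function(s, idx) {
  vapply(idx, function(i) {
    side_base <- function(range) {
      if (length(range) == 0) return(s[i])
      lo <- s[i]
      for (j in range) {
        if (s[j] > s[i]) break
        lo <- min(lo, s[j])
      }
      lo
    }
    left <- side_base(rev(seq_len(i - 1)))
    right <- side_base(if (i < length(s)) (i + 1):length(s) else integer(0))
    s[i] - max(left, right)
  }, numeric(1))
}

#' Detect peaks in a gradient profile
#'
#' Smooths the profile with a centred moving average (partial windows at the
#' edges), finds local maxima, filters them by topographic prominence relative
#' to the profile maximum, and refines each retained peak position by
#' three-point parabolic interpolation on the smoothed trace.
#'
#' @param profile A gradient profile (see [validate_profile()]).
#' @param smoothing_window Odd window length `>= 1` and shorter than the
#'   profile; default 3 (suited to ~31-fraction gradients).
#' @param min_prominence Minimum peak prominence as a fraction of the maximum
#'   smoothed intensity; default 0.1. Raising it can only remove peaks.
#'
#' @return A tibble sorted by fraction with columns `fraction` (refined,
#'   real-valued), `index` (integer fraction of the maximum), `height`
#'   (smoothed intensity at the peak) and `prominence`. A flat or all-zero
#'   profile yields zero rows.
#' @export
#' @examples
#' cal <- calibrate_gradient(data.frame(
#'   mass_kda = c(66, 200), peak_fraction = c(23, 15)
#' ))
#' prof <- simulate_gradient_profile(gradient_design(
#'   species = data.frame(mass_kda = 66, abundance = 1),
#'   calibration = cal, noise_sd = 0, seed = 1
#' ))
#' detect_peaks(prof)
detect_peaks <- function(profile, smoothing_window = 3, min_prominence = 0.1) {
  profile <- validate_profile(profile)
  n <- nrow(profile)
  if (smoothing_window < 1 || smoothing_window %% 2 == 0 ||
      smoothing_window >= n) {
    abort("`smoothing_window` must be an odd integer in [1, profile length).")
  }
  s <- moving_average(profile$intensity, smoothing_window)
  empty <- tibble(
    fraction = numeric(), index = integer(),
    height = numeric(), prominence = numeric()
  )
  if (max(s) <= 0 || diff(range(s)) == 0) return(empty)
  interior <- 2:(n - 1)
  is_max <- s[interior] > s[interior - 1] & s[interior] >= s[interior + 1]
  idx <- interior[is_max]
  if (length(idx) == 0) return(empty)
  prom <- peak_prominences(s, idx)
  keep <- prom >= min_prominence * max(s)
  idx <- idx[keep]
  prom <- prom[keep]
  if (length(idx) == 0) return(empty)
  refined <- vapply(idx, function(i) {
    denom <- s[i - 1] - 2 * s[i] + s[i + 1]
    if (denom == 0) return(as.numeric(i))
    i + 0.5 * (s[i - 1] - s[i + 1]) / denom
  }, numeric(1))
  tibble(
    fraction = refined, index = as.integer(idx),
    height = s[idx], prominence = prom
  ) |>
    arrange(.data$fraction)
}

#' Assign oligomer orders to detected peaks
#'
#' Converts each detected peak position to an apparent mass via the gradient
#' calibration and assigns the nearest integer multiple of the subunit mass,
#' provided the relative mass error is within `tolerance`; otherwise the peak
#' is flagged unassigned (`order = NA`), never an error.
#'
#' @param peaks Output of [detect_peaks()] (columns `fraction`, `height` at
#'   minimum).
#' @param calibration A [calibrate_gradient()] fit.
#' @param subunit_mass Monomer mass in kDa (e.g. ~66 for an eGFP-tagged
#'   packaging ATPase subunit).
#' @param tolerance Maximum relative error `|mass - n * subunit| / (n * subunit)`
#'   for assignment; default 0.1.
#'
#' @return The `peaks` tibble with added columns `mass_kda` (apparent mass),
#'   `order` (integer oligomer order, `NA` if unassigned) and `assigned`.
#' @export
assign_oligomer_states <- function(peaks, calibration, subunit_mass,
                                   tolerance = 0.1) {
  if (!is.numeric(subunit_mass) || length(subunit_mass) != 1 ||
      subunit_mass <= 0) {
    abort("`subunit_mass` must be a single positive mass in kDa.")
  }
  if (tolerance < 0) abort("`tolerance` must be >= 0.")
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) {
    return(mutate(peaks, mass_kda = numeric(0), order = integer(0),
                  assigned = logical(0)))
  }
  peaks |>
    mutate(
      mass_kda = predict_mass(calibration, .data$fraction),
      order = pmax(1L, as.integer(round(.data$mass_kda / subunit_mass))),
      assigned = abs(.data$mass_kda - .data$order * subunit_mass) <=
        tolerance * .data$order * subunit_mass,
      order = ifelse(.data$assigned, .data$order, NA_integer_)
    )
}

#' Plot a gradient profile with detected peaks
#'
#' @param profile A gradient profile.
#' @param peaks Optional [detect_peaks()] output to overlay.
#' @return A ggplot object.
#' @export
plot_gradient <- function(profile, peaks = NULL) {
  profile <- validate_profile(profile)
  p <- ggplot2::ggplot(
    profile, ggplot2::aes(x = .data$fraction, y = .data$intensity)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "fraction (1 = gradient bottom)",
      y = "fluorescence intensity (a.u.)"
    )
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = peaks$fraction, linetype = "dashed", colour = "firebrick"
    )
  }
  p
}
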