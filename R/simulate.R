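#' Design of a synthetic mutant-titration experiment
#'
#' Captures the structure of the in vitro assembly-inhibition assay: mutant
#' and wild-type subunits are mixed at a grid of mutant fractions, virions are
#' assembled, and infectivity is read out as plaque counts. Replicate counts
#' at mutant fraction `p` are Poisson with mean
#' `control_mean * scale * A(p)` under the true ring model.
#'
#' @param p_grid Mutant fractions; must include 0 (the wild-type control).
#'   Default `seq(0, 0.9, 0.1)`, a ten-point titration.
#' @param n_replicates Replicate plates per fraction; default 3.
#' @param control_mean Expected plaque count at `p = 0` per unit scale;
#'   default 500 (a comfortably countable plate).
#' @param scale Effective volume/dilution factor per replicate (scalar or one
#'   per replicate); default 1.
#' @param model True [ring_model()]; default hexamer with single-mutant
#'   blocking, random assembly.
#' @param rule True [dimer_rule()].
#' @param seed Optional integer seed.
#' @return An object of class `titration_design`.
#' @export
titration_design <- function(p_grid = seq(0, 0.9, by = 0.1),
                             n_replicates = 3, control_mean = 500,
                             scale = 1, model = ring_model(6, 1, "random"),
                             rule = dimer_rule(), seed = NULL) {
  check_fraction(p_grid, "p_grid")
  if (!any(p_grid == 0)) abort("`p_grid` must include the p = 0 control.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (control_mean <= 0) abort("`control_mean` must be positive.")
  if (any(scale <= 0)) abort("`scale` must be positive.")
  if (!length(scale) %in% c(1L, as.integer(n_replicates))) {
    abort("`scale` must have length 1 or n_replicates.")
  }
  stopifnot(inherits(model, "ring_model"), inherits(rule, "dimer_rule"))
  structure(
    list(
      p_grid = as.numeric(p_grid), n_replicates = as.integer(n_replicates),
      control_mean = control_mean, scale = scale, model = model, rule = rule,
      seed = seed
    ),
    class = "titration_design"
  )
}

#' Simulate a mutant-titration dataset
#'
#' @param design A [titration_design()].
#' @return A titration tibble (`mutant_fraction`, `replicate`, `count`,
#'   `scale`) with the generating design attached as attribute `"truth"`;
#'   identical designs and seeds give identical datasets.
#' @export
#' @examples
#' d <- simulate_titration(titration_design(seed = 1))
#' dplyr::count(d, mutant_fraction)
simulate_titration <- function(design) {
  stopifnot(inherits(design, "titration_design"))
  scale <- rep(design$scale, length.out = design$n_replicates)
  layout <- tidyr::expand_grid(
    mutant_fraction = design$p_grid,
    replicate = seq_len(design$n_replicates)
  ) |>
    mutate(scale = scale[.data$replicate])
  a <- suppressWarnings(
    relative_activity(layout$mutant_fraction, design$model, design$rule)
  )
  mu <- design$control_mean * layout$scale * a
  draw <- function() rpois(length(mu), mu)
  counts <- if (is.null(design$seed)) draw() else {
    withr::with_seed(design$seed, draw())
  }
  out <- mutate(layout, count = counts) |>
    select("mutant_fraction", "replicate", "count", "scale")
  attr(out, "truth") <- design
  out
}

#' Design of a synthetic gradient fractionation profile
#'
#' Emulates a rate-zonal gradient read out by fluorescence over `n_fractions`
#' fractions (bottom-to-top): each species contributes a Gaussian band centred
#' at the fraction its mass predicts under the calibration, with peak height
#' equal to its relative abundance; i.i.d. Gaussian measurement noise is added
#' and the trace truncated at zero.
#'
#' @param species Data frame with columns `mass_kda` (positive) and
#'   `abundance` (positive peak heights, arbitrary units).
#' @param calibration A [calibrate_gradient()] fit (or a marker data frame,
#'   which is calibrated on the fly).
#' @param peak_width Band standard deviation in fractions; default 1.2.
#' @param noise_sd Measurement noise standard deviation in intensity units;
#'   default 0.03 (a clean plate-reader trace; SNR 20 for a peak of height
#'   0.6).
#' @param n_fractions Number of fractions; default 31.
#' @param seed Optional integer seed.
#' @return An object of class `gradient_design`.
#' @export
gradient_design <- function(species, calibration, peak_width = 1.2,
                            noise_sd = 0.03, n_fractions = 31, seed = NULL) {
  if (!all(c("mass_kda", "abundance") %in% names(species))) {
    abort("`species` needs columns `mass_kda` and `abundance`.")
  }
  species <- as_tibble(species)
  if (nrow(species) > 0 &&
      (any(species$mass_kda <= 0) || any(species$abundance <= 0))) {
    abort("species masses and abundances must be positive.")
  }
  if (is.data.frame(calibration)) calibration <- calibrate_gradient(calibration)
  stopifnot(inherits(calibration, "gradient_calibration"))
  if (peak_width <= 0) abort("`peak_width` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_fractions < 2) abort("`n_fractions` must be >= 2.")
  if (nrow(species) > 0) {
    centers <- predict_fraction(calibration, species$mass_kda)
    if (any(centers < 1 | centers > n_fractions)) {
      abort("a species' predicted peak falls outside [1, n_fractions].")
    }
  }
  structure(
    list(
      species = species, calibration = calibration, peak_width = peak_width,
      noise_sd = noise_sd, n_fractions = as.integer(n_fractions), seed = seed
    ),
    class = "gradient_design"
  )
}

#' Simulate a gradient fractionation profile
#'
#' @param design A [gradient_design()].
#' @return A gradient profile tibble (`fraction`, `intensity`) with the design
#'   attached as attribute `"truth"`. Intensities are never negative.
#' @export
#' @examples
#' cal <- calibrate_gradient(data.frame(
#'   mass_kda = c(66, 200), peak_fraction = c(23, 15)
#' ))
#' prof <- simulate_gradient_profile(gradient_design(
#'   species = data.frame(mass_kda = c(66, 132), abundance = c(1, 0.6)),
#'   calibration = cal, seed = 1
#' ))
simulate_gradient_profile <- function(design) {
  stopifnot(inherits(design, "gradient_design"))
  f <- seq_len(design$n_fractions)
  signal <- rep(0, design$n_fractions)
  if (nrow(design$species) > 0) {
    centers <- predict_fraction(design$calibration, design$species$mass_kda)
    for (i in seq_len(nrow(design$species))) {
      signal <- signal + design$species$abundance[i] *
        exp(-(f - centers[i])^2 / (2 * design$peak_width^2))
    }
  }
  draw <- function() rnorm(length(f), 0, design$noise_sd)
  noise <- if (design$noise_sd == 0) {
    0
  } else if (is.null(design$seed)) {
    draw()
  } else {
    withr::with_seed(design$seed, draw())
  }
  out <- tibble(fraction = f, intensity = pmax(0, signal + noise))
  attr(out, "truth") <- design
  out
}
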