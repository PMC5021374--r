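# Shared fixtures: the published marker anchors (BSA 66 kDa ~ fraction 23,
# alcohol dehydrogenase 140 kDa ~ 18, beta-amylase 200 kDa ~ 15) and a
# wild-type-like two-species (monomer + dimer) gradient design.

markers_two_point <- function() {
  data.frame(mass_kda = c(66, 200), peak_fraction = c(23, 15))
}

markers_three_point <- function() {
  data.frame(mass_kda = c(66, 140, 200), peak_fraction = c(23, 18, 15))
}

wildtype_gradient_design <- function(seed = NULL, noise_sd = 0.03) {
  gradient_design(
    species = data.frame(mass_kda = c(66, 132), abundance = c(1, 0.6)),
    calibration = calibrate_gradient(markers_three_point()),
    noise_sd = noise_sd,
    seed = seed
  )
}

# One-row titration tibble builder for likelihood unit tests.
titration_row <- function(p, count, scale = 1) {
  tibble::tibble(mutant_fraction = p, replicate = 1L, count = count,
                 scale = scale)
}
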