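# ringstoich

Infer the subunit stoichiometry of an oligomeric ring ATPase from
subunit-poisoning titrations — and analyse the gradient and mechanism data
that go with it.

Ring motors such as the phi29 genome-packaging ATPase gp16 assemble `z`
identical subunits into a ring whose activity collapses once `K` or more
subunits are catalytically dead. Mixing inactive (arginine-finger mutant)
subunits into the assembly pool at fraction `p` and measuring motor output
(plaque-forming units from an in vitro virion-assembly assay) therefore
traces the cumulative-binomial poisoning curve

```
A(p) = sum_{m=0}^{K-1} C(z, m) p^m (1-p)^(z-m)
```

whose shape identifies both `z` and `K`. `ringstoich` implements this model
(plus an arginine-finger-constrained *dimer-seeded* assembly mode in which
mutant–mutant dimers cannot form), fits it to replicate plaque counts by
exact Poisson maximum likelihood over the integer `(z, K, mode)` grid with
AIC selection and bootstrap intervals, and provides three companion tools:

* **Gradient analysis** — log-mass calibration from marker proteins,
  peak detection on 31-fraction rate-zonal profiles, and monomer/dimer
  (oligomer-order) assignment.
* **Sequential-cycle simulator** — a qualitative state machine of the
  one-subunit-at-a-time translocation cycle, with permanent stalling when the
  DNA is handed to a mutant subunit, plus a Monte-Carlo assembly oracle.
* **Synthetic-data generators** — seeded titration datasets and gradient
  profiles with exactly the statistical structure the inference assumes, for
  power analysis and end-to-end recovery tests.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods on fitted objects.

## Worked example

Simulate a hexamer titration (10 mutant fractions × 3 replicates, control
mean 500 counts) and refit it blind over `z = 1..12`, `K = 1..z`:

```r
library(ringstoich)

data <- simulate_titration(titration_design(seed = 1))
fit  <- fit_stoichiometry(data, modes = "random")
fit
#> <ring_fit> subunit-poisoning maximum-likelihood fit
#>   selected: z = 6, K = 1, random assembly
#>   A0 = 504.784 counts/unit scale, logLik = -67.914, AIC = 139.828
#>   grid: 78 candidate models
```

The fit recovers a hexamer (`z = 6`) in which a single poisoned subunit
blocks the motor (`K = 1`); `A0` is the fitted control amplitude (expected
plaque count at `p = 0` per unit scale). `tidy(fit)` ranks all 78 candidate
models — the runner-up (`z = 7, K = 1`) trails by ~21 log-likelihood units:

```r
head(tidy(fit), 3)
#>   mode       z     K    A0 loglik   aic
#> 1 random     6     1  505.  -67.9  140.
#> 2 random     7     1  552.  -89.4  183.
#> 3 random     5     1  452. -106.   216.
```

`autoplot(fit)` overlays the normalised counts on the selected activity
curve, and `bootstrap_ci(data)` gives percentile intervals for `z` and `K`.

Calibrate a gradient from the 66- and 200-kDa marker anchors and locate the
140-kDa marker:

```r
cal <- calibrate_gradient(data.frame(mass_kda = c(66, 200),
                                     peak_fraction = c(23, 15)))
predict_fraction(cal, 140)
#> [1] 17.57373   # rounds to fraction 18
```

Detect and assign peaks on a synthetic wild-type-like profile (monomer 66 kDa
plus dimer 132 kDa):

```r
cal3 <- calibrate_gradient(data.frame(mass_kda = c(66, 140, 200),
                                      peak_fraction = c(23, 18, 15)))
prof <- simulate_gradient_profile(gradient_design(
  species = data.frame(mass_kda = c(66, 132), abundance = c(1, 0.6)),
  calibration = cal3, seed = 1))
assign_oligomer_states(detect_peaks(prof), cal3, subunit_mass = 66)
#>   fraction index height prominence mass_kda order assigned
#> 1     18.2    18  0.499      0.161    131.      2 TRUE
#> 2     23.0    23  0.793      0.791     66.7     1 TRUE
```

The two detected peaks map back to ~66 and ~131 kDa: a monomer (order 1) and
a dimer (order 2).

A thin command-line wrapper over the same functions lives at
`inst/cli/ringstoich.R` (subcommands `simulate`, `fit`, `gradient`,
`ringsim`). The methods vignette
(`vignettes/ring-stoichiometry.Rmd`) documents the model, its assumptions and
every default.

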