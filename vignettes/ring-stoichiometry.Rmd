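---
title: "Inferring ring stoichiometry from subunit-poisoning titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ring stoichiometry from subunit-poisoning titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringstoich)
library(dplyr)
```

## The biological question

Many viral genome-packaging motors are built around a ring of identical
ATPase subunits — in the phi29 bacteriophage, the gp16 ATPase — that
translocates double-stranded DNA into a preformed capsid. Two structural
parameters of such a ring can be read out biochemically without ever seeing
the ring:

* **z**, the number of subunits in the ring, and
* **K**, the *blocking number*: how many catalytically dead subunits a single
  ring tolerates before it stops working. `K = 1` means one poison subunit
  kills the whole motor — the signature of an obligatorily sequential
  mechanism in which every subunit must fire in turn.

The readout is a *subunit-poisoning titration*: inactive mutant subunits
(here, arginine-finger mutants, which can neither hydrolyse ATP nor pass the
catalytic arginine to their neighbour) are mixed with wild-type subunits at a
mutant fraction `p` before rings assemble, and motor output is measured as
plaque-forming units from an in vitro virion-assembly assay.

## The poisoning model

If rings draw their `z` subunits independently from the pool, the number of
mutants per ring is Binomial(`z`, `p`) and the fraction of rings still active
is the cumulative binomial

$$A(p) \;=\; \sum_{m=0}^{K-1} \binom{z}{m} p^m (1-p)^{z-m},$$

the classical one-hit poisoning curve. `relative_activity()` implements it;
`relative_activity_enumerate()` recomputes it by brute-force enumeration of
all $2^z$ subunit strings and serves as an independent oracle in the tests.

Pulldown and gel-shift data motivate a second assembly mode. Dimerisation is
mediated by the arginine finger itself: two finger-mutant subunits do not
dimerise, while any pair with at least one intact finger does. If a ring
nucleates from one preformed dimer plus `z - 2` pool monomers
(`mode = "dimer_seeded"`), the dimer's composition is not binomial — the
mutant/mutant class is excluded and the remaining classes renormalise to

$$P(\mathrm{WW}) = \frac{1-p}{1+p}, \qquad P(\mathrm{WM}) = \frac{2p}{1+p},$$

(`dimer_type_distribution()`), and the ring's activity becomes a small mixture
of cumulative binomials over the dimer's mutant count. For the hexamer with
`K = 1` this collapses to $A(p) = \frac{1-p}{1+p}(1-p)^{4}$.

Modelling choices worth stating explicitly:

* Dimers are **unordered pairs** with an at-least-one-donor rule. The finger
  is directional in structure, but pair-composition data cannot resolve
  orientation, so orientation is not a free parameter.
* Monomers are assumed to fill the remaining `z - 2` positions at pool
  frequency `p`: there is no evidence for selection against mutant monomers
  at assembly.
* The mixing ratio is treated as the realised subunit fraction (equal
  specific concentrations of both stocks).
* `K` may formally exceed `z` in the fitting grid; such models can never be
  blocked and saturate at `A(p) = 1`. At `p = 1` under the donor rule no ring
  assembles at all, so the dimer-seeded activity is 0 by convention there
  (with a warning), whatever `K`.
* Whether the wild-type member of a WM dimer can still donate its finger
  onward into the ring would matter only for interface-level blocking models
  with `K > 1`; with the fitted `K = 1` it is unobservable, and we deliberately
  leave it unmodelled rather than guess.

## Likelihood, model selection, uncertainty

Plaque formation is a count process, so replicate counts at mutant fraction
`p` are modelled as Poisson with mean $A_0 \cdot s \cdot (A(p) + \varepsilon)$,
where $A_0$ is the control amplitude (expected count at `p = 0` per unit
scale), `s` a per-replicate volume/dilution factor, and $\varepsilon$ an
optional background rate (default 0) that absorbs rare nonzero counts where
the model predicts none. An overdispersed readout would call for a negative
binomial; the hook exists in the design space but plain Poisson is the
default because nothing in a clean plaque assay demands more.

For fixed `(z, K, mode)` the amplitude has the closed-form MLE
$\hat A_0 = \sum c_i / \sum s_i (A(p_i) + \varepsilon)$ (`profile_A0()`), so
fitting reduces to an exhaustive, exact grid search over
`z ∈ z_range`, `K ∈ 1..z` and the assembly modes (`fit_stoichiometry()`).
Cells are compared by AIC; since every cell has the same number of free
parameters, this is maximised likelihood plus an optional structural penalty
(off by default). Ties — which arise, e.g., when the data contain only
controls — break deterministically toward the smallest `z`, then smallest
`K`, then random mode. The default `z_range` stops at 12 because no ring
larger than the 12-subunit connector is structurally plausible for this
motor.

Display normalisation divides counts by the *fitted* $\hat A_0$, not by the
raw control mean, to avoid double-using the noisy controls.

Uncertainty comes from a case-resampling bootstrap over titration levels
(`bootstrap_ci()`): the nonzero-`p` levels are resampled with replacement
while the controls are always retained (otherwise $A_0$ can become
unidentifiable in a replicate), each replicate is refit, and percentile
intervals are reported for `z` and `K`. Resampling whole levels rather than
individual plates respects the titration design. There is deliberately no
Bayesian posterior over `(z, K)`: the integer grid is small enough that the
profiled likelihood surface itself is the honest summary.

```{r}
data <- simulate_titration(titration_design(seed = 1))
fit <- fit_stoichiometry(data, modes = "random")
glance(fit)
head(tidy(fit), 3)
```

## Gradient analysis

Glycerol-gradient ultracentrifugation separates monomers from dimers; the
gradient is collected bottom-to-top into 31 fractions, so **heavier species
peak at smaller fraction indices**. Over the narrow mass range spanned by the
marker proteins (66–200 kDa), rate-zonal migration is well approximated by a
line in log mass, so `calibrate_gradient()` fits
`fraction = a · log10(mass) + b` by least squares — exact interpolation with
two markers, residual-reporting with more. The published anchors (66 kDa at
fraction 23, 200 kDa at 15) predict the 140-kDa marker at fraction 17.6,
which rounds to its published anchor, 18 — a useful one-line sanity check of
the functional form.

`detect_peaks()` smooths the 31-point trace with a short centred moving
average (default window 3 — wider windows visibly merge the monomer and dimer
bands, which sit only ~5 fractions apart), keeps local maxima whose
topographic prominence exceeds a fraction (default 0.1) of the trace maximum,
and refines each peak by three-point parabolic interpolation. Parabolic
refinement rather than mixture fitting is a deliberate choice: a 31-point,
two-band trace cannot support a stable mixture likelihood, and full
deconvolution is out of scope. `assign_oligomer_states()` converts peak
positions to apparent masses through the calibration and assigns the nearest
integer multiple of the subunit mass within a relative tolerance (default
10%); peaks outside tolerance are flagged, never fatal. The subunit mass is a
parameter (≈66 kDa for the eGFP-tagged ATPase subunit), not a constant.

## The sequential-cycle state machine

The mechanistic picture is a ring in which exactly one subunit engages the
DNA at a time: it binds ATP (high DNA affinity), hydrolyses upon engagement,
advances the DNA by `step_size` base pairs, flips to the ADP-bound
low-affinity state and hands the DNA to its neighbour. A mutant subunit
cannot bind ATP, so a handoff into a mutant stalls the ring permanently — an
absorbing state, not an error. `step_cycle()`/`simulate_ring()` implement
this cycle event-by-event; no kinetic rates are modelled because none are
measured, and `step_size` defaults to 1 bp purely as a unit of progress.
Handoff direction is fixed by convention; all results are
direction-symmetric. The migrating dimer interface is represented implicitly
by the advancing engagement index rather than as a separate state.

Two consequences are testable and tested: a ring with any mutant translocates
at most `z - 1` steps before stalling, and survival at a horizon of at least
`z` handoffs coincides ring-for-ring with the `K = 1` composition criterion
(zero mutants) — which is why `activity_from_simulation()` refuses `K > 1`,
where the stall mechanism and the blocking count part ways.
`assemble_rings_mc()` provides the composition-level Monte-Carlo oracle for
both assembly modes. Subunit exchange after a stall (fresh monomers rescuing
packaging intermediates) is a documented biological observation but no
exchange mechanism is specified anywhere, so stalled rings stay stalled here.

## What the generators emulate — and what they do not

`simulate_titration()` draws Poisson counts around
$A_0 \, s \, A(p)$ under a chosen truth. The default design is the study
design: mutant fractions 0–0.9 in steps of 0.1, three replicates, control
mean 500 counts (plaque counts are reported per volume without plate-level
numbers; 500 is a comfortably countable plate and is configurable).

`simulate_gradient_profile()` sums one Gaussian band per species — centred
where the calibration puts its mass, peak height equal to its relative
abundance — over 31 fractions, adds i.i.d. Gaussian noise and truncates at
zero. Defaults: band s.d. 1.2 fractions and noise s.d. 0.03 against
abundances 1.0 (monomer) and 0.6 (dimer), i.e. signal-to-noise ≈ 20 for the
weaker band, chosen to resemble a clean plate-reader fluorescence trace with
the two bands, ~5 fractions apart, clearly but not trivially resolved.

Features of real data these generators do **not** reproduce: pipetting error
in the realised mutant fraction, partial-activity mutants, overdispersed
plaque counts, baseline drift and asymmetric band shapes in gradients, and
cross-contamination between fractions. Passing recovery tests therefore shows
the inference is correct *under its own noise model*, not that real assays
are this clean.

## Numerical and testing choices

All randomness is seed-controlled (`withr::with_seed`), so every dataset,
Monte-Carlo estimate and bootstrap is exactly reproducible. Problem sizes
used by the test suite — 20 seeded titrations of 30 observations for recovery,
$10^5$ Monte-Carlo draws for oracle agreement (3-standard-error bands), 50
seeded gradients for peak closure — keep the whole suite under half a minute
while leaving the statistical assertions comfortably powered. Closed-form
activities are validated to 1e-12 against exhaustive enumeration up to
`z = 10` (the $2^z$ enumeration is the oracle, never the implementation).

Known limitations: no dilution-only control-curve model (only the
mutant-titration branch is implemented); no svedberg-coefficient physics or
shape corrections in the gradient calibration; no continuous stoichiometry —
`z` and `K` are integers by construction, which is the point of the method.
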