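#' Specify a ring model
#'
#' A ring model is the structural hypothesis under test in a subunit-poisoning
#' titration: a ring of `z` identical subunits whose activity is abolished as
#' soon as it contains `K` or more mutant (poison) subunits, assembled either
#' from a well-mixed monomer pool (`"random"`) or from one preformed dimer plus
#' `z - 2` independent monomers (`"dimer_seeded"`, the asymmetric
#' one-dimer-plus-monomers ring).
#'
#' `K` may exceed `z`, in which case the blocking threshold can never be
#' reached and the model is always active; such models are admissible in the
#' fitting grid but trivially saturate.
#'
#' @param z Integer number of subunits in the ring (`z >= 1`).
#' @param K Integer blocking number: the minimum count of mutant subunits that
#'   inactivates a ring (`K >= 1`). `K = 1` is the one-hit (single-poison)
#'   model.
#' @param mode Assembly mode, `"random"` or `"dimer_seeded"`.
#'   `"dimer_seeded"` requires `z >= 2`.
#'
#' @return An object of class `ring_model`.
#' @seealso [relative_activity()], [fit_stoichiometry()]
#' @export
#' @examples
#' ring_model(6, 1, "random")
ring_model <- function(z, K = 1L, mode = c("random", "dimer_seeded")) {
  mode <- match.arg(mode)
  if (length(z) != 1L || is.na(z) || z < 1 || z != round(z)) {
    abort("`z` must be a single integer >= 1.")
  }
  if (length(K) != 1L || is.na(K) || K < 1 || K != round(K)) {
    abort("`K` must be a single integer >= 1.")
  }
  if (mode == "dimer_seeded" && z < 2) {
    abort("dimer-seeded assembly requires a ring of at least 2 subunits.")
  }
  structure(
    list(z = as.integer(z), K = as.integer(K), mode = mode),
    class = "ring_model"
  )
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf(
    "<ring_model> z = %d subunits, K = %d (blocking number), %s assembly\n",
    x$z, x$K, gsub("_", "-", x$mode)
  ))
  invisible(x)
}

#' Specify the dimer-formation rule
#'
#' Dimers in the assembly pool form through an arginine finger that one
#' subunit donates into its partner's nucleotide pocket. When
#' `requires_donor = TRUE` (the behaviour seen in pulldown/EMSA data: mutant
#' pairs do not shift, mutant + finger-bearing partner does), a dimer forms
#' only if at least one partner carries an intact finger, so mutant-mutant
#' dimers have probability zero.
#'
#' @param requires_donor Logical; must at least one dimer partner carry an
#'   intact arginine finger?
#'
#' @return An object of class `dimer_rule`.
#' @export
dimer_rule <- function(requires_donor = TRUE) {
  if (!is.logical(requires_donor) || length(requires_donor) != 1L ||
      is.na(requires_donor)) {
    abort("`requires_donor` must be TRUE or FALSE.")
  }
  structure(list(requires_donor = requires_donor), class = "dimer_rule")
}

check_fraction <- function(p, arg = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be a mutant fraction in [0, 1].", arg))
  }
  invisible(p)
}

#' Dimer composition distribution under the donor rule
#'
#' Probability that a dimer drawn from a pool with mutant fraction `p` is
#' wild-type/wild-type (WW), wild-type/mutant (WM), or mutant/mutant (MM).
#' Pairs are unordered. Under `requires_donor`, MM dimers cannot form and the
#' remaining classes are renormalised: P(WW) = (1-p)/(1+p),
#' P(WM) = 2p/(1+p).
#'
#' @param p Mutant fraction in the pool, in `[0, 1]`. With
#'   `requires_donor = TRUE`, `p = 1` is an error: an all-mutant pool cannot
#'   form any dimer.
#' @param rule A [dimer_rule()].
#'
#' @return A tibble with columns `pair` and `probability` (summing to 1).
#' @export
#' @examples
#' dimer_type_distribution(0.5)
dimer_type_distribution <- function(p, rule = dimer_rule()) {
  check_fraction(p)
  stopifnot(inherits(rule, "dimer_rule"), length(p) == 1L)
  if (rule$requires_donor) {
    if (p == 1) {
      abort(paste(
        "no dimer can form: the pool is entirely arginine-finger mutants",
        "and dimerisation requires at least one intact finger."
      ))
    }
    tibble(
      pair = c("WW", "WM"),
      probability = c((1 - p) / (1 + p), 2 * p / (1 + p))
    )
  } else {
    tibble(
      pair = c("WW", "WM", "MM"),
      probability = c((1 - p)^2, 2 * p * (1 - p), p^2)
    )
  }
}

activity_random_one <- function(p, z, K) {
  # P(# mutants < K) with # mutants ~ Binomial(z, p); pbinom(K-1, ...) and
  # K - 1 >= z gives 1, K - 1 < 0 cannot occur (K >= 1)
  pbinom(K - 1, size = z, prob = p)
}

activity_dimer_one <- function(p, z, K, rule) {
  if (rule$requires_donor && p == 1) {
    warn("no dimers form at p = 1; returning activity 0 by convention.")
    return(0)
  }
  if (rule$requires_donor) {
    d <- c(0, 1)
    pd <- c((1 - p) / (1 + p), 2 * p / (1 + p))
  } else {
    d <- c(0, 1, 2)
    pd <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  }
  # total mutants = dimer mutants + Binomial(z - 2, p) monomer mutants;
  # pbinom with a negative quantile is 0, so impossible branches drop out
  sum(pd * pbinom(K - 1 - d, size = z - 2, prob = p))
}

#' Relative ring activity at a given mutant fraction
#'
#' Closed-form probability that a ring assembled from a pool with mutant
#' fraction `p` contains fewer than `K` mutant subunits and is therefore
#' active. For random assembly this is the cumulative binomial
#' \deqn{A(p) = \sum_{m=0}^{K-1} \binom{z}{m} p^m (1-p)^{z-m},}
#' the standard one-hit poisoning model. For dimer-seeded assembly the ring is
#' one dimer drawn from [dimer_type_distribution()] plus `z - 2` independent
#' monomers; for `K = 1`, `z = 6` this reduces to
#' `(1-p)/(1+p) * (1-p)^4`.
#'
#' @param p Numeric vector of mutant fractions in `[0, 1]`.
#' @param model A [ring_model()].
#' @param rule A [dimer_rule()]; used only in dimer-seeded mode.
#'
#' @return Numeric vector of activities in `[0, 1]`, one per element of `p`.
#'   `A(0) = 1`, `A(1) = 0` whenever `K <= z`, and `A` is nonincreasing in `p`.
#' @export
#' @examples
#' relative_activity(c(0, 0.5, 1), ring_model(6, 1))
relative_activity <- function(p, model, rule = dimer_rule()) {
  stopifnot(inherits(model, "ring_model"))
  check_fraction(p)
  if (model$mode == "random") {
    activity_random_one(p, model$z, model$K)
  } else {
    vapply(p, activity_dimer_one, numeric(1),
      z = model$z, K = model$K, rule = rule
    )
  }
}

#' Tabulate an activity curve over a grid of mutant fractions
#'
#' @param model A [ring_model()].
#' @param p_grid Numeric vector of mutant fractions in `[0, 1]`; order is
#'   preserved. An empty grid yields an empty curve.
#' @param rule A [dimer_rule()]; used only in dimer-seeded mode.
#'
#' @return A tibble with columns `p` and `activity`.
#' @export
#' @examples
#' activity_curve(ring_model(6, 1), seq(0, 1, 0.1))
activity_curve <- function(model, p_grid, rule = dimer_rule()) {
  if (length(p_grid) == 0) {
    return(tibble(p = numeric(), activity = numeric()))
  }
  check_fraction(p_grid, "p_grid")
  tibble(p = as.numeric(p_grid), activity = relative_activity(p_grid, model, rule))
}

#' Exhaustive-enumeration activity (independent oracle)
#'
#' Computes the random-assembly activity by enumerating all `2^z` wild/mutant
#' subunit strings with their pool weights — an O(2^z) cross-check for the
#' closed form, practical for `z <= ~15`.
#'
#' @inheritParams relative_activity
#' @return Activity in `[0, 1]`.
#' @export
relative_activity_enumerate <- function(p, model) {
  stopifnot(inherits(model, "ring_model"), model$mode == "random",
            length(p) == 1L)
  check_fraction(p)
  z <- model$z
  total <- 0
  for (code in 0:(2^z - 1)) {
    m <- sum(bitwAnd(code, bitwShiftL(1L, 0:(z - 1))) != 0)
    if (m < model$K) total <- total + p^m * (1 - p)^(z - m)
  }
  total
}
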