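#' Monte-Carlo estimate of the active ring fraction
#'
#' Stochastic oracle for the closed-form activity curves: draws `n_rings`
#' ring compositions from the pool (independently per subunit in random mode;
#' one dimer from [dimer_type_distribution()] plus `z - 2` independent
#' monomers in dimer-seeded mode), declares a ring active iff it carries fewer
#' than `K` mutants, and returns the active proportion with its binomial
#' standard error.
#'
#' @param p Mutant fraction in `[0, 1]`.
#' @param model A [ring_model()].
#' @param rule A [dimer_rule()] (dimer-seeded mode only).
#' @param n_rings Number of rings to draw (`>= 1`).
#' @param seed Optional integer seed; results are reproducible given it.
#'
#' @return A one-row tibble: `active_fraction`, `se`, `n_rings`.
#' @export
#' @examples
#' assemble_rings_mc(0.5, ring_model(6, 1), n_rings = 1e4, seed = 1)
assemble_rings_mc <- function(p, model, rule = dimer_rule(), n_rings = 1e5,
                              seed = NULL) {
  stopifnot(inherits(model, "ring_model"))
  check_fraction(p)
  if (n_rings < 1) abort("`n_rings` must be >= 1.")
  n_rings <- as.integer(n_rings)
  if (model$mode == "dimer_seeded" && rule$requires_donor && p == 1) {
    warn("no dimers form at p = 1; active fraction is 0.")
    return(tibble(active_fraction = 0, se = 0, n_rings = n_rings))
  }
  draw <- function() {
    m <- if (model$mode == "random") {
      rbinom(n_rings, model$z, p)
    } else {
      d <- if (rule$requires_donor) {
        as.integer(runif(n_rings) < 2 * p / (1 + p))
      } else {
        rbinom(n_rings, 2L, p)
      }
      d + rbinom(n_rings, model$z - 2L, p)
    }
    mean(m < model$K)
  }
  f <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(
    active_fraction = f,
    se = sqrt(f * (1 - f) / n_rings),
    n_rings = n_rings
  )
}

#' Simulation configuration for the sequential translocation cycle
#'
#' The cycle is event-ordered, not time-ordered: no kinetic rates are
#' modelled, only the order of conformational events around the ring.
#'
#' @param step_size Base pairs of DNA advanced per hydrolysis event
#'   (positive integer; default 1 — the per-step distance is a model knob,
#'   not a measured constant).
#' @param n_cycles Number of handoff cycles to simulate.
#' @param seed Optional integer seed (composition draws only; a given
#'   composition translocates deterministically).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(step_size = 1L, n_cycles = 12L, seed = NULL) {
  if (step_size < 1 || step_size != round(step_size)) {
    abort("`step_size` must be a positive integer (bp per hydrolysis).")
  }
  if (n_cycles < 0 || n_cycles != round(n_cycles)) {
    abort("`n_cycles` must be a nonnegative integer.")
  }
  structure(
    list(step_size = as.integer(step_size), n_cycles = as.integer(n_cycles),
         seed = seed),
    class = "sim_config"
  )
}

#' Construct a ring state for the sequential cycle
#'
#' Exactly one subunit engages the DNA at any time. A wild-type subunit that
#' engages DNA is in the ATP-bound, high-DNA-affinity conformation; after
#' hydrolysis it flips to the ADP-bound, low-affinity conformation and hands
#' the DNA to the adjacent subunit. A mutant subunit cannot bind ATP, so a
#' ring whose engaged subunit is mutant is stalled — an absorbing state, not
#' an error.
#'
#' @param is_mutant Logical vector, one entry per subunit in ring order.
#' @param start Index of the subunit initially engaging the DNA.
#' @return An object of class `ring_state`: `subunits` (tibble with
#'   `position`, `is_mutant`, `state`), `engaged`, `translocated` (bp),
#'   `stalled`.
#' @export
ring_state <- function(is_mutant, start = 1L) {
  z <- length(is_mutant)
  if (z < 1 || !is.logical(is_mutant) || anyNA(is_mutant)) {
    abort("`is_mutant` must be a logical vector with one entry per subunit.")
  }
  if (start < 1 || start > z) abort("`start` must index a subunit.")
  state <- rep("apo", z)
  stalled <- is_mutant[start]
  if (!stalled) state[start] <- "atp_bound_high_affinity"
  structure(
    list(
      subunits = tibble(
        position = seq_len(z), is_mutant = is_mutant, state = state
      ),
      engaged = as.integer(start),
      translocated = 0L,
      stalled = stalled
    ),
    class = "ring_state"
  )
}

#' @export
print.ring_state <- function(x, ...) {
  z <- nrow(x$subunits)
  comp <- paste(ifelse(x$subunits$is_mutant, "M", "W"), collapse = "")
  cat(sprintf(
    "<ring_state> z = %d [%s], engaged = %d, translocated = %d bp%s\n",
    z, comp, x$engaged, x$translocated, if (x$stalled) " (STALLED)" else ""
  ))
  invisible(x)
}

#' Advance the sequential cycle by one handoff
#'
#' One cycle for a wild-type engaged subunit: ATP is hydrolysed upon DNA
#' engagement, the DNA advances by `step_size` bp, the subunit flips to the
#' ADP-bound low-affinity state, and the DNA transfers to the next subunit in
#' ring order. If that next subunit is a mutant (unable to bind ATP), the ring
#' stalls permanently. A stalled ring is returned unchanged.
#'
#' @param ring A [ring_state()].
#' @param config A [sim_config()].
#' @return The updated `ring_state`.
#' @export
step_cycle <- function(ring, config = sim_config()) {
  stopifnot(inherits(ring, "ring_state"), inherits(config, "sim_config"))
  if (ring$stalled) return(ring)
  z <- nrow(ring$subunits)
  cur <- ring$engaged
  nxt <- cur %% z + 1L
  ring$translocated <- ring$translocated + config$step_size
  ring$subunits$state[cur] <- "adp_low_affinity"
  ring$engaged <- nxt
  if (ring$subunits$is_mutant[nxt]) {
    ring$stalled <- TRUE
  } else {
    ring$subunits$state[nxt] <- "atp_bound_high_affinity"
  }
  ring
}

#' Run the sequential cycle and record the trajectory
#'
#' @param ring A [ring_state()].
#' @param config A [sim_config()]; `config$n_cycles` handoffs are attempted.
#' @return A tibble with one row per cycle: `cycle`, `engaged_subunit`,
#'   `translocated_bp`, `stalled`.
#' @export
#' @examples
#' traj <- simulate_ring(ring_state(rep(FALSE, 6)), sim_config(n_cycles = 12))
#' tail(traj, 1)
simulate_ring <- function(ring, config = sim_config()) {
  rows <- vector("list", config$n_cycles)
  for (cycle in seq_len(config$n_cycles)) {
    ring <- step_cycle(ring, config)
    rows[[cycle]] <- tibble(
      cycle = cycle,
      engaged_subunit = ring$engaged,
      translocated_bp = ring$translocated,
      stalled = ring$stalled
    )
  }
  bind_rows(rows)
}

draw_compositions <- function(p, model, rule, n_rings) {
  z <- model$z
  if (model$mode == "random") {
    matrix(runif(n_rings * z) < p, nrow = n_rings)
  } else {
    # positions 1-2 hold the seeding dimer, the rest are pool monomers
    comp <- matrix(runif(n_rings * z) < p, nrow = n_rings)
    if (rule$requires_donor) {
      wm <- runif(n_rings) < 2 * p / (1 + p)
      comp[, 1] <- wm & (runif(n_rings) < 0.5)
      comp[, 2] <- wm & !comp[, 1]
    }
    comp
  }
}

# Handoffs a composition completes before stalling, starting from `start`:
# the ring-order distance to the first mutant (0 if the start subunit is
# mutant, Inf if the ring is all wild type). Equals the step_cycle outcome;
# asserted against it in the test suite.
steps_until_stall <- function(is_mutant, start = 1L) {
  z <- length(is_mutant)
  if (!any(is_mutant)) return(Inf)
  pos <- which(is_mutant)
  min((pos - start) %% z)
}

#' Active ring fraction from the sequential-cycle simulation
#'
#' Draws `n_rings` compositions, runs each through the sequential cycle for
#' `horizon_cycles` handoffs, and reports the fraction still translocating.
#' With a horizon of at least `z` handoffs, any ring containing a mutant has
#' stalled, so the surviving fraction equals the composition-based activity of
#' [assemble_rings_mc()] ring-for-ring. Only `K = 1` models are meaningful
#' here: the stall mechanism (a single mutant halts the ring) *is* the
#' single-poison blocking rule.
#'
#' @inheritParams assemble_rings_mc
#' @param config A [sim_config()]; its `seed` is used unless `seed` is given.
#' @param horizon_cycles Handoffs to simulate; must be `>= model$z` for the
#'   surviving fraction to equal the composition criterion (below `z`, a ring
#'   whose first mutant lies beyond the horizon has not stalled yet).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `active_fraction`, `se`, `n_rings`,
#'   `horizon_cycles`.
#' @export
activity_from_simulation <- function(p, model, rule = dimer_rule(),
                                     config = sim_config(),
                                     n_rings = 1e4,
                                     horizon_cycles = 2L * model$z,
                                     seed = config$seed) {
  stopifnot(inherits(model, "ring_model"))
  check_fraction(p)
  if (model$K != 1L) {
    abort(paste(
      "the sequential-cycle stall criterion corresponds to K = 1",
      "(one mutant halts the ring); use assemble_rings_mc() for K > 1."
    ))
  }
  if (horizon_cycles < model$z) {
    warn("horizon_cycles < z: rings with distant mutants may not have stalled yet.")
  }
  if (model$mode == "dimer_seeded" && rule$requires_donor && p == 1) {
    warn("no dimers form at p = 1; active fraction is 0.")
    return(tibble(active_fraction = 0, se = 0, n_rings = as.integer(n_rings),
                  horizon_cycles = as.integer(horizon_cycles)))
  }
  run <- function() {
    comp <- draw_compositions(p, model, rule, n_rings)
    surv <- apply(comp, 1, function(m) steps_until_stall(m) > horizon_cycles)
    mean(surv)
  }
  f <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble(
    active_fraction = f,
    se = sqrt(f * (1 - f) / n_rings),
    n_rings = as.integer(n_rings),
    horizon_cycles = as.integer(horizon_cycles)
  )
}
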