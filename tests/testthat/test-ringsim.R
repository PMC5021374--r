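test_that("Monte-Carlo assembly matches the closed forms within 3 SE", {
  hexamer <- ring_model(6, 1)
  expect_identical(
    assemble_rings_mc(0, hexamer, n_rings = 1e4, seed = 1)$active_fraction, 1
  )
  mc <- assemble_rings_mc(0.5, hexamer, n_rings = 1e5, seed = 2)
  expect_lt(abs(mc$active_fraction - 1 / 64), 3 * max(mc$se, 1e-4))
  dimer <- ring_model(6, 1, "dimer_seeded")
  mcd <- assemble_rings_mc(0.5, dimer, n_rings = 1e5, seed = 3)
  expect_lt(abs(mcd$active_fraction - 1 / 48), 3 * max(mcd$se, 1e-4))
  # all mutant fractions, both modes
  for (p in seq(0.1, 0.9, by = 0.2)) {
    for (model in list(hexamer, dimer, ring_model(6, 2))) {
      truth <- relative_activity(p, model)
      est <- assemble_rings_mc(p, model, n_rings = 1e5, seed = 17)
      expect_lt(abs(est$active_fraction - truth), 3 * max(est$se, 1e-4))
    }
  }
})

test_that("Monte-Carlo error shrinks at the root-n rate", {
  truth <- relative_activity(0.3, ring_model(6, 1))
  for (n in c(1e3, 1e4, 1e5)) {
    est <- assemble_rings_mc(0.3, ring_model(6, 1), n_rings = n, seed = 4)
    se_bound <- 3 * max(est$se, sqrt(truth * (1 - truth) / n))
    expect_lt(abs(est$active_fraction - truth), se_bound)
  }
})

test_that("Monte-Carlo draws are reproducible by seed", {
  a <- assemble_rings_mc(0.4, ring_model(6, 1), n_rings = 1e4, seed = 99)
  b <- assemble_rings_mc(0.4, ring_model(6, 1), n_rings = 1e4, seed = 99)
  expect_identical(a, b)
  expect_warning(
    z <- assemble_rings_mc(1, ring_model(6, 1, "dimer_seeded"), n_rings = 10),
    "no dimers"
  )
  expect_identical(z$active_fraction, 0)
})

test_that("an all-wild-type ring cycles deterministically", {
  ring <- ring_state(rep(FALSE, 6))
  traj <- simulate_ring(ring, sim_config(n_cycles = 12))
  expect_identical(tail(traj$translocated_bp, 1), 12L)
  expect_false(any(traj$stalled))
  # DNA returns to the start subunit after each full revolution
  expect_identical(traj$engaged_subunit[c(6, 12)], c(1L, 1L))
  # configurable step size scales the per-cycle advance
  traj2 <- simulate_ring(ring_state(rep(FALSE, 6)),
                         sim_config(step_size = 2, n_cycles = 5))
  expect_identical(tail(traj2$translocated_bp, 1), 10L)
})

test_that("one mutant stalls the ring within z handoffs, permanently", {
  for (pos in 1:6) {
    comp <- rep(FALSE, 6)
    comp[pos] <- TRUE
    ring <- ring_state(comp)
    traj <- simulate_ring(ring, sim_config(n_cycles = 20))
    final <- tail(traj, 1)
    expect_true(final$stalled)
    expect_lte(final$translocated_bp, 5)
    expect_identical(final$translocated_bp, pos - 1L)
    # translocation is frozen after the stall
    after <- traj$translocated_bp[traj$stalled]
    expect_true(all(after == final$translocated_bp))
  }
})

test_that("stepping a stalled ring is a no-op and states transition in order", {
  ring <- ring_state(c(FALSE, TRUE, FALSE))
  expect_identical(ring$subunits$state[1], "atp_bound_high_affinity")
  ring <- step_cycle(ring)
  expect_true(ring$stalled)
  expect_identical(ring$subunits$state[1], "adp_low_affinity")
  again <- step_cycle(ring)
  expect_identical(again$translocated, ring$translocated)
  # a ring that starts on a mutant never translocates
  dead <- ring_state(c(TRUE, FALSE, FALSE))
  expect_true(dead$stalled)
  expect_identical(simulate_ring(dead, sim_config(n_cycles = 5))$translocated_bp,
                   rep(0L, 5))
})

test_that("the stall horizon reproduces the composition criterion per ring", {
  # the state machine's survival at horizon >= z must equal 'zero mutants'
  withr::with_seed(123, {
    for (rep in 1:50) {
      comp <- runif(6) < 0.3
      traj <- simulate_ring(ring_state(comp), sim_config(n_cycles = 12))
      surviving <- !tail(traj$stalled, 1)
      expect_identical(surviving, sum(comp) < 1)
    }
  })
})

test_that("simulation-based activity matches the closed form within 3 SE", {
  hexamer <- ring_model(6, 1)
  expect_identical(
    activity_from_simulation(0, hexamer, n_rings = 100, seed = 1)$active_fraction,
    1
  )
  for (mode in c("random", "dimer_seeded")) {
    model <- ring_model(6, 1, mode)
    truth <- relative_activity(0.5, model)
    est <- activity_from_simulation(0.5, model, n_rings = 2e4,
                                    horizon_cycles = 12, seed = 6)
    expect_lt(abs(est$active_fraction - truth), 3 * max(est$se, 1e-3))
  }
  expect_error(
    activity_from_simulation(0.5, ring_model(6, 2), n_rings = 10),
    "K = 1"
  )
  expect_warning(
    activity_from_simulation(0.5, hexamer, n_rings = 10, horizon_cycles = 3,
                             seed = 1),
    "horizon"
  )
})

test_that("identical seeds give identical simulated activities", {
  a <- activity_from_simulation(0.3, ring_model(6, 1), n_rings = 1e3, seed = 5)
  b <- activity_from_simulation(0.3, ring_model(6, 1), n_rings = 1e3, seed = 5)
  expect_identical(a, b)
})
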