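test_that("exchange probability follows the Metropolis criterion", {
  beta <- beta_of(298.15)
  ## equal s (identical reference energies cross-wise): exponent 0, p = 1
  expect_identical(exchange_probability(-3, -3, -7, -7, beta), 1)
  ## downhill swaps always accepted
  expect_identical(exchange_probability(0, -2, 0, -1, beta), 1)
  ## frozen scalar evaluation: Delta = +2 kJ/mol at 298.15 K
  expect_equal(exchange_probability(0, 1, 0, 1, beta), 0.446287948469415,
               tolerance = 1e-12)
  expect_error(exchange_probability(NA, 0, 0, 0, beta), "non-finite")
})

test_that("the criterion is symmetric under relabelling the two replicas", {
  beta <- beta_of(298.15)
  set.seed(31)
  for (rep in 1:10) {
    v <- rnorm(4, 0, 10)
    p1 <- exchange_probability(v[1], v[2], v[3], v[4], beta)
    p2 <- exchange_probability(v[3], v[4], v[1], v[2], beta)
    expect_equal(p1, p2, tolerance = 1e-14)
  }
})

test_that("swapping s-assignments only reproduces the same p via Eq-2 energies", {
  ## recomputing the criterion from per-state energies after exchanging which
  ## configuration sits at which s gives the identical probability
  beta <- beta_of(298.15)
  offs <- c(0.5, -0.5)
  Vk <- c(2, 9); Vl <- c(6, 3)
  sk <- 1; sl <- 0.4
  vr <- function(V, s) reference_energy(V, eds_parameters(s, offs))
  p_fwd <- exchange_probability(vr(Vk, sk), vr(Vk, sl), vr(Vl, sl), vr(Vl, sk), beta)
  p_swp <- exchange_probability(vr(Vl, sl), vr(Vl, sk), vr(Vk, sk), vr(Vk, sl), beta)
  expect_equal(p_fwd, p_swp, tolerance = 1e-14)
})

test_that("sweeps over identical configurations always accept and are
           reproducible bit-exactly under a seed", {
  ladder <- replica_ladder(c(1, 0.5, 0.2, 0.1),
                           list(pos = matrix(0, 1, 3), vel = matrix(0, 1, 3)))
  V <- rep(list(c(1, 2)), 4)
  set.seed(7)
  sw1 <- attempt_sweep(ladder, "even", V, offsets = c(0, 0))
  expect_true(all(sw1$log$p == 1))
  expect_true(all(sw1$log$accepted))
  set.seed(7)
  sw2 <- attempt_sweep(ladder, "even", V, offsets = c(0, 0))
  expect_identical(sw1$log, sw2$log)
  ## odd phase attempts the complementary disjoint pairs
  sw3 <- attempt_sweep(ladder, "odd", V, offsets = c(0, 0))
  expect_identical(sw3$log$level_a, 2L)
})

test_that("round trips are counted from extreme-to-extreme traversals", {
  ## replica 1: top -> bottom -> top = 1 round trip (columns are levels)
  h1 <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 2, 1), c(2, 3, 1), c(1, 2, 3))
  rt1 <- round_trip_stats(h1)
  expect_identical(unname(rt1$round_trips["1"]), 1L)
  ## top -> middle -> top = 0
  h2 <- rbind(c(1, 2, 3), c(2, 1, 3), c(1, 2, 3))
  expect_identical(unname(round_trip_stats(h2)$round_trips["1"]), 0L)
  ## hand-enumerated 3-replica fixture:
  ## replica 2 path over levels: 2,1,2,3,2,1 -> extremes T,B,T -> 1 trip
  h3 <- rbind(c(2, 1, 3), c(1, 2, 3), c(1, 3, 2), c(1, 2, 3), c(2, 1, 3),
              c(1, 2, 3))
  ## columns are levels; reconstruct by hand: see fixture comment
  rt3 <- round_trip_stats(h3)
  expect_identical(unname(rt3$round_trips["2"]), 1L)
  expect_identical(rt3$total, sum(rt3$round_trips))
})

test_that("with flat energies the top level is shared uniformly", {
  ## all states identical: every swap accepted; over many alternating sweeps
  ## each replica occupies the top level equally often
  L <- 4
  ladder <- replica_ladder(c(1, 0.6, 0.3, 0.1),
                           list(pos = matrix(0, 1, 3), vel = matrix(0, 1, 3)))
  V <- rep(list(c(0, 0)), L)
  set.seed(41)
  top_id <- integer(400)
  phase <- "even"
  for (t in 1:400) {
    sw <- attempt_sweep(ladder, phase, V, offsets = c(0, 0))
    ladder <- sw$ladder
    phase <- if (phase == "even") "odd" else "even"
    top_id[t] <- ladder$replicas[[1]]$replica_id
  }
  counts <- tabulate(top_id, nbins = L)
  chi <- sum((counts - 100)^2 / 100)
  expect_gt(stats::pchisq(chi, df = L - 1, lower.tail = FALSE), 0.01)
})

test_that("replica-exchange EDS runs are deterministic under a seed", {
  fx <- make_harmonic_set(list(harmonic_state_spec(1000, v0 = 0, dims = 1L),
                               harmonic_state_spec(2000, v0 = 3, dims = 1L)))
  int <- integrator_settings(dt = 5e-4, thermostat = "sd", gamma = 20)
  r1 <- run_re_eds(fx$system, fx$states, fx$settings, int,
                   s_values = c(1, 0.2), offsets = c(0, 3), n_steps = 300,
                   save_every = 10, seed = 12)
  r2 <- run_re_eds(fx$system, fx$states, fx$settings, int,
                   s_values = c(1, 0.2), offsets = c(0, 3), n_steps = 300,
                   save_every = 10, seed = 12)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$exchange_log, r2$exchange_log)
})

test_that("level occupancy of a two-replica flat ladder is balanced
           (sampling-balance smoke test against the symmetry reference)", {
  ## two identical end-states and a 2-level ladder: by construction each
  ## configuration should spend half its time at each s-level; the direct
  ## Boltzmann reference for the occupancy fraction is exactly 1/2
  fx <- make_harmonic_set(list(harmonic_state_spec(1500, v0 = 0, dims = 1L),
                               harmonic_state_spec(1500, v0 = 0, dims = 1L)))
  int <- integrator_settings(dt = 5e-4, thermostat = "sd", gamma = 20)
  run <- run_re_eds(fx$system, fx$states, fx$settings, int,
                    s_values = c(1, 0.55), offsets = c(0, 0), n_steps = 8000,
                    exchange_every = 20, save_every = 20, seed = 13)
  occ <- as.numeric(run$history[, 1] == 1L)
  frac_top <- mean(occ)
  ## blocked standard error: the occupancy series is autocorrelated
  blocks <- split(occ, cut(seq_along(occ), 10, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- stats::sd(bm) / sqrt(length(bm))
  expect_lt(abs(frac_top - 0.5), 3 * se + 0.05)
})

test_that("the ladder constructor enforces its invariants", {
  cfg <- list(pos = matrix(0, 1, 3), vel = matrix(0, 1, 3))
  expect_error(replica_ladder(c(0.5, 0.2), cfg), "s = 1.0")
  expect_error(replica_ladder(c(1, 0.5, 0.5), cfg), "descending")
  expect_error(replica_ladder(c(1, 0.5, -0.1), cfg), "descending|positive")
})
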