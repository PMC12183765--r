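test_that("zwanzig_pair degenerate cases are exact", {
  set.seed(51)
  V <- cbind(rnorm(100, 5, 2), rnorm(100, 5, 2))
  rec <- fake_records(V)
  beta <- beta_of(298.15)
  expect_identical(zwanzig_pair(rec, 1, 1, beta)$dg, 0)
  ## frame-wise identical states
  rec2 <- fake_records(cbind(V[, 1], V[, 1]))
  expect_equal(zwanzig_pair(rec2, 1, 2, beta)$dg, 0, tolerance = 1e-12)
})

test_that("zwanzig recovers the analytic harmonic free-energy difference", {
  ## two 1D harmonic states, k = 1000 / 4000, dV0 = 2 kJ/mol, T = 298.15:
  ## dG = 2 + ln(4)/(2 beta) = 3.71828 kJ/mol (frozen closed form), also
  ## cross-checked against numerical quadrature of both partition functions
  spec_a <- harmonic_state_spec(1000, v0 = 0, dims = 1L)
  spec_b <- harmonic_state_spec(4000, v0 = 2, dims = 1L)
  beta <- beta_of(298.15)
  closed <- analytic_harmonic_dg(spec_a, spec_b, beta)
  expect_equal(closed, 3.71828207576648, tolerance = 1e-10)
  expect_equal(quadrature_dg(spec_a, spec_b, beta), closed, tolerance = 1e-8)
  fx <- make_harmonic_set(list(spec_a, spec_b))
  int <- integrator_settings(dt = 5e-4, thermostat = "sd", gamma = 20)
  run <- run_re_eds(fx$system, fx$states, fx$settings, int,
                    s_values = c(1, 0.3, 0.05), offsets = c(0, 2),
                    n_steps = 12000, exchange_every = 20, save_every = 10,
                    seed = 52)
  zp <- zwanzig_pair(run$records[[1]], 1, 2, beta)
  expect_lt(abs(zp$dg - fx$analytic_dg[2, 1]), 3 * zp$se)
  expect_false(zp$unreliable)
})

test_that("dg_matrix is antisymmetric, zero-diagonal and closes cycles exactly", {
  set.seed(53)
  V <- cbind(rnorm(200, 0, 3), rnorm(200, 4, 3), rnorm(200, 9, 3))
  rec <- fake_records(V)
  beta <- beta_of(298.15)
  res <- dg_matrix(rec, beta)
  expect_equal(res$dg, -t(res$dg), tolerance = 1e-12)
  expect_true(all(diag(res$dg) == 0))
  closure <- res$dg[2, 1] + res$dg[3, 2] + res$dg[1, 3]
  expect_lt(abs(closure), 1e-10)
  ## N = 2 consistency with zwanzig_pair
  rec2 <- fake_records(V[, 1:2])
  res2 <- dg_matrix(rec2, beta)
  zp <- zwanzig_pair(rec2, 1, 2, beta)
  expect_equal(res2$dg[2, 1], zp$dg, tolerance = 1e-12)
})

test_that("estimates are invariant under a uniform offset shift", {
  set.seed(54)
  V <- cbind(rnorm(150, 0, 3), rnorm(150, 5, 3))
  beta <- beta_of(298.15)
  r0 <- dg_matrix(fake_records(V, s = 0.8, offsets = c(1, -1)), beta)
  r1 <- dg_matrix(fake_records(V, s = 0.8, offsets = c(1, -1) + 37.5), beta)
  expect_lt(max(abs(r0$dg - r1$dg)), 1e-9)
})

test_that("hydration cycle combines water and vacuum legs", {
  set.seed(55)
  V <- cbind(rnorm(100), rnorm(100, 2))
  beta <- beta_of(298.15)
  wat <- dg_matrix(fake_records(V), beta)
  ## vacuum leg equal to the water leg: all relative hydration zero
  expect_true(all(abs(hydration_cycle(wat, wat)) < 1e-12))
  ## zero vacuum matrix equals the single-simulation (embedded-QM) mode
  vac0 <- wat; vac0$dg <- 0 * vac0$dg
  expect_equal(hydration_cycle(wat, vac0), hydration_cycle(wat))
  wrong <- dg_matrix(fake_records(cbind(V, rnorm(100))), beta)
  expect_error(hydration_cycle(wat, wrong), "dimensions")
})

test_that("experimental anchoring removes constant shifts and is
           reference-invariant", {
  dg_exp <- c(-12.1, -7.4, -3.3, -9.8)
  ## computed relatives off by a constant: output reproduces experiment
  out <- anchor_absolute(dg_exp + 13.7, dg_exp)
  expect_equal(out, dg_exp, tolerance = 1e-12)
  ## mean identity
  set.seed(56)
  rel <- rnorm(4)
  out2 <- anchor_absolute(rel, dg_exp)
  expect_lt(abs(mean(out2) - mean(dg_exp)), 1e-12)
  ## changing the reference shifts all relatives by a constant: no effect
  out3 <- anchor_absolute(rel - rel[3], dg_exp)
  expect_lt(max(abs(out3 - out2)), 1e-10)
  expect_error(anchor_absolute(rel, c(dg_exp[1:3], NA)), "missing")
})

test_that("sampling fractions classify frames by the minimal offset energy", {
  ## crafted 10-frame stream with a known minima pattern: state 1 minimal in
  ## frames 1-6, state 2 in frames 7-10
  V <- cbind(c(rep(0, 6), rep(5, 4)), c(rep(5, 6), rep(0, 4)))
  rec <- fake_records(V)
  sf <- sampling_fractions(rec, offsets = c(0, 0))
  expect_equal(sf$occurrence, c(0.6, 0.4))
  expect_false(sf$undersampled)
  ## a stream where state 2 is always 10 kJ/mol lower
  rec2 <- fake_records(cbind(rep(10, 5), rep(0, 5)))
  expect_equal(sampling_fractions(rec2, offsets = c(0, 0))$occurrence, c(0, 1))
  ## exact ties go to the lowest state index (documented tie rule)
  rec3 <- fake_records(cbind(rep(1, 4), rep(1, 4)))
  expect_equal(sampling_fractions(rec3, offsets = c(0, 0))$occurrence, c(1, 0))
  ## offsets enter the classification
  sf4 <- sampling_fractions(rec2, offsets = c(20, 0))
  expect_equal(sf4$occurrence, c(1, 0))
})

test_that("ranking metrics match hand-enumerated cases", {
  x <- c(-10, -5, -2, 1)
  m <- ranking_metrics(x, x)
  expect_equal(m$mae, 0)
  expect_equal(m$kendall, 1)
  expect_equal(m$r2, 1)
  ## fully reversed ranking
  expect_equal(ranking_metrics(rev(x), x)$kendall, -1)
  ## exactly one discordant pair among the 6: tau = (5 - 1)/6 = 2/3
  expect_equal(ranking_metrics(c(-5, -10, -2, 1), x)$kendall, 2 / 3,
               tolerance = 1e-12)
  expect_error(ranking_metrics(1, 1), "at least 2")
  ## rmse/mae on a known error vector
  m2 <- ranking_metrics(x + c(1, -1, 1, -1), x)
  expect_equal(m2$mae, 1)
  expect_equal(m2$rmse, 1)
})

test_that("combining repeats reports mean and over-repeat scatter", {
  set.seed(57)
  beta <- beta_of(298.15)
  reps <- lapply(1:4, function(r) {
    V <- cbind(rnorm(150, 0, 3), rnorm(150, 5, 3))
    dg_matrix(fake_records(V), beta)
  })
  comb <- combine_repeats(reps)
  expect_equal(comb$dg[2, 1], mean(vapply(reps, function(r) r$dg[2, 1],
                                          numeric(1))), tolerance = 1e-12)
  expect_equal(comb$se[2, 1], sd(vapply(reps, function(r) r$dg[2, 1],
                                        numeric(1))), tolerance = 1e-12)
  expect_identical(comb$n_repeats, 4L)
})
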