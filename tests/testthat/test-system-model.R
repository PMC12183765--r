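test_that("LJ pair force vanishes at the potential minimum", {
  c12 <- 2.5e-6; c6 <- 2.5e-3
  rmin <- (2 * c12 / c6)^(1 / 6)
  sys <- particle_system(rbind(c(0, 0, 0), c(rmin, 0, 0)),
                         c12 = c12, c6 = c6, roles = 0L)
  res <- mm_energy_forces(sys, test_settings(), "environment")
  expect_lt(max(abs(res$forces)), 1e-8)
})

test_that("a single particle has zero energy and forces", {
  sys <- particle_system(rbind(c(0.5, 0.5, 0.5)), c12 = 1e-6, c6 = 1e-3)
  res <- mm_energy_forces(sys, test_settings(), "environment")
  expect_identical(res$energy, 0)
  expect_true(all(res$forces == 0))
})

test_that("3-particle LJ energy equals an independent scalar pair sum", {
  ## right-triangle geometry with pair distances 0.3 / 0.4 / 0.5 nm
  pos <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.3, 0.4, 0))
  sys <- particle_system(pos, c12 = 2.5e-6, c6 = 2.5e-3, roles = 0L)
  res <- mm_energy_forces(sys, test_settings(), "environment")
  oracle <- slow_pair_sum(pos, rbind(c(1, 2), c(1, 3), c(2, 3)),
                          rep(0, 3), rep(2.5e-6, 3), rep(2.5e-3, 3),
                          cutoff = 1.2, eps_rf = 78.5, coulomb = "none")
  expect_equal(res$energy, oracle, tolerance = 1e-12)
})

test_that("reaction-field pair energy matches its closed form", {
  s <- test_settings()
  ## vacuum limit: eps_rf = 1 gives the cutoff-shifted Coulomb potential
  s1 <- test_settings(eps_rf = 1)
  expect_equal(reaction_field_pair(1, 1, 0.5, s1),
               138.935458 * (1 / 0.5 - 1 / 1.2), tolerance = 1e-12)
  ## zero charge
  expect_identical(reaction_field_pair(0, 1, 0.5, s), 0)
  ## frozen symbolic evaluation: q = 1 e each, r = 0.5, Rc = 1.2, eps 78.5
  expect_equal(reaction_field_pair(1, 1, 0.5, s), 115.160245809064,
               tolerance = 1e-12)
  ## the shift makes the potential exactly zero at the cutoff
  expect_equal(reaction_field_pair(1, 1, 1.2, s), 0, tolerance = 1e-12)
  ## beyond-cutoff requests are a caller error
  expect_error(reaction_field_pair(1, 1, 1.3, s), "cutoff")
})

test_that("distance restraints: energy, closed form and exact gradient", {
  pos <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  ## at r = r0 energy and forces vanish
  r1 <- distance_restraint_energy(pos, rbind(c(1, 2)), k = 5000, r0 = 0.1)
  expect_equal(r1$energy, 0)
  expect_true(all(abs(r1$forces) < 1e-12))
  ## k = 5000, r0 = 0, |r| = 0.1: E = 1/2 * 5000 * 0.01 = 25
  r2 <- distance_restraint_energy(pos, rbind(c(1, 2)), k = 5000, r0 = 0)
  expect_equal(r2$energy, 25, tolerance = 1e-12)
  ## analytic force = exact negative gradient (central differences)
  pos3 <- rbind(c(0, 0, 0), c(0.13, 0.05, -0.02), c(0.4, 0.1, 0.2))
  pr <- rbind(c(1, 2), c(2, 3))
  res <- distance_restraint_energy(pos3, pr, k = c(5000, 800), r0 = c(0.1, 0.25))
  g <- num_gradient(function(p) distance_restraint_energy(p, pr, c(5000, 800),
                                                          c(0.1, 0.25))$energy,
                    pos3, h = 1e-6)
  expect_lt(max(abs(res$forces + g)) / max(abs(g)), 1e-6)
  ## degenerate pair is refused
  expect_error(distance_restraint_energy(pos, rbind(c(1, 1)), 5000, 0), "twice")
})

test_that("analytic forces match finite differences on random toy systems", {
  s <- test_settings()
  worst <- 0
  for (case in 1:20) {
    box <- if (case %% 2 == 0) 3.0 else NULL
    sys <- random_toy_system(n = 6, seed = case, box = box)
    res <- mm_energy_forces(sys, s, "environment")
    g <- num_gradient(function(p) {
      s2 <- sys; s2$pos <- p
      mm_energy_forces(s2, s, "environment")$energy
    }, sys$pos, h = 1e-5)
    worst <- max(worst, max(abs(res$forces + g)) / max(abs(g), 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("energies are translation invariant and net force is zero", {
  s <- test_settings()
  for (case in 1:5) {
    box <- if (case %% 2 == 0) 3.0 else NULL
    sys <- random_toy_system(n = 7, seed = 40 + case, box = box)
    e0 <- mm_energy_forces(sys, s, "environment")
    shift <- c(0.31, -0.12, 0.07)
    sys2 <- sys
    sys2$pos <- sys$pos + matrix(shift, nrow(sys$pos), 3, byrow = TRUE)
    e1 <- mm_energy_forces(sys2, s, "environment")
    expect_lt(abs(e1$energy - e0$energy), 1e-10)
    expect_lt(max(abs(colSums(e0$forces))), 1e-9)
  }
})

test_that("system validation enforces the structural invariants", {
  ## cutoff vs box
  sys <- particle_system(rbind(c(0, 0, 0), c(1, 0, 0)), box = 2.0)
  expect_error(validate_system(sys, test_settings(cutoff = 1.2)), "box/2")
  ## non-integer environment charge
  expect_error(particle_system(rbind(c(0, 0, 0)), charges = 0.3), "integer")
  ## molecule roles may carry any partial charge
  expect_silent(validate_system(
    particle_system(rbind(c(0, 0, 0)), charges = 0.3, roles = 1L)))
  ## overlapping particles are a numerical-overlap error
  sys2 <- particle_system(rbind(c(0, 0, 0), c(1e-8, 0, 0)), c12 = 1e-6, c6 = 1e-3)
  expect_error(mm_energy_forces(sys2, test_settings(), "environment"), "overlap")
})

test_that("bonded terms (bonds and angles) have exact gradients", {
  pos <- rbind(c(0, 0, 0), c(0.11, 0.01, 0), c(0.2, 0.09, 0.03))
  bonds <- data.frame(i = c(1, 2), j = c(2, 3), k = c(4e5, 3e5), r0 = c(0.1, 0.12))
  angles <- data.frame(i = 1, j = 2, k = 3, theta0 = 1.9, kth = 300)
  sys <- particle_system(pos, bonds = bonds, angles = angles)
  res <- mm_energy_forces(sys, test_settings(), "environment")
  g <- num_gradient(function(p) {
    s2 <- sys; s2$pos <- p
    mm_energy_forces(s2, test_settings(), "environment")$energy
  }, pos, h = 1e-6)
  expect_lt(max(abs(res$forces + g)) / max(abs(g)), 1e-6)
})
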