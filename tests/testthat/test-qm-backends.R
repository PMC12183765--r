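make_embed_sys <- function(pc_pos, pc_q, qm_pos = rbind(c(0, 0, 0)),
                           qm_q = 0.5, box = NULL) {
  pos <- rbind(qm_pos, pc_pos)
  nq <- nrow(qm_pos)
  particle_system(pos,
                  charges = c(rep(qm_q, nq), pc_q),
                  roles = c(rep(1L, nq), rep(0L, nrow(pc_pos))),
                  box = box)
}

test_that("embedding collection applies the cutoff with union semantics", {
  s <- test_settings()
  ## included at 1.0 nm, excluded at 1.3 nm (R_QM-MM = 1.2)
  sys <- make_embed_sys(rbind(c(1.0, 0, 0), c(1.3, 0, 0)), c(-1, 1))
  emb <- collect_embedding_charges(sys, 1L, s)
  expect_identical(emb$indices, 2L)
  ## two QM atoms with overlapping spheres: the shared MM particle once
  sys2 <- make_embed_sys(rbind(c(0.5, 0, 0)), 0,
                         qm_pos = rbind(c(0, 0, 0), c(1, 0, 0)), qm_q = c(0.5))
  emb2 <- collect_embedding_charges(sys2, 1:2, s)
  expect_identical(emb2$indices, 3L)
  expect_identical(nrow(emb2$positions), 1L)
  ## molecules of other end-states are never embedded
  sys3 <- particle_system(rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.8, 0, 0)),
                          charges = c(0.5, 0.3, 0),
                          roles = c(1L, 2L, 0L))
  emb3 <- collect_embedding_charges(sys3, 1L, s)
  expect_identical(emb3$indices, 3L)
  expect_error(collect_embedding_charges(sys3, integer(0), s), "non-empty")
})

test_that("classical-mirror: vacuum energy is intramolecular only and the
           embedded minus vacuum energy is the plain Coulomb coupling", {
  qp <- list(charges = c(1), bonds = NULL)
  vac <- qm_compute("classical-mirror", rbind(c(0, 0, 0)), qp, NULL)
  expect_identical(vac$energy, 0)
  emb <- structure(list(positions = rbind(c(0.5, 0, 0)), charges = -1,
                        indices = 1L), class = "embedded_point_charges")
  ee <- qm_compute("classical-mirror", rbind(c(0, 0, 0)), qp, emb)
  ## -f q1 q2 / r = -138.935458 / 0.5
  expect_equal(ee$energy - vac$energy, -277.870916, tolerance = 1e-9)
  ## with intramolecular toy terms, vacuum equals exactly those terms
  qp2 <- list(charges = c(0.3, -0.3),
              bonds = data.frame(i = 1, j = 2, k = 1e5, r0 = 0.1))
  vac2 <- qm_compute("classical-mirror", rbind(c(0, 0, 0), c(0.12, 0, 0)), qp2, NULL)
  expect_equal(vac2$energy, 0.5 * 1e5 * 0.02^2, tolerance = 1e-12)
})

test_that("classical-mirror embedded energy equals an independent scalar loop", {
  set.seed(7)
  qm_pos <- rbind(c(0, 0, 0), c(0.15, 0, 0))
  qp <- list(charges = c(0.4, -0.4),
             bonds = data.frame(i = 1, j = 2, k = 2e5, r0 = 0.15))
  pc_pos <- matrix(runif(9, 0.4, 1.0), 3, 3)
  emb <- structure(list(positions = pc_pos, charges = c(-0.3, 0.1, 0.2),
                        indices = 1:3), class = "embedded_point_charges")
  res <- qm_compute("classical-mirror", qm_pos, qp, emb)
  e_loop <- 0.5 * 2e5 * (0.15 - 0.15)^2
  for (a in 1:2) for (j in 1:3) {
    r <- sqrt(sum((qm_pos[a, ] - pc_pos[j, ])^2))
    e_loop <- e_loop + 138.935458 * qp$charges[a] * emb$charges[j] / r
  }
  expect_equal(res$energy, e_loop, tolerance = 1e-12)
})

test_that("field-scaled reduces to classical-mirror at alpha = 0", {
  set.seed(8)
  qm_pos <- rbind(c(0, 0, 0), c(0.14, 0.02, 0))
  pc_pos <- matrix(runif(9, 0.35, 0.9), 3, 3)
  emb <- structure(list(positions = pc_pos, charges = c(-0.2, 0.4, -0.2),
                        indices = 1:3), class = "embedded_point_charges")
  qp <- list(charges = c(0.25, -0.25),
             bonds = data.frame(i = 1, j = 2, k = 2e5, r0 = 0.14))
  e_mirror <- qm_compute("classical-mirror", qm_pos, qp, emb)$energy
  e_fs0 <- qm_compute("field-scaled", qm_pos, c(qp, alpha = 0), emb)$energy
  e_fs <- qm_compute("field-scaled", qm_pos, c(qp, alpha = 0.05), emb)$energy
  expect_lt(abs(e_fs0 - e_mirror), 1e-12)
  expect_gt(abs(e_fs - e_mirror), 1e-8)   # polarization stand-in does act
})

test_that("mock backend forces are exact gradients and conserve momentum", {
  set.seed(9)
  qm_pos <- rbind(c(0, 0, 0), c(0.15, 0.01, -0.02))
  pc_pos <- matrix(runif(12, 0.4, 1.0), 4, 3)
  pc_q <- c(-0.3, 0.2, 0.25, -0.15)
  qp <- list(charges = c(0.35, -0.35),
             bonds = data.frame(i = 1, j = 2, k = 2e5, r0 = 0.15),
             morse = data.frame(i = 1, j = 2, de = 300, a = 20, r0 = 0.15))
  for (backend in c("classical-mirror", "field-scaled")) {
    efun <- function(all_pos) {
      qm <- all_pos[1:2, , drop = FALSE]
      pc <- all_pos[3:6, , drop = FALSE]
      emb <- structure(list(positions = pc, charges = pc_q, indices = 1:4),
                       class = "embedded_point_charges")
      qm_compute(backend, qm, qp, emb)$energy
    }
    all_pos <- rbind(qm_pos, pc_pos)
    emb <- structure(list(positions = pc_pos, charges = pc_q, indices = 1:4),
                     class = "embedded_point_charges")
    res <- qm_compute(backend, qm_pos, qp, emb)
    frc <- rbind(res$forces_qm, res$forces_pc)
    g <- num_gradient(efun, all_pos, h = 1e-6)
    expect_lt(max(abs(frc + g)) / max(abs(g)), 1e-6)
    expect_lt(max(abs(colSums(frc))), 1e-9)
  }
})

test_that("backend registry rejects unknown ids and exposes the built-ins", {
  expect_true(all(c("classical-mirror", "field-scaled", "harmonic-well",
                    "external-adapter") %in% qm_backend_ids()))
  expect_error(qm_compute("no-such-engine", rbind(c(0, 0, 0)), list()), "unknown")
  expect_error(qm_compute("external-adapter", rbind(c(0, 0, 0)), list()),
               "no engine command")
  expect_error(register_qm_backend("classical-mirror", identity), "already")
})
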