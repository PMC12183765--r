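## Backend registry: maps a string id to a function
##   function(qm_positions, qm_params, embedding) -> list(energy, forces_qm, forces_pc)
## Mock backends model the quantum zone with point charges and toy bonded
## terms; their forces are the exact negative gradient of their energy.
.backends <- new.env(parent = emptyenv())

#' Register / query QM backends
#'
#' A backend is a function `f(qm_positions, qm_params, embedding)` returning a
#' list with `energy` (kJ/mol), `forces_qm` (n_qm x 3) and `forces_pc`
#' (n_pc x 3 or NULL) -- the forces on the embedded point charges (Newton's
#' third law partners of the embedding field acting on the QM zone).
#' `embedding = NULL` requests the vacuum energy.
#'
#' @param id Backend id (string).
#' @param fun Backend function.
#' @param overwrite Replace an existing registration.
#' @return `register_qm_backend` returns `id` invisibly;
#'   `qm_backend_ids` the registered ids.
#' @export
register_qm_backend <- function(id, fun, overwrite = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fun))
  if (!overwrite && !is.null(.backends[[id]])) stop(sprintf("backend '%s' already registered", id))
  assign(id, fun, envir = .backends)
  invisible(id)
}

#' @rdname register_qm_backend
#' @export
qm_backend_ids <- function() ls(.backends)

#' Collect MM point charges for electrostatic embedding
#'
#' Builds the union, over all QM atoms, of environment particles within the
#' embedding cutoff R_QM-MM of any QM atom. Each MM particle appears at most
#' once even when inside several QM atoms' cutoff spheres. Particles belonging
#' to any end-state molecule are never embedded: under dual topology the other
#' end-states are invisible to each state.
#'
#' @param system A [particle_system()].
#' @param qm_particles Indices of the QM-zone particles (non-empty).
#' @param settings A [nonbonded_settings()] (uses `embedding_cutoff`).
#' @return List of class `embedded_point_charges` with `positions`, `charges`
#'   and `indices` (source particle indices, possibly empty).
#' @export
collect_embedding_charges <- function(system, qm_particles, settings) {
  if (!length(qm_particles)) stop("qm_particles must be non-empty")
  env <- environment_indices(system)
  if (!length(env)) {
    return(structure(list(positions = matrix(0, 0, 3), charges = numeric(0),
                          indices = integer(0)),
                     class = "embedded_point_charges"))
  }
  ## positions are re-imaged relative to the QM-zone centroid so that a
  ## backend working on absolute coordinates (as a real engine would) sees
  ## the same geometry as the periodic classical routines
  centroid <- colMeans(system$pos[qm_particles, , drop = FALSE])
  dc <- min_image(system$pos[env, , drop = FALSE] -
                    matrix(centroid, length(env), 3, byrow = TRUE), system$box)
  imaged <- dc + matrix(centroid, length(env), 3, byrow = TRUE)
  keep <- logical(length(env))
  rc2 <- settings$embedding_cutoff^2
  for (q in qm_particles) {
    d <- imaged - matrix(system$pos[q, ], length(env), 3, byrow = TRUE)
    keep <- keep | rowSums(d * d) <= rc2
  }
  idx <- env[keep]
  structure(list(positions = imaged[keep, , drop = FALSE],
                 charges = system$charge[idx],
                 indices = idx),
            class = "embedded_point_charges")
}

#' Evaluate a QM backend
#'
#' With `embedding` supplied this returns the combined embedded energy (the
#' QM-zone energy plus its electrostatic coupling to the point charges, which
#' are inseparable in a real engine); with `embedding = NULL` it returns the
#' vacuum energy of the QM zone.
#'
#' @param backend Backend id (see [qm_backend_ids()]).
#' @param qm_positions n_qm x 3 coordinates (nm).
#' @param qm_params Backend parameter list (per-atom mock charges, toy bonded
#'   terms, ...).
#' @param embedding An `embedded_point_charges` object or NULL.
#' @return A `qm_result` list: `energy`, `forces_qm`, `forces_pc`.
#' @export
qm_compute <- function(backend, qm_positions, qm_params, embedding = NULL) {
  fun <- .backends[[backend]]
  if (is.null(fun)) stop(sprintf("unknown QM backend '%s'", backend))
  qm_positions <- as.matrix(qm_positions)
  res <- fun(qm_positions, qm_params, embedding)
  if (!is.null(res$forces_qm) && nrow(res$forces_qm) != nrow(qm_positions)) {
    stop("backend returned forces_qm of wrong size")
  }
  if (!is.null(embedding) && !is.null(res$forces_pc) &&
      nrow(res$forces_pc) != nrow(embedding$positions)) {
    stop("backend returned forces_pc of wrong size")
  }
  structure(res, class = "qm_result")
}

## ---- mock backends ---------------------------------------------------------

## intramolecular toy terms shared by the mock backends: harmonic and/or
## Morse bonds, harmonic angles. qm_params fields: bonds (i, j, k, r0) and/or
## morse (i, j, de, a, r0); angles (i, j, k, theta0, kth).
mock_intra <- function(pos, qm_params) {
  res <- bonded_energy_forces(pos, NULL, qm_params$bonds, qm_params$angles)
  m <- qm_params$morse
  if (!is.null(m) && nrow(m)) {
    for (b in seq_len(nrow(m))) {
      d <- pos[m$j[b], ] - pos[m$i[b], ]
      r <- sqrt(sum(d * d))
      ex <- exp(-m$a[b] * (r - m$r0[b]))
      res$energy <- res$energy + m$de[b] * (1 - ex)^2
      dvdr <- 2 * m$de[b] * (1 - ex) * m$a[b] * ex
      fj <- -d * (dvdr / r)
      res$forces[m$j[b], ] <- res$forces[m$j[b], ] + fj
      res$forces[m$i[b], ] <- res$forces[m$i[b], ] - fj
    }
  }
  res
}

## plain 1/r Coulomb between QM atom charges and embedded point charges,
## deliberately without reaction field: mirrors the mismatch between the
## embedding list and the classical LJ cutoff list.
mock_embed_coulomb <- function(pos, q_atom, embedding) {
  nq <- nrow(pos); npc <- nrow(embedding$positions)
  e <- 0
  fq <- matrix(0, nq, 3); fp <- matrix(0, npc, 3)
  for (a in seq_len(nq)) {
    d <- embedding$positions - matrix(pos[a, ], npc, 3, byrow = TRUE)
    r2 <- rowSums(d * d)
    r <- sqrt(r2)
    qq <- coulomb_prefactor * q_atom[a] * embedding$charges
    e <- e + sum(qq / r)
    fpc <- d * (qq / (r2 * r))         # -dV/dr * unit = +qq/r^2 * unit(d)... sign below
    ## V = qq/r, dV/dr = -qq/r^2; force on pc (at +d) = -dV/dr * unit(d) = qq/r^2 * unit(d)
    fp <- fp + fpc
    fq[a, ] <- fq[a, ] - colSums(fpc)
  }
  list(energy = e, forces_qm = fq, forces_pc = fp)
}

backend_classical_mirror <- function(qm_positions, qm_params, embedding) {
  intra <- mock_intra(qm_positions, qm_params)
  e <- intra$energy
  fq <- intra$forces
  fp <- NULL
  if (!is.null(embedding) && nrow(embedding$positions)) {
    emb <- mock_embed_coulomb(qm_positions, qm_params$charges, embedding)
    e <- e + emb$energy
    fq <- fq + emb$forces_qm
    fp <- emb$forces_pc
  } else if (!is.null(embedding)) {
    fp <- matrix(0, 0, 3)
  }
  list(energy = e, forces_qm = fq, forces_pc = fp)
}

## "field-scaled" polarization stand-in: each atomic charge q_n is replaced by
## q_n (1 + alpha * kappa * phi_n), phi_n the electrostatic potential at atom
## n from the embedding charges (kJ mol^-1 e^-1). Energy:
##   E = sum_n q_n phi_n + alpha kappa sum_n q_n phi_n^2
## with analytic gradient through phi_n. alpha has units e^2 mol kJ^-1;
## defaults alpha = 0.05, kappa = 1. alpha = 0 recovers classical-mirror.
backend_field_scaled <- function(qm_positions, qm_params, embedding) {
  alpha <- qm_params$alpha %||% 0.05
  kappa <- qm_params$kappa %||% 1
  intra <- mock_intra(qm_positions, qm_params)
  e <- intra$energy
  fq <- intra$forces
  fp <- NULL
  if (!is.null(embedding) && nrow(embedding$positions)) {
    q <- qm_params$charges
    nq <- nrow(qm_positions); npc <- nrow(embedding$positions)
    fp <- matrix(0, npc, 3)
    for (a in seq_len(nq)) {
      d <- embedding$positions - matrix(qm_positions[a, ], npc, 3, byrow = TRUE)
      r2 <- rowSums(d * d); r <- sqrt(r2)
      phi <- coulomb_prefactor * sum(embedding$charges / r)
      coef <- q[a] * (1 + 2 * alpha * kappa * phi)     # dE/dphi_a
      e <- e + q[a] * phi + alpha * kappa * q[a] * phi^2
      ## grad of phi wrt pc j position: -f Zj (d_j)/r^3 * ... phi = f sum Zj/r
      gphi_pc <- -coulomb_prefactor * embedding$charges / (r2 * r) * d  # dphi/d(pc_j)
      fp <- fp - coef * gphi_pc
      fq[a, ] <- fq[a, ] - coef * (-colSums(gphi_pc))
    }
  } else if (!is.null(embedding)) {
    fp <- matrix(0, 0, 3)
  }
  list(energy = e, forces_qm = fq, forces_pc = fp)
}

## external-potential backend used by the synthetic fixtures: a (possibly
## quartic-perturbed) well acting on each atom's first `dims` coordinates,
##   V = sum_dim 1/2 k (x - x0)^2 + c4 (x - x0)^4, plus offset v0.
## Ignores embedding (it models a state defined by an external field);
## passing an embedding is an error to avoid silent misuse.
backend_harmonic_well <- function(qm_positions, qm_params, embedding) {
  if (!is.null(embedding)) stop("harmonic-well backend takes no embedding")
  k <- qm_params$k
  c4 <- qm_params$c4 %||% 0
  dims <- qm_params$dims %||% 3L
  x0 <- qm_params$x0
  if (is.null(dim(x0))) x0 <- matrix(x0, nrow(qm_positions), 3, byrow = TRUE)
  d <- qm_positions - x0
  if (dims < 3L) d[, (dims + 1L):3L] <- 0
  e <- sum(0.5 * k * d^2 + c4 * d^4) + (qm_params$v0 %||% 0)
  f <- -(k * d + 4 * c4 * d^3)
  list(energy = e, forces_qm = f, forces_pc = NULL)
}

## Adapter stub documenting the exchange contract with a real semiempirical
## engine: XYZ-with-charges written to `input`, energy/gradient table expected
## back. Not used by any test; calling it without a configured command errors.
backend_external_adapter <- function(qm_positions, qm_params, embedding) {
  cmd <- qm_params$command
  if (is.null(cmd)) {
    stop(paste("external adapter: no engine command configured.",
               "Contract: the engine receives an XYZ file whose comment line",
               "lists charge/multiplicity and, when embedding is present, a",
               "point-charge table (x y z q, nm and e); it must print",
               "'energy <kJ/mol>' followed by one 'grad i fx fy fz' line per",
               "QM atom and per point charge (kJ mol^-1 nm^-1)."))
  }
  stop("external adapter: subprocess execution is not enabled in this build")
}

register_builtin_backends <- function() {
  for (id in c("classical-mirror", "field-scaled", "harmonic-well", "external-adapter")) {
    if (!is.null(.backends[[id]])) next
    fun <- switch(id,
                  "classical-mirror" = backend_classical_mirror,
                  "field-scaled" = backend_field_scaled,
                  "harmonic-well" = backend_harmonic_well,
                  "external-adapter" = backend_external_adapter)
    register_qm_backend(id, fun)
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_backends()
}
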