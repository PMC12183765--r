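#' Define an EDS end-state
#'
#' Under dual topology each end-state is a complete molecule superimposed on
#' the others; its potential V_i is built from the chosen coupling:
#' \describe{
#'   \item{"qmmm"}{V_i = V_i^QM,EE - V_i^QM,vac + V_i^MM,vdW: the embedded QM
#'     energy minus the vacuum QM energy plus the classical Lennard-Jones
#'     coupling to the environment. The intramolecular part cancels in V_i by
#'     construction, so intramolecular terms are never perturbed; the vacuum
#'     relative free energy of any two end-states is identically zero.}
#'   \item{"classical"}{V_i = intramolecular MM + plain-Coulomb coupling to
#'     the environment (within the embedding cutoff) + LJ coupling. Used for
#'     the two-simulation hydration cycle; in vacuum V_i reduces to the
#'     intramolecular terms.}
#'   \item{"direct"}{V_i is the backend energy of the molecule's coordinates
#'     alone (an external-potential state; used by the synthetic fixtures).}
#' }
#'
#' @param molecule_id Role id of the molecule in the [particle_system()].
#' @param particles Particle indices of the molecule.
#' @param backend QM backend id (must be registered).
#' @param qm_params Backend parameters; for "classical-mirror"/"field-scaled"
#'   in qmmm mode, NULL derives charges and bonds from the system.
#' @param coupling One of "qmmm", "classical", "direct".
#' @return An object of class `end_state_definition`.
#' @export
end_state_definition <- function(molecule_id, particles, backend = "classical-mirror",
                                 qm_params = NULL,
                                 coupling = c("qmmm", "classical", "direct")) {
  coupling <- match.arg(coupling)
  if (!(backend %in% qm_backend_ids())) stop(sprintf("backend '%s' is not registered", backend))
  structure(list(molecule_id = as.integer(molecule_id),
                 particles = as.integer(particles),
                 backend = backend, qm_params = qm_params,
                 coupling = coupling),
            class = "end_state_definition")
}

check_states <- function(system, states) {
  seen <- integer(0)
  for (st in states) {
    mol <- molecule_indices(system, st$molecule_id)
    if (!setequal(mol, st$particles)) {
      stop(sprintf("end-state %d particle set inconsistent with system roles", st$molecule_id))
    }
    if (length(intersect(seen, st$particles))) stop("end-state particle sets overlap")
    seen <- c(seen, st$particles)
  }
  invisible(TRUE)
}

## derive mock-backend parameters from the system topology when not given
state_qm_params <- function(system, state) {
  if (!is.null(state$qm_params)) return(state$qm_params)
  idx <- state$particles
  remap <- match(seq_len(nrow(system$pos)), idx)
  b <- system$bonds
  if (!is.null(b) && nrow(b)) {
    sel <- b$i %in% idx & b$j %in% idx
    b <- b[sel, , drop = FALSE]
    b$i <- remap[b$i]; b$j <- remap[b$j]
  }
  a <- system$angles
  if (!is.null(a) && nrow(a)) {
    sel <- a$i %in% idx & a$j %in% idx & a$k %in% idx
    a <- a[sel, , drop = FALSE]
    a$i <- remap[a$i]; a$j <- remap[a$j]; a$k <- remap[a$k]
  }
  list(charges = system$charge[idx], bonds = b, angles = a)
}

#' End-state energy and force components
#'
#' Evaluates one end-state's potential V_i and its force contributions.
#' In qmmm coupling, the embedded QM energy uses point charges collected from
#' the environment only (other end-states are invisible), the vacuum QM energy
#' uses no embedding, and the van der Waals coupling is the classical LJ
#' interaction between the molecule and the environment.
#'
#' @param system A [particle_system()].
#' @param state An [end_state_definition()].
#' @param settings A [nonbonded_settings()].
#' @return An `end_state_energies` list: `V_qm_ee`, `V_qm_vac`, `V_mm_vdw`,
#'   `V_i`, `f_coupling` (n x 3, the full-system -dV_i/dr) and `f_vac`
#'   (n x 3, the unweighted intramolecular vacuum-QM force of this molecule;
#'   zero for "classical" and "direct" couplings, whose intramolecular forces
#'   travel inside `f_coupling`).
#' @export
end_state_energy_forces <- function(system, state, settings) {
  n <- nrow(system$pos)
  idx <- state$particles
  qp <- state_qm_params(system, state)
  zero <- matrix(0, n, 3)
  expand <- function(sub, at) {
    out <- matrix(0, n, 3)
    if (length(at)) out[at, ] <- out[at, ] + sub
    out
  }
  res <- tryCatch({
    if (state$coupling == "direct") {
      qr <- qm_compute(state$backend, system$pos[idx, , drop = FALSE], qp, NULL)
      list(V_qm_ee = qr$energy, V_qm_vac = 0, V_mm_vdw = 0,
           V_i = qr$energy,
           f_coupling = expand(qr$forces_qm, idx), f_vac = zero)
    } else if (state$coupling == "classical") {
      intra <- mm_energy_forces(system, settings, "molecule-internal",
                                molecule = state$molecule_id)
      ## plain Coulomb over the same union point-charge list the embedding
      ## scheme uses, so classical and qmmm couplings share one interaction
      ## form and the hydration-cycle comparison is purely statistical
      emb <- collect_embedding_charges(system, idx, settings)
      coul <- list(energy = 0, forces = zero)
      if (length(emb$indices)) {
        ec <- mock_embed_coulomb(system$pos[idx, , drop = FALSE],
                                 system$charge[idx], emb)
        coul$energy <- ec$energy
        coul$forces <- expand(ec$forces_qm, idx) + expand(ec$forces_pc, emb$indices)
      }
      vdw <- mm_energy_forces(system, settings, "molecule-environment",
                              molecule = state$molecule_id, coulomb = "none")
      list(V_qm_ee = intra$energy + coul$energy, V_qm_vac = 0,
           V_mm_vdw = vdw$energy,
           V_i = intra$energy + coul$energy + vdw$energy,
           f_coupling = intra$forces + coul$forces + vdw$forces,
           f_vac = zero)
    } else {
      emb <- collect_embedding_charges(system, idx, settings)
      ee <- qm_compute(state$backend, system$pos[idx, , drop = FALSE], qp, emb)
      vac <- qm_compute(state$backend, system$pos[idx, , drop = FALSE], qp, NULL)
      vdw <- mm_energy_forces(system, settings, "molecule-environment",
                              molecule = state$molecule_id, coulomb = "none")
      f_c <- expand(ee$forces_qm, idx) - expand(vac$forces_qm, idx) + vdw$forces
      if (length(emb$indices)) f_c <- f_c + expand(ee$forces_pc, emb$indices)
      list(V_qm_ee = ee$energy, V_qm_vac = vac$energy, V_mm_vdw = vdw$energy,
           V_i = ee$energy - vac$energy + vdw$energy,
           f_coupling = f_c, f_vac = expand(vac$forces_qm, idx))
    }
  }, error = function(e) {
    stop(sprintf("end-state %d: %s", state$molecule_id, conditionMessage(e)))
  })
  structure(res, class = "end_state_energies")
}

#' Assemble the total force field from per-state components
#'
#' Total force = unperturbed MM-zone force (environment internal terms)
#' + each molecule's unweighted intramolecular vacuum-QM force
#' + the w_i-weighted sum of the end-state coupling forces
#' (+ restraint forces, added by the caller or the engine).
#' The result is the exact negative gradient of
#' V^MM,env + sum_i V_i^QM,vac + V_R.
#'
#' @param system A [particle_system()].
#' @param per_state List of `end_state_energies`.
#' @param weights EDS weights (sum to 1 within 1e-9).
#' @param settings A [nonbonded_settings()].
#' @param f_env Optional precomputed environment MM forces (n x 3).
#' @return n x 3 force matrix.
#' @export
assemble_system_forces <- function(system, per_state, weights, settings,
                                   f_env = NULL) {
  if (length(per_state) != length(weights)) stop("per_state/weights length mismatch")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (is.null(f_env)) {
    f_env <- mm_energy_forces(system, settings, "environment")$forces
  }
  f <- f_env
  for (i in seq_along(per_state)) {
    f <- f + per_state[[i]]$f_vac + weights[i] * per_state[[i]]$f_coupling
  }
  f
}

#' Build a reusable EDS evaluation engine
#'
#' Returns a function `f(pos, params)` evaluating the full EDS Hamiltonian
#' H = V^MM,env + sum_i V_i^QM,vac + V_R(s, E^R) + restraints at the given
#' coordinates, with analytic forces and the frame record (V_i, V_R, w_i).
#' The system geometry is updated in place; topology is fixed.
#'
#' @param system A [particle_system()].
#' @param states List of [end_state_definition()]s.
#' @param settings A [nonbonded_settings()].
#' @return Function `(pos, params) -> list(energy, forces, V, V_R, w)`.
#' @export
eds_engine <- function(system, states, settings) {
  check_states(system, states)
  validate_system(system, settings)
  base <- system
  n <- nrow(base$pos)
  box <- base$box
  ## static structures: exclusions, environment pair list, per-state
  ## molecule-environment pair lists, per-state backend parameters
  excl <- exclusion_pairs(base)
  env <- environment_indices(base)
  env_pairs <- drop_excluded(make_pairs(env), excl, n)
  sel_bonded <- function(idx) {
    b <- base$bonds; a <- base$angles
    list(bonds = if (!is.null(b) && nrow(b)) b[b$i %in% idx & b$j %in% idx, , drop = FALSE],
         angles = if (!is.null(a) && nrow(a)) a[a$i %in% idx & a$j %in% idx & a$k %in% idx, , drop = FALSE])
  }
  env_bonded <- sel_bonded(env)
  st_pre <- lapply(states, function(st) {
    list(def = st,
         idx = st$particles,
         pairs_env = make_pairs(st$particles, env),
         qp = state_qm_params(base, st),
         bonded = sel_bonded(st$particles))
  })
  restr <- base$restraints
  has_restr <- !is.null(restr) && nrow(restr) > 0
  expand <- function(sub, at) {
    out <- matrix(0, n, 3)
    if (length(at)) out[at, ] <- out[at, ] + sub
    out
  }
  function(pos, params) {
    sys <- base
    sys$pos <- pos
    e_env <- pair_energy_forces(pos, box, env_pairs, sys$charge, sys$c12,
                                sys$c6, settings, coulomb = "rf")
    eb <- bonded_energy_forces(pos, box, env_bonded$bonds, env_bonded$angles)
    f_env <- e_env$forces + eb$forces
    e_env_tot <- e_env$energy + eb$energy
    N <- length(st_pre)
    V <- numeric(N)
    Vvac <- numeric(N)
    f_coup <- vector("list", N)
    f_vac_sum <- matrix(0, n, 3)
    for (i in seq_len(N)) {
      sp <- st_pre[[i]]
      st <- sp$def
      if (st$coupling == "direct") {
        qr <- qm_compute(st$backend, pos[sp$idx, , drop = FALSE], sp$qp, NULL)
        V[i] <- qr$energy
        f_coup[[i]] <- expand(qr$forces_qm, sp$idx)
      } else if (st$coupling == "classical") {
        intra <- bonded_energy_forces(pos, box, sp$bonded$bonds, sp$bonded$angles)
        emb <- collect_embedding_charges(sys, sp$idx, settings)
        e_c <- 0; f_c <- intra$forces
        if (length(emb$indices)) {
          ec <- mock_embed_coulomb(pos[sp$idx, , drop = FALSE],
                                   sys$charge[sp$idx], emb)
          e_c <- ec$energy
          f_c <- f_c + expand(ec$forces_qm, sp$idx) + expand(ec$forces_pc, emb$indices)
        }
        vdw <- pair_energy_forces(pos, box, sp$pairs_env, sys$charge, sys$c12,
                                  sys$c6, settings, coulomb = "none")
        V[i] <- intra$energy + e_c + vdw$energy
        f_coup[[i]] <- f_c + vdw$forces
      } else {
        emb <- collect_embedding_charges(sys, sp$idx, settings)
        ee <- qm_compute(st$backend, pos[sp$idx, , drop = FALSE], sp$qp, emb)
        vac <- qm_compute(st$backend, pos[sp$idx, , drop = FALSE], sp$qp, NULL)
        vdw <- pair_energy_forces(pos, box, sp$pairs_env, sys$charge, sys$c12,
                                  sys$c6, settings, coulomb = "none")
        V[i] <- ee$energy - vac$energy + vdw$energy
        Vvac[i] <- vac$energy
        f_c <- expand(ee$forces_qm, sp$idx) - expand(vac$forces_qm, sp$idx) + vdw$forces
        if (length(emb$indices)) f_c <- f_c + expand(ee$forces_pc, emb$indices)
        f_coup[[i]] <- f_c
        f_vac_sum <- f_vac_sum + expand(vac$forces_qm, sp$idx)
      }
    }
    vr <- reference_energy(V, params)
    w <- state_weights(V, params)
    f <- f_env + f_vac_sum
    for (i in seq_len(N)) f <- f + w[i] * f_coup[[i]]
    e <- e_env_tot + sum(Vvac) + vr
    if (has_restr) {
      rr <- distance_restraint_energy(pos, cbind(restr$i, restr$j),
                                      restr$k, restr$r0, box)
      e <- e + rr$energy; f <- f + rr$forces
    }
    if (!is.null(sys$posres) && nrow(sys$posres)) {
      pr <- position_restraint_energy(pos, sys$posres, box)
      e <- e + pr$energy; f <- f + pr$forces
    }
    list(energy = e, forces = f, V = V, V_R = vr, w = w)
  }
}
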