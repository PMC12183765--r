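#' Harmonic end-state specification
#'
#' One end-state defined by an external well acting on a single particle:
#' V(x) = sum over the first `dims` coordinates of
#' 1/2 k (x - x0)^2 + c4 (x - x0)^4, plus the offset v0. With c4 = 0 the
#' analytic free-energy difference between two states is
#' dG = dV0 + (d / (2 beta)) ln(k_B / k_A).
#'
#' @param k Force constant (kJ mol^-1 nm^-2), > 0.
#' @param x0 Minimum position (length-3, nm).
#' @param v0 Energy offset of the well (kJ/mol).
#' @param dims Confined dimensionality, 1..3.
#' @param c4 Quartic perturbation coefficient (kJ mol^-1 nm^-4), default 0.
#' @return A `harmonic_state_spec`.
#' @export
harmonic_state_spec <- function(k, x0 = c(0, 0, 0), v0 = 0, dims = 3L, c4 = 0) {
  if (k <= 0) stop("k must be > 0")
  stopifnot(dims %in% 1:3, length(x0) == 3L)
  structure(list(k = k, x0 = as.numeric(x0), v0 = v0, dims = as.integer(dims),
                 c4 = c4), class = "harmonic_state_spec")
}

#' Analytic free-energy difference between two harmonic specs
#'
#' dG_BA = dV0 + (d / (2 beta)) ln((k_B + k_extra) / (k_A + k_extra)),
#' requiring c4 = 0 and equal dims. `k_extra` accounts for an additional
#' state-independent harmonic confinement superimposed on both states (see
#' [make_harmonic_set()]).
#'
#' @param spec_a,spec_b `harmonic_state_spec`s.
#' @param beta Inverse temperature (mol/kJ).
#' @param k_extra Confinement force constant added to both wells.
#' @return dG in kJ/mol.
#' @export
analytic_harmonic_dg <- function(spec_a, spec_b, beta, k_extra = 0) {
  if (spec_a$c4 != 0 || spec_b$c4 != 0) stop("closed form requires c4 = 0")
  if (spec_a$dims != spec_b$dims) stop("closed form requires equal dims")
  (spec_b$v0 - spec_a$v0) +
    (spec_a$dims / (2 * beta)) * log((spec_b$k + k_extra) / (spec_a$k + k_extra))
}

#' Free-energy difference by numerical quadrature
#'
#' dG = -1/beta ln(Z_B / Z_A) with each per-dimension partition function
#' integrated adaptively over +/- 10 sigma of the harmonic part; the
#' independent oracle for anharmonic (quartic-perturbed) states where no
#' closed form exists. Unconfined dimensions are identical in both states
#' and cancel.
#'
#' @inheritParams analytic_harmonic_dg
#' @return dG in kJ/mol.
#' @export
quadrature_dg <- function(spec_a, spec_b, beta, k_extra = 0) {
  if (spec_a$dims != spec_b$dims) stop("specs must have equal dims")
  lnz <- function(sp) {
    keff <- sp$k + k_extra
    sig <- sqrt(1 / (beta * keff))
    val <- stats::integrate(function(x) exp(-beta * (0.5 * keff * x^2 + sp$c4 * x^4)),
                            lower = -10 * sig, upper = 10 * sig,
                            rel.tol = 1e-12, abs.tol = 0)$value
    sp$dims * log(val) - beta * sp$v0
  }
  -(lnz(spec_b) - lnz(spec_a)) / beta
}

#' Build a harmonic EDS test set
#'
#' One particle per end-state (dual topology), each feeling only its own
#' external well through the "harmonic-well" backend (direct coupling). A
#' weak state-independent harmonic position restraint (force constant
#' `k_conf`, centred on each particle's own well minimum) confines the
#' spectator particles whose state carries negligible weight; it acts outside
#' the EDS mixture, and the attached analytic oracle accounts for it exactly.
#'
#' @param specs List of at least two [harmonic_state_spec()]s.
#' @param temperature Temperature (K).
#' @param k_conf Confinement force constant (kJ mol^-1 nm^-2), default 1.
#' @param mass Particle mass (u), default 10.
#' @return List: `system` ([particle_system()]), `states`
#'   ([end_state_definition()]s), `settings`, `analytic_dg` (N x N matrix,
#'   entry (j, i) = dG from i to j; quadrature-based when any c4 != 0),
#'   `manifest` (all generator parameters).
#' @export
make_harmonic_set <- function(specs, temperature = 298.15, k_conf = 1,
                              mass = 10) {
  if (length(specs) < 2L) stop("need >= 2 state specs")
  N <- length(specs)
  beta <- beta_of(temperature)
  pos <- do.call(rbind, lapply(specs, function(sp) sp$x0))
  sys <- particle_system(pos, charges = 0, masses = mass, roles = seq_len(N),
                         posres = data.frame(i = seq_len(N), k = k_conf,
                                             x = pos[, 1], y = pos[, 2],
                                             z = pos[, 3]),
                         labels = paste0("S", seq_len(N)))
  states <- lapply(seq_len(N), function(i) {
    sp <- specs[[i]]
    end_state_definition(i, i, backend = "harmonic-well",
                         qm_params = list(k = sp$k, x0 = sp$x0, v0 = sp$v0,
                                          dims = sp$dims, c4 = sp$c4),
                         coupling = "direct")
  })
  anal <- matrix(0, N, N)
  anharmonic <- any(vapply(specs, function(sp) sp$c4 != 0, logical(1)))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    anal[j, i] <- if (anharmonic) {
      quadrature_dg(specs[[i]], specs[[j]], beta, k_extra = k_conf)
    } else {
      analytic_harmonic_dg(specs[[i]], specs[[j]], beta, k_extra = k_conf)
    }
  }
  list(system = sys, states = states,
       settings = nonbonded_settings(cutoff = 1.2, eps_rf = 1),
       analytic_dg = anal,
       manifest = list(type = "harmonic_set", n_states = N,
                       specs = lapply(specs, unclass),
                       temperature = temperature, k_conf = k_conf,
                       mass = mass))
}

#' Toy solute templates for the droplet fixture
#'
#' Two-atom molecules with a stiff harmonic bond, varying partial charges and
#' LJ parameters -- stand-ins for the small polar molecules of a hydration
#' set. Template `m` has charges +/- q_m so every solute is net-neutral.
#'
#' @param n Number of templates (2..8).
#' @param dq Charge increment between consecutive templates (e).
#' @return List of template lists (`pos`, `charges`, `c12`, `c6`, `mass`,
#'   `bonds`).
#' @export
toy_solute_templates <- function(n, dq = 0.05) {
  stopifnot(n >= 1, n <= 8)
  lapply(seq_len(n), function(m) {
    q <- 0.15 + (m - 1) * dq
    list(pos = rbind(c(-0.075, 0, 0), c(0.075, 0, 0)),
         charges = c(-q, q),
         c12 = c(2.5e-6, 2.0e-6) * (1 + 0.05 * (m - 1)),
         c6 = c(2.5e-3, 2.0e-3),
         mass = c(12, 12),
         bonds = data.frame(i = 1L, j = 2L, k = 4e5, r0 = 0.15))
  })
}

#' Droplet specification
#'
#' A cubic box of two-site dipolar solvent molecules (stiff harmonic bond
#' 0.1 nm, charges +/- 0.42 e) with 2..8 solute end-state molecules
#' superimposed at the centre, aligned by distance restraints
#' (k = 5000 kJ mol^-1 nm^-2) between two atoms per molecule.
#'
#' @param n_solvent Number of solvent molecules (default 40).
#' @param box Cubic edge length (nm), default 3.0.
#' @param solutes List of solute templates (default
#'   [toy_solute_templates()] for `n_states`).
#' @param n_states Number of end-states when `solutes` is NULL (default 3).
#' @param restraint_k Alignment restraint force constant (default 5000).
#' @param seed Placement seed.
#' @return A `droplet_spec`.
#' @export
droplet_spec <- function(n_solvent = 40L, box = 3.0, solutes = NULL,
                         n_states = 3L, restraint_k = 5000, seed = 1L) {
  solutes <- solutes %||% toy_solute_templates(n_states)
  structure(list(n_solvent = as.integer(n_solvent), box = box,
                 solutes = solutes, restraint_k = restraint_k,
                 seed = as.integer(seed)),
            class = "droplet_spec")
}

#' Build a solvated droplet test system
#'
#' Solvent molecules are placed on a jittered cubic lattice and relaxed by a
#' short steepest-descent minimization; solute end-state molecules are
#' superimposed at the box centre with alignment restraints between
#' corresponding atoms of consecutive molecules. With `n_solvent = 0` the
#' returned system is a vacuum system.
#'
#' @param spec A [droplet_spec()].
#' @param settings A [nonbonded_settings()]; the default uses eps_rf = 78.5.
#' @param coupling Coupling mode for the end-state definitions.
#' @param backend QM backend id for qmmm coupling.
#' @param minimize_steps Steepest-descent steps (default 150).
#' @return List: `system`, `states`, `settings`, `manifest`.
#' @export
make_droplet <- function(spec, settings = nonbonded_settings(eps_rf = 78.5),
                         coupling = "qmmm", backend = "classical-mirror",
                         minimize_steps = 150L) {
  set.seed(spec$seed)
  nmol <- length(spec$solutes)
  box <- if (spec$n_solvent > 0) spec$box else NULL
  centre <- spec$box / 2
  pos <- NULL; charge <- NULL; c12 <- NULL; c6 <- NULL; mass <- NULL
  role <- integer(0); bonds <- NULL; labels <- character(0)
  add_mol <- function(template, at, role_id, lab) {
    n0 <- if (is.null(pos)) 0L else nrow(pos)
    p <- template$pos + matrix(at, nrow(template$pos), 3, byrow = TRUE)
    pos <<- rbind(pos, p)
    charge <<- c(charge, template$charges)
    c12 <<- c(c12, template$c12)
    c6 <<- c(c6, template$c6)
    mass <<- c(mass, template$mass)
    role <<- c(role, rep(role_id, nrow(p)))
    labels <<- c(labels, paste0(lab, seq_len(nrow(p))))
    b <- template$bonds
    if (!is.null(b) && nrow(b)) {
      b$i <- b$i + n0; b$j <- b$j + n0
      bonds <<- rbind(bonds, b)
    }
    n0
  }
  ## solutes superimposed at the centre (small per-molecule jitter so no two
  ## atoms coincide exactly)
  offsets0 <- vector("list", nmol)
  for (m in seq_len(nmol)) {
    jit <- stats::runif(3, -0.02, 0.02)
    offsets0[[m]] <- add_mol(spec$solutes[[m]], c(centre, centre, centre) + jit,
                             m, sprintf("M%d.", m))
  }
  ## solvent on a jittered lattice, skipping sites too close to the centre
  if (spec$n_solvent > 0) {
    solvent <- list(pos = rbind(c(-0.05, 0, 0), c(0.05, 0, 0)),
                    charges = c(-0.42, 0.42),
                    c12 = c(2.6e-6, 0), c6 = c(2.6e-3, 0),
                    mass = c(9, 9),
                    bonds = data.frame(i = 1L, j = 2L, k = 4e5, r0 = 0.1))
    per_side <- ceiling(spec$n_solvent^(1 / 3))
    a <- spec$box / per_side
    if (a < 0.25) {
      stop(sprintf("density too high to place solvent without overlap (lattice spacing %.3f nm)", a))
    }
    sites <- as.matrix(expand.grid(x = seq_len(per_side), y = seq_len(per_side),
                                   z = seq_len(per_side))) * a - a / 2
    d2c <- rowSums((sites - matrix(centre, nrow(sites), 3, byrow = TRUE))^2)
    ## fill nearest-first so the solutes are actually solvated, skipping the
    ## sites that would overlap the superimposed molecules at the centre
    keep <- d2c >= 0.35^2
    sites <- sites[keep, , drop = FALSE][order(d2c[keep]), , drop = FALSE]
    if (nrow(sites) < spec$n_solvent) {
      stop("density too high to place solvent without overlap")
    }
    for (sv in seq_len(spec$n_solvent)) {
      at <- sites[sv, ] + stats::runif(3, -0.05, 0.05)
      add_mol(solvent, at, 0L, "W")
    }
  }
  restraints <- NULL
  if (nmol > 1) {
    rs <- list()
    for (m in 2:nmol) {
      i1 <- offsets0[[1]]; im <- offsets0[[m]]
      rs[[m - 1]] <- data.frame(i = c(i1 + 1L, i1 + 2L),
                                j = c(im + 1L, im + 2L),
                                k = spec$restraint_k, r0 = 0)
    }
    restraints <- do.call(rbind, rs)
  }
  sys <- particle_system(pos, charges = charge, masses = mass, c12 = c12,
                         c6 = c6, roles = role, bonds = bonds, box = box,
                         restraints = restraints, labels = labels)
  validate_system(sys, settings)
  if (minimize_steps > 0 && spec$n_solvent > 0) {
    sys <- minimize_droplet(sys, settings, minimize_steps)
  }
  states <- lapply(seq_len(nmol), function(m) {
    end_state_definition(m, molecule_indices(sys, m), backend = backend,
                         coupling = coupling)
  })
  list(system = sys, states = states, settings = settings,
       manifest = list(type = "droplet", n_solvent = spec$n_solvent,
                       box = spec$box, n_states = nmol,
                       restraint_k = spec$restraint_k, seed = spec$seed,
                       coupling = coupling, backend = backend,
                       minimize_steps = minimize_steps))
}

## steepest descent with adaptive step on the relaxation surface: solvent +
## restraints + every molecule's internal and LJ-vs-environment terms
## (unweighted; used only to remove bad contacts before sampling)
minimize_droplet <- function(sys, settings, n_steps) {
  energy_forces <- function(pos) {
    s2 <- sys; s2$pos <- pos
    res <- mm_energy_forces(s2, settings, "everything")
    if (!is.null(s2$restraints)) {
      rr <- distance_restraint_energy(pos, cbind(s2$restraints$i, s2$restraints$j),
                                      s2$restraints$k, s2$restraints$r0, s2$box)
      res$energy <- res$energy + rr$energy
      res$forces <- res$forces + rr$forces
    }
    res
  }
  pos <- sys$pos
  ev <- energy_forces(pos)
  step <- 1e-4
  for (i in seq_len(n_steps)) {
    fmax <- max(abs(ev$forces))
    if (fmax < 10) break
    trial <- pos + step * ev$forces / fmax
    evt <- tryCatch(energy_forces(trial), error = function(e) NULL)
    if (!is.null(evt) && evt$energy < ev$energy) {
      pos <- trial; ev <- evt; step <- min(step * 1.2, 0.01)
    } else {
      step <- step / 2
      if (step < 1e-9) break
    }
  }
  sys$pos <- pos
  sys
}
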