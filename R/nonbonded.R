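#' Nonbonded interaction settings
#'
#' @param cutoff Spherical cutoff for LJ and reaction-field electrostatics
#'   (nm). Default 1.2 nm.
#' @param eps_rf Reaction-field dielectric permittivity (>= 1). 1 recovers
#'   plain Coulomb truncation shifted to zero at the cutoff.
#' @param embedding_cutoff Cutoff R_QM-MM (nm) for collecting MM point
#'   charges around QM atoms (electrostatic embedding). Default 1.2 nm.
#' @return An object of class `nonbonded_settings`.
#' @export
nonbonded_settings <- function(cutoff = 1.2, eps_rf = 1, embedding_cutoff = 1.2) {
  stopifnot(cutoff > 0, eps_rf >= 1, embedding_cutoff > 0)
  structure(list(cutoff = cutoff, eps_rf = eps_rf,
                 embedding_cutoff = embedding_cutoff),
            class = "nonbonded_settings")
}

## minimum-image displacement for a cubic box (NULL box = vacuum)
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

## all unordered pairs within a set, or all pairs between two disjoint sets
make_pairs <- function(a, b = NULL) {
  if (is.null(b)) {
    if (length(a) < 2) return(matrix(integer(0), 0, 2))
    t(utils::combn(a, 2L))
  } else {
    cbind(rep(a, each = length(b)), rep(b, times = length(a)))
  }
}

drop_excluded <- function(pairs, excl, n) {
  if (is.null(excl) || !nrow(excl) || !nrow(pairs)) return(pairs)
  pairs[!(pair_key(pairs[, 1], pairs[, 2], n) %in%
            pair_key(excl[, 1], excl[, 2], n)), , drop = FALSE]
}

#' Reaction-field pair electrostatic energy (Barker--Watts form)
#'
#' V = f qi qj (1/r + C_rf r^2 / (2 Rc^3) - (1 + C_rf/2)/Rc), with
#' C_rf = 2(eps_rf - 1)/(2 eps_rf + 1) and f the Coulomb prefactor. The
#' constant term shifts the potential to exactly zero at r = Rc
#' (1/Rc + C_rf/(2 Rc) - (1 + C_rf/2)/Rc = 0), so pair energies are
#' continuous as pairs cross the cutoff; with eps_rf = 1 (C_rf = 0) the form
#' reduces to the cutoff-shifted vacuum Coulomb potential f qi qj (1/r - 1/Rc).
#'
#' @param qi,qj Charges (e).
#' @param r Distance (nm), 0 < r <= cutoff.
#' @param settings A [nonbonded_settings()].
#' @return Energy in kJ/mol.
#' @export
reaction_field_pair <- function(qi, qj, r, settings) {
  if (any(r > settings$cutoff)) stop("reaction_field_pair: r beyond cutoff (excluded pair)")
  if (any(r <= 0)) stop("reaction_field_pair: nonpositive distance")
  crf <- rf_crf(settings$eps_rf)
  rc <- settings$cutoff
  coulomb_prefactor * qi * qj * (1 / r + crf * r^2 / (2 * rc^3) - (1 + crf / 2) / rc)
}

rf_crf <- function(eps_rf) 2 * (eps_rf - 1) / (2 * eps_rf + 1)

## Vectorized pair energies + forces between indexed pairs.
## coulomb: "rf" (reaction field, cutoff-shifted), "plain" (bare 1/r, used by
## the embedding mirror where no RF applies), or "none".
## Returns total energy and an n x 3 force matrix.
pair_energy_forces <- function(pos, box, pairs, charge, c12, c6, settings,
                               coulomb = "rf", lj = TRUE,
                               apply_cutoff = TRUE) {
  n <- nrow(pos)
  frc <- matrix(0, n, 3)
  if (!nrow(pairs)) return(list(energy = 0, forces = frc))
  ii <- pairs[, 1]; jj <- pairs[, 2]
  d <- min_image(pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE], box)
  r2 <- rowSums(d * d)
  if (apply_cutoff) {
    keep <- r2 <= settings$cutoff^2
    if (!all(keep)) {
      ii <- ii[keep]; jj <- jj[keep]; d <- d[keep, , drop = FALSE]; r2 <- r2[keep]
      if (!length(ii)) return(list(energy = 0, forces = frc))
    }
  }
  if (any(r2 < 1e-12)) {
    stop(sprintf("numerical overlap: particles %d and %d closer than 1e-6 nm",
                 ii[which(r2 < 1e-12)[1]], jj[which(r2 < 1e-12)[1]]))
  }
  r <- sqrt(r2)
  e <- numeric(length(r))
  dvdr <- numeric(length(r))          # dV/dr
  if (lj) {
    cc12 <- sqrt(c12[ii] * c12[jj])
    cc6 <- sqrt(c6[ii] * c6[jj])
    inv6 <- 1 / r2^3
    e <- e + (cc12 * inv6 - cc6) * inv6
    dvdr <- dvdr + (-12 * cc12 * inv6 / r + 6 * cc6 / r) * inv6
  }
  if (coulomb != "none") {
    qq <- coulomb_prefactor * charge[ii] * charge[jj]
    if (coulomb == "rf") {
      crf <- rf_crf(settings$eps_rf); rc <- settings$cutoff
      e <- e + qq * (1 / r + crf * r2 / (2 * rc^3) - (1 + crf / 2) / rc)
      dvdr <- dvdr + qq * (-1 / r2 + crf * r / rc^3)
    } else {
      e <- e + qq / r
      dvdr <- dvdr + -qq / r2
    }
  }
  ## force on j is -dV/dr * unit(d); Newton's third law for i
  fij <- -d * (dvdr / r)
  frc <- accumulate_forces(frc, jj, fij)
  frc <- accumulate_forces(frc, ii, -fij)
  list(energy = sum(e), forces = frc)
}

## scatter-add pair contributions into the force array (single rowsum call)
accumulate_forces <- function(frc, idx, contrib) {
  s <- rowsum(contrib, idx, reorder = FALSE)
  tgt <- as.integer(rownames(s))
  frc[tgt, ] <- frc[tgt, ] + s
  frc
}

## harmonic bonds and angles; returns energy + full-size forces
bonded_energy_forces <- function(pos, box, bonds = NULL, angles = NULL) {
  n <- nrow(pos)
  frc <- matrix(0, n, 3)
  e <- 0
  if (!is.null(bonds) && nrow(bonds)) {
    d <- min_image(pos[bonds$j, , drop = FALSE] - pos[bonds$i, , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    dr <- r - bonds$r0
    e <- e + sum(0.5 * bonds$k * dr^2)
    fij <- -d * (bonds$k * dr / r)     # force on j
    frc <- accumulate_forces(frc, bonds$j, fij)
    frc <- accumulate_forces(frc, bonds$i, -fij)
  }
  if (!is.null(angles) && nrow(angles)) {
    for (a in seq_len(nrow(angles))) {
      i <- angles$i[a]; j <- angles$j[a]; k <- angles$k[a]
      rij <- min_image(pos[i, ] - pos[j, ], box)
      rkj <- min_image(pos[k, ] - pos[j, ], box)
      nij <- sqrt(sum(rij^2)); nkj <- sqrt(sum(rkj^2))
      ct <- sum(rij * rkj) / (nij * nkj)
      ct <- max(-1, min(1, ct))
      th <- acos(ct)
      dth <- th - angles$theta0[a]
      e <- e + 0.5 * angles$kth[a] * dth^2
      st <- sqrt(max(1 - ct^2, 1e-12))
      dEdth <- angles$kth[a] * dth
      di <- (rkj / (nij * nkj) - ct * rij / nij^2) * (-1 / st) * dEdth
      dk <- (rij / (nij * nkj) - ct * rkj / nkj^2) * (-1 / st) * dEdth
      frc[i, ] <- frc[i, ] - di
      frc[k, ] <- frc[k, ] - dk
      frc[j, ] <- frc[j, ] + di + dk
    }
  }
  list(energy = e, forces = frc)
}

#' Harmonic distance-restraint energy and forces
#'
#' E = sum over pairs of 1/2 k (|r_ij| - r0)^2, with analytic forces.
#' Used to keep superimposed end-state molecules aligned during sampling;
#' applied outside the EDS mixture (unweighted).
#'
#' @param positions n x 3 coordinate matrix (nm).
#' @param pairs 2-column matrix (or data frame) of particle indices.
#' @param k Force constants (kJ mol^-1 nm^-2), recycled over pairs.
#' @param r0 Reference distances (nm), recycled over pairs.
#' @param box Optional cubic box edge (minimum image).
#' @return List with `energy` (kJ/mol) and `forces` (n x 3).
#' @export
distance_restraint_energy <- function(positions, pairs, k, r0, box = NULL) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  if (any(pairs[, 1] == pairs[, 2])) stop("restraint pair references one particle twice")
  np <- nrow(pairs)
  bonds <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      k = rep_len(k, np), r0 = rep_len(r0, np))
  ## guard r = 0 with r0 = 0: gradient is zero there, but 1/r blows up;
  ## treated as exactly zero force (the harmonic minimum).
  d <- min_image(positions[bonds$j, , drop = FALSE] - positions[bonds$i, , drop = FALSE], box)
  r <- sqrt(rowSums(d * d))
  dr <- r - bonds$r0
  e <- sum(0.5 * bonds$k * dr^2)
  frc <- matrix(0, nrow(positions), 3)
  ok <- r > 1e-12
  if (any(ok)) {
    fij <- -d[ok, , drop = FALSE] * (bonds$k[ok] * dr[ok] / r[ok])
    frc <- accumulate_forces(frc, bonds$j[ok], fij)
    frc <- accumulate_forces(frc, bonds$i[ok], -fij)
  }
  list(energy = e, forces = frc)
}

## harmonic position restraints to fixed reference points
position_restraint_energy <- function(positions, posres, box = NULL) {
  frc <- matrix(0, nrow(positions), 3)
  if (is.null(posres) || !nrow(posres)) return(list(energy = 0, forces = frc))
  idx <- posres$i
  ref <- cbind(posres$x, posres$y, posres$z)
  d <- positions[idx, , drop = FALSE] - ref   # no minimum image: absolute anchor
  e <- sum(0.5 * posres$k * rowSums(d * d))
  frc[idx, ] <- frc[idx, ] - posres$k * d
  list(energy = e, forces = frc)
}

#' Classical (MM) energy and forces for a role-filtered interaction subset
#'
#' Sums the requested interaction classes with analytic forces:
#' \describe{
#'   \item{"environment"}{environment-environment nonbonded (LJ + reaction
#'     field) plus environment bonded terms -- the unperturbed MM zone.}
#'   \item{"molecule-environment"}{nonbonded interactions between the atoms of
#'     molecule `molecule` and the environment; `coulomb` selects the
#'     electrostatic form ("none" gives the pure van der Waals coupling).}
#'   \item{"molecule-internal"}{bonded terms within molecule `molecule`.}
#'   \item{"everything"}{all of the above over all molecules, with RF
#'     electrostatics (used for relaxation, not for EDS end states).}
#' }
#' Intramolecular 1-2/1-3 pairs implied by bonds are excluded from nonbonded
#' sums; the minimum-image convention applies when the system has a box.
#'
#' @param system A [particle_system()].
#' @param settings A [nonbonded_settings()].
#' @param subset One of the classes above.
#' @param molecule Molecule id for the molecule-* subsets.
#' @param coulomb "rf", "plain" or "none" (molecule-environment only).
#' @return List with `energy` (kJ/mol) and `forces` (n x 3, kJ mol^-1 nm^-1).
#' @export
mm_energy_forces <- function(system, settings,
                             subset = c("environment", "molecule-environment",
                                        "molecule-internal", "everything"),
                             molecule = NULL, coulomb = "rf") {
  subset <- match.arg(subset)
  validate_system(system, settings)
  n <- nrow(system$pos)
  excl <- exclusion_pairs(system)
  env <- environment_indices(system)
  sel_bonded <- function(idx) {
    b <- system$bonds; a <- system$angles
    list(bonds = if (!is.null(b)) b[b$i %in% idx & b$j %in% idx, , drop = FALSE],
         angles = if (!is.null(a)) a[a$i %in% idx & a$j %in% idx & a$k %in% idx, , drop = FALSE])
  }
  tot_e <- 0; tot_f <- matrix(0, n, 3)
  add <- function(res) {
    tot_e <<- tot_e + res$energy
    tot_f <<- tot_f + res$forces
  }
  if (subset == "environment" || subset == "everything") {
    pr <- drop_excluded(make_pairs(env), excl, n)
    add(pair_energy_forces(system$pos, system$box, pr, system$charge,
                           system$c12, system$c6, settings, coulomb = "rf"))
    sb <- sel_bonded(env)
    add(bonded_energy_forces(system$pos, system$box, sb$bonds, sb$angles))
  }
  if (subset == "molecule-environment" || subset == "molecule-internal") {
    if (is.null(molecule)) stop("molecule id required for this subset")
    mol <- molecule_indices(system, molecule)
    if (!length(mol)) stop(sprintf("no particles with role %d", molecule))
    if (subset == "molecule-environment") {
      pr <- make_pairs(mol, env)
      add(pair_energy_forces(system$pos, system$box, pr, system$charge,
                             system$c12, system$c6, settings, coulomb = coulomb))
    } else {
      sb <- sel_bonded(mol)
      add(bonded_energy_forces(system$pos, system$box, sb$bonds, sb$angles))
    }
  }
  if (subset == "everything") {
    mols <- setdiff(sort(unique(system$role)), 0L)
    for (m in mols) {
      mol <- molecule_indices(system, m)
      pr <- make_pairs(mol, env)
      add(pair_energy_forces(system$pos, system$box, pr, system$charge,
                             system$c12, system$c6, settings, coulomb = "rf"))
      prm <- drop_excluded(make_pairs(mol), excl, n)
      add(pair_energy_forces(system$pos, system$box, prm, system$charge,
                             system$c12, system$c6, settings, coulomb = "rf"))
      sb <- sel_bonded(mol)
      add(bonded_energy_forces(system$pos, system$box, sb$bonds, sb$angles))
    }
  }
  list(energy = tot_e, forces = tot_f)
}
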