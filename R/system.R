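#' Particle system container
#'
#' Holds coordinates, velocities, masses, charges, Lennard-Jones parameters,
#' toy bonded terms, an optional cubic periodic box and per-particle roles.
#' Roles tag each particle as part of the unperturbed environment (role 0,
#' the MM zone) or as a member of alchemical end-state molecule i (role i > 0,
#' dual topology: every end-state is a complete molecule superimposed in
#' space). Role sets with i > 0 must be disjoint.
#'
#' @param positions n x 3 numeric matrix of coordinates (nm).
#' @param charges Length-n vector of partial charges (e). Recycled if scalar.
#' @param masses Length-n vector of masses (u). Recycled if scalar.
#' @param c12,c6 Per-particle Lennard-Jones C12 (kJ mol^-1 nm^12) and C6
#'   (kJ mol^-1 nm^6); cross terms use the geometric-mean combination rule.
#' @param roles Integer vector: 0 = environment, i > 0 = molecule of
#'   end-state i.
#' @param bonds Data frame with columns `i`, `j`, `k` (kJ mol^-1 nm^-2),
#'   `r0` (nm) for harmonic bonds, or NULL.
#' @param angles Data frame with columns `i`, `j`, `k`, `theta0` (rad),
#'   `kth` (kJ mol^-1 rad^-2) for harmonic angles (j is the apex), or NULL.
#' @param box Cubic box edge length (nm) or NULL for vacuum.
#' @param velocities n x 3 matrix (nm/ps) or NULL (zeros).
#' @param restraints Data frame with columns `i`, `j`, `k`, `r0`: harmonic
#'   distance restraints applied outside the EDS mixture (unweighted), or NULL.
#' @param posres Data frame with columns `i`, `k`, `x`, `y`, `z`: harmonic
#'   position restraints to fixed points, applied unweighted, or NULL.
#' @param labels Character particle-type labels (used in the XYZ element
#'   column), or NULL.
#'
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, charges = 0, masses = 1, c12 = 0,
                            c6 = 0, roles = 0L, bonds = NULL, angles = NULL,
                            box = NULL, velocities = NULL, restraints = NULL,
                            posres = NULL, labels = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  rec <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1L) rep(x, n) else x
  }
  sys <- structure(list(
    pos = unname(positions),
    vel = if (is.null(velocities)) matrix(0, n, 3) else unname(as.matrix(velocities)),
    mass = rec(masses),
    charge = rec(charges),
    c12 = rec(c12),
    c6 = rec(c6),
    role = {
      r <- as.integer(roles)
      if (length(r) == 1L) rep(r, n) else r
    },
    bonds = bonds,
    angles = angles,
    box = if (is.null(box)) NULL else as.numeric(box),
    restraints = restraints,
    posres = posres,
    labels = labels %||% rep("X", n)
  ), class = "particle_system")
  validate_system(sys)
  sys
}

#' Validate a particle system's structural invariants
#'
#' Checks array shapes, role consistency and that the total environment charge
#' is an integer (within 1e-9 e). When `settings` is supplied, also checks
#' that all cutoffs are smaller than half the box edge.
#'
#' @param sys A `particle_system`.
#' @param settings Optional [nonbonded_settings()].
#' @return `sys`, invisibly; errors on violation.
#' @export
validate_system <- function(sys, settings = NULL) {
  n <- nrow(sys$pos)
  for (f in c("mass", "charge", "c12", "c6", "role")) {
    if (length(sys[[f]]) != n) stop(sprintf("field '%s' has length %d, expected %d", f, length(sys[[f]]), n))
  }
  if (!all(dim(sys$vel) == c(n, 3L))) stop("velocities must be n x 3")
  if (any(!is.finite(sys$pos))) stop("non-finite coordinates")
  if (any(sys$role < 0L)) stop("roles must be >= 0 (0 = environment, i = molecule i)")
  if (any(sys$mass <= 0)) stop("masses must be positive")
  qenv <- sum(sys$charge[sys$role == 0L])
  if (abs(qenv - round(qenv)) > 1e-9) {
    stop(sprintf("total environment charge %.12f e is not an integer", qenv))
  }
  if (!is.null(sys$box)) {
    if (sys$box <= 0) stop("box edge must be positive")
    if (!is.null(settings)) {
      if (max(settings$cutoff, settings$embedding_cutoff) >= sys$box / 2) {
        stop("nonbonded cutoffs must be < box/2")
      }
    }
  }
  for (df in list(sys$bonds, sys$restraints)) {
    if (!is.null(df) && nrow(df)) {
      if (any(df$i == df$j)) stop("a pair term references one particle twice")
      if (any(df$i < 1 | df$j < 1 | df$i > n | df$j > n)) stop("pair term index out of range")
    }
  }
  invisible(sys)
}

#' @export
print.particle_system <- function(x, ...) {
  nmol <- length(setdiff(unique(x$role), 0L))
  cat(sprintf("particle_system: %d particles (%d environment, %d molecules)%s\n",
              nrow(x$pos), sum(x$role == 0L), nmol,
              if (is.null(x$box)) ", vacuum" else sprintf(", box %.3f nm", x$box)))
  invisible(x)
}

#' Particle index helpers
#'
#' @param sys A `particle_system`.
#' @param i Molecule (end-state) id.
#' @return Integer indices.
#' @export
environment_indices <- function(sys) which(sys$role == 0L)

#' @rdname environment_indices
#' @export
molecule_indices <- function(sys, i) which(sys$role == as.integer(i))

## 1-2 and 1-3 intramolecular exclusions implied by the bonded terms,
## returned as a 2-column matrix of sorted pairs.
exclusion_pairs <- function(sys) {
  b <- sys$bonds
  if (is.null(b) || !nrow(b)) return(matrix(integer(0), 0, 2))
  p12 <- cbind(pmin(b$i, b$j), pmax(b$i, b$j))
  ## 1-3: particles bonded to a common centre
  adj <- split(c(b$j, b$i), c(b$i, b$j))
  p13 <- list()
  for (centre in names(adj)) {
    nb <- unique(adj[[centre]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      p13[[centre]] <- t(cmb)
    }
  }
  out <- rbind(p12, do.call(rbind, p13))
  unique(out)
}

pair_key <- function(i, j, n) pmin(i, j) * (n + 1) + pmax(i, j)
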