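## Independent scalar evaluators and finite-difference helpers used as
## oracles; deliberately written as plain double loops, independent of the
## vectorized implementation they check.

## central finite-difference gradient of a scalar energy function
num_gradient <- function(efun, pos, h = 1e-5) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (k in 1:3) {
      p1 <- pos; p1[i, k] <- p1[i, k] + h
      p2 <- pos; p2[i, k] <- p2[i, k] - h
      g[i, k] <- (efun(p1) - efun(p2)) / (2 * h)
    }
  }
  g
}

## brute-force pair sum: LJ (geometric combination) + selected Coulomb form,
## plain double loop over explicitly given pairs, no cutoff logic
slow_pair_sum <- function(pos, pairs, charge, c12, c6, cutoff, eps_rf,
                          coulomb = c("rf", "plain", "none"), box = NULL) {
  coulomb <- match.arg(coulomb)
  f <- 138.935458
  crf <- 2 * (eps_rf - 1) / (2 * eps_rf + 1)
  e <- 0
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    d <- pos[j, ] - pos[i, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (r > cutoff) next
    cc12 <- sqrt(c12[i] * c12[j]); cc6 <- sqrt(c6[i] * c6[j])
    e <- e + cc12 / r^12 - cc6 / r^6
    if (coulomb == "rf") {
      e <- e + f * charge[i] * charge[j] *
        (1 / r + crf * r^2 / (2 * cutoff^3) - (1 + crf / 2) / cutoff)
    } else if (coulomb == "plain") {
      e <- e + f * charge[i] * charge[j] / r
    }
  }
  e
}

## small random LJ/charge cluster used by force-consistency property tests
random_toy_system <- function(n = 6, seed = 1, box = NULL, charged = TRUE) {
  set.seed(seed)
  repeat {
    pos <- matrix(stats::runif(3 * n, if (is.null(box)) 0.1 else 0.4,
                               if (is.null(box)) 1.4 else box - 0.4),
                  n, 3)
    dmin <- min(stats::dist(pos))
    if (dmin > 0.22) break
  }
  q <- if (charged) stats::runif(n, -0.3, 0.3) else rep(0, n)
  q <- q - mean(q)     # keep the environment net charge integral (zero)
  particle_system(pos,
                  charges = q,
                  masses = stats::runif(n, 5, 20),
                  c12 = stats::runif(n, 1e-6, 4e-6),
                  c6 = stats::runif(n, 1e-3, 4e-3),
                  roles = 0L, box = box)
}

## fabricate a reference-state record stream from explicit V_i series
fake_records <- function(V, s = 1, offsets = NULL, temperature = 298.15) {
  V <- as.matrix(V)
  N <- ncol(V)
  if (is.null(offsets)) offsets <- rep(0, N)
  vr <- apply(V, 1L, function(v)
    reference_energy(v, eds_parameters(s, offsets, temperature)))
  w <- t(apply(V, 1L, function(v)
    state_weights(v, eds_parameters(s, offsets, temperature))))
  df <- data.frame(time = seq_len(nrow(V)) * 0.01, V_R = vr)
  for (i in seq_len(N)) df[[paste0("V", i)]] <- V[, i]
  for (i in seq_len(N)) df[[paste0("w", i)]] <- w[, i]
  df$s <- s
  attr(df, "offsets") <- offsets
  attr(df, "temperature") <- temperature
  df
}

## default settings used across tests
test_settings <- function(cutoff = 1.2, eps_rf = 78.5) {
  nonbonded_settings(cutoff = cutoff, eps_rf = eps_rf, embedding_cutoff = cutoff)
}

## a compact solvated 2- or 3-state droplet for the heavier checks
small_droplet <- function(n_states = 2, seed = 3, coupling = "qmmm",
                          n_solvent = 24, identical_solutes = FALSE) {
  solutes <- toy_solute_templates(n_states)
  if (identical_solutes) {
    solutes <- rep(toy_solute_templates(1), n_states)
  }
  make_droplet(droplet_spec(n_solvent = n_solvent, box = 3.0,
                            solutes = solutes, seed = seed),
               coupling = coupling)
}
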