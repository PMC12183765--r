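## Free-energy estimation from reference-state records, hydration-cycle
## analysis, sampling diagnostics and accuracy metrics.

record_matrix <- function(records, what = c("V", "w")) {
  what <- match.arg(what)
  cols <- grep(sprintf("^%s[0-9]+$", what), names(records), value = TRUE)
  as.matrix(records[, cols[order(as.integer(sub(what, "", cols)))], drop = FALSE])
}

## per-state log-mean-exp of -beta (V_i - V_R); the building block of the
## Zwanzig estimates. Returns a length-N vector L_i with
## dG_iR = -L_i / beta.
state_log_averages <- function(records, beta) {
  V <- record_matrix(records, "V")
  x <- -beta * (V - records$V_R)
  apply(x, 2L, logmeanexp)
}

block_indices <- function(n, n_blocks) {
  n_blocks <- max(1L, min(n_blocks, n))
  split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
}

#' Zwanzig (FEP) free-energy difference between two end-states
#'
#' dG_ji = -1/beta (ln <exp(-beta (V_j - V_R))>_R
#'                  - ln <exp(-beta (V_i - V_R))>_R),
#' evaluated from the physical (s = 1) reference-state records with
#' log-mean-exp stability. The standard error is a seeded block bootstrap on
#' the time series (autocorrelation-robust).
#'
#' @param records Reference-state record data frame (columns `V_R`,
#'   `V1..VN`).
#' @param i,j End-state indices (dG from i to j).
#' @param beta Inverse temperature (mol/kJ).
#' @param n_blocks Contiguous blocks for the bootstrap (default 20).
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Bootstrap seed (default 1).
#' @return List with `dg`, `se`, `n`, `ess` (per-state effective sample
#'   sizes) and `unreliable` (TRUE when either state's ESS < 10; the value is
#'   still returned).
#' @export
zwanzig_pair <- function(records, i, j, beta, n_blocks = 20L, n_boot = 200L,
                         seed = 1L) {
  if (!nrow(records)) stop("empty record stream")
  V <- record_matrix(records, "V")
  if (i == j) {
    return(list(dg = 0, se = 0, n = nrow(records),
                ess = effective_samples(V, records$V_R, beta)[c(i, j)],
                unreliable = FALSE))
  }
  xj <- -beta * (V[, j] - records$V_R)
  xi <- -beta * (V[, i] - records$V_R)
  dg <- -(logmeanexp(xj) - logmeanexp(xi)) / beta
  blocks <- block_indices(length(xi), n_blocks)
  withr_seed <- .Random.seed_save()
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    pick <- sample.int(length(blocks), replace = TRUE)
    idx <- unlist(blocks[pick], use.names = FALSE)
    -(logmeanexp(xj[idx]) - logmeanexp(xi[idx])) / beta
  }, numeric(1))
  .Random.seed_restore(withr_seed)
  ess <- effective_samples(V, records$V_R, beta)
  list(dg = dg, se = stats::sd(boots), n = nrow(records),
       ess = ess[c(i, j)], unreliable = any(ess[c(i, j)] < 10))
}

## Kish effective sample size of the reweighting factors per state
effective_samples <- function(V, V_R, beta) {
  apply(-beta * (V - V_R), 2L, function(x) {
    lw <- x - logsumexp(x)
    exp(-logsumexp(2 * lw))
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(saved) {
  if (!is.null(saved)) assign(".Random.seed", saved, globalenv())
}

#' All pairwise free-energy differences from one reference-state stream
#'
#' Every dG_ji is the difference of per-state log-averages from the single
#' stream, so antisymmetry (dG_ji = -dG_ij), a zero diagonal and exact cycle
#' closure (dG_AB + dG_BC + dG_CA = 0) hold by construction.
#'
#' @inheritParams zwanzig_pair
#' @return A `free_energy_result`: `dg` (N x N matrix, kJ/mol, entry (j, i)
#'   is dG from state i to state j), `se` (block-bootstrap SEs), `ess`,
#'   `n`, `unreliable` flags per state.
#' @export
dg_matrix <- function(records, beta, n_blocks = 20L, n_boot = 200L, seed = 1L) {
  if (!nrow(records)) stop("empty record stream")
  L <- state_log_averages(records, beta)
  N <- length(L)
  dg <- outer(L, L, function(a, b) -(a - b) / beta)  # dg[j, i] = dG_{j<-i}
  V <- record_matrix(records, "V")
  x <- -beta * (V - records$V_R)
  blocks <- block_indices(nrow(V), n_blocks)
  saved <- .Random.seed_save()
  set.seed(seed)
  boots <- array(NA_real_, c(N, N, n_boot))
  for (b in seq_len(n_boot)) {
    pick <- sample.int(length(blocks), replace = TRUE)
    idx <- unlist(blocks[pick], use.names = FALSE)
    Lb <- apply(x[idx, , drop = FALSE], 2L, logmeanexp)
    boots[, , b] <- outer(Lb, Lb, function(a, bb) -(a - bb) / beta)
  }
  .Random.seed_restore(saved)
  se <- apply(boots, c(1, 2), stats::sd)
  ess <- effective_samples(V, records$V_R, beta)
  structure(list(dg = dg, se = se, ess = ess, n = nrow(records),
                 unreliable = ess < 10, beta = beta),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("free_energy_result: %d states, %d frames\n", nrow(x$dg), x$n))
  m <- x$dg
  dimnames(m) <- list(paste0("to_", seq_len(nrow(m))), paste0("from_", seq_len(ncol(m))))
  print(round(m, 4))
  invisible(x)
}

#' Combine independent production repeats
#'
#' Estimates are computed per repeat; the report is the mean with the
#' standard deviation over repeats as the uncertainty.
#'
#' @param results List of `free_energy_result`s (equal dimensions).
#' @return A `free_energy_result` with `dg` = mean, `se` = SD over repeats
#'   (0 when a single repeat is given, falling back to its bootstrap SE).
#' @export
combine_repeats <- function(results) {
  stopifnot(length(results) >= 1L)
  dgs <- simplify2array(lapply(results, function(r) r$dg))
  if (length(results) == 1L) {
    return(results[[1]])
  }
  structure(list(dg = apply(dgs, c(1, 2), mean),
                 se = apply(dgs, c(1, 2), stats::sd),
                 n = sum(vapply(results, function(r) r$n, numeric(1))),
                 n_repeats = length(results),
                 ess = rowMeans(vapply(results, function(r) r$ess,
                                       numeric(nrow(results[[1]]$dg)))),
                 unreliable = Reduce(`|`, lapply(results, function(r) r$unreliable)),
                 beta = results[[1]]$beta),
            class = "free_energy_result")
}

#' Relative hydration free energies from the thermodynamic cycle
#'
#' ddG^hyd_ji = dG^wat_ji - dG^vac_ji. When the end-states are defined
#' through the embedded-QM construction, their vacuum relative free energies
#' are identically zero, so `vacuum_result = NULL` returns the water leg
#' alone (single-simulation mode).
#'
#' @param water_result A `free_energy_result` from the solvated simulation.
#' @param vacuum_result A `free_energy_result` from the vacuum simulation, or
#'   NULL.
#' @return N x N matrix of ddG^hyd (kJ/mol).
#' @export
hydration_cycle <- function(water_result, vacuum_result = NULL) {
  dgw <- water_result$dg
  if (is.null(vacuum_result)) return(dgw)
  if (!identical(dim(vacuum_result$dg), dim(dgw))) {
    stop("water and vacuum results have different dimensions")
  }
  dgw - vacuum_result$dg
}

#' Anchor relative hydration free energies to an experimental mean
#'
#' dG^hyd_i = ddG^hyd_Ri - (mean_j ddG^hyd_Rj - mean_j dG^exp_j): the
#' computed relatives (reference state R to each molecule) are shifted so
#' their mean matches the experimental mean. The output is invariant under
#' the choice of R (changing R shifts all relatives by a constant, which the
#' mean-centering removes) and its mean equals the experimental mean exactly.
#'
#' @param ddg_r Vector ddG^hyd_Ri, reference-to-each (kJ/mol); the reference
#'   entry itself is 0.
#' @param dg_exp Experimental dG^hyd per molecule (kJ/mol), same order and
#'   length (no missing values).
#' @return Absolute dG^hyd vector (kJ/mol).
#' @export
anchor_absolute <- function(ddg_r, dg_exp) {
  if (length(ddg_r) != length(dg_exp)) stop("computed/experimental length mismatch")
  if (any(!is.finite(dg_exp))) stop("missing experimental entry")
  ddg_r - (mean(ddg_r) - mean(dg_exp))
}

#' Per-state sampling fractions and undersampling classification
#'
#' A frame "belongs" to end-state i when V_i - E_i^R is minimal (ties broken
#' by the lowest state index, the behaviour of `which.min`). The stream is
#' flagged undersampled when the smallest occurrence fraction is below
#' `theta`; physical sampling requires every fraction to be at least
#' `theta_phys`.
#'
#' @param records Record data frame (columns `V1..VN`).
#' @param offsets Energy offsets E^R used for the classification (defaults to
#'   the offsets stored on the records).
#' @param theta Undersampling threshold (default 0.05).
#' @param theta_phys Physical-sampling threshold (default 0.1).
#' @return List: `occurrence` (fractions summing to 1), `undersampled`,
#'   `physical` (logical), `n`.
#' @export
sampling_fractions <- function(records, offsets = NULL, theta = 0.05,
                               theta_phys = 0.1) {
  if (!nrow(records)) stop("empty record stream")
  V <- record_matrix(records, "V")
  offsets <- offsets %||% attr(records, "offsets") %||% rep(0, ncol(V))
  shifted <- sweep(V, 2L, offsets)
  winner <- apply(shifted, 1L, which.min)
  occ <- tabulate(winner, nbins = ncol(V)) / nrow(V)
  list(occurrence = occ, undersampled = min(occ) < theta,
       physical = all(occ >= theta_phys), n = nrow(V))
}

#' Accuracy and ranking metrics against experiment
#'
#' MAE, RMSE, Kendall's tau (tau-b, tie-corrected, via [stats::cor()]),
#' Spearman's rho, Pearson's r and R^2 (the squared Pearson coefficient).
#'
#' @param computed,experimental Equal-length numeric vectors (length >= 2
#'   for the correlation metrics).
#' @return Named list of metrics.
#' @export
ranking_metrics <- function(computed, experimental) {
  if (length(computed) != length(experimental)) stop("length mismatch")
  if (length(computed) < 2) stop("need at least 2 values for correlation metrics")
  err <- computed - experimental
  pear <- stats::cor(computed, experimental, method = "pearson")
  list(mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       kendall = stats::cor(computed, experimental, method = "kendall"),
       spearman = stats::cor(computed, experimental, method = "spearman"),
       pearson = pear,
       r2 = pear^2)
}

#' Full hydration report
#'
#' Combines the cycle, anchoring and metrics into one serialisable report.
#'
#' @param water_result,vacuum_result As in [hydration_cycle()].
#' @param dg_exp Experimental reference vector (kJ/mol) or NULL.
#' @param reference Reference state index R for the anchoring (default 1).
#' @return A `hydration_report` list: `ddg` matrix, `dg_hyd` (when `dg_exp`
#'   given), `dg_exp`, `metrics`.
#' @export
hydration_report <- function(water_result, vacuum_result = NULL,
                             dg_exp = NULL, reference = 1L) {
  ddg <- hydration_cycle(water_result, vacuum_result)
  out <- list(ddg = ddg, reference = reference)
  if (!is.null(dg_exp)) {
    rel <- ddg[, reference]              # ddG_{i <- R} for each i
    out$dg_hyd <- anchor_absolute(rel, dg_exp)
    out$dg_exp <- dg_exp
    out$metrics <- ranking_metrics(out$dg_hyd, dg_exp)
  }
  structure(out, class = "hydration_report")
}
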