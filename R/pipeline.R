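#' Pipeline configuration
#'
#' Stage lengths are in integration steps; the defaults are desk-scale
#' analogues of the three-phase procedure (exploration, optimization,
#' production). The exploration bias (+/-500 kJ/mol), the 21-point
#' log-spaced s grid from 1 to 1e-5, ten optimization iterations and ten
#' production repeats mirror the standard protocol.
#'
#' @param explore_steps Steps per biased exploration run (one per end-state).
#' @param bias Exploration offset magnitude (kJ/mol): +bias for the target
#'   end-state, -bias for all others. Default 500.
#' @param grid_size Points in the s lower-bound grid (default 21).
#' @param s_min_grid_floor Smallest grid s (default 1e-5).
#' @param lower_bound_steps Steps per grid-point EDS run.
#' @param theta Undersampling occurrence threshold (default 0.05).
#' @param theta_phys Physical-sampling threshold at s = 1 (default 0.1).
#' @param n_replicas Initial ladder size (default 6).
#' @param offset_steps Steps of the initial-offset RE-EDS run.
#' @param opt_iterations Optimization iterations (default 10).
#' @param opt_steps Steps per optimization iteration.
#' @param prod_steps Production steps per repeat.
#' @param n_repeats Independent production repeats (default 10).
#' @param exchange_every Steps between swap attempts (default 50).
#' @param save_every Record stride (default 10).
#' @param min_acceptance Neighbour acceptance below which the pair is
#'   bisected during optimization (default 0.05).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(explore_steps = 1000L, bias = 500,
                            grid_size = 21L, s_min_grid_floor = 1e-5,
                            lower_bound_steps = 400L, theta = 0.05,
                            theta_phys = 0.1, n_replicas = 6L,
                            offset_steps = 1000L, opt_iterations = 10L,
                            opt_steps = 2000L, prod_steps = 10000L,
                            n_repeats = 10L, exchange_every = 50L,
                            save_every = 10L, min_acceptance = 0.05) {
  cfg <- list(explore_steps = as.integer(explore_steps), bias = bias,
              grid_size = as.integer(grid_size),
              s_min_grid_floor = s_min_grid_floor,
              lower_bound_steps = as.integer(lower_bound_steps),
              theta = theta, theta_phys = theta_phys,
              n_replicas = as.integer(n_replicas),
              offset_steps = as.integer(offset_steps),
              opt_iterations = as.integer(opt_iterations),
              opt_steps = as.integer(opt_steps),
              prod_steps = as.integer(prod_steps),
              n_repeats = as.integer(n_repeats),
              exchange_every = as.integer(exchange_every),
              save_every = as.integer(save_every),
              min_acceptance = min_acceptance)
  for (f in c("explore_steps", "lower_bound_steps", "offset_steps",
              "opt_steps", "prod_steps")) {
    if (cfg[[f]] <= 0) stop(sprintf("%s must be > 0", f))
  }
  if (cfg$grid_size < 1 || cfg$n_repeats < 1 || cfg$opt_iterations < 1) {
    stop("counts must be >= 1")
  }
  if (cfg$s_min_grid_floor < 1e-7) stop("grid floor below 1e-7 is not supported")
  structure(cfg, class = "pipeline_config")
}

s_grid <- function(config) {
  10^seq(0, log10(config$s_min_grid_floor), length.out = config$grid_size)
}

#' Exploration: one relevant configuration per end-state
#'
#' For each end-state i a short EDS run at s = 1 is performed with offsets
#' biased toward that state (+bias for i, -bias for the others), which makes
#' state i dominate the reference state. The final frame must have
#' w_i > 0.99; otherwise an exploration-failure error names the state.
#'
#' @param system A [particle_system()].
#' @param states List of [end_state_definition()]s.
#' @param settings A [nonbonded_settings()].
#' @param int_settings An [integrator_settings()].
#' @param config A [pipeline_config()].
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @return List of configurations `list(pos, vel)`, one per end-state.
#' @export
generate_state_configs <- function(system, states, settings, int_settings,
                                   config, temperature = 298.15, seed = 1L) {
  N <- length(states)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    offs <- rep(-config$bias, N)
    offs[i] <- config$bias
    run <- run_re_eds(system, states, settings, int_settings, s_values = 1,
                      offsets = offs, n_steps = config$explore_steps,
                      temperature = temperature,
                      exchange_every = config$explore_steps,
                      save_every = config$save_every, seed = seed + i)
    rec <- run$records[[1]]
    w_final <- rec[nrow(rec), paste0("w", i)]
    if (N > 1L && w_final <= 0.99) {
      stop(sprintf("exploration failed for end-state %d: final weight %.3f <= 0.99",
                   i, w_final))
    }
    out[[i]] <- list(pos = run$ladder$replicas[[1]]$pos,
                     vel = run$ladder$replicas[[1]]$vel)
  }
  out
}

#' Lower bound of the s-ladder from a log-spaced grid scan
#'
#' Runs an independent EDS simulation at every grid s (offsets all zero),
#' assigning start frames round-robin from the exploration configurations
#' (starting-state mixing). s_min is the largest grid s at which every
#' end-state is the minimum-energy state in at least `theta` of the frames;
#' when no grid point qualifies the smallest grid value is returned with a
#' warning.
#'
#' @inheritParams generate_state_configs
#' @param configs Exploration configurations from
#'   [generate_state_configs()].
#' @return List: `s_min`, `table` (per-s occurrence fractions), `grid`.
#' @export
find_s_lower_bound <- function(system, states, settings, int_settings,
                               configs, config, temperature = 298.15,
                               seed = 1L) {
  grid <- s_grid(config)
  N <- length(states)
  occ <- matrix(NA_real_, length(grid), N)
  for (g in seq_along(grid)) {
    start <- configs[[(g - 1L) %% N + 1L]]
    run <- run_re_eds(system, states, settings, int_settings,
                      s_values = grid[g], offsets = rep(0, N),
                      n_steps = config$lower_bound_steps,
                      temperature = temperature,
                      exchange_every = config$lower_bound_steps,
                      save_every = config$save_every, seed = seed + 100L + g,
                      configs = list(start))
    occ[g, ] <- sampling_fractions(run$records[[1]],
                                   offsets = rep(0, N))$occurrence
  }
  qualifies <- apply(occ, 1L, function(o) min(o) >= config$theta)
  if (any(qualifies)) {
    s_min <- grid[which(qualifies)[1]]   # grid descends: first hit is largest
  } else {
    warning("no grid s qualifies; falling back to the smallest grid value")
    s_min <- grid[length(grid)]
  }
  tab <- data.frame(s = grid, occ)
  names(tab) <- c("s", paste0("occ", seq_len(N)))
  list(s_min = s_min, table = tab, grid = grid)
}

#' Initial energy offsets from a Zwanzig estimate
#'
#' E_i^R is set to dG_iR = -1/beta ln <exp(-beta (V_i - V_R))>_R computed on
#' the lowest-s replica's records (where all states are sampled), then
#' mean-centred so that sum_i E_i^R = 0. With E_i^R = dG_iR all end-states
#' are equally likely in the reference state.
#'
#' @param records Record data frame from the lowest-s replica.
#' @param temperature Temperature (K).
#' @return Offset vector (kJ/mol) summing to zero.
#' @export
estimate_initial_offsets <- function(records, temperature = 298.15) {
  beta <- beta_of(temperature)
  V <- record_matrix(records, "V")
  x <- -beta * (V - records$V_R)
  ## the test for "no effective samples" is shift-invariant (log domain):
  ## V_R carries a configuration-independent -ln(N)/(beta s) term that would
  ## make the raw exp() underflow at small s without implying undersampling
  ess <- apply(x, 2L, function(col) {
    lw <- col - logsumexp(col)
    exp(-logsumexp(2 * lw))
  })
  if (any(!is.finite(ess)) || any(ess <= 1 + 1e-9 & nrow(V) > 1)) {
    bad <- which(!is.finite(ess) | ess <= 1 + 1e-9)
    stop(sprintf("undersampled offset estimate: state %s has no effective samples",
                 paste(bad, collapse = ", ")))
  }
  dgr <- -apply(x, 2L, logmeanexp) / beta
  dgr - mean(dgr)
}

## flux-balancing replacement of interior s-values: fraction of up-moving
## replica labels per level should decrease linearly across the ladder.
rebalance_s <- function(s_values, history, L_target = length(s_values)) {
  L <- length(s_values)
  if (L < 3L || nrow(history) < 4L) return(s_values)
  ids <- sort(unique(as.vector(history)))
  dir_counts <- matrix(0, L, 2L)   # up, down visits per level
  for (id in ids) {
    lev <- apply(history, 1L, function(row) which(row == id)[1])
    lab <- NA_character_
    for (t in seq_along(lev)) {
      if (lev[t] == L) lab <- "up"          # at the bottom: next move is upward
      if (lev[t] == 1L) lab <- "down"
      if (!is.na(lab)) {
        dir_counts[lev[t], if (lab == "up") 1L else 2L] <-
          dir_counts[lev[t], if (lab == "up") 1L else 2L] + 1L
      }
    }
  }
  tot <- rowSums(dir_counts)
  if (any(tot == 0)) return(s_values)
  f <- dir_counts[, 2L] / tot            # fraction moving down (from top)
  ## enforce monotone non-decreasing f from top(1) to bottom(L)... use the
  ## cumulative maximum, then invert at equally spaced targets
  f <- cummax(f)
  if (f[L] - f[1] < 1e-9) return(s_values)
  xs <- log10(s_values)
  targets <- seq(f[1], f[L], length.out = L_target)
  interior <- stats::approx(f, xs, xout = targets, ties = "ordered")$y
  out <- 10^interior
  out[1] <- s_values[1]
  out[L_target] <- s_values[L]
  out <- sort(unique(pmin(pmax(out, s_values[L]), 1)), decreasing = TRUE)
  if (length(out) != L_target || any(diff(log10(out)) > -1e-12)) return(s_values)
  out
}

#' Optimize the s-ladder and energy offsets
#'
#' Iterates (default 10 times): run a short RE-EDS simulation, re-estimate
#' the offsets from the lowest-s replica, and re-place the interior s-values
#' by flux balancing (a round-trip-time heuristic: interior s-values are
#' moved so the fraction of downward-moving replica labels changes evenly
#' across the ladder). When any neighbour acceptance falls below
#' `min_acceptance` the worst pair is bisected (geometric mean), growing the
#' ladder. Terminates early when every end-state's occurrence at s = 1
#' reaches `theta_phys` and every replica completed at least one round trip
#' in the iteration. Non-convergence returns the best parameters so far with
#' diagnostics rather than an error.
#'
#' @inheritParams generate_state_configs
#' @param s_min Lower bound from [find_s_lower_bound()].
#' @param offsets Initial offsets (e.g. [estimate_initial_offsets()]).
#' @param configs Optional starting configurations per replica.
#' @return List: `s_values`, `offsets`, `converged`, `diagnostics` (per
#'   iteration), `configs` (final replica configurations).
#' @export
optimize_parameters <- function(system, states, settings, int_settings,
                                s_min, offsets, config, temperature = 298.15,
                                seed = 1L, configs = NULL) {
  N <- length(states)
  L <- config$n_replicas
  s_values <- 10^seq(0, log10(s_min), length.out = L)
  if (s_min >= 1) s_values <- c(1)
  diagnostics <- list()
  converged <- FALSE
  run <- NULL
  for (it in seq_len(config$opt_iterations)) {
    run <- run_re_eds(system, states, settings, int_settings, s_values,
                      offsets, n_steps = config$opt_steps,
                      temperature = temperature,
                      exchange_every = config$exchange_every,
                      save_every = config$save_every, seed = seed + 200L + it,
                      configs = configs)
    configs <- lapply(run$ladder$replicas, function(r) list(pos = r$pos, vel = r$vel))
    low <- run$records[[length(run$records)]]
    offsets_new <- tryCatch(estimate_initial_offsets(low, temperature),
                            error = function(e) offsets)
    occ_top <- sampling_fractions(run$records[[1]],
                                  offsets = offsets)$occurrence
    rts <- round_trip_stats(run$history)
    acc <- run$acceptance
    diagnostics[[it]] <- list(iteration = it, s_values = s_values,
                              offsets = offsets, occurrence_top = occ_top,
                              round_trips = rts$round_trips,
                              acceptance = acc)
    if (all(occ_top >= config$theta_phys) &&
        length(rts$round_trips) &&
        all(rts$round_trips >= 1L)) {
      converged <- TRUE
      offsets <- offsets_new
      break
    }
    offsets <- offsets_new
    if (length(s_values) > 1L) {
      if (!is.null(acc) && nrow(acc) && min(acc$acceptance) < config$min_acceptance) {
        worst <- acc$pair[which.min(acc$acceptance)]
        s_new <- sqrt(s_values[worst] * s_values[worst + 1L])
        s_values <- sort(unique(c(s_values, s_new)), decreasing = TRUE)
        configs <- NULL                  # ladder grew; re-seed configurations
      } else {
        s_values <- rebalance_s(s_values, run$history)
      }
    }
  }
  list(s_values = s_values, offsets = offsets, converged = converged,
       diagnostics = diagnostics, configs = configs,
       last_run = run)
}

#' Production runs
#'
#' `n_repeats` independent RE-EDS runs with re-drawn starting velocities
#' (seeded per repeat). A repeat whose integration blows up is marked failed
#' and its partial output discarded; all other repeats are returned.
#'
#' @inheritParams optimize_parameters
#' @param s_values Optimized ladder.
#' @param offsets Optimized offsets.
#' @param configs Starting configurations (e.g. from the optimizer).
#' @return List with `repeats` (each: `records`, `history`, `acceptance`,
#'   `seed`, `failed`) and parameters used. The top-level (`records[[1]]`)
#'   stream of each repeat is the physical replica used for estimation.
#' @export
run_production <- function(system, states, settings, int_settings, s_values,
                           offsets, config, temperature = 298.15, seed = 1L,
                           configs = NULL) {
  if (config$prod_steps <= 0) stop("zero-length production rejected")
  reps <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    cfgs <- configs
    if (!is.null(cfgs)) {
      cfgs <- lapply(cfgs, function(cc) list(pos = cc$pos, vel = NULL))
    }
    res <- tryCatch({
      run <- run_re_eds(system, states, settings, int_settings, s_values,
                        offsets, n_steps = config$prod_steps,
                        temperature = temperature,
                        exchange_every = config$exchange_every,
                        save_every = config$save_every,
                        seed = seed + 1000L + r, configs = cfgs)
      list(records = run$records, history = run$history,
           acceptance = run$acceptance, exchange_log = run$exchange_log,
           seed = seed + 1000L + r, failed = FALSE)
    }, error = function(e) {
      list(records = NULL, history = NULL, acceptance = NULL,
           seed = seed + 1000L + r, failed = TRUE,
           message = conditionMessage(e))
    })
    reps[[r]] <- res
  }
  list(repeats = reps, s_values = s_values, offsets = offsets,
       temperature = temperature)
}

#' Run the full three-phase pipeline and estimate free energies
#'
#' explore -> lower bound -> initial offsets -> optimize -> production ->
#' Zwanzig estimation on the physical replica of each repeat, combined as
#' mean +/- SD over repeats.
#'
#' @inheritParams generate_state_configs
#' @return List with the stage outputs (`configs`, `lower_bound`, `offsets`,
#'   `optimization`, `production`) and `result` (a combined
#'   `free_energy_result`).
#' @export
run_reeds_pipeline <- function(system, states, settings, int_settings,
                               config = pipeline_config(),
                               temperature = 298.15, seed = 1L) {
  configs <- generate_state_configs(system, states, settings, int_settings,
                                    config, temperature, seed)
  lb <- find_s_lower_bound(system, states, settings, int_settings, configs,
                           config, temperature, seed)
  N <- length(states)
  ## short RE-EDS at the initial ladder for offset estimation
  s0 <- 10^seq(0, log10(lb$s_min), length.out = max(2L, config$n_replicas))
  if (lb$s_min >= 1) s0 <- 1
  init_run <- run_re_eds(system, states, settings, int_settings, s0,
                         rep(0, N), n_steps = config$offset_steps,
                         temperature = temperature,
                         exchange_every = config$exchange_every,
                         save_every = config$save_every, seed = seed + 500L,
                         configs = rep(list(configs[[1]]), length(s0)))
  offs0 <- estimate_initial_offsets(init_run$records[[length(init_run$records)]],
                                    temperature)
  opt <- optimize_parameters(system, states, settings, int_settings,
                             lb$s_min, offs0, config, temperature, seed)
  prod <- run_production(system, states, settings, int_settings,
                         opt$s_values, opt$offsets, config, temperature,
                         seed, configs = opt$configs)
  beta <- beta_of(temperature)
  per_rep <- list()
  for (rep_res in prod$repeats) {
    if (!rep_res$failed) {
      per_rep[[length(per_rep) + 1L]] <- dg_matrix(rep_res$records[[1]], beta)
    }
  }
  if (!length(per_rep)) stop("all production repeats failed")
  list(configs = configs, lower_bound = lb, initial_offsets = offs0,
       optimization = opt, production = prod,
       per_repeat = per_rep, result = combine_repeats(per_rep))
}
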