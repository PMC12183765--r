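#' Metropolis acceptance probability for a replica swap
#'
#' p = min(1, exp(-beta ((V_R(r_k; s_l) + V_R(r_l; s_k))
#' - (V_R(r_k; s_k) + V_R(r_l; s_l))))).
#' Only the reference-state potential energies enter: at equal temperature
#' the kinetic terms cancel. The criterion is symmetric under relabelling
#' the two replicas.
#'
#' @param v_k_at_sk,v_k_at_sl Reference energies of configuration k at its
#'   own s and at the neighbour's s (kJ/mol).
#' @param v_l_at_sl,v_l_at_sk Same for configuration l.
#' @param beta Inverse temperature (mol/kJ).
#' @return Probability in \[0, 1\].
#' @export
exchange_probability <- function(v_k_at_sk, v_k_at_sl, v_l_at_sl, v_l_at_sk, beta) {
  vals <- c(v_k_at_sk, v_k_at_sl, v_l_at_sl, v_l_at_sk)
  if (any(!is.finite(vals))) stop("non-finite reference energy in exchange criterion")
  delta <- (v_k_at_sl + v_l_at_sk) - (v_k_at_sk + v_l_at_sl)
  min(1, exp(-beta * delta))
}

#' Build a replica ladder
#'
#' @param s_values Strictly descending smoothness values in (0, 1] with
#'   s_values[1] == 1 (the physical replica sits on top).
#' @param configs List of starting configurations, each `list(pos, vel)`;
#'   recycled if a single configuration is given.
#' @param exchange_period Steps between swap attempts.
#' @return An object of class `replica_ladder`. Each replica carries a
#'   persistent `replica_id` that follows its configuration through swaps.
#' @export
replica_ladder <- function(s_values, configs, exchange_period = 50L) {
  s_values <- as.numeric(s_values)
  if (any(diff(s_values) >= 0)) stop("s_values must be strictly descending")
  if (abs(s_values[1] - 1) > 1e-12) stop("top replica must have s = 1.0")
  if (any(s_values <= 0)) stop("s must be positive")
  L <- length(s_values)
  if (!is.null(configs$pos)) configs <- list(configs)
  if (length(configs) == 1L) configs <- rep(configs, L)
  if (length(configs) != L) stop("need one starting configuration per replica")
  reps <- lapply(seq_len(L), function(i) {
    list(pos = configs[[i]]$pos, vel = configs[[i]]$vel, replica_id = i)
  })
  structure(list(s_values = s_values, replicas = reps,
                 exchange_period = as.integer(exchange_period)),
            class = "replica_ladder")
}

#' Attempt one sweep of neighbour swaps
#'
#' Attempts the disjoint neighbour pairs (1-2, 3-4, ...) for `phase = "even"`
#' or (2-3, 4-5, ...) for `phase = "odd"`, each with a single uniform draw.
#' On acceptance the configurations (coordinates, velocities and replica id)
#' swap between the two s-levels. `V_per_level` must hold the current
#' end-state energy vector of the configuration at each level; reference
#' energies at both s-values are recomputed from it (the end-state energies
#' themselves do not depend on s).
#'
#' @param ladder A [replica_ladder()].
#' @param phase "even" or "odd".
#' @param V_per_level List of per-state energy vectors, one per level.
#' @param offsets Global energy offsets E^R.
#' @param temperature Temperature (K).
#' @return List: updated `ladder` and a data frame `log` with one row per
#'   attempted pair (`level_a`, `level_b`, `delta`, `p`, `accepted`).
#' @export
attempt_sweep <- function(ladder, phase = c("even", "odd"), V_per_level,
                          offsets, temperature = 298.15) {
  phase <- match.arg(phase)
  L <- length(ladder$s_values)
  first <- if (phase == "even") 1L else 2L
  starts <- if (first > L - 1L) integer(0) else seq(first, L - 1L, by = 2L)
  beta <- beta_of(temperature)
  logs <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    a <- starts[m]; b <- a + 1L
    pa <- eds_parameters(ladder$s_values[a], offsets, temperature)
    pb <- eds_parameters(ladder$s_values[b], offsets, temperature)
    vaa <- reference_energy(V_per_level[[a]], pa)
    vab <- reference_energy(V_per_level[[a]], pb)
    vbb <- reference_energy(V_per_level[[b]], pb)
    vba <- reference_energy(V_per_level[[b]], pa)
    p <- exchange_probability(vaa, vab, vbb, vba, beta)
    acc <- stats::runif(1) < p
    if (acc) {
      tmp <- ladder$replicas[[a]]
      ladder$replicas[[a]] <- ladder$replicas[[b]]
      ladder$replicas[[b]] <- tmp
      tmpV <- V_per_level[[a]]
      V_per_level[[a]] <- V_per_level[[b]]
      V_per_level[[b]] <- tmpV
    }
    logs[[m]] <- data.frame(level_a = a, level_b = b,
                            delta = (vab + vba) - (vaa + vbb),
                            p = p, accepted = acc)
  }
  list(ladder = ladder, V_per_level = V_per_level,
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(level_a = integer(0), level_b = integer(0),
                    delta = numeric(0), p = numeric(0), accepted = logical(0)))
}

#' Round-trip statistics from an exchange history
#'
#' A round trip is one traversal from one ladder extreme to the other and
#' back (top s = 1 -> bottom -> top, or the reverse). The history records,
#' per exchange step, which replica id sat at which level.
#'
#' @param history Integer matrix, rows = snapshots, columns = levels,
#'   entries = replica ids (as produced by [run_re_eds()]).
#' @return A `round_trip_stats` list: per-replica round-trip counts,
#'   extreme-visit labels, and total round trips.
#' @export
round_trip_stats <- function(history) {
  history <- as.matrix(history)
  L <- ncol(history)
  ids <- sort(unique(as.vector(history)))
  trips <- stats::setNames(integer(length(ids)), ids)
  labels <- list()
  for (id in ids) {
    lev <- apply(history, 1L, function(row) which(row == id)[1])
    ext <- ifelse(lev == 1L, "top", ifelse(lev == L, "bottom", NA))
    ext <- ext[!is.na(ext)]
    if (length(ext)) ext <- ext[c(TRUE, ext[-1] != ext[-length(ext)])]
    labels[[as.character(id)]] <- ext
    trips[as.character(id)] <- max(0L, (length(ext) - 1L) %/% 2L)
  }
  structure(list(round_trips = trips, total = sum(trips), labels = labels),
            class = "round_trip_stats")
}

#' Run a replica-exchange EDS simulation
#'
#' Propagates one EDS replica per s-level with the given integrator, attempts
#' alternating even/odd neighbour sweeps every `exchange_every` steps, and
#' records reference-state frames (time, s, V_R, V_i, w_i) every `save_every`
#' steps for every level. With a single s-level this is a plain EDS run.
#'
#' @param system A [particle_system()] providing topology and starting
#'   geometry.
#' @param states List of [end_state_definition()]s.
#' @param settings A [nonbonded_settings()].
#' @param int_settings An [integrator_settings()].
#' @param s_values Descending s-ladder (top = 1), or a single s.
#' @param offsets Energy offsets E^R (global, shared by all replicas).
#' @param n_steps Integration steps per replica.
#' @param temperature Temperature (K).
#' @param exchange_every Steps between sweeps (default 50).
#' @param save_every Recording stride (default 10).
#' @param seed Integer seed; set before velocity drawing and propagation.
#' @param configs Optional per-replica starting configurations
#'   (`list(list(pos, vel), ...)`, velocities may be NULL to re-draw).
#' @return List with `records` (one data.frame per level; the top level is
#'   the physical replica), `exchange_log`, `history` (replica-id matrix),
#'   `ladder` (final), `acceptance` (per neighbour pair).
#' @export
run_re_eds <- function(system, states, settings, int_settings, s_values,
                       offsets, n_steps, temperature = 298.15,
                       exchange_every = 50L, save_every = 10L, seed = NULL,
                       configs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  engine <- eds_engine(system, states, settings)
  L <- length(s_values)
  if (is.null(configs)) {
    configs <- list(list(pos = system$pos, vel = NULL))
  }
  if (!is.null(configs$pos)) configs <- list(configs)
  if (length(configs) == 1L) configs <- rep(configs, L)
  for (i in seq_len(L)) {
    if (is.null(configs[[i]]$vel)) {
      configs[[i]]$vel <- maxwell_velocities(system$mass, int_settings$t_ref)
    }
  }
  if (L > 1L) {
    ladder <- replica_ladder(s_values, configs, exchange_every)
  } else {
    ## single-replica EDS runs at any s are allowed (no top-of-ladder check)
    ladder <- structure(list(s_values = as.numeric(s_values),
                             replicas = list(list(pos = configs[[1]]$pos,
                                                  vel = configs[[1]]$vel,
                                                  replica_id = 1L)),
                             exchange_period = as.integer(exchange_every)),
                        class = "replica_ladder")
  }
  params <- lapply(ladder$s_values, eds_parameters, offsets = offsets,
                   temperature = temperature)
  n_chunks <- max(1L, ceiling(n_steps / exchange_every))
  nrec_max <- ceiling(n_steps / save_every) + 1L
  N <- length(states)
  recs <- lapply(seq_len(L), function(i) matrix(NA_real_, nrec_max, 3 + 2 * N))
  nrec <- integer(L)
  states_md <- vector("list", L)
  V_per_level <- vector("list", L)
  ex_logs <- list()
  history <- matrix(NA_integer_, n_chunks + 1L, L)
  step_done <- 0L
  phase <- "even"
  for (chunk in seq_len(n_chunks)) {
    nthis <- min(exchange_every, n_steps - step_done)
    if (nthis <= 0) break
    for (lev in seq_len(L)) {
      rep_i <- ladder$replicas[[lev]]
      ffn <- local({
        p <- params[[lev]]
        function(pos) engine(pos, p)
      })
      rec_fn <- local({
        lev0 <- lev
        function(step, st) {
          nrec[lev0] <<- nrec[lev0] + 1L
          recs[[lev0]][nrec[lev0], ] <<-
            c((step_done + step) * int_settings$dt, st$eval$V_R,
              st$eval$V, st$eval$w, ladder$s_values[lev0])
        }
      })
      st <- if (is.null(states_md[[lev]]) ||
                !identical(states_md[[lev]]$replica_id, rep_i$replica_id)) {
        list(pos = rep_i$pos, vel = rep_i$vel, mass = system$mass)
      } else states_md[[lev]]
      st$replica_id <- rep_i$replica_id
      out <- propagate(st$pos, st$vel, system$mass, ffn, int_settings, nthis,
                       save_every = save_every, record_fn = rec_fn)
      out$replica_id <- rep_i$replica_id
      states_md[[lev]] <- out
      ladder$replicas[[lev]]$pos <- out$pos
      ladder$replicas[[lev]]$vel <- out$vel
      V_per_level[[lev]] <- out$eval$V
    }
    step_done <- step_done + nthis
    history[chunk, ] <- vapply(ladder$replicas, function(r) r$replica_id, integer(1))
    if (L > 1L) {
      sw <- attempt_sweep(ladder, phase, V_per_level, offsets, temperature)
      ladder <- sw$ladder
      V_per_level <- sw$V_per_level
      if (nrow(sw$log)) {
        sw$log$step <- step_done
        ex_logs[[length(ex_logs) + 1L]] <- sw$log
      }
      phase <- if (phase == "even") "odd" else "even"
      ## configurations moved between levels: refresh MD states
      for (lev in seq_len(L)) {
        if (!identical(states_md[[lev]]$replica_id, ladder$replicas[[lev]]$replica_id)) {
          states_md[lev] <- list(NULL)
        }
      }
    }
  }
  history[n_chunks + 1L, ] <- vapply(ladder$replicas, function(r) r$replica_id, integer(1))
  ex_log <- if (length(ex_logs)) do.call(rbind, ex_logs) else NULL
  acc <- NULL
  if (!is.null(ex_log) && nrow(ex_log)) {
    acc <- stats::aggregate(accepted ~ level_a, data = ex_log, FUN = mean)
    names(acc) <- c("pair", "acceptance")
  }
  records <- lapply(seq_len(L), function(lev) {
    m <- recs[[lev]][seq_len(nrec[lev]), , drop = FALSE]
    df <- as.data.frame(m)
    names(df) <- c("time", "V_R", paste0("V", seq_len(N)), paste0("w", seq_len(N)), "s")
    attr(df, "offsets") <- offsets
    attr(df, "temperature") <- temperature
    df
  })
  list(records = records, exchange_log = ex_log, history = history,
       ladder = ladder, acceptance = acc,
       s_values = ladder$s_values)
}
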