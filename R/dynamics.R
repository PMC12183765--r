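#' Integrator settings
#'
#' One thermostatting mode is active at a time: "sd" (stochastic dynamics,
#' BAOAB-splitting Langevin with friction `gamma`), "berendsen"
#' (velocity-Verlet with weak-coupling velocity scaling, coupling time
#' `tau_t`) or "none" (plain velocity-Verlet, NVE).
#'
#' @param dt Time step (ps). Defaults 0.0005 for embedded-QM runs; 0.002 is
#'   typical for pure MM.
#' @param t_ref Reference temperature (K), default 298.15.
#' @param gamma Langevin friction (1/ps), default 20 (used by "sd").
#' @param tau_t Berendsen coupling time (ps) (used by "berendsen").
#' @param thermostat "sd", "berendsen" or "none".
#' @param seed Optional integer seed applied before a propagation run.
#' @return An object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 5e-4, t_ref = 298.15, gamma = 20,
                                tau_t = 0.1,
                                thermostat = c("sd", "berendsen", "none"),
                                seed = NULL) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, t_ref > 0, gamma >= 0)
  if (thermostat == "berendsen" && (is.null(tau_t) || tau_t <= 0)) {
    stop("berendsen thermostat requires tau_t > 0")
  }
  structure(list(dt = dt, t_ref = t_ref, gamma = gamma, tau_t = tau_t,
                 thermostat = thermostat, seed = seed),
            class = "integrator_settings")
}

#' Maxwell-Boltzmann velocities
#'
#' @param masses Particle masses (u).
#' @param temperature Temperature (K).
#' @return n x 3 velocity matrix (nm/ps), drawn from the current RNG stream.
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  sd <- sqrt(kb_kjmol * temperature / masses)
  matrix(stats::rnorm(3 * n), n, 3) * sd
}

#' Instantaneous kinetic temperature
#'
#' T = 2 Ekin / (ndof kB) with ndof = 3 n by default (no constraints; the
#' centre of mass is not removed).
#'
#' @param velocities n x 3 matrix (nm/ps).
#' @param masses Masses (u).
#' @param ndof Degrees of freedom; default 3 n.
#' @return Temperature in K.
#' @export
instantaneous_temperature <- function(velocities, masses, ndof = NULL) {
  ekin <- 0.5 * sum(masses * rowSums(velocities^2))
  ndof <- ndof %||% (3 * length(masses))
  2 * ekin / (ndof * kb_kjmol)
}

#' Berendsen velocity-scaling factor applied to all velocities
#'
#' lambda = sqrt(1 + (dt/tau_t) (T_ref/T_inst - 1)); lambda -> 1 both when
#' T_inst = T_ref and in the decoupled limit tau_t -> Inf.
#'
#' @param velocities n x 3 matrix.
#' @param instantaneous_t Current kinetic temperature (K), > 0.
#' @param settings An [integrator_settings()].
#' @return Scaled velocity matrix.
#' @export
berendsen_scale <- function(velocities, instantaneous_t, settings) {
  if (is.null(settings$tau_t) || settings$tau_t <= 0) stop("tau_t must be > 0")
  if (instantaneous_t <= 0) stop("instantaneous temperature must be > 0")
  lambda <- sqrt(1 + (settings$dt / settings$tau_t) *
                   (settings$t_ref / instantaneous_t - 1))
  velocities * lambda
}

#' One stochastic-dynamics (BAOAB Langevin) step
#'
#' Splitting B(dt/2) A(dt/2) O(dt) A(dt/2) B(dt/2); with gamma = 0 and
#' thermostat "none" the O-step is the identity and the scheme reduces to
#' velocity-Verlet. The force function is called once per step (for the
#' final B half-kick); `state$forces` must be current for `state$pos` on
#' entry, as after the previous step.
#'
#' @param state List with `pos`, `vel`, `mass`, `forces` (all current).
#' @param force_fn Function `pos -> list(forces = ...)` (extra elements kept
#'   in `state$eval`).
#' @param settings An [integrator_settings()].
#' @return Updated state (positions, velocities, forces, eval).
#' @export
sd_step <- function(state, force_fn, settings) {
  dt <- settings$dt
  m <- state$mass
  v <- state$vel + 0.5 * dt * state$forces / m
  x <- state$pos + 0.5 * dt * v
  if (settings$thermostat == "sd" && settings$gamma > 0) {
    c1 <- exp(-settings$gamma * dt)
    sig <- sqrt((1 - c1^2) * kb_kjmol * settings$t_ref / m)
    v <- c1 * v + sig * matrix(stats::rnorm(length(m) * 3), length(m), 3)
  }
  x <- x + 0.5 * dt * v
  if (any(!is.finite(x))) stop("integration blow-up: non-finite coordinates")
  ev <- force_fn(x)
  v <- v + 0.5 * dt * ev$forces / m
  if (settings$thermostat == "berendsen") {
    ti <- instantaneous_temperature(v, m)
    if (ti > 0) v <- berendsen_scale(v, ti, settings)
  }
  state$pos <- x
  state$vel <- v
  state$forces <- ev$forces
  state$eval <- ev
  state
}

#' Propagate a system with a given force field
#'
#' Runs `n_steps` of [sd_step()], optionally calling `record_fn(step, state)`
#' every `save_every` steps. Deterministic for a fixed RNG state.
#'
#' @param pos,vel Starting coordinates and velocities (n x 3).
#' @param mass Masses (u).
#' @param force_fn Function `pos -> list(energy, forces, ...)`.
#' @param settings An [integrator_settings()].
#' @param n_steps Number of steps.
#' @param save_every Recording stride (0 = never).
#' @param record_fn Callback `(step, state)`.
#' @return Final state list (`pos`, `vel`, `forces`, `eval`, `n_steps`).
#' @export
propagate <- function(pos, vel, mass, force_fn, settings, n_steps,
                      save_every = 0, record_fn = NULL) {
  state <- list(pos = pos, vel = vel, mass = mass)
  ev <- force_fn(pos)
  state$forces <- ev$forces
  state$eval <- ev
  for (step in seq_len(n_steps)) {
    state <- tryCatch(sd_step(state, force_fn, settings),
                      error = function(e) {
                        stop(sprintf("step %d: %s", step, conditionMessage(e)))
                      })
    if (save_every > 0 && step %% save_every == 0 && !is.null(record_fn)) {
      record_fn(step, state)
    }
  }
  state$n_steps <- n_steps
  state
}
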