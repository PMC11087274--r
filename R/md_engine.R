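#' Molecular dynamics parameters
#'
#' @param dt time step (fs); the sampling protocols use 0.5 fs.
#' @param friction Langevin friction constant (1/fs); 0.01 in the
#'   case-study protocols. `friction = 0` gives plain velocity Verlet.
#' @param record_interval steps between recorded frames.
#' @param monitor_interval steps between uncertainty checks during
#'   nanoreactor runs (the workflow monitors every 5-50 steps; the default
#'   is the midpoint 25).
#' @return list of class `nr_md_params`.
#' @export
md_params <- function(dt = 0.5, friction = 0.01, record_interval = 100L,
                      monitor_interval = 25L) {
  if (dt <= 0) stop("dt must be > 0")
  if (friction < 0) stop("friction must be >= 0")
  if (record_interval < 1L || monitor_interval < 1L)
    stop("intervals must be >= 1")
  structure(list(dt = dt, friction = friction,
                 record_interval = as.integer(record_interval),
                 monitor_interval = as.integer(monitor_interval)),
            class = "nr_md_params")
}

#' MD state
#'
#' @param config an [configuration()].
#' @param velocities N x 3 matrix (A/fs); defaults to zeros.
#' @param time current simulation time (fs).
#' @return list of class `nr_md_state`.
#' @export
md_state <- function(config, velocities = NULL, time = 0) {
  N <- n_atoms(config)
  if (is.null(velocities)) velocities <- matrix(0, N, 3)
  velocities <- as.matrix(velocities)
  if (nrow(velocities) != N || ncol(velocities) != 3L)
    stop("velocities must be N x 3")
  structure(list(config = config, velocities = velocities, time = time),
            class = "nr_md_state")
}

#' Maxwell-Boltzmann velocities
#'
#' Each component is drawn with variance `k_B T / m_i` (internal units);
#' the center-of-mass velocity is removed by default.
#'
#' @param species element symbols.
#' @param T temperature (K), `>= 0`.
#' @param remove_com subtract the mass-weighted mean velocity.
#' @return N x 3 velocity matrix (A/fs).
#' @export
maxwell_boltzmann_velocities <- function(species, T, remove_com = TRUE) {
  if (T < 0) stop("T must be >= 0")
  N <- length(species)
  if (T == 0) return(matrix(0, N, 3))
  m <- atomic_masses(species)
  sd_v <- sqrt(NR_KB * T * NR_ACC / m)
  v <- matrix(stats::rnorm(3 * N), N, 3) * sd_v
  if (remove_com && N > 1L) {
    vcom <- colSums(v * m) / sum(m)
    v <- sweep(v, 2, vcom, "-")
  }
  v
}

#' Instantaneous kinetic temperature
#'
#' @param state an [md_state()].
#' @return temperature (K) from equipartition over 3N degrees of freedom.
#' @export
instantaneous_temperature <- function(state) {
  m <- atomic_masses(state$config$species)
  ke <- 0.5 * sum(m * rowSums(state$velocities^2)) / NR_ACC   # kcal/mol
  2 * ke / (3 * n_atoms(state$config) * NR_KB)
}

#' One BAOAB Langevin step
#'
#' Velocity-Verlet splitting with an Ornstein-Uhlenbeck kick in the middle
#' (B-A-O-A-B). With `friction = 0` and `T_target = 0` the step reduces
#' exactly to velocity Verlet.
#'
#' @param state an [md_state()].
#' @param calc an `nr_calculator`.
#' @param T_target thermostat target temperature (K).
#' @param params an [md_params()].
#' @param forces optional precomputed forces for the current configuration
#'   (avoids one evaluation when stepping in a loop).
#' @return list with the new `state`, the `energy` and `forces` at the new
#'   configuration.
#' @export
langevin_step <- function(state, calc, T_target, params = md_params(),
                          forces = NULL) {
  m <- atomic_masses(state$config$species)
  dt <- params$dt
  if (is.null(forces)) {
    res <- calc$evaluate(state$config)
    forces <- res$forces
  }
  check_finite_forces(forces)
  a <- forces * NR_ACC / m
  v <- state$velocities + 0.5 * dt * a
  x <- state$config$positions + 0.5 * dt * v
  if (params$friction > 0 || T_target > 0) {
    c1 <- exp(-params$friction * dt)
    c2 <- sqrt(pmax(0, (1 - c1^2)) * NR_KB * T_target * NR_ACC / m)
    if (c1 != 1 || any(c2 > 0)) {
      v <- c1 * v + matrix(stats::rnorm(length(v)), nrow(v), 3) * c2
    }
  }
  x <- x + 0.5 * dt * v
  cfg <- state$config
  cfg$positions <- x
  cfg <- wrap_config(cfg)
  res2 <- calc$evaluate(cfg)
  check_finite_forces(res2$forces)
  v <- v + 0.5 * dt * (res2$forces * NR_ACC / m)
  list(state = md_state(cfg, v, state$time + dt),
       energy = res2$energy, forces = res2$forces)
}

check_finite_forces <- function(forces) {
  if (!all(is.finite(forces))) {
    bad <- which(!apply(is.finite(forces), 1, all))[1]
    stop("non-finite force on atom ", bad)
  }
  invisible(TRUE)
}

#' Rescale a configuration to a target density
#'
#' Scales cell edges and positions by the same factor so that fractional
#' coordinates are preserved exactly; velocities are left unchanged (the
#' thermostat re-equilibrates kinetic energy).
#'
#' @param state an [md_state()] (or an [configuration()]).
#' @param target target density (g/cc), `> 0`.
#' @return the rescaled state (or configuration).
#' @export
rescale_to_density <- function(state, target) {
  if (!is.finite(target) || target <= 0) stop("target density must be > 0")
  cfg <- if (inherits(state, "nr_md_state")) state$config else state
  fac <- (mass_density(cfg) / target)^(1 / 3)
  cfg$cell$edge_lengths <- cfg$cell$edge_lengths * fac
  cfg$positions <- cfg$positions * fac
  if (inherits(state, "nr_md_state")) {
    state$config <- cfg
    state
  } else cfg
}

#' Temperature programs
#'
#' Builders for the thermostat target as a function of time (fs):
#' constant, a linear ramp between two times, and a piecewise-linear
#' program through `(time, temperature)` knots (e.g. relax, ramp, hold,
#' cool).
#'
#' @param T,T0,T1 temperatures (K).
#' @param t0,t1 ramp times (fs).
#' @param times,temps piecewise knots.
#' @return function `f(t) -> K`.
#' @export
temp_constant <- function(T) function(t) rep(T, length(t))

#' @rdname temp_constant
#' @export
temp_ramp <- function(T0, T1, t0, t1) {
  function(t) {
    f <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
    T0 + f * (T1 - T0)
  }
}

#' @rdname temp_constant
#' @export
temp_piecewise <- function(times, temps) {
  stopifnot(length(times) == length(temps), !is.unsorted(times))
  function(t) stats::approx(times, temps, xout = t, rule = 2)$y
}

#' Run molecular dynamics
#'
#' Langevin dynamics under a temperature program, with frames recorded
#' every `record_interval` steps (plus the initial frame), carrying
#' per-frame time, temperature, density and potential energy.
#'
#' @param state initial [md_state()].
#' @param calc an `nr_calculator`.
#' @param temperature_program function of time (fs) returning the target
#'   temperature (K); see [temp_constant()].
#' @param params an [md_params()].
#' @param duration total simulated time (fs), `> 0`.
#' @return list with `trajectory` (an [trajectory()]) and the final
#'   `state`. On a calculator failure the partial trajectory is attached
#'   to the rethrown error condition.
#' @export
run_md <- function(state, calc, temperature_program, params = md_params(),
                   duration) {
  if (duration <= 0) stop("duration must be > 0")
  n_steps <- round(duration / params$dt)
  frames <- list(state$config)
  times <- state$time
  scal <- data.frame(temperature = instantaneous_temperature(state),
                     density = mass_density(state$config),
                     energy = calc$evaluate(state$config)$energy)
  forces <- NULL
  for (k in seq_len(n_steps)) {
    Tt <- temperature_program(state$time)
    stepres <- tryCatch(
      langevin_step(state, calc, Tt, params, forces = forces),
      error = function(e) {
        e$partial_trajectory <- trajectory(frames, times, scal)
        stop(e)
      })
    state <- stepres$state
    forces <- stepres$forces
    if (k %% params$record_interval == 0L) {
      frames[[length(frames) + 1L]] <- state$config
      times <- c(times, state$time)
      scal <- rbind(scal, data.frame(
        temperature = instantaneous_temperature(state),
        density = mass_density(state$config),
        energy = stepres$energy))
    }
  }
  list(trajectory = trajectory(frames, times, scal), state = state)
}

#' Run a nanoreactor sampling simulation
#'
#' Drives Langevin dynamics while the thermostat target and the box
#' density follow the drawn oscillating schedules (the density is applied
#' by [rescale_to_density()] once per step before the force evaluation,
#' clamped below at 0.05 g/cc). Every `monitor_interval` steps the
#' query-by-committee uncertainty of the current configuration is
#' evaluated; at the first strict exceedance of the thresholds the
#' simulation ends and that configuration is returned for labeling.
#'
#' If the model drives the system into a numerically unstable region
#' before the monitor catches it (non-finite forces), the last finite
#' configuration is returned as flagged with `reason = "nonfinite"`.
#'
#' @param config initial [configuration()].
#' @param schedules list with `temperature` and `density`
#'   [schedule_params()] (from [draw_schedule()]).
#' @param ensemble an `nr_ensemble` (also provides the MD forces via the
#'   member mean).
#' @param thresholds an [selection_thresholds()].
#' @param params an [md_params()].
#' @param t_max maximum simulated time (fs); defaults to the schedules'
#'   `t_max`.
#' @param record record frames into a trajectory (default TRUE).
#' @return list with `flagged` (an `nr_config` or `NULL`), `flag_time`
#'   (fs or `NA`), `uncertainty` (at flag time), `reason`
#'   (`"threshold"`, `"nonfinite"` or `"completed"`), `elapsed` (fs run)
#'   and `trajectory`.
#' @export
run_nanoreactor <- function(config, schedules, ensemble,
                            thresholds = selection_thresholds(),
                            params = md_params(), t_max = NULL,
                            record = TRUE) {
  if (ensemble$n_members < 2L) stop("ensemble must have >= 2 members")
  if (is.null(t_max)) t_max <- schedules$temperature$t_max
  T0 <- oscillating_value(0, schedules$temperature)
  v0 <- maxwell_boltzmann_velocities(config$species, T0)
  state <- md_state(config, v0, time = 0)
  m <- atomic_masses(config$species)
  dt <- params$dt
  n_steps <- round(t_max / params$dt)
  frames <- list(); times <- numeric(0); scal <- NULL
  last_finite <- state
  flagged <- NULL; flag_time <- NA_real_; reason <- "completed"
  unc <- NULL
  pred <- NULL   # member-resolved prediction at the current configuration
  safe_predict <- function(cfg) {
    p <- tryCatch(ensemble_predict(ensemble, cfg),
                  error = function(e) e)
    if (inherits(p, "error") || !all(is.finite(p$mean_forces)) ||
        !all(is.finite(p$energies))) return(NULL)
    p
  }
  for (k in seq_len(n_steps)) {
    t_now <- state$time
    rho <- max(NR_MIN_DENSITY,
               oscillating_value(min(t_now, schedules$density$t_max),
                                 schedules$density))
    rescaled <- abs(rho - mass_density(state$config)) > 1e-12
    if (rescaled) {
      state <- rescale_to_density(state, rho)
      pred <- NULL
    }
    if (is.null(pred)) pred <- safe_predict(state$config)
    if (is.null(pred)) { reason <- "nonfinite"; break }
    Tt <- oscillating_value(min(t_now, schedules$temperature$t_max),
                            schedules$temperature)
    # BAOAB with the member-mean force
    a <- pred$mean_forces * NR_ACC / m
    v <- state$velocities + 0.5 * dt * a
    x <- state$config$positions + 0.5 * dt * v
    c1 <- exp(-params$friction * dt)
    c2 <- sqrt(pmax(0, 1 - c1^2) * NR_KB * Tt * NR_ACC / m)
    v <- c1 * v + matrix(stats::rnorm(length(v)), nrow(v), 3) * c2
    x <- x + 0.5 * dt * v
    if (!all(is.finite(x))) { reason <- "nonfinite"; break }
    cfg <- state$config
    cfg$positions <- x
    cfg <- wrap_config(cfg)
    pred <- safe_predict(cfg)
    if (is.null(pred)) { reason <- "nonfinite"; break }
    v <- v + 0.5 * dt * (pred$mean_forces * NR_ACC / m)
    state <- md_state(cfg, v, t_now + dt)
    last_finite <- state
    if (record && k %% params$record_interval == 0L) {
      frames[[length(frames) + 1L]] <- state$config
      times <- c(times, state$time)
      scal <- rbind(scal, data.frame(
        temperature = instantaneous_temperature(state),
        density = mass_density(state$config),
        energy = pred$mean_energy))
    }
    if (k %% params$monitor_interval == 0L) {
      unc <- qbc_uncertainty(ensemble, state$config, prediction = pred)
      if (exceeds_thresholds(unc, thresholds)) {
        flagged <- state$config
        flag_time <- state$time
        reason <- "threshold"
        break
      }
    }
  }
  if (reason == "nonfinite") {
    flagged <- last_finite$config
    flag_time <- last_finite$time
  }
  traj <- if (length(frames))
    trajectory(frames, times, scal) else NULL
  list(flagged = flagged, flag_time = flag_time, uncertainty = unc,
       reason = reason,
       elapsed = if (reason == "completed") n_steps * params$dt else
         max(flag_time, 0),
       trajectory = traj)
}
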