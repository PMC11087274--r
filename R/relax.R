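#' Relax a configuration on a calculator's surface
#'
#' FIRE (fast inertial relaxation engine) minimization: velocity-quenched
#' dynamics with adaptive time step, stopping when the maximum force
#' component drops below `fmax` or after `max_steps` evaluations. Used to
#' bring freshly packed boxes to the labeler's (or current model's)
#' equilibrium before dynamics, in the spirit of the minimum-energy
#' initialization used by the case-study protocols.
#'
#' @param config an [configuration()].
#' @param calc an `nr_calculator`.
#' @param fmax convergence threshold on the max force component
#'   (kcal/mol/A).
#' @param max_steps iteration cap.
#' @param dt0 initial FIRE time step (arbitrary mass-1 units).
#' @param max_disp per-step displacement cap (A).
#' @return the relaxed configuration (attributes `energy`, `fmax`,
#'   `steps`).
#' @export
relax_configuration <- function(config, calc, fmax = 10, max_steps = 400L,
                                dt0 = 0.02, max_disp = 0.15) {
  res <- calc$evaluate(config)
  f <- res$forces
  v <- matrix(0, nrow(f), 3)
  dt <- dt0; alpha <- 0.1; n_pos <- 0L
  dtmax <- 10 * dt0
  k <- 0L
  best <- config; best_e <- res$energy; best_fmax <- max(abs(f))
  while (k < max_steps && max(abs(f)) > fmax) {
    p <- sum(f * v)
    if (p > 0) {
      vn <- sqrt(sum(v^2)); fn <- sqrt(sum(f^2))
      if (fn > 0) v <- (1 - alpha) * v + alpha * vn * f / fn
      n_pos <- n_pos + 1L
      if (n_pos > 5L) {
        dt <- min(dt * 1.1, dtmax)
        alpha <- alpha * 0.99
      }
    } else {
      v[] <- 0; alpha <- 0.1; dt <- dt * 0.5; n_pos <- 0L
    }
    v <- v + dt * f
    dx <- dt * v
    mag <- sqrt(rowSums(dx^2))
    cap <- mag > max_disp
    if (any(cap)) dx[cap, ] <- dx[cap, ] * (max_disp / mag[cap])
    trial <- config
    trial$positions <- config$positions + dx
    trial <- wrap_config(trial)
    tres <- tryCatch(calc$evaluate(trial), error = function(err) NULL)
    if (is.null(tres) || !is.finite(tres$energy)) {
      v[] <- 0; dt <- dt * 0.5
      if (dt < 1e-6 * dt0) break
    } else {
      config <- trial
      res <- tres
      f <- res$forces
      if (res$energy < best_e) {
        best <- config; best_e <- res$energy; best_fmax <- max(abs(f))
      }
    }
    k <- k + 1L
  }
  if (max(abs(f)) <= best_fmax) {
    best <- config; best_e <- res$energy; best_fmax <- max(abs(f))
  }
  attr(best, "energy") <- best_e
  attr(best, "fmax") <- best_fmax
  attr(best, "steps") <- k
  best
}
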