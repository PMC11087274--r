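#' Oscillating schedule parameters
#'
#' Parameters of the oscillating ramp used for both temperature and density
#' in nanoreactor sampling:
#' \deqn{x(t) = x_{start} + (t / t_{max}) (x_{end} - x_{start}) +
#'   x_{amp} \sin^2(t / t_{per})}
#' with the sine argument in radians and `t` in fs.
#'
#' @param start,end endpoint values (K or g/cc); must be positive.
#' @param amp oscillation amplitude (same units), `>= 0`.
#' @param t_per period scale (fs), `> 0`.
#' @param t_max total schedule duration (fs), `> 0`.
#' @return list of class `nr_schedule`.
#' @export
schedule_params <- function(start, end, amp, t_per, t_max) {
  if (!all(is.finite(c(start, end, amp, t_per, t_max))))
    stop("schedule parameters must be finite")
  if (t_per <= 0 || t_max <= 0) stop("t_per and t_max must be > 0")
  if (amp < 0) stop("amp must be >= 0")
  if (start <= 0 || end <= 0) stop("start and end must be positive")
  structure(list(start = start, end = end, amp = amp,
                 t_per = t_per, t_max = t_max),
            class = "nr_schedule")
}

#' @export
print.nr_schedule <- function(x, ...) {
  cat(sprintf(
    "<nr_schedule> start %.4g end %.4g amp %.4g t_per %.4g fs t_max %.4g fs\n",
    x$start, x$end, x$amp, x$t_per, x$t_max))
  invisible(x)
}

#' Evaluate an oscillating schedule
#'
#' @param t time (fs), vectorized; each value must lie in `[0, t_max]`.
#' @param p an [schedule_params()] object.
#' @return schedule value(s) at `t`.
#' @export
oscillating_value <- function(t, p) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > p$t_max))
    stop("t must lie within [0, t_max = ", p$t_max, "]")
  p$start + (t / p$t_max) * (p$end - p$start) + p$amp * sin(t / p$t_per)^2
}

#' Random-schedule policy
#'
#' Per-parameter uniform ranges from which nanoreactor temperature and
#' density schedules are drawn. The defaults straddle the case-study
#' conditions (temperatures up to 3,000 K, condensed-phase densities).
#'
#' @param T_start,T_end,T_amp ranges (K), each `c(min, max)`.
#' @param rho_start,rho_end,rho_amp ranges (g/cc).
#' @param t_per range of the oscillation period scale (fs).
#' @param t_max total simulation duration (fs), a single value.
#' @return list of class `nr_schedule_policy`.
#' @export
schedule_policy <- function(T_start = c(300, 3000), T_end = c(300, 3000),
                            T_amp = c(0, 1000),
                            rho_start = c(0.3, 2.0), rho_end = c(0.3, 2.0),
                            rho_amp = c(0, 0.5),
                            t_per = c(50, 500), t_max = 10000) {
  rng_ok <- function(r) length(r) == 2 && is.finite(r[1]) && r[1] <= r[2]
  for (r in list(T_start, T_end, T_amp, rho_start, rho_end, rho_amp, t_per))
    if (!rng_ok(r)) stop("each policy range must be c(min, max) with min <= max")
  if (t_max <= 0) stop("t_max must be > 0")
  structure(list(T_start = T_start, T_end = T_end, T_amp = T_amp,
                 rho_start = rho_start, rho_end = rho_end, rho_amp = rho_amp,
                 t_per = t_per, t_max = t_max),
            class = "nr_schedule_policy")
}

#' Draw a random temperature/density schedule pair
#'
#' Each parameter is drawn uniformly within its policy range; the two
#' schedules share `t_max` (and each draws its own `t_per`).
#'
#' @param policy an [schedule_policy()].
#' @return list with elements `temperature` and `density`, both
#'   [schedule_params()].
#' @export
draw_schedule <- function(policy = schedule_policy()) {
  u <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  list(
    temperature = schedule_params(u(policy$T_start), u(policy$T_end),
                                  u(policy$T_amp), u(policy$t_per),
                                  policy$t_max),
    density = schedule_params(u(policy$rho_start), u(policy$rho_end),
                              u(policy$rho_amp), u(policy$t_per),
                              policy$t_max)
  )
}

# Density floor applied before any box rescaling: the sampler is not meant
# to visit near-vacuum densities.
NR_MIN_DENSITY <- 0.05

#' Serialize / deserialize schedules as plain key-value lists
#'
#' @param p an [schedule_params()] object.
#' @return `schedule_to_list` returns a plain named list;
#'   `schedule_from_list` the corresponding `nr_schedule`.
#' @export
schedule_to_list <- function(p) unclass(p)

#' @rdname schedule_to_list
#' @param x a named list with entries start, end, amp, t_per, t_max.
#' @export
schedule_from_list <- function(x) {
  schedule_params(x$start, x$end, x$amp, x$t_per, x$t_max)
}
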