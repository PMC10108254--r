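# Rotation-forestry carbon calculus on a fitted NEP(age) curve: cumulative
# NEP, optimum rotation age (mean-annual-increment culmination), carbon
# compensation point, and long-term sequestration rate.

#' Cumulative NEP trajectory
#'
#' Trapezoidal integral of an NEP(age) curve from `from` to `horizon`
#' (error O(step^2)). When the curve is only defined from some minimum age
#' (the log-quadratic trend requires age >= 1), `min_age` clamps the
#' evaluation age so NEP on `[from, min_age)` is treated as `NEP(min_age)`.
#'
#' @param nep Function of age returning NEP in g C m-2 yr-1.
#' @param horizon Integration end, years.
#' @param step Grid step, years (> 0).
#' @param from Integration start, years (default 0).
#' @param min_age Optional clamp for the evaluation age.
#' @return Data frame: `age`, `nep` (g C m-2 yr-1), `cumulative_gc_m2` and
#'   `cumulative_t_c_ha` (1 g C m-2 = 0.01 t C ha-1), starting at 0.
#' @export
#' @examples
#' tr <- cumulative_nep(function(a) a * (60 - a) / 100, horizon = 60)
#' tr$cumulative_t_c_ha[tr$age == 45]  # 3.0375
cumulative_nep <- function(nep, horizon, step = 0.1, from = 0,
                           min_age = NULL) {
  if (step <= 0) stop("step must be > 0")
  if (horizon < from + step) stop("horizon must be >= from + step")
  age <- seq(from, horizon, by = step)
  eval_age <- if (is.null(min_age)) age else pmax(age, min_age)
  v <- nep(eval_age)
  cum <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * step))
  data.frame(age = age, nep = v, cumulative_gc_m2 = cum,
             cumulative_t_c_ha = cum / 100)
}

#' Optimum rotation age (mean-annual-increment culmination)
#'
#' The optimum rotation age is where the current annual NEP crosses the
#' cumulative-mean annual NEP from above, i.e. the smallest
#' `a* > argmax NEP` with `NEP(a*) = C(a*)/a*`. By the culmination identity
#' this is also the argmax of the mean annual increment `C(a)/a`. The
#' crossing is located on a fine grid and refined by linear root bracketing
#' to 0.01 yr.
#'
#' @inheritParams cumulative_nep
#' @return List: `optimum_age` (years), `no_interior_optimum` (TRUE when the
#'   curves never cross before the horizon, in which case the horizon is
#'   returned).
#' @export
#' @examples
#' optimum_rotation(function(a) a * (60 - a) / 100, horizon = 60)$optimum_age  # 45
optimum_rotation <- function(nep, horizon, from = 0, min_age = NULL) {
  grid <- 0.01
  tr <- cumulative_nep(nep, horizon, step = grid, from = from, min_age = min_age)
  age <- tr$age
  pos <- age > max(from, 1e-9)
  mean_nep <- rep(NA_real_, length(age))
  mean_nep[pos] <- tr$cumulative_gc_m2[pos] / (age[pos] - from)
  f <- tr$nep - mean_nep
  i_max <- which.max(tr$nep)
  idx <- which(seq_along(age) > i_max & !is.na(f) & f < -1e-9)
  if (!length(idx)) {
    return(list(optimum_age = horizon, no_interior_optimum = TRUE))
  }
  i <- idx[1]
  # linear interpolation of f between the bracketing grid points
  a0 <- age[i - 1]; a1 <- age[i]
  f0 <- f[i - 1]; f1 <- f[i]
  a_star <- if (is.na(f0) || f0 <= 0) a1 else a0 + grid * f0 / (f0 - f1)
  list(optimum_age = a_star, no_interior_optimum = FALSE)
}

#' Carbon compensation point
#'
#' The stand age at which the cumulative NEP trajectory, negative during the
#' post-harvest years, first returns to zero (linear interpolation between
#' grid points). Zero if the trajectory never goes negative; the horizon,
#' with a flag, if it never recovers.
#'
#' @param trajectory Output of [cumulative_nep()].
#' @return List: `ccp` (years), `recovered` (FALSE when cumulative NEP stays
#'   negative to the horizon).
#' @export
#' @examples
#' tr <- cumulative_nep(function(a) a - 6, horizon = 20)
#' compensation_point(tr)$ccp  # 12
compensation_point <- function(trajectory) {
  cum <- trajectory$cumulative_gc_m2
  age <- trajectory$age
  eps <- 1e-12
  if (min(cum) >= -eps) return(list(ccp = 0, recovered = TRUE))
  neg <- which(cum < -eps)
  after <- which(seq_along(cum) > neg[1] & cum >= -eps)
  if (!length(after)) {
    return(list(ccp = age[length(age)], recovered = FALSE))
  }
  i <- after[1]
  a0 <- age[i - 1]; a1 <- age[i]
  c0 <- cum[i - 1]; c1 <- cum[i]
  ccp <- if (c1 == c0) a1 else a0 + (a1 - a0) * (-c0) / (c1 - c0)
  list(ccp = ccp, recovered = TRUE)
}

#' Long-term carbon sequestration rate and steady-state harvest rate
#'
#' Over repeated rotations of the optimum length, the landscape-average
#' carbon stock of an idealized sawtooth (linear accumulation to the
#' end-of-rotation cumulative NEP, then harvest) is half the end value;
#' `mode = "half"` therefore returns `cumulative_at_optimum / 2` per
#' rotation. `mode = "sawtooth"` instead time-averages the actual non-linear
#' trajectory over the rotation. The steady-state harvest rate is
#' `100 / optimum_age` % of stands per year.
#'
#' @param cumulative_at_optimum End-of-rotation cumulative NEP, t C ha-1.
#' @param optimum_age Rotation length, years (> 0).
#' @param mode `"half"` or `"sawtooth"`.
#' @param trajectory Required for `mode = "sawtooth"`: [cumulative_nep()]
#'   output covering the rotation.
#' @return List: `lcsr` (t C ha-1 per rotation), `harvest_rate` (% yr-1).
#' @export
#' @examples
#' long_term_rate(173, 138)$lcsr  # 86.5
long_term_rate <- function(cumulative_at_optimum, optimum_age,
                           mode = c("half", "sawtooth"), trajectory = NULL) {
  mode <- match.arg(mode)
  if (optimum_age <= 0) stop("optimum_age must be > 0")
  if (cumulative_at_optimum < 0) stop("cumulative_at_optimum must be >= 0")
  lcsr <- if (mode == "half") {
    cumulative_at_optimum / 2
  } else {
    if (is.null(trajectory)) stop("sawtooth mode needs the trajectory")
    sel <- trajectory$age <= optimum_age
    mean(trajectory$cumulative_t_c_ha[sel])
  }
  list(lcsr = lcsr, harvest_rate = 100 / optimum_age)
}

#' Full rotation-forestry summary for an NEP age curve
#'
#' Convenience wrapper running [cumulative_nep()], [optimum_rotation()],
#' [compensation_point()] and [long_term_rate()] on one NEP(age) function.
#'
#' @inheritParams cumulative_nep
#' @param lcsr_mode Passed to [long_term_rate()].
#' @return Object of class `rotation_summary`: `optimum_age`, `ccp`,
#'   `cumulative_at_optimum` (t C ha-1), `lcsr`, `harvest_rate`,
#'   `trajectory`, plus the flags of the underlying steps.
#' @export
rotation_summary <- function(nep, horizon = 220, step = 0.1, from = 0,
                             min_age = 1, lcsr_mode = c("half", "sawtooth")) {
  lcsr_mode <- match.arg(lcsr_mode)
  trajectory <- cumulative_nep(nep, horizon, step = step, from = from,
                               min_age = min_age)
  opt <- optimum_rotation(nep, horizon, from = from, min_age = min_age)
  ccp <- compensation_point(trajectory)
  cum_at_opt <- stats::approx(trajectory$age, trajectory$cumulative_t_c_ha,
                              xout = opt$optimum_age)$y
  rate <- long_term_rate(max(cum_at_opt, 0), opt$optimum_age,
                         mode = lcsr_mode, trajectory = trajectory)
  structure(list(
    optimum_age = opt$optimum_age,
    no_interior_optimum = opt$no_interior_optimum,
    ccp = ccp$ccp, ccp_recovered = ccp$recovered,
    cumulative_at_optimum = cum_at_opt,
    lcsr = rate$lcsr, harvest_rate = rate$harvest_rate,
    trajectory = trajectory
  ), class = "rotation_summary")
}

#' @export
print.rotation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Rotation summary:\n",
    "  optimum rotation age : %.1f yr%s\n",
    "  C compensation point : %.1f yr\n",
    "  cumulative NEP at opt: %.1f t C ha-1\n",
    "  LCSR                 : %.1f t C ha-1 per rotation\n",
    "  harvest rate         : %.2f %% yr-1\n"),
    x$optimum_age, if (x$no_interior_optimum) " (no interior optimum)" else "",
    x$ccp, x$cumulative_at_optimum, x$lcsr, x$harvest_rate))
  invisible(x)
}
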