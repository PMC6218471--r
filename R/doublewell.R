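#' One-dimensional double-well benchmark potentials
#'
#' Four quartic double-well variants used to benchmark the sampling schemes.
#' They differ in the basin width and/or depth of the two wells:
#' \describe{
#'   \item{`a`}{`V = x^4/4 - x^2/2`: symmetric — equal basins, equal depth.}
#'   \item{`b`}{variant `a` minus a linear tilt `0.2 x`: basin boundary stays
#'     near 0 (nearly equal basins) but the right well is deeper (more
#'     stable).}
#'   \item{`c`}{piecewise quartic `V0 ((x/w)^2 - 1)^2 - V0` with half-width
#'     `w = 0.5` left of the origin and `w = 1.5` right of it: minima at
#'     -0.5 and +1.5 of equal depth, but the right basin is three times
#'     wider. The two pieces join with continuous value and slope at the
#'     barrier `x = 0`.}
#'   \item{`d`}{variant `c` plus a linear tilt `+0.5 x`: the narrow left
#'     well becomes the deeper (more stable) one while the right basin
#'     remains the wider.}
#' }
#' These shapes realize the four qualitative basin-width/stability
#' combinations the scheme comparison requires; constants are package design
#' choices (the depth asymmetries of `b` and `d` are several times the "low"
#' benchmark noise level so the stability ordering is unambiguous).
#'
#' `double_well(variant)` returns the system object; its elements `V` and
#' `dV` are vectorized functions, `minima` the two well positions, `barrier`
#' the basin boundary, `depths` the two well depths relative to the barrier
#' top, and `box` the interval from which initial conditions are drawn
#' (`minima + c(-1, 1)`).
#'
#' @param variant one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return An object of class `double_well`.
#' @examples
#' dw <- double_well("c")
#' dw$minima    # -0.5, 1.5
#' dw$depths    # equal
#' @export
double_well <- function(variant = c("a", "b", "c", "d")) {
  variant <- match.arg(variant)
  tilt_b <- 0.2
  tilt_d <- 0.5
  V0 <- 1; wL <- 0.5; wR <- 1.5
  piece <- function(x) ifelse(x < 0, wL, wR)
  Vc <- function(x) V0 * ((x / piece(x))^2 - 1)^2 - V0
  dVc <- function(x) 4 * V0 * x * ((x / piece(x))^2 - 1) / piece(x)^2
  fns <- switch(variant,
    a = list(V = function(x) x^4 / 4 - x^2 / 2,
             dV = function(x) x^3 - x),
    b = list(V = function(x) x^4 / 4 - x^2 / 2 - tilt_b * x,
             dV = function(x) x^3 - x - tilt_b),
    c = list(V = Vc, dV = dVc),
    d = list(V = function(x) Vc(x) + tilt_d * x,
             dV = function(x) dVc(x) + tilt_d))
  guess <- switch(variant, a = c(-1, 1), b = c(-1, 1),
                  c = c(-0.5, 1.5), d = c(-0.5, 1.5))
  left <- stats::optimize(fns$V, c(guess[1] - 1, 0))$minimum
  right <- stats::optimize(fns$V, c(0, guess[2] + 1))$minimum
  barrier <- stats::optimize(fns$V, c(left, right), maximum = TRUE)$maximum
  minima <- c(left = left, right = right)
  depths <- fns$V(barrier) - fns$V(minima)   # positive well depths
  structure(list(variant = variant, V = fns$V, dV = fns$dV,
                 minima = minima, barrier = barrier, depths = depths,
                 box = c(left - 1, right + 1)),
            class = "double_well")
}

#' @export
print.double_well <- function(x, ...) {
  cat("<double_well> variant ", x$variant,
      ": minima at ", signif(x$minima[1], 3), " / ",
      signif(x$minima[2], 3),
      ", depths ", signif(x$depths[1], 3), " / ", signif(x$depths[2], 3),
      ", barrier at ", signif(x$barrier, 3), "\n", sep = "")
  invisible(x)
}

#' Benchmark noise levels for a double-well system
#'
#' Noise amplitudes chosen relative to the shallower well depth `d`: the
#' effective temperature of the Langevin dynamics is `D^2/2`, and the
#' presets set it to `d`, `d/3` and `d/25` (so `D = sqrt(2d)`,
#' `sqrt(2d/3)`, `sqrt(2d/25)`). At the high level barrier crossings are
#' frequent (all sampling schemes agree); at the low level crossings are
#' essentially absent on benchmark time scales (a single trajectory stays
#' trapped).
#'
#' @param system a [double_well()] object.
#' @return Named numeric vector `c(high, intermediate, low)`.
#' @export
dw_noise_levels <- function(system) {
  d <- min(system$depths)
  sqrt(2 * c(high = d, intermediate = d / 3, low = d / 25))
}

# Vectorized Euler-Maruyama for n particles on a 1-D potential.
# Returns the particle positions at the recorded steps as a
# (record x particle) matrix.
dw_integrate <- function(system, x0, D, dt, nsteps, rec_steps = nsteps) {
  x <- x0
  nrec <- length(rec_steps)
  out <- matrix(NA_real_, nrec, length(x0))
  amp <- D * sqrt(dt)
  j <- 1L
  for (s in seq_len(nsteps)) {
    x <- x - system$dV(x) * dt
    if (D > 0) x <- x + amp * stats::rnorm(length(x))
    if (j <= nrec && s == rec_steps[j]) {
      out[j, ] <- x
      j <- j + 1L
    }
  }
  out
}

#' Simulate a particle in a double-well potential
#'
#' Overdamped Langevin dynamics `dx = -V'(x) dt + D sqrt(dt) eta` on the
#' chosen potential variant (`D` the noise amplitude; effective temperature
#' `D^2/2`).
#'
#' @param variant potential variant (see [double_well()]), or a
#'   `double_well` object.
#' @param config a [sim_config()]; `dt` defaults are coarser than needed
#'   here, a step of 0.01 is used unless the config sets one explicitly.
#' @param x0 starting position; default: random uniform over the system box.
#' @return A `trajectory` object with a single column `x`.
#' @export
double_well_simulate <- function(variant, config = sim_config(dt = 0.01),
                                 x0 = NULL) {
  system <- if (inherits(variant, "double_well")) variant
            else double_well(variant)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(x0)) x0 <- stats::runif(1, system$box[1], system$box[2])
  nsteps <- round(config$T / config$dt)
  rec <- record_steps(config$record_times, config$dt, nsteps)
  traj <- dw_integrate(system, x0, config$D, config$dt, nsteps, rec)
  structure(list(times = rec * config$dt,
                 expression = matrix(traj[, 1], ncol = 1,
                                     dimnames = list(NULL, "x")),
                 circuit = paste0("double_well_", system$variant)),
            class = "trajectory")
}

#' Occupancy of the two wells
#'
#' Fraction of records left/right of the basin boundary of the potential.
#'
#' @param result an `ensemble_result` from a double-well run, or a numeric
#'   vector of positions.
#' @param system the [double_well()] object.
#' @return An `occupancy_profile` with states `left` and `right`.
#' @export
dw_occupancy <- function(result, system) {
  x <- if (inherits(result, "ensemble_result")) result$expression[, 1]
       else as.numeric(result)
  labels <- ifelse(x < system$barrier, "left", "right")
  occupancy_profile(factor(labels, levels = c("left", "right")),
                    scheme = if (inherits(result, "ensemble_result"))
                      result$scheme else NA_character_,
                    D = if (inherits(result, "ensemble_result"))
                      result$D[1] else NA_real_)
}
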