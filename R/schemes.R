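#' Annealing noise ladder
#'
#' An ordered sequence of noise levels, strictly decreasing from `D_max` to
#' exactly 0, each level held for a relaxation time `tau`. Used by
#' [run_sa()]: the ensemble starts at the top level from random initial
#' conditions, relaxes at each level, and carries its terminal states down
#' to the next level.
#'
#' Defaults (`D_max = 50`, 30 linear levels, `tau = 5` time units) span the
#' 0-50 noise range used in the circuit analyses with a total simulated time
#' per model (150) of the same order as thirty constant-noise runs.
#'
#' @param D_max top noise level (`> 0`).
#' @param n_levels number of levels (>= 2; the last level is exactly 0).
#' @param tau relaxation time per level (`> 0`).
#' @return An object of class `noise_ladder` with elements `levels` and
#'   `tau`.
#' @export
noise_ladder <- function(D_max = 50, n_levels = 30, tau = 5) {
  if (D_max <= 0) stop("D_max must be positive")
  if (n_levels < 2) stop("a ladder needs at least two levels")
  if (tau <= 0) stop("tau must be positive")
  levels <- seq(D_max, 0, length.out = n_levels)
  structure(list(levels = levels, tau = tau), class = "noise_ladder")
}

#' @export
print.noise_ladder <- function(x, ...) {
  cat("<noise_ladder> ", length(x$levels), " levels, D = ",
      signif(x$levels[1], 4), " .. 0, tau = ", x$tau, "\n", sep = "")
  invisible(x)
}

# Constructor for the common result container of all schemes: a matrix of
# terminal (or sampled) expression records plus per-record annotations.
ensemble_result <- function(expression, scheme, D, model_id, circuit_name,
                            time = NA_real_) {
  expression <- as.matrix(expression)
  structure(list(scheme = scheme,
                 circuit = circuit_name,
                 expression = expression,
                 D = rep_len(as.numeric(D), nrow(expression)),
                 model_id = rep_len(as.integer(model_id), nrow(expression)),
                 time = time),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  dr <- range(x$D)
  cat("<ensemble_result> scheme ", x$scheme, ", circuit ", x$circuit, ": ",
      nrow(x$expression), " records x ", ncol(x$expression), " genes, D ",
      if (dr[1] == dr[2]) paste0("= ", signif(dr[1], 4)) else
        paste0("in [", signif(dr[1], 4), ", ", signif(dr[2], 4), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ensemble_result <- function(x, ...) {
  data.frame(model_id = x$model_id, scheme = x$scheme, D = x$D,
             x$expression, check.names = FALSE)
}

#' Persist / load an ensemble result
#'
#' Tab-delimited table with columns `model_id`, `scheme`, `D` and one column
#' per gene.
#' @param result an `ensemble_result`.
#' @param path file path.
#' @return `read_ensemble_result()` returns an `ensemble_result`.
#' @export
write_ensemble_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_result
#' @export
read_ensemble_result <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  genes <- setdiff(names(tab), c("model_id", "scheme", "D"))
  ensemble_result(as.matrix(tab[genes]), scheme = tab$scheme[1],
                  D = tab$D, model_id = tab$model_id,
                  circuit_name = NA_character_)
}

#' Single-initial-condition (SIC) sampling
#'
#' One long stochastic trajectory at constant noise, recorded at equidistant
#' time points; the histogram of the records estimates the stationary
#' distribution — but at low noise the trajectory stays trapped in the basin
#' it started in, so SIC converges slowly (or not at all) for multistable
#' systems.
#'
#' @param system a [double_well()] object, or a `model_parameters` object
#'   (then `circuit` must be given).
#' @param D constant noise level.
#' @param T_total total simulated time.
#' @param record_interval spacing of the records.
#' @param seed integer seed.
#' @param dt integration step.
#' @param circuit required when `system` is a `model_parameters`.
#' @param burn_in time discarded before the first record (default
#'   `10 * record_interval`).
#' @return An `ensemble_result` with scheme `"SIC"` (all records share
#'   `model_id = 1`).
#' @export
run_sic <- function(system, D, T_total, record_interval, seed = 1,
                    dt = NULL, circuit = NULL, burn_in = NULL) {
  UseMethod("run_sic")
}

#' @export
run_sic.double_well <- function(system, D, T_total, record_interval,
                                seed = 1, dt = 0.01, circuit = NULL,
                                burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- 10 * record_interval
  set.seed(seed)
  x0 <- stats::runif(1, system$box[1], system$box[2])
  nsteps <- round((T_total + burn_in) / dt)
  rec <- seq(round((burn_in + record_interval) / dt), nsteps,
             by = round(record_interval / dt))
  pos <- dw_integrate(system, x0, D, dt, nsteps, as.integer(rec))
  ensemble_result(matrix(pos[, 1], ncol = 1,
                         dimnames = list(NULL, "x")),
                  scheme = "SIC", D = D, model_id = 1L,
                  circuit_name = paste0("double_well_", system$variant))
}

#' @export
run_sic.model_parameters <- function(system, D, T_total, record_interval,
                                     seed = 1, dt = 0.05, circuit = NULL,
                                     burn_in = NULL) {
  if (is.null(circuit)) stop("circuit must be supplied for a circuit model")
  if (is.null(burn_in)) burn_in <- 10 * record_interval
  times <- seq(burn_in + record_interval, burn_in + T_total,
               by = record_interval)
  cfg <- sim_config(dt = dt, T = burn_in + T_total, D = D,
                    record_times = times, seed = seed)
  tr <- simulate_model(system, circuit, cfg)
  ensemble_result(tr$expression, scheme = "SIC", D = D, model_id = 1L,
                  circuit_name = circuit$name)
}

#' Constant-noise multiple-initial-condition (MIC) sampling
#'
#' One short, independent simulation per model from a random initial
#' condition, recorded once at the end. At low noise each trajectory settles
#' into the basin its initial condition belongs to, so the record histogram
#' estimates the basins of attraction; at high noise it estimates the
#' stationary distribution.
#'
#' For circuit ensembles this follows the one-initial-condition-per-model
#' design: with many random models, models with similar parameters
#' collectively cover all states, and enlarging the ensemble converges the
#' expression distribution faster than adding initial conditions per model.
#'
#' @param system a [sample_ensemble()] object, or a [double_well()] (then
#'   `n` replicas of the particle are simulated).
#' @param D constant noise level (scalar, or per model).
#' @param T simulation time per model.
#' @param seed integer seed.
#' @param dt integration step.
#' @param n number of particles (double-well method only).
#' @param noise `"additive"` or `"multiplicative"` (circuit method only).
#' @return An `ensemble_result` with scheme `"MIC"`, one record per model.
#' @export
run_mic <- function(system, D, T = 50, seed = 1, dt = NULL, ...) {
  UseMethod("run_mic")
}

#' @rdname run_mic
#' @export
run_mic.parameter_ensemble <- function(system, D, T = 50, seed = 1,
                                       dt = 0.05, noise = "additive", ...) {
  set.seed(seed)
  x0 <- random_initial_conditions(system$circuit, n_models(system))
  term <- simulate_ensemble(system, x0 = x0, D = D, T = T, dt = dt,
                            noise = noise)
  ensemble_result(term, scheme = "MIC", D = D,
                  model_id = seq_len(n_models(system)),
                  circuit_name = system$circuit$name, time = T)
}

#' @rdname run_mic
#' @export
run_mic.double_well <- function(system, D, T = 50, seed = 1, dt = 0.01,
                                n = 1000, ...) {
  set.seed(seed)
  x0 <- stats::runif(n, system$box[1], system$box[2])
  nsteps <- round(T / dt)
  pos <- dw_integrate(system, x0, rep_len(D, 1), dt, nsteps)
  ensemble_result(matrix(pos[1, ], ncol = 1, dimnames = list(NULL, "x")),
                  scheme = "MIC", D = D, model_id = seq_len(n),
                  circuit_name = paste0("double_well_", system$variant),
                  time = T)
}

#' Simulated-annealing (SA) sampling
#'
#' Every model starts from a random initial condition at the top noise level
#' of the ladder and relaxes for `tau` time units; its terminal state seeds
#' the simulation at the next (lower) level, down to exactly zero noise.
#' Records are kept at every level, so the scheme yields stationary
#' distributions across the whole noise range; the final (zero-noise) level
#' concentrates the ensemble in the most stable states, because intermediate
#' noise permits escapes from shallow basins but not returns from deep ones.
#'
#' @param system a [sample_ensemble()] or [double_well()] object.
#' @param ladder a [noise_ladder()].
#' @param seed integer seed.
#' @param dt integration step.
#' @param n particle count (double-well method only).
#' @param noise `"additive"` or `"multiplicative"` (circuit method only).
#' @return A list of `ensemble_result` objects (scheme `"SA"`), one per
#'   ladder level, named by noise level.
#' @export
run_sa <- function(system, ladder, seed = 1, dt = NULL, ...) {
  UseMethod("run_sa")
}

#' @rdname run_sa
#' @export
run_sa.parameter_ensemble <- function(system, ladder = noise_ladder(),
                                      seed = 1, dt = 0.05,
                                      noise = "additive", ...) {
  stopifnot(inherits(ladder, "noise_ladder"))
  set.seed(seed)
  x <- random_initial_conditions(system$circuit, n_models(system))
  out <- vector("list", length(ladder$levels))
  for (l in seq_along(ladder$levels)) {
    x <- simulate_ensemble(system, x0 = x, D = ladder$levels[l],
                           T = ladder$tau, dt = dt, noise = noise)
    out[[l]] <- ensemble_result(x, scheme = "SA", D = ladder$levels[l],
                                model_id = seq_len(n_models(system)),
                                circuit_name = system$circuit$name,
                                time = ladder$tau * l)
  }
  names(out) <- format(ladder$levels)
  out
}

#' @rdname run_sa
#' @export
run_sa.double_well <- function(system, ladder = NULL, seed = 1, dt = 0.01,
                               n = 1000, ...) {
  if (is.null(ladder))
    # start at an effective temperature D^2/2 of twice the deeper well
    # depth, so the top level mixes freely across both basins
    ladder <- noise_ladder(D_max = 2 * sqrt(max(system$depths)),
                           n_levels = 25, tau = 20)
  set.seed(seed)
  x <- stats::runif(n, system$box[1], system$box[2])
  nsteps <- round(ladder$tau / dt)
  out <- vector("list", length(ladder$levels))
  for (l in seq_along(ladder$levels)) {
    x <- dw_integrate(system, x, ladder$levels[l], dt, nsteps)[1, ]
    out[[l]] <- ensemble_result(matrix(x, ncol = 1,
                                       dimnames = list(NULL, "x")),
                                scheme = "SA", D = ladder$levels[l],
                                model_id = seq_len(n),
                                circuit_name =
                                  paste0("double_well_", system$variant),
                                time = ladder$tau * l)
  }
  names(out) <- format(ladder$levels)
  out
}

#' MIC with a randomized noise level
#'
#' Treats the noise level as an additional random model parameter: each
#' model is assigned `D ~ Uniform(0, D_max)` and simulated once under MIC.
#' Binning the records by `D` afterwards ([global_bifurcation()]) turns the
#' run into a global bifurcation analysis with noise as the control
#' parameter.
#'
#' @param ensemble a [sample_ensemble()] object.
#' @param D_max upper end of the uniform noise range (default 50).
#' @param T,dt simulation time and step.
#' @param seed integer seed.
#' @return An `ensemble_result` (scheme `"MIC"`) whose `D` field holds each
#'   model's own noise level.
#' @export
run_noise_randomized_mic <- function(ensemble, D_max = 50, T = 50,
                                     dt = 0.05, seed = 1) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  if (D_max < 0) stop("D_max must be nonnegative")
  set.seed(seed)
  D <- stats::runif(n_models(ensemble), 0, D_max)
  x0 <- random_initial_conditions(ensemble$circuit, n_models(ensemble))
  term <- simulate_ensemble(ensemble, x0 = x0, D = D, T = T, dt = dt)
  ensemble_result(term, scheme = "MIC", D = D,
                  model_id = seq_len(n_models(ensemble)),
                  circuit_name = ensemble$circuit$name, time = T)
}
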