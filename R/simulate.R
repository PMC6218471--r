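#' Shifted Hill regulation function
#'
#' The regulatory multiplier applied to a target gene's production rate by a
#' regulator at level `X`:
#' \deqn{H^S(X) = \lambda + \frac{1-\lambda}{1 + (X/X_0)^n}.}
#' It equals 1 when the regulator is absent (`X = 0`), approaches the
#' fold-change `lambda` as `X` grows, and is exactly `(1 + lambda)/2` at the
#' threshold `X = X0`. `lambda > 1` encodes activation, `0 < lambda < 1`
#' inhibition, and `lambda = 1` an inert edge.
#'
#' @param X regulator expression level(s), `>= 0`.
#' @param X0 regulation threshold, `> 0`.
#' @param n Hill coefficient, `>= 1`.
#' @param lambda fold-change.
#' @return Dimensionless multiplier, same length as `X`.
#' @examples
#' shifted_hill(0, 10, 4, 9)    # 1: no regulator, baseline
#' shifted_hill(10, 10, 4, 9)   # (1 + 9) / 2 = 5
#' @export
shifted_hill <- function(X, X0, n, lambda) {
  if (any(X0 <= 0)) stop("threshold X0 must be positive")
  if (any(n < 1)) stop("Hill coefficient must be >= 1")
  lambda + (1 - lambda) / (1 + (X / X0)^n)
}

#' Rate equations of a circuit model
#'
#' The deterministic part of the dynamics: for each gene i,
#' \deqn{dx_i/dt = G_i \prod_j H^S(x_j; X_{0,ji}, n_{ji}, \lambda_{ji})
#'       - k_i x_i,}
#' with the product over all regulators j of gene i (empty product = 1, i.e.
#' an unregulated gene is a linear birth-death process with fixed point
#' `G/k`).
#'
#' @param x expression vector (one entry per gene, `>= 0`).
#' @param params a `model_parameters` object ([sample_model()]).
#' @param circuit the [circuit()] the parameters belong to.
#' @return Rate vector `dx/dt`, same length as `x`.
#' @export
derivative <- function(x, params, circuit) {
  prod <- rep(1, n_genes(circuit))
  src <- match(circuit$edges$source, circuit$genes)
  tgt <- match(circuit$edges$target, circuit$genes)
  for (e in seq_len(n_edges(circuit))) {
    h <- shifted_hill(x[src[e]], params$X0[e], params$N[e], params$LAMBDA[e])
    prod[tgt[e]] <- prod[tgt[e]] * h
  }
  unname(params$G) * prod - unname(params$K) * x
}

# Vectorized derivative over a state matrix (rows = instances), with
# parameter matrices indexed per instance through midx. Used by tests and
# convergence checks; mirrors the C++ core exactly.
derivative_matrix <- function(X, ensemble, circuit, midx = NULL) {
  n <- nrow(X)
  if (is.null(midx)) midx <- seq_len(n)
  src <- match(circuit$edges$source, circuit$genes)
  tgt <- match(circuit$edges$target, circuit$genes)
  prod <- matrix(1, n, n_genes(circuit))
  for (e in seq_len(n_edges(circuit))) {
    lam <- ensemble$LAMBDA[midx, e]
    h <- lam + (1 - lam) /
      (1 + (X[, src[e]] / ensemble$X0[midx, e])^ensemble$N[midx, e])
    prod[, tgt[e]] <- prod[, tgt[e]] * h
  }
  ensemble$G[midx, , drop = FALSE] * prod -
    ensemble$K[midx, , drop = FALSE] * X
}

#' One Euler-Maruyama step
#'
#' Advances the state by
#' `x' = max(0, x + f(x) dt + D sqrt(dt) eta)`, with `f` the deterministic
#' rate ([derivative()]) and `eta` i.i.d. standard normal per gene. `D` is
#' the noise amplitude (expression units per sqrt(time)); the corresponding
#' diffusion constant is `D^2/2`, so a single unregulated gene is an
#' Ornstein-Uhlenbeck process with stationary variance `D^2 / (2 k)`. With
#' `D = 0` no random numbers are drawn and the step is exactly forward
#' Euler. The `max(0, .)` clamp enforces nonnegative expression.
#'
#' @inheritParams derivative
#' @param dt time step (`> 0`).
#' @param D noise amplitude (`>= 0`).
#' @param noise `"additive"` (default) or `"multiplicative"`
#'   (expression-proportional term `D sqrt(dt) x eta`).
#' @return Updated expression vector.
#' @export
step_em <- function(x, params, circuit, dt, D,
                    noise = c("additive", "multiplicative")) {
  noise <- match.arg(noise)
  stopifnot(dt > 0, D >= 0)
  xn <- x + derivative(x, params, circuit) * dt
  if (D > 0) {
    eta <- stats::rnorm(length(x))
    amp <- D * sqrt(dt)
    xn <- xn + if (noise == "multiplicative") amp * x * eta else amp * eta
  }
  pmax(xn, 0)
}

#' Simulation configuration
#'
#' @param dt integration step, time units (default 0.05).
#' @param T total simulated time (default 50; degradation rates of at most 1
#'   per time unit mean relaxation times of 1-10 time units, so 50 leaves
#'   ample margin for convergence at zero noise).
#' @param D noise amplitude of the expression noise (see [step_em()]).
#' @param record_times times at which the state is recorded; `NULL` records
#'   the end point only (the MIC convention: one record per simulation).
#' @param seed optional seed applied before the run.
#' @param noise `"additive"` or `"multiplicative"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.05, T = 50, D = 0, record_times = NULL,
                       seed = NULL, noise = "additive") {
  if (dt <= 0) stop("dt must be positive")
  if (T < dt) stop("T must be at least one step")
  if (D < 0) stop("noise level D must be nonnegative")
  noise <- match.arg(noise, c("additive", "multiplicative"))
  structure(list(dt = dt, T = T, D = D, record_times = record_times,
                 seed = seed, noise = noise), class = "sim_config")
}

#' Simulate one circuit model
#'
#' Repeated [step_em()] from a given initial condition, recording the
#' expression vector at the requested times (default: end point only).
#'
#' @param params a `model_parameters` object.
#' @param circuit the matching [circuit()].
#' @param config a [sim_config()].
#' @param x0 initial expression vector; defaults to a random log-uniform
#'   draw (see [random_initial_conditions()]).
#' @return A `trajectory` object: list with `times` and the
#'   `expression` matrix (rows = recorded times, columns = genes).
#' @examples
#' ts <- fixture_circuit("TS")
#' m <- sample_model(ts, default_ranges(ts), seed = 7)
#' tr <- simulate_model(m, ts, sim_config(T = 50))
#' tr$expression
#' @export
simulate_model <- function(params, circuit, config = sim_config(),
                           x0 = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(x0))
    x0 <- as.vector(random_initial_conditions(circuit, n = 1,
                                              G_max = max(params$G),
                                              k_min = min(params$K)))
  stopifnot(length(x0) == n_genes(circuit), all(x0 >= 0))
  nsteps <- round(config$T / config$dt)
  rec <- record_steps(config$record_times, config$dt, nsteps)
  out <- matrix(NA_real_, length(rec), n_genes(circuit),
                dimnames = list(NULL, circuit$genes))
  x <- x0
  j <- 1L
  for (s in seq_len(nsteps)) {
    x <- step_em(x, params, circuit, config$dt, config$D, config$noise)
    if (j <= length(rec) && s == rec[j]) {
      out[j, ] <- x
      j <- j + 1L
    }
  }
  structure(list(times = rec * config$dt, expression = out,
                 circuit = circuit$name),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$expression), " records x ",
      ncol(x$expression), " genes (t = ",
      signif(min(x$times), 4), " .. ", signif(max(x$times), 4), ")\n",
      sep = "")
  invisible(x)
}

#' Export a trajectory as a tab-delimited time x gene table
#' @param trajectory a `trajectory` object.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- data.frame(time = trajectory$times, trajectory$expression,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Map requested record times onto integer step indices (end point if NULL).
record_steps <- function(record_times, dt, nsteps) {
  if (is.null(record_times)) return(nsteps)
  rec <- sort(unique(pmin(pmax(round(record_times / dt), 1L), nsteps)))
  as.integer(rec)
}

#' Random initial conditions
#'
#' Initial expression levels drawn log-uniformly between 1 and the maximum
#' unregulated level `max(G) / min(k)` so the draws cover the full dynamic
#' range attainable by the model's attractors.
#'
#' @param circuit a [circuit()] object.
#' @param n number of initial-condition vectors.
#' @param G_max,k_min bounds used for the upper level; default to the
#'   standard range extremes (100 and 0.1, i.e. an upper level of 1000).
#' @param seed optional seed.
#' @return `n` x genes matrix.
#' @export
random_initial_conditions <- function(circuit, n, G_max = 100, k_min = 0.1,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  upper <- log(G_max / k_min)
  m <- matrix(exp(stats::runif(n * n_genes(circuit), 0, upper)),
              nrow = n, dimnames = list(NULL, circuit$genes))
  m
}
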