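#' Integrate a whole model ensemble
#'
#' Euler-Maruyama integration of many circuit model instances at once (C++
#' core). Each instance is one initial condition attached to one parameter
#' set; several instances may share a parameter set through `midx` (used,
#' e.g., when enumerating the stable states of each model from many initial
#' conditions).
#'
#' @param ensemble a [sample_ensemble()] object.
#' @param x0 matrix of initial conditions (rows = instances, columns =
#'   genes); defaults to one random log-uniform initial condition per model.
#' @param D diffusion constant: scalar, or one value per instance.
#' @param T,dt total time and step size.
#' @param record_times times to record (default: end point only).
#' @param midx integer map from instance to model row (default: identity).
#' @param noise `"additive"` or `"multiplicative"`.
#' @param seed optional seed set before the integration.
#' @return If one record time: instances x genes matrix of expression.
#'   Otherwise a list of such matrices, named by record time.
#' @export
simulate_ensemble <- function(ensemble, x0 = NULL, D = 0, T = 50,
                              dt = 0.05, record_times = NULL, midx = NULL,
                              noise = "additive", seed = NULL) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  circuit <- ensemble$circuit
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0))
    x0 <- random_initial_conditions(circuit, n_models(ensemble))
  x0 <- as.matrix(x0)
  n_inst <- nrow(x0)
  if (is.null(midx)) {
    if (n_inst != n_models(ensemble))
      stop("x0 rows must match the number of models when midx is NULL")
    midx <- seq_len(n_inst)
  }
  stopifnot(length(midx) == n_inst, ncol(x0) == n_genes(circuit))
  D <- rep_len(as.numeric(D), n_inst)
  if (any(D < 0)) stop("noise level D must be nonnegative")
  nsteps <- as.integer(round(T / dt))
  rec <- record_steps(record_times, dt, nsteps)
  src <- match(circuit$edges$source, circuit$genes)
  tgt <- match(circuit$edges$target, circuit$genes)
  res <- sim_ensemble_cpp(x0, ensemble$G, ensemble$K, ensemble$X0,
                          ensemble$N, ensemble$LAMBDA,
                          as.integer(src), as.integer(tgt),
                          as.integer(midx), dt, nsteps, D,
                          as.integer(rec),
                          as.integer(noise == "multiplicative"))
  res <- lapply(res, function(m) {
    colnames(m) <- circuit$genes
    m
  })
  names(res) <- format(rec * dt)
  if (length(res) == 1L) res[[1]] else res
}
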