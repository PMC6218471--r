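#' Draw one random kinetic model
#'
#' Draws every kinetic parameter of the circuit uniformly from its range:
#' production and degradation rates per gene; Hill coefficient (uniform over
#' the integers of the scaled range), fold-change and threshold per edge.
#' Fold-changes are drawn from the `fold_change` range and inverted
#' (`1/lambda`) for inhibitory edges, so stored `lambda > 1` means
#' activation and `0 < lambda < 1` inhibition.
#'
#' Draw order is fixed (all `G`, all `k`, then per edge `n`, `lambda`,
#' `X0`), so a given seed always yields the same model.
#'
#' @param circuit a [circuit()] object.
#' @param ranges a [default_ranges()] object for this circuit.
#' @param seed optional integer seed; when given, `set.seed(seed)` is called
#'   first so the draw is reproducible in isolation.
#' @return An object of class `model_parameters`: named numeric vectors `G`,
#'   `K` (per gene) and `X0`, `N`, `LAMBDA` (per edge).
#' @export
sample_model <- function(circuit, ranges, seed = NULL) {
  stopifnot(inherits(circuit, "circuit"), inherits(ranges, "parameter_ranges"))
  if (!identical(ranges$genes, circuit$genes) ||
      !identical(ranges$edges, edge_ids(circuit)))
    stop("ranges were built for a different circuit")
  if (!is.null(seed)) set.seed(seed)
  ng <- n_genes(circuit); ne <- n_edges(circuit)
  runif_range <- function(m) m[, "min"] + stats::runif(nrow(m)) *
    (m[, "max"] - m[, "min"])
  G <- runif_range(ranges$production)
  K <- runif_range(ranges$degradation)
  N <- numeric(ne); LAMBDA <- numeric(ne); X0 <- numeric(ne)
  n_lo <- round(ranges$hill[, "min"]); n_hi <- round(ranges$hill[, "max"])
  for (e in seq_len(ne)) {
    N[e] <- if (n_hi[e] > n_lo[e])
      sample(seq.int(n_lo[e], n_hi[e]), 1L) else n_lo[e]
    lam <- ranges$fold_change[e, "min"] + stats::runif(1) *
      diff(ranges$fold_change[e, ])
    LAMBDA[e] <- if (circuit$edges$type[e] == 2L) 1 / lam else lam
    X0[e] <- ranges$threshold[e, "min"] + stats::runif(1) *
      diff(ranges$threshold[e, ])
  }
  names(G) <- names(K) <- circuit$genes
  names(N) <- names(LAMBDA) <- names(X0) <- edge_ids(circuit)
  structure(list(G = G, K = K, X0 = X0, N = N, LAMBDA = LAMBDA,
                 circuit = circuit$name),
            class = "model_parameters")
}

# Deterministic per-model seed stream: keeps every derived seed a valid
# 32-bit integer.
derive_model_seed <- function(seed, i)
  as.integer((as.double(seed) + 104729 * as.double(i)) %% 2147483647)

#' Draw an ensemble of random models
#'
#' Draws `n_models` independent random models (see [sample_model()]); model
#' `i` uses a seed derived deterministically from the master seed, so any
#' single row can be regenerated in isolation and the whole ensemble is
#' bitwise reproducible.
#'
#' @param circuit a [circuit()] object.
#' @param ranges a [default_ranges()] object; defaults to the standard
#'   ranges for this circuit.
#' @param n_models number of models (>= 1).
#' @param seed master integer seed.
#' @return An object of class `parameter_ensemble`: matrices `G`, `K`
#'   (`n_models` x genes) and `X0`, `N`, `LAMBDA` (`n_models` x edges), plus
#'   the `circuit` and `ranges` used.
#' @examples
#' ens <- sample_ensemble(fixture_circuit("TS"), n_models = 10, seed = 1)
#' dim(ens$G)
#' @export
sample_ensemble <- function(circuit, ranges = default_ranges(circuit),
                            n_models, seed = 1) {
  stopifnot(inherits(circuit, "circuit"))
  if (!is.numeric(n_models) || n_models < 1)
    stop("n_models must be >= 1")
  n_models <- as.integer(n_models)
  ng <- n_genes(circuit); ne <- n_edges(circuit)
  G <- K <- matrix(0, n_models, ng, dimnames = list(NULL, circuit$genes))
  X0 <- LAMBDA <- matrix(0, n_models, ne,
                         dimnames = list(NULL, edge_ids(circuit)))
  N <- matrix(0L, n_models, ne, dimnames = list(NULL, edge_ids(circuit)))
  for (i in seq_len(n_models)) {
    m <- sample_model(circuit, ranges, seed = derive_model_seed(seed, i))
    G[i, ] <- m$G; K[i, ] <- m$K
    X0[i, ] <- m$X0; N[i, ] <- as.integer(m$N); LAMBDA[i, ] <- m$LAMBDA
  }
  structure(list(circuit = circuit, ranges = ranges, seed = seed,
                 G = G, K = K, X0 = X0, N = N, LAMBDA = LAMBDA),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat("<parameter_ensemble> ", nrow(x$G), " models of circuit ",
      x$circuit$name, " (P = ", x$ranges$P, "%, seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Number of models in a parameter ensemble
#' @param ensemble a [sample_ensemble()] object.
#' @export
n_models <- function(ensemble) nrow(ensemble$G)

#' Extract one model from an ensemble
#' @param ensemble a [sample_ensemble()] object.
#' @param i model index.
#' @return A `model_parameters` object (as from [sample_model()]).
#' @export
ensemble_model <- function(ensemble, i) {
  structure(list(G = ensemble$G[i, ], K = ensemble$K[i, ],
                 X0 = ensemble$X0[i, ], N = ensemble$N[i, ],
                 LAMBDA = ensemble$LAMBDA[i, ],
                 circuit = ensemble$circuit$name),
            class = "model_parameters")
}

#' Subset a parameter ensemble by model index
#' @param ensemble a [sample_ensemble()] object.
#' @param idx integer vector of model indices to keep.
#' @export
subset_ensemble <- function(ensemble, idx) {
  for (f in c("G", "K", "X0", "N", "LAMBDA"))
    ensemble[[f]] <- ensemble[[f]][idx, , drop = FALSE]
  ensemble
}

#' Export / import a parameter ensemble as a flat table
#'
#' One row per model; columns `G_<gene>`, `k_<gene>`, `n_<src>_<tgt>`,
#' `lambda_<src>_<tgt>`, `X0_<src>_<tgt>`. The tab-delimited file written by
#' `write_parameters()` is read back by `read_parameters()` given the same
#' circuit, reproducing the ensemble exactly (up to numeric printing
#' precision; 17 significant digits are written, so the round trip is
#' lossless for doubles).
#'
#' @param ensemble a [sample_ensemble()] object.
#' @param path file path.
#' @param circuit the [circuit()] the parameters belong to.
#' @return `as_parameter_table()` returns a data frame;
#'   `read_parameters()` a `parameter_ensemble`.
#' @export
as_parameter_table <- function(ensemble) {
  eid <- colnames(ensemble$X0)
  out <- cbind(ensemble$G, ensemble$K, ensemble$N, ensemble$LAMBDA,
               ensemble$X0)
  colnames(out) <- c(paste0("G_", colnames(ensemble$G)),
                     paste0("k_", colnames(ensemble$K)),
                     paste0("n_", eid), paste0("lambda_", eid),
                     paste0("X0_", eid))
  as.data.frame(out)
}

#' @rdname as_parameter_table
#' @export
write_parameters <- function(ensemble, path) {
  tab <- as_parameter_table(ensemble)
  tab[] <- lapply(tab, function(col) format(col, digits = 17,
                                            scientific = TRUE, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname as_parameter_table
#' @export
read_parameters <- function(path, circuit) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  eid <- edge_ids(circuit)
  pick <- function(prefix, ids) {
    cols <- paste0(prefix, ids)
    if (!all(cols %in% names(tab)))
      stop("parameter table is missing columns: ",
           paste(setdiff(cols, names(tab)), collapse = ", "))
    m <- as.matrix(tab[cols]); colnames(m) <- ids; m
  }
  structure(list(circuit = circuit, ranges = NULL, seed = NA_integer_,
                 G = pick("G_", circuit$genes),
                 K = pick("k_", circuit$genes),
                 X0 = pick("X0_", eid),
                 N = matrix(as.integer(pick("n_", eid)), nrow = nrow(tab),
                            dimnames = list(NULL, eid)),
                 LAMBDA = pick("lambda_", eid)),
            class = "parameter_ensemble")
}
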