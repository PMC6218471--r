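#' Kinetic parameter ranges for an ensemble
#'
#' Holds, for a given circuit, the sampling range of every kinetic parameter:
#' per-gene production rate `G` (molecules/time) and degradation rate `k`
#' (1/time), and per-edge Hill coefficient `n` (dimensionless integer),
#' fold-change `lambda` (dimensionless) and regulation threshold `X0`
#' (expression units). Models are drawn uniformly from these ranges by
#' [sample_model()] / [sample_ensemble()].
#'
#' Thresholds follow the half-functional rule: for an edge j -> i the
#' threshold range is `c(0.02, 1.98) * M_j`, where `M_j` is the median
#' unregulated expression `G_j / k_j` of the source gene under its own
#' ranges. The symmetric 0.02/1.98 bracket keeps the range midpoint at
#' `M_j`, so a regulator is on average near its half-effect point. `M_j` is
#' computed on a deterministic quantile-midpoint grid (no random draws).
#'
#' @param circuit a [circuit()] object.
#' @param production,degradation,hill,fold_change length-2 `c(min, max)`
#'   default ranges applied to every gene/edge. The defaults are the
#'   conventional ensemble-modeling ranges: production 1-100, degradation
#'   0.1-1, integer Hill coefficients 1-6, fold-change 1-100 (inverted to
#'   `1/lambda` when the edge is inhibitory).
#' @param P parametric-variation index in percent; see [scale_ranges()].
#'   The stored ranges are the defaults rescaled to this `P`.
#'
#' @return An object of class `parameter_ranges`: per-gene matrices
#'   `production`, `degradation` (rows = genes, columns `min`, `max`),
#'   per-edge matrices `hill`, `fold_change`, `threshold` (rows = edges),
#'   and the scalar `P`.
#' @examples
#' rng <- default_ranges(fixture_circuit("TS"))
#' rng
#' @export
default_ranges <- function(circuit,
                           production = c(1, 100),
                           degradation = c(0.1, 1),
                           hill = c(1, 6),
                           fold_change = c(1, 100),
                           P = 100) {
  stopifnot(inherits(circuit, "circuit"))
  check_range <- function(r, nm, lo_ok = 0) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] <= lo_ok)
      stop("invalid ", nm, " range")
  }
  check_range(production, "production")
  check_range(degradation, "degradation")
  check_range(fold_change, "fold_change")
  if (length(hill) != 2L || hill[1] < 1 || hill[1] > hill[2])
    stop("invalid hill range (minimum Hill coefficient is 1)")

  ng <- n_genes(circuit); ne <- n_edges(circuit)
  per <- function(r, n, ids) {
    m <- matrix(rep(as.numeric(r), each = n), nrow = n,
                dimnames = list(ids, c("min", "max")))
    m
  }
  med <- unregulated_median(production, degradation)
  thr <- per(c(0.02, 1.98) * med, ne, edge_ids(circuit))
  # thresholds depend on the source gene's ranges; with per-gene defaults all
  # genes share the same median, but keep the mapping explicit.
  ranges <- structure(list(
    circuit = circuit$name,
    genes = circuit$genes,
    edges = edge_ids(circuit),
    production = per(production, ng, circuit$genes),
    degradation = per(degradation, ng, circuit$genes),
    hill = per(hill, ne, edge_ids(circuit)),
    fold_change = per(fold_change, ne, edge_ids(circuit)),
    threshold = thr,
    P = 100), class = "parameter_ranges")
  if (P != 100) ranges <- scale_ranges(ranges, P)
  ranges
}

#' @export
print.parameter_ranges <- function(x, ...) {
  fmt <- function(m) paste0("[", signif(m[1, "min"], 4), ", ",
                            signif(m[1, "max"], 4), "]")
  cat("<parameter_ranges> circuit ", x$circuit, " (P = ", x$P, "%)\n",
      "  production  ", fmt(x$production),
      "   degradation ", fmt(x$degradation), "\n",
      "  hill        ", fmt(x$hill),
      "   fold-change ", fmt(x$fold_change), "\n",
      "  threshold   ", fmt(x$threshold), "\n", sep = "")
  invisible(x)
}

# Median of the unregulated steady-state level G/k for G ~ U(g_range),
# k ~ U(k_range), evaluated on a deterministic quantile-midpoint grid.
unregulated_median <- function(g_range, k_range, n_grid = 100) {
  q <- (seq_len(n_grid) - 0.5) / n_grid
  g <- g_range[1] + q * diff(g_range)
  k <- k_range[1] + q * diff(k_range)
  stats::median(outer(g, 1 / k))
}

# The range transform: (x_min, x_max) -> midpoint -/+ half-width * P/100,
# evaluated as the algebraically identical convex combination
#   y_min = x_min (1+p)/2 + x_max (1-p)/2,   p = P/100,
# which is bit-exact at the endpoints: P = 100 returns the inputs
# unchanged and P = 0 returns the midpoint. Works on a 2-column min/max
# matrix; midpoints are conserved to machine precision for every P.
rescale_minmax <- function(m, P) {
  p <- P / 100
  a <- (1 + p) / 2
  b <- (1 - p) / 2
  out <- cbind(min = a * m[, "min"] + b * m[, "max"],
               max = b * m[, "min"] + a * m[, "max"])
  rownames(out) <- rownames(m)
  out
}

#' Parameter ranges enriched for quadrastability
#'
#' A documented range configuration for the double-self-activating toggle
#' switch under which a useful fraction (roughly 2-3%) of random models is
#' quadrastable with the four low/high states LL, LH, HL, HH. Relative to
#' [default_ranges()]: self-activation edges get fold-change in `[20, 100]`,
#' Hill coefficients in `{4, 5, 6}` and thresholds in `[M, 2M]` (above the
#' basal level `M = median(G/k)`, so the un-activated branch of each gene
#' exists); mutual-inhibition edges get a moderate fold-change in
#' `[1.5, 6]` so that the doubly-active high-high state survives the
#' cross-inhibition. Under the plain defaults, exactly-4-state models do
#' occur but are nested-hysteresis variants rather than the LL/LH/HL/HH
#' set.
#'
#' @param circuit a two-gene [circuit()] with self-activation on both genes
#'   (typically `fixture_circuit("TS_SA2")`).
#' @return A `parameter_ranges` object.
#' @seealso [find_quadrastable()], [induction_experiment()]
#' @export
quadrastable_ranges <- function(circuit) {
  stopifnot(inherits(circuit, "circuit"))
  r <- default_ranges(circuit)
  self <- which(circuit$edges$source == circuit$edges$target)
  if (length(self) == 0L)
    stop("circuit has no self-activation edges")
  M <- unregulated_median(c(1, 100), c(0.1, 1))
  inh <- setdiff(seq_len(n_edges(circuit)), self)
  r$fold_change[self, ] <- rep(c(20, 100), each = length(self))
  r$hill[self, ] <- rep(c(4, 6), each = length(self))
  r$threshold[self, ] <- rep(c(1, 2) * M, each = length(self))
  r$fold_change[inh, ] <- rep(c(1.5, 6), each = length(inh))
  r
}

#' Rescale parameter ranges by the parametric-variation index
#'
#' The parametric-variation index `P` (in percent) controls the spread of
#' every parameter range about its midpoint while keeping the midpoint
#' fixed: a range `(x_min, x_max)` becomes
#' \deqn{y_{min} = \frac{x_{max}+x_{min}}{2} -
#'       \frac{x_{max}-x_{min}}{2}\frac{P}{100}, \quad
#'       y_{max} = \frac{x_{max}+x_{min}}{2} +
#'       \frac{x_{max}-x_{min}}{2}\frac{P}{100}.}
#' `P = 100` leaves every range unchanged; `P = 0` collapses each range to
#' its midpoint (all models become identical).
#'
#' The transform always acts on the ranges passed in, so it is a pure
#' function of `(ranges, P)`; `ranges$P` records the index used.
#'
#' @param ranges a [default_ranges()] object.
#' @param P parametric variation in percent, in `[0, 100]`.
#' @return A `parameter_ranges` object with every range rescaled.
#' @examples
#' r <- default_ranges(fixture_circuit("TS"))
#' scale_ranges(r, 50)$production[1, ]   # (25.75, 75.25) from (1, 100)
#' @export
scale_ranges <- function(ranges, P) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  if (!is.numeric(P) || length(P) != 1L || is.na(P) || P < 0 || P > 100)
    stop("P must be a single value in [0, 100]")
  for (f in c("production", "degradation", "hill", "fold_change",
              "threshold"))
    ranges[[f]] <- rescale_minmax(ranges[[f]], P)
  ranges$P <- P
  ranges
}
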