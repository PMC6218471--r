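#' Per-state occupancy of an ensemble
#'
#' Counts and fractions of records per state label.
#'
#' @param labels factor (or coercible) of per-record state labels.
#' @param scheme,D optional annotations.
#' @return An object of class `occupancy_profile` with `states`, `counts`,
#'   `fractions` (summing to 1), `n`, `scheme`, `D`.
#' @export
occupancy_profile <- function(labels, scheme = NA_character_,
                              D = NA_real_) {
  labels <- as.factor(labels)
  counts <- table(labels)
  structure(list(states = names(counts),
                 counts = as.integer(counts),
                 fractions = as.numeric(counts) / sum(counts),
                 n = sum(counts), scheme = scheme, D = D),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("<occupancy_profile> ", x$n, " records",
      if (!is.na(x$scheme)) paste0(" (", x$scheme, ")"), ":\n", sep = "")
  for (i in seq_along(x$states))
    cat(sprintf("  %-10s %6d  %.3f\n", x$states[i], x$counts[i],
                x$fractions[i]))
  invisible(x)
}

#' Normalize ensemble expression
#'
#' Applies `log2(x + pseudo_count)` and z-scores each gene against a
#' reference mean/sd. The reference defaults to the matrix being
#' normalized; passing a stored `transform` re-applies a previous
#' normalization, so expression slices taken at different noise levels stay
#' on a common scale and are directly comparable.
#'
#' A pseudo-count rather than a hard floor keeps the transform continuous
#' at zero: stochastic runs clamp negative noise excursions at zero
#' expression, and a floored log would tear that boundary mass away from
#' the adjacent low-expression records. The default pseudo-count, 0.5, is
#' half the minimum attainable unregulated level under the standard
#' parameter ranges (`G_min / k_max = 1`).
#'
#' @param x an `ensemble_result` or an expression matrix.
#' @param transform a transform returned by a previous call (element
#'   `$transform`), or `NULL` to fit one.
#' @param pseudo_count positive offset added before the log.
#' @return A list of class `normalized_expression`: `matrix` (normalized
#'   values) and `transform` (`pseudo_count`, per-gene `mean`, `sd`).
#' @export
normalize_expression <- function(x, transform = NULL, pseudo_count = 0.5) {
  m <- if (inherits(x, "ensemble_result")) x$expression else as.matrix(x)
  if (is.null(transform)) {
    lx <- log2(m + pseudo_count)
    mu <- colMeans(lx)
    sd <- apply(lx, 2, stats::sd)
    if (any(bad <- !is.finite(sd) | sd == 0)) {
      warning("zero-variance gene(s): ",
              paste(colnames(m)[bad], collapse = ", "),
              "; unit-variance fallback applied")
      sd[bad] <- 1
    }
    transform <- list(pseudo_count = pseudo_count, mean = mu, sd = sd)
  }
  lx <- log2(m + transform$pseudo_count)
  z <- sweep(sweep(lx, 2, transform$mean), 2, transform$sd, "/")
  structure(list(matrix = z, transform = transform),
            class = "normalized_expression")
}

#' Count the distinct expression states of an ensemble
#'
#' A state is a well-separated cluster of the record distribution. The
#' counter proceeds in three steps, all via \pkg{mclust}: (i) fit Gaussian
#' mixtures with 1 to `k_max` components and select one by BIC; (ii)
#' combine mixture components hierarchically by the entropy criterion of
#' Baudry et al. (2010) ([mclust::clustCombi()]), which merges components
#' that jointly model one non-Gaussian cluster — BIC alone legitimately
#' spends several Gaussians on a single heavy-tailed state; (iii) drop
#' combined clusters holding less than `min_fraction` of the records
#' (boundary atoms created by the nonnegativity clamp, and other sampling
#' artifacts below the resolution at which ensemble states are read).
#' Records of dropped clusters are reassigned to the nearest surviving
#' cluster. Degenerate inputs (all records identical) short-cut to a
#' single state.
#'
#' @param x a `normalized_expression`, or a numeric matrix of records.
#' @param k_max largest number of mixture components considered (default
#'   5).
#' @param min_records minimum records required (default 50; mixture fits on
#'   fewer records are not trustworthy).
#' @param min_fraction smallest record fraction a cluster must hold to
#'   count as a state (default 0.1).
#' @param seed seed for the (deterministic) mixture initialization.
#' @param scheme,D annotations forwarded to the occupancy profile.
#' @return A list of class `state_count`: `k` (number of states), `labels`
#'   (per-record state assignment), `occupancy` ([occupancy_profile()]),
#'   `means` (state centroids, states x genes), `fit_G` (BIC-selected
#'   component count) and `bic` (BIC trace).
#' @references Baudry, J.-P., Raftery, A. E., Celeux, G., Lo, K. and
#'   Gottardo, R. (2010) Combining mixture components for clustering.
#'   Journal of Computational and Graphical Statistics 19, 332-353.
#' @export
count_states <- function(x, k_max = 5, min_records = 50,
                         min_fraction = 0.1, seed = 1,
                         scheme = NA_character_, D = NA_real_) {
  m <- if (inherits(x, "normalized_expression")) x$matrix else as.matrix(x)
  if (nrow(m) < min_records)
    stop("too few records (", nrow(m), " < ", min_records,
         ") for state counting")
  spread <- apply(m, 2, function(col) diff(range(col)))
  if (all(spread < 1e-10)) {
    labels <- rep(1L, nrow(m))
    return(structure(list(k = 1L, labels = labels,
                          occupancy = occupancy_profile(labels, scheme, D),
                          means = m[1, , drop = FALSE], fit_G = 1L,
                          bic = NULL),
                     class = "state_count"))
  }
  set.seed(seed)
  fit <- mclust::Mclust(m, G = seq_len(k_max), verbose = FALSE)
  if (fit$G == 1L) {
    labels <- rep(1L, nrow(m))
    cl_k <- 1L
  } else {
    cc <- mclust::clustCombi(object = fit, data = m)
    cl_k <- mclust::clustCombiOptim(cc)$numClusters.combi
    labels <- cc$classification[[cl_k]]
  }
  frac <- tabulate(labels, cl_k) / length(labels)
  keep <- which(frac >= min_fraction)
  if (!length(keep)) keep <- which.max(frac)
  centroid <- function(rows) colMeans(m[rows, , drop = FALSE])
  means_all <- t(vapply(seq_len(cl_k),
                        function(j) centroid(which(labels == j)),
                        numeric(ncol(m))))
  relabel <- integer(cl_k)
  for (j in seq_len(cl_k)) {
    if (j %in% keep) relabel[j] <- match(j, keep)
    else {
      d2 <- rowSums((means_all[keep, , drop = FALSE] -
                     matrix(means_all[j, ], length(keep), ncol(m),
                            byrow = TRUE))^2)
      relabel[j] <- which.min(d2)
    }
  }
  labels <- relabel[labels]
  means <- means_all[keep, , drop = FALSE]
  colnames(means) <- colnames(m)
  structure(list(k = length(keep), labels = labels,
                 occupancy = occupancy_profile(labels, scheme, D),
                 means = means, fit_G = fit$G, bic = fit$BIC),
            class = "state_count")
}

#' @export
print.state_count <- function(x, ...) {
  cat("<state_count> ", x$k, " state(s), ", x$occupancy$n, " records\n",
      sep = "")
  invisible(x)
}

#' Global bifurcation analysis over a randomized control parameter
#'
#' Bins the records of a noise-randomized (or otherwise annotated) run by
#' the control value, then counts the expression states in every bin. With
#' the noise level as the control this provides a bifurcation-diagram-like
#' view in which all other parameters vary randomly as well; any randomized
#' parameter can serve as the axis by passing its per-record values as
#' `control`.
#'
#' Normalization is fitted once on the pooled records, so bins share a
#' common scale.
#'
#' @param result an `ensemble_result` (e.g. from
#'   [run_noise_randomized_mic()]).
#' @param n_bins number of equal-width control bins.
#' @param control per-record control values (default: the noise levels
#'   stored in `result`).
#' @param control_range range to bin over (default: range of `control`).
#' @param k_max,min_records passed to [count_states()]; bins with fewer
#'   than `min_records` records are flagged (`k = NA`), not dropped.
#' @param seed seed for the state counting.
#' @return A data frame of class `bifurcation_profile`: one row per bin
#'   with `bin`, `lower`, `upper`, `n`, `k` and the per-gene mean
#'   normalized expression. The per-bin state counts and labels are
#'   attached as attribute `"detail"`.
#' @export
global_bifurcation <- function(result, n_bins = 50, control = NULL,
                               control_range = NULL, k_max = 5,
                               min_records = 50, seed = 1) {
  stopifnot(inherits(result, "ensemble_result"))
  if (is.null(control)) control <- result$D
  if (is.null(control_range)) control_range <- range(control)
  breaks <- seq(control_range[1], control_range[2], length.out = n_bins + 1)
  bin <- cut(control, breaks, include.lowest = TRUE, labels = FALSE)
  norm <- normalize_expression(result)
  rows <- vector("list", n_bins)
  detail <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    sel <- which(bin == b)
    k <- NA_integer_
    if (length(sel) >= min_records) {
      sc <- count_states(norm$matrix[sel, , drop = FALSE], k_max = k_max,
                         min_records = min_records, seed = seed)
      k <- sc$k
      detail[[b]] <- sc
    }
    mu <- if (length(sel)) colMeans(norm$matrix[sel, , drop = FALSE])
          else stats::setNames(rep(NA_real_, ncol(norm$matrix)),
                               colnames(norm$matrix))
    rows[[b]] <- data.frame(bin = b, lower = breaks[b],
                            upper = breaks[b + 1], n = length(sel),
                            k = k, t(mu), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  attr(out, "transform") <- norm$transform
  class(out) <- c("bifurcation_profile", class(out))
  out
}

#' Bhattacharyya distance between two histograms
#'
#' `BD(p, q) = -ln sum_i sqrt(p_i q_i)` over a shared binning. Zero iff the
#' histograms coincide; symmetric; infinite for disjoint supports, capped
#' at `cap` (default 20, far beyond any value reachable with the sample
#' sizes used here).
#'
#' @param p,q nonnegative histogram vectors on the same binning, each
#'   summing to 1 (within 1e-6).
#' @param cap ceiling returned for (near-)disjoint supports.
#' @return The distance (dimensionless scalar).
#' @examples
#' bhattacharyya_distance(c(.5, .5), c(.9, .1))   # 0.1116
#' @export
bhattacharyya_distance <- function(p, q, cap = 20) {
  if (length(p) != length(q))
    stop("histograms are on different binnings (",
         length(p), " vs ", length(q), " bins)")
  if (any(p < 0) || any(q < 0)) stop("histogram masses must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("histograms must each sum to 1")
  bc <- sum(sqrt(p * q))
  if (bc <= exp(-cap)) return(cap)
  min(-log(bc), cap)
}

# Shared-binning histogram of a vector: counts normalized to sum 1.
hist_fractions <- function(x, breaks) {
  h <- graphics::hist(pmin(pmax(x, breaks[1]), breaks[length(breaks)]),
                      breaks = breaks, plot = FALSE)
  h$counts / sum(h$counts)
}

#' Bhattacharyya distance between two expression ensembles
#'
#' Per-gene histograms of log2 expression on `n_bins` uniform bins spanning
#' the pooled range of both ensembles, with the per-gene distances averaged
#' over genes. Averaging per gene keeps the value comparable across
#' circuits of different size (a joint multi-dimensional binning would be
#' dominated by dimensionality).
#'
#' @param x,y expression matrices (or `ensemble_result`s) with identical
#'   gene columns.
#' @param n_bins histogram bins per gene (default 100).
#' @param pseudo_count offset applied before the log2 transform.
#' @param log2_transform set `FALSE` to bin raw values (used for the 1-D
#'   double-well positions).
#' @return Mean per-gene Bhattacharyya distance.
#' @export
bd_expression <- function(x, y, n_bins = 100, pseudo_count = 0.5,
                          log2_transform = TRUE) {
  mx <- if (inherits(x, "ensemble_result")) x$expression else as.matrix(x)
  my <- if (inherits(y, "ensemble_result")) y$expression else as.matrix(y)
  if (ncol(mx) != ncol(my)) stop("ensembles have different gene sets")
  if (log2_transform) {
    mx <- log2(mx + pseudo_count)
    my <- log2(my + pseudo_count)
  }
  bd <- numeric(ncol(mx))
  for (g in seq_len(ncol(mx))) {
    r <- range(mx[, g], my[, g])
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    breaks <- seq(r[1], r[2], length.out = n_bins + 1)
    bd[g] <- bhattacharyya_distance(hist_fractions(mx[, g], breaks),
                                    hist_fractions(my[, g], breaks))
  }
  mean(bd)
}

#' Convergence of the ensemble distribution over simulation time
#'
#' Runs a MIC ensemble at noise `D`, recording expression at `record_times`,
#' and computes the Bhattacharyya distance between each time point's
#' distribution and a zero-noise end-of-run reference distribution.
#' Saturation of BD(t) signals that the ensemble distribution has relaxed;
#' for `D = 0` the curve decays toward zero, and its crossing time under a
#' small threshold measures the circuit's response time.
#'
#' @param circuit a [circuit()] object.
#' @param ranges parameter ranges (default: [default_ranges()]).
#' @param n_models ensemble size.
#' @param D noise level of the probed run.
#' @param record_times times at which BD is evaluated (default 1..50).
#' @param T reference time (end of run, default 50).
#' @param dt integration step.
#' @param seed integer seed (models, initial conditions and noise).
#' @param reference optional precomputed reference expression matrix (the
#'   `D = 0` terminal distribution); computed from the same model ensemble
#'   when `NULL`.
#' @param n_bins histogram bins for [bd_expression()].
#' @return A data frame of class `response_curve` with columns `time` and
#'   `BD`.
#' @export
response_curve <- function(circuit, ranges = default_ranges(circuit),
                           n_models = 2000, D = 0,
                           record_times = seq_len(50), T = 50, dt = 0.05,
                           seed = 1, reference = NULL, n_bins = 100) {
  ens <- sample_ensemble(circuit, ranges, n_models, seed = seed)
  set.seed(seed + 1)
  x0 <- random_initial_conditions(circuit, n_models)
  if (is.null(reference)) {
    reference <- if (D == 0) NULL else
      simulate_ensemble(ens, x0 = x0, D = 0, T = T, dt = dt)
  }
  set.seed(seed + 2)
  snaps <- simulate_ensemble(ens, x0 = x0, D = D, T = T, dt = dt,
                             record_times = record_times)
  if (length(record_times) == 1L) snaps <- list(snaps)
  if (is.null(reference)) reference <- snaps[[length(snaps)]]
  bd <- vapply(snaps, bd_expression, numeric(1), y = reference,
               n_bins = n_bins)
  out <- data.frame(time = record_times, BD = unname(bd))
  class(out) <- c("response_curve", class(out))
  out
}

#' Earliest time after which a response curve stays below a threshold
#'
#' @param curve a [response_curve()] data frame.
#' @param threshold BD threshold (default 0.01).
#' @return The smallest recorded time `t*` with `BD(t) < threshold` for all
#'   `t >= t*` (`Inf` when the curve never settles below the threshold).
#' @export
response_time <- function(curve, threshold = 0.01) {
  below <- curve$BD < threshold
  stays <- rev(cumprod(rev(below))) == 1
  if (!any(stays)) return(Inf)
  curve$time[which(stays)[1]]
}

#' Noise robustness of a circuit
#'
#' Simulates matched MIC ensembles (same models, same initial conditions)
#' over a grid of noise levels and computes the Bhattacharyya distance of
#' each terminal expression distribution from the zero-noise one. The
#' noise-robustness index is reported two ways: `RD` is the BD at
#' `D = 1.0` (the primary, operational index — the larger the BD, the lower
#' the robustness) and `slope` is the fitted rate of increase of BD with
#' `D` in the low-noise limit (least squares through the origin over the
#' grid points with `D <= 1`).
#'
#' @param circuit a [circuit()] object.
#' @param ranges parameter ranges.
#' @param n_models ensemble size.
#' @param D_grid noise levels; must contain 0 and 1.
#' @param T,dt simulation time and step.
#' @param seed integer seed.
#' @param n_bins histogram bins for [bd_expression()].
#' @return An object of class `robustness_report`: `circuit`, data frame
#'   `curve` (`D`, `BD`), `RD`, `slope`.
#' @export
noise_robustness <- function(circuit, ranges = default_ranges(circuit),
                             n_models = 2000,
                             D_grid = c(0, 0.1, 0.25, 0.5, 1, 2, 5, 10,
                                        20, 50),
                             T = 50, dt = 0.05, seed = 1, n_bins = 100) {
  if (!all(c(0, 1) %in% D_grid))
    stop("D_grid must contain both 0 and 1")
  D_grid <- sort(D_grid)
  ens <- sample_ensemble(circuit, ranges, n_models, seed = seed)
  set.seed(seed + 1)
  x0 <- random_initial_conditions(circuit, n_models)
  term <- vector("list", length(D_grid))
  for (i in seq_along(D_grid)) {
    set.seed(seed + 2)  # matched noise stream across levels
    term[[i]] <- simulate_ensemble(ens, x0 = x0, D = D_grid[i], T = T,
                                   dt = dt)
  }
  ref <- term[[which(D_grid == 0)]]
  bd <- vapply(term, bd_expression, numeric(1), y = ref, n_bins = n_bins)
  curve <- data.frame(D = D_grid, BD = unname(bd))
  low <- curve[curve$D <= 1 & curve$D > 0, ]
  slope <- sum(low$BD * low$D) / sum(low$D^2)
  structure(list(circuit = circuit$name, curve = curve,
                 RD = curve$BD[curve$D == 1], slope = slope,
                 n_models = n_models, seed = seed),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report> circuit ", x$circuit, " (", x$n_models,
      " models)\n  BD at D = 1: ", signif(x$RD, 4),
      "   low-noise slope: ", signif(x$slope, 4), "\n", sep = "")
  invisible(x)
}

#' PCA embedding of normalized expression
#'
#' Standard principal components analysis (centered, unscaled) with a fixed
#' sign convention — in each component the largest-magnitude loading is
#' made positive — so embeddings are bit-reproducible.
#'
#' @param x a `normalized_expression` or numeric matrix (>= 2 genes).
#' @param n_components components to return (default 2).
#' @return A list of class `pca_embedding`: `scores` (records x
#'   components), `loadings`, `var_explained`.
#' @export
pca_embed <- function(x, n_components = 2) {
  m <- if (inherits(x, "normalized_expression")) x$matrix else as.matrix(x)
  if (ncol(m) < 2) stop("PCA embedding needs at least 2 genes")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  for (j in seq_len(k)) {
    flip <- sign(p$rotation[which.max(abs(p$rotation[, j])), j])
    if (flip < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 var_explained = p$sdev^2 / sum(p$sdev^2)),
            class = "pca_embedding")
}

#' Average-linkage hierarchical clustering of expression records
#'
#' Euclidean distance, average linkage; a thin wrapper kept for a uniform
#' analysis surface.
#'
#' @param x a `normalized_expression` or numeric matrix.
#' @param k optional number of clusters to cut the tree into.
#' @return A list of class `hclust_result`: `tree` (the [stats::hclust()]
#'   object) and `labels` (cluster memberships, `NULL` unless `k` given).
#' @export
hierarchical_cluster <- function(x, k = NULL) {
  m <- if (inherits(x, "normalized_expression")) x$matrix else as.matrix(x)
  tree <- stats::hclust(stats::dist(m), method = "average")
  labels <- if (!is.null(k)) stats::cutree(tree, k = k)
  structure(list(tree = tree, labels = labels), class = "hclust_result")
}
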