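#' Enumerate the stable states of every model in an ensemble
#'
#' Deterministic (zero-noise) simulation of `n_ic` random initial conditions
#' per model, followed by clustering of the terminal points into distinct
#' fixed points: two terminals belong to the same state when every gene
#' agrees within relative tolerance `tol` (denominators floored at
#' `floor_level` so indistinguishable near-zero levels merge). Instances
#' whose terminal derivative is still large (relative residual above
#' `conv_tol`) are treated as non-converged and dropped from the state
#' count.
#'
#' This enumeration is the one place the one-initial-condition-per-model
#' convention is deliberately broken: identifying coexisting stable states
#' of a single model requires covering its basins.
#'
#' Trajectories passing near a saddle (or a saddle-node ghost) can still be
#' crawling at the end of the run; the residual filter removes clearly
#' unconverged instances, and a polish phase then relaxes each candidate
#' state for `polish_T` more time units and re-clusters, which merges
#' same-basin stragglers that the tolerance would otherwise split into
#' spurious extra states.
#'
#' @param ensemble a [sample_ensemble()] object.
#' @param n_ic initial conditions per model (default 100).
#' @param T,dt integration time and step (default `T = 150`; the slowest
#'   linear relaxation time scale is `1/k_min = 10`).
#' @param tol relative clustering tolerance (default 1e-2).
#' @param floor_level expression floor for the relative comparison.
#' @param conv_tol relative residual above which a terminal is discarded.
#' @param polish_T extra relaxation per polish round (two rounds).
#' @param seed integer seed (initial conditions).
#' @return An object of class `state_enumeration`: `n_states` (per model),
#'   `states` (list of per-model matrices, one row per distinct state),
#'   `occupancy` (list of per-state basin counts out of the converged
#'   instances), `converged` (fraction of converged instances per model).
#' @export
enumerate_states <- function(ensemble, n_ic = 100, T = 150, dt = 0.05,
                             tol = 1e-2, floor_level = 1,
                             conv_tol = 1e-4, polish_T = 100, seed = 1) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  nm <- n_models(ensemble)
  circuit <- ensemble$circuit
  set.seed(seed)
  midx <- rep(seq_len(nm), each = n_ic)
  x0 <- random_initial_conditions(circuit, nm * n_ic)
  term <- simulate_ensemble(ensemble, x0 = x0, D = 0, T = T, dt = dt,
                            midx = midx)
  rate <- derivative_matrix(term, ensemble, circuit, midx)
  resid <- sqrt(rowSums(rate^2)) / pmax(sqrt(rowSums(term^2)), floor_level)
  ok <- resid < conv_tol

  okm <- midx[ok]
  assign <- cluster_fixed_points_cpp(term[ok, , drop = FALSE],
                                     as.integer(okm), tol, floor_level)
  # cluster representatives (means), per model
  key <- paste(okm, assign)
  reps <- rowsum(term[ok, , drop = FALSE], key, reorder = FALSE) /
    as.vector(table(factor(key, levels = unique(key))))
  rep_model <- as.integer(sub(" .*", "", unique(key)))
  ord <- order(rep_model)
  reps <- reps[ord, , drop = FALSE]
  rep_model <- rep_model[ord]
  # polish: relax the representatives further and re-cluster; repeat once
  for (round in 1:2) {
    reps <- simulate_ensemble(ensemble, x0 = reps, D = 0, T = polish_T,
                              dt = dt, midx = rep_model)
    merged <- cluster_fixed_points_cpp(reps, as.integer(rep_model), tol,
                                       floor_level)
    key2 <- paste(rep_model, merged)
    keep <- !duplicated(key2)
    # remap record assignments through the merge
    old_key <- paste(rep_model, ave(seq_along(rep_model), rep_model,
                                    FUN = seq_along))
    remap <- stats::setNames(merged, old_key)
    assign <- as.integer(remap[paste(okm, assign)])
    reps <- reps[keep, , drop = FALSE]
    rep_model <- rep_model[keep]
  }
  n_states <- integer(nm)
  states <- occupancy <- vector("list", nm)
  converged <- numeric(nm)
  for (m in seq_len(nm)) {
    rows <- which(okm == m)
    converged[m] <- length(rows) / n_ic
    if (!length(rows)) next
    a <- assign[rows]
    n_states[m] <- max(a)
    sm <- reps[rep_model == m, , drop = FALSE]
    colnames(sm) <- circuit$genes
    states[[m]] <- sm
    occupancy[[m]] <- tabulate(a, max(a))
  }
  structure(list(n_states = n_states, states = states,
                 occupancy = occupancy, converged = converged,
                 circuit = circuit$name, n_ic = n_ic, tol = tol),
            class = "state_enumeration")
}

#' @export
print.state_enumeration <- function(x, ...) {
  tab <- table(x$n_states)
  cat("<state_enumeration> circuit ", x$circuit, ", ",
      length(x$n_states), " models, ", x$n_ic, " initial conditions each\n",
      "  states per model: ",
      paste(names(tab), "states:", as.integer(tab), collapse = " | "),
      "\n", sep = "")
  invisible(x)
}

# Label the states of a two-gene model low/high per gene, using the
# midpoint of the log2 range of that model's fixed-point levels as the
# per-gene threshold. Returns labels like "LL", "LH", "HL", "HH"
# (first letter = gene 1).
label_states_2g <- function(state_matrix, thresholds = NULL,
                            floor_level = 0.01) {
  lx <- log2(pmax(state_matrix, floor_level))
  if (is.null(thresholds))
    thresholds <- (apply(lx, 2, min) + apply(lx, 2, max)) / 2
  hi <- t(t(lx) > thresholds)
  labels <- paste0(ifelse(hi[, 1], "H", "L"), ifelse(hi[, 2], "H", "L"))
  list(labels = labels, thresholds = thresholds)
}

#' Select the quadrastable models of a two-gene ensemble
#'
#' Keeps the models with exactly four coexisting stable states and labels
#' each state low/high per gene (`"LL"`, `"LH"`, `"HL"`, `"HH"`); only
#' models whose four states carry all four distinct labels are retained.
#' The per-gene low/high threshold is the midpoint of the log2 range of the
#' model's own fixed-point levels.
#'
#' @param ensemble a two-gene [sample_ensemble()] (typically of the
#'   `TS_SA2` circuit).
#' @param enumeration optionally a precomputed [enumerate_states()] result
#'   for `ensemble`; computed if missing.
#' @param ... passed to [enumerate_states()].
#' @return An object of class `quadrastable_set`: the subset `ensemble`,
#'   `model_idx` (indices into the original ensemble), `state_coords` (list
#'   of 4 x 2 matrices with rows named LL/LH/HL/HH) and `thresholds` (per
#'   model, log2 scale).
#' @export
find_quadrastable <- function(ensemble, enumeration = NULL, ...) {
  if (n_genes(ensemble$circuit) != 2L)
    stop("quadrastable selection is defined for two-gene circuits")
  if (is.null(enumeration)) enumeration <- enumerate_states(ensemble, ...)
  idx <- which(enumeration$n_states == 4L)
  keep <- integer(0)
  coords <- list()
  thresholds <- list()
  for (m in idx) {
    lab <- label_states_2g(enumeration$states[[m]])
    if (length(unique(lab$labels)) == 4L) {
      sm <- enumeration$states[[m]]
      rownames(sm) <- lab$labels
      sm <- sm[c("LL", "LH", "HL", "HH"), , drop = FALSE]
      keep <- c(keep, m)
      coords[[length(coords) + 1L]] <- sm
      thresholds[[length(thresholds) + 1L]] <- lab$thresholds
    }
  }
  structure(list(ensemble = subset_ensemble(ensemble, keep),
                 model_idx = keep, state_coords = coords,
                 thresholds = thresholds,
                 circuit = ensemble$circuit),
            class = "quadrastable_set")
}

#' @export
print.quadrastable_set <- function(x, ...) {
  cat("<quadrastable_set> ", length(x$model_idx),
      " quadrastable models of circuit ", x$circuit$name, "\n", sep = "")
  invisible(x)
}

# Label terminal expression rows of quadrastable models with their per-model
# thresholds.
label_terminals <- function(qset, term, floor_level = 0.01) {
  lx <- log2(pmax(term, floor_level))
  thr <- do.call(rbind, qset$thresholds)
  hi <- lx > thr
  paste0(ifelse(hi[, 1], "H", "L"), ifelse(hi[, 2], "H", "L"))
}

#' Self-activation induction experiment on quadrastable models
#'
#' Models experimental drug induction of the self-activation links of a
#' double-self-activating toggle switch: at each stage the strength of each
#' self-activation edge is scaled by an induction factor (IF) — the
#' fold-change is multiplied by IF and the activation threshold divided by
#' IF, so induction both amplifies the engaged loop and lets it engage at
#' lower expression. Every model is then simulated from its current state
#' and the resulting states are labeled LL/LH/HL/HH. Stages are applied
#' sequentially, each starting from the previous stage's terminal states,
#' so ramped induction and induction removal (IF back to 1) exhibit the
#' hysteresis of the underlying multistable landscape. `IF = 1` is exactly
#' the identity.
#'
#' @param qset a [find_quadrastable()] object for a circuit with
#'   self-activation edges on both genes.
#' @param schedule data frame with one row per stage and one column per
#'   self-activation edge (named after the gene, e.g. `A`, `B`), holding
#'   the induction factor applied to that edge's fold-change at that stage.
#' @param initial_state one of `"LL"`, `"LH"`, `"HL"`, `"HH"`: the labeled
#'   fixed point every model starts from.
#' @param config a [sim_config()]; the default zero-noise configuration
#'   reproduces the low-noise regime in which the experimental circuit
#'   operates (state changes are then driven purely by induction-induced
#'   bifurcations, and `IF = 1` is exactly the identity).
#' @return An object of class `induction_result`: per stage the
#'   `ensemble_result`, the state labels and the label fractions.
#' @export
induction_experiment <- function(qset, schedule, initial_state = "LL",
                                 config = sim_config()) {
  stopifnot(inherits(qset, "quadrastable_set"))
  initial_state <- match.arg(initial_state, c("LL", "LH", "HL", "HH"))
  circuit <- qset$circuit
  self_edges <- which(circuit$edges$source == circuit$edges$target)
  if (!length(self_edges)) stop("circuit has no self-activation edges")
  names(self_edges) <- circuit$edges$source[self_edges]
  schedule <- as.data.frame(schedule)
  if (!all(names(schedule) %in% names(self_edges)))
    stop("schedule columns must name self-activating genes: ",
         paste(names(self_edges), collapse = ", "))
  nm <- length(qset$model_idx)
  if (nm == 0L) stop("no quadrastable models in the set")
  if (!is.null(config$seed)) set.seed(config$seed)

  x <- t(vapply(qset$state_coords, function(s) s[initial_state, ],
                numeric(2)))
  colnames(x) <- circuit$genes
  stages <- vector("list", nrow(schedule))
  for (st in seq_len(nrow(schedule))) {
    ens <- qset$ensemble
    for (g in names(schedule)) {
      e <- self_edges[[g]]
      IF <- schedule[st, g]
      ens$LAMBDA[, e] <- ens$LAMBDA[, e] * IF
      ens$X0[, e] <- ens$X0[, e] / IF
    }
    x <- simulate_ensemble(ens, x0 = x, D = config$D, T = config$T,
                           dt = config$dt, noise = config$noise)
    labels <- label_terminals(qset, x)
    res <- ensemble_result(x, scheme = "MIC", D = config$D,
                           model_id = seq_len(nm),
                           circuit_name = circuit$name, time = config$T)
    stages[[st]] <- list(
      result = res, labels = labels,
      fractions = prop.table(table(factor(labels,
                                          c("LL", "LH", "HL", "HH")))))
  }
  structure(list(stages = stages, schedule = schedule,
                 initial_state = initial_state),
            class = "induction_result")
}

#' @export
print.induction_result <- function(x, ...) {
  cat("<induction_result> from ", x$initial_state, ", ",
      nrow(x$schedule), " stages\n", sep = "")
  for (st in seq_along(x$stages)) {
    f <- x$stages[[st]]$fractions
    cat("  stage ", st, " (",
        paste(names(x$schedule), "=", unlist(x$schedule[st, ]),
              collapse = ", "),
        "): ", paste(names(f), sprintf("%.2f", f), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}
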