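#' Gene regulatory circuit topology
#'
#' A circuit is a small directed, signed graph: a set of genes connected by
#' transcriptional interactions that either activate or inhibit their target.
#' The topology is the sole required input of the whole pipeline; every
#' kinetic parameter is randomized downstream.
#'
#' Gene order is fixed at construction and defines the column order of every
#' expression matrix produced by the simulators, so results are reproducible
#' across runs and file round trips.
#'
#' @param genes character vector of unique gene identifiers.
#' @param edges data frame with columns `source`, `target` (gene identifiers)
#'   and `type` (integer, `1` = activation, `2` = inhibition). Self-loops
#'   (auto-regulation) are allowed; duplicate `(source, target)` pairs are
#'   not.
#' @param name a label for the circuit.
#'
#' @return An object of class `circuit`: a list with elements `name`,
#'   `genes` and `edges`.
#' @examples
#' ts <- circuit(c("A", "B"),
#'               data.frame(source = c("A", "B"), target = c("B", "A"),
#'                          type = c(2L, 2L)),
#'               name = "toggle_switch")
#' ts
#' @export
circuit <- function(genes, edges, name = "circuit") {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("circuit must contain at least one gene")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source", "target", "type")
  if (!all(req %in% names(edges)))
    stop("edges must have columns 'source', 'target', 'type'")
  edges <- edges[req]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (nrow(edges) == 0L) stop("circuit must contain at least one edge")
  if (any(is.na(edges$source)) || any(is.na(edges$target)) ||
      any(edges$source == "") || any(edges$target == ""))
    stop("edge with empty or missing gene identifier")
  if (!all(edges$type %in% c(1L, 2L)))
    stop("unknown interaction type code: ",
         paste(unique(edges$type[!edges$type %in% c(1L, 2L)]),
               collapse = ", "),
         " (expected 1 = activation, 2 = inhibition)")
  edges$type <- as.integer(edges$type)
  missing_genes <- setdiff(unique(c(edges$source, edges$target)), genes)
  if (length(missing_genes))
    stop("edge endpoint not in gene list: ",
         paste(missing_genes, collapse = ", "))
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge: ",
         paste(unique(paste(edges$source, "->", edges$target)[duplicated(key)]),
               collapse = ", "))
  rownames(edges) <- NULL
  structure(list(name = name, genes = genes, edges = edges),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  sym <- ifelse(x$edges$type == 1L, "->", "-|")
  cat("<circuit> ", x$name, ": ", length(x$genes), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("  genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  cat(paste0("  ", x$edges$source, " ", sym, " ", x$edges$target,
             collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' @export
format.circuit <- function(x, ...) {
  paste0(x$name, " (", length(x$genes), " genes, ", nrow(x$edges), " edges)")
}

#' Number of genes / edges of a circuit
#'
#' @param circuit a [circuit()] object.
#' @return integer count.
#' @export
n_genes <- function(circuit) length(circuit$genes)

#' @rdname n_genes
#' @export
n_edges <- function(circuit) nrow(circuit$edges)

#' Read a circuit topology file
#'
#' Reads the conventional three-column whitespace-delimited topology format:
#' a header line `Source Target Type` followed by one row per regulatory
#' edge, with `Type` `1` for activation and `2` for inhibition. Genes are
#' ordered by first appearance (scanning each row source-then-target), which
#' fixes the downstream expression-matrix column order.
#'
#' @param path path to the topology file.
#' @param name circuit label; defaults to the file name without extension.
#' @return A [circuit()] object.
#' @seealso [write_topology()], [fixture_circuit()]
#' @export
read_topology <- function(path, name = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("source", "target", "type"),
                           colClasses = "character", fill = FALSE)
  # drop header line if present (third field non-numeric)
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab$type[1]))))
    tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("topology file contains no edge rows: ", path)
  type_num <- suppressWarnings(as.numeric(tab$type))
  if (any(is.na(type_num)))
    stop("malformed interaction type in ", path, ": ",
         paste(unique(tab$type[is.na(type_num)]), collapse = ", "))
  genes <- unique(as.vector(t(cbind(tab$source, tab$target))))
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  circuit(genes,
          data.frame(source = tab$source, target = tab$target,
                     type = type_num, stringsAsFactors = FALSE),
          name = name)
}

#' Write a circuit topology file
#'
#' Writes the tab-delimited `Source Target Type` format read by
#' [read_topology()]. Reading the file back reproduces the circuit exactly
#' (for circuits whose gene order equals first-appearance order in the edge
#' list, which holds for all shipped fixtures).
#'
#' @param circuit a [circuit()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(circuit, path) {
  stopifnot(inherits(circuit, "circuit"))
  isolated <- setdiff(circuit$genes,
                      unique(c(circuit$edges$source, circuit$edges$target)))
  if (length(isolated))
    warning("gene(s) without edges are not representable in the topology ",
            "format and will be lost on read-back: ",
            paste(isolated, collapse = ", "))
  out <- data.frame(Source = circuit$edges$source,
                    Target = circuit$edges$target,
                    Type = circuit$edges$type)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Built-in benchmark circuits
#'
#' The toggle-switch family used throughout the package:
#' \describe{
#'   \item{`TS`}{toggle switch: two mutually inhibiting genes.}
#'   \item{`TS_SA1`}{toggle switch with a self-activation on gene A.}
#'   \item{`TS_SA2`}{toggle switch with self-activations on both genes (the
#'     quadrastable circuit: low-low, low-high, high-low, high-high states
#'     can coexist).}
#'   \item{`FIVE_TS`}{five toggle switches (A1/B1 ... A5/B5) coupled in a
#'     ring: within each pair the genes mutually inhibit, and each B_i
#'     additionally inhibits A_(i+1) (B5 closing the ring onto A1).}
#' }
#' The five-switch coupling pattern is one reasonable realization of a
#' ring-coupled multi-switch circuit; only the figure of the original study
#' depicts it, so the exact coupling is a package design choice.
#'
#' @param name one of `"TS"`, `"TS_SA1"`, `"TS_SA2"`, `"FIVE_TS"`.
#' @return A [circuit()] object.
#' @examples
#' fixture_circuit("TS_SA2")
#' @export
fixture_circuit <- function(name = c("TS", "TS_SA1", "TS_SA2", "FIVE_TS")) {
  name <- match.arg(name)
  edge <- function(s, t, ty) data.frame(source = s, target = t, type = ty,
                                        stringsAsFactors = FALSE)
  switch(name,
    TS = circuit(c("A", "B"),
                 edge(c("A", "B"), c("B", "A"), c(2L, 2L)), name = "TS"),
    TS_SA1 = circuit(c("A", "B"),
                     edge(c("A", "A", "B"), c("A", "B", "A"),
                          c(1L, 2L, 2L)), name = "TS_SA1"),
    TS_SA2 = circuit(c("A", "B"),
                     edge(c("A", "B", "A", "B"), c("A", "B", "B", "A"),
                          c(1L, 1L, 2L, 2L)), name = "TS_SA2"),
    FIVE_TS = {
      a <- paste0("A", 1:5); b <- paste0("B", 1:5)
      genes <- as.vector(rbind(a, b))
      pairs <- edge(c(rbind(a, b)), c(rbind(b, a)), 2L)
      ring <- edge(b, a[c(2:5, 1)], 2L)
      circuit(genes, rbind(pairs, ring), name = "FIVE_TS")
    })
}

#' Names of the built-in benchmark circuits
#' @return character vector of fixture names accepted by
#'   [fixture_circuit()].
#' @export
fixture_circuit_names <- function() c("TS", "TS_SA1", "TS_SA2", "FIVE_TS")

# Edge identifiers used for parameter column names: "<source>_<target>".
edge_ids <- function(circuit)
  paste(circuit$edges$source, circuit$edges$target, sep = "_")
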