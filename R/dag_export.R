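# Structural analysis and export of the learned dependency DAG: key-attribute
# identification, local dependent/independent substructures around a node,
# and DOT / edge-list serialization.

#' Classify attributes as key, secondary, or source
#'
#' A key attribute both has at least one attribute parent and is itself a
#' parent of at least one attribute — it is affected by other attributes and
#' acts on others, which is what makes it a first-stop variable when mining
#' the DAG. Attributes with children but no attribute parent (e.g. the tree
#' root) are annotated `"source"`; everything else is `"secondary"`.
#'
#' @param structure A `bn_structure`.
#' @return Character vector over attributes with values `"key"`,
#'   `"secondary"`, `"source"`.
#' @export
classify_key_attributes <- function(structure) {
  n <- structure$n
  indeg <- vapply(structure$parents, length, integer(1))
  outdeg <- integer(n)
  for (i in seq_len(n)) for (p in structure$parents[[i]])
    outdeg[p] <- outdeg[p] + 1L
  roles <- rep("secondary", n)
  roles[indeg >= 1L & outdeg >= 1L] <- "key"
  roles[indeg == 0L & outdeg >= 1L] <- "source"
  roles
}

#' Local dependency structure around an attribute
#'
#' `"ancestors"` returns the induced sub-DAG on every attribute with a
#' directed path to `node` — the chain of variables the node depends on;
#' `"descendants"` returns everything reachable from it — the variables it
#' acts on.
#'
#' @param structure A `bn_structure`.
#' @param node Attribute index.
#' @param direction `"ancestors"` or `"descendants"`.
#' @return List with `nodes` (integer vector, excluding `node` itself) and
#'   `arcs` (two-column matrix, the arcs induced on `nodes` + `node`).
#' @export
local_structure <- function(structure, node,
                            direction = c("ancestors", "descendants")) {
  direction <- match.arg(direction)
  n <- structure$n
  stopifnot(node >= 1L, node <= n)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in structure$parents[[i]])
    children[[p]] <- c(children[[p]], i)
  step <- if (direction == "ancestors") structure$parents else children
  seen <- logical(n)
  queue <- step[[node]]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    queue <- c(queue, step[[v]])
  }
  nodes <- which(seen)
  sub <- sort(unique(c(nodes, node)))
  arcs <- structure_arcs(structure)
  keep <- arcs[, 1] %in% sub & arcs[, 2] %in% sub
  list(nodes = nodes, arcs = arcs[keep, , drop = FALSE])
}

#' Render a structure as DOT
#'
#' Emits a standard Graphviz digraph: the class node points to every
#' attribute (dashed, to keep the attribute-attribute skeleton readable),
#' key attributes are drawn filled, and arc labels carry the CMI weight at
#' three decimals when a weight matrix is supplied. Output is byte-stable
#' for identical inputs.
#'
#' @param structure A `bn_structure`.
#' @param weights Optional symmetric CMI matrix for arc labels.
#' @param names Attribute display names (default `X1..Xn`).
#' @param class_name Display name of the class node.
#' @return A single DOT string.
#' @export
to_dot <- function(structure, weights = NULL, names = NULL,
                   class_name = "Class") {
  n <- structure$n
  if (is.null(names)) names <- paste0("X", seq_len(n))
  roles <- classify_key_attributes(structure)
  q <- function(s) paste0("\"", s, "\"")
  node_lines <- vapply(seq_len(n), function(i) {
    style <- if (roles[i] == "key")
      " [style=filled, fillcolor=lightblue]" else ""
    paste0("  ", q(names[i]), style, ";")
  }, character(1))
  class_lines <- c(
    paste0("  ", q(class_name), " [shape=box];"),
    vapply(seq_len(n), function(i)
      paste0("  ", q(class_name), " -> ", q(names[i]), " [style=dashed];"),
      character(1)))
  arcs <- structure_arcs(structure)
  arc_lines <- if (nrow(arcs)) vapply(seq_len(nrow(arcs)), function(e) {
    lbl <- if (!is.null(weights))
      sprintf(" [label=\"%.3f\"]", weights[arcs[e, 1], arcs[e, 2]]) else ""
    paste0("  ", q(names[arcs[e, 1]]), " -> ", q(names[arcs[e, 2]]),
           lbl, ";")
  }, character(1)) else character(0)
  paste(c("digraph dependencies {", class_lines, node_lines, arc_lines, "}"),
        collapse = "\n")
}

#' Write a flat edge list (parent, child, weight)
#'
#' @param structure A `bn_structure`.
#' @param path Output path.
#' @param weights Optional symmetric CMI matrix; weight column omitted when
#'   `NULL`.
#' @param names Attribute display names.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(structure, path, weights = NULL, names = NULL) {
  n <- structure$n
  if (is.null(names)) names <- paste0("X", seq_len(n))
  arcs <- structure_arcs(structure)
  df <- data.frame(parent = names[arcs[, 1]], child = names[arcs[, 2]],
                   stringsAsFactors = FALSE)
  if (!is.null(weights))
    df$weight <- sprintf("%.6g", weights[arcs])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
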