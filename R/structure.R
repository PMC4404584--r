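# Structure learning for the restricted Bayesian classifier family. A
# NetworkStructure stores, per attribute, its attribute parents (the class is
# an implicit parent of every attribute). All ties — edge weights, mutual
# information, pair order — break by attribute index ascending, so every
# learner is deterministic.

#' Construct a network structure
#'
#' @param algorithm Tag: `"nb"`, `"tan"`, `"kdb"`, or `"fkbn"`.
#' @param n Number of attributes.
#' @param parents List of integer vectors, `parents[[i]]` = attribute parents
#'   of attribute `i` (class excluded and implicit).
#' @param max_parents Dependence bound K (0 for naive Bayes, 1 for TAN).
#' @param root Root attribute for tree-based learners (`NA` otherwise).
#' @param order Total order over attributes used for arc orientation.
#' @return An object of class `bn_structure`.
#' @export
bn_structure <- function(algorithm, n, parents, max_parents,
                         root = NA_integer_, order = seq_len(n)) {
  parents <- lapply(parents, as.integer)
  stopifnot(length(parents) == n)
  if (any(vapply(parents, length, integer(1)) > max_parents))
    stop("a parent set exceeds the dependence bound K = ", max_parents)
  for (i in seq_len(n)) {
    p <- parents[[i]]
    if (length(p) && (anyDuplicated(p) || any(p < 1L | p > n) || i %in% p))
      stop("invalid parent set for attribute ", i)
  }
  s <- structure(list(algorithm = algorithm, n = n, parents = parents,
                      max_parents = as.integer(max_parents),
                      root = as.integer(root), order = as.integer(order)),
                 class = "bn_structure")
  if (is.null(topological_order(s)))
    stop("parent sets contain a directed cycle")
  s
}

#' @export
print.bn_structure <- function(x, ...) {
  arcs <- sum(vapply(x$parents, length, integer(1)))
  cat(sprintf("bn_structure[%s] K=%d: %d attributes, %d attribute arc(s)\n",
              x$algorithm, x$max_parents, x$n, arcs))
  invisible(x)
}

#' Attribute arcs of a structure
#' @param structure A `bn_structure`.
#' @return Two-column integer matrix (`from`, `to`); one row per arc.
#' @export
structure_arcs <- function(structure) {
  to <- rep.int(seq_len(structure$n),
                vapply(structure$parents, length, integer(1)))
  from <- unlist(structure$parents, use.names = FALSE)
  m <- cbind(from = as.integer(from), to = to)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Kahn topological sort over attribute arcs; NULL when cyclic.
topological_order <- function(structure) {
  n <- structure$n
  indeg <- vapply(structure$parents, length, integer(1))
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in structure$parents[[i]])
    children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) NULL else out
}

#' Naive Bayes structure
#'
#' The 0-dependence classifier: the class is the sole parent of every
#' attribute, so every attribute parent set is empty.
#'
#' @param n Number of attributes (>= 1).
#' @return A `bn_structure` with `max_parents = 0`.
#' @export
learn_nb <- function(n) {
  stopifnot(n >= 1L)
  bn_structure("nb", n, rep(list(integer(0)), n), 0L)
}

# Kruskal maximum-weight spanning tree; edges sorted by weight descending,
# ties by (i, j) ascending. Returns an (n-1) x 2 matrix of undirected edges.
max_spanning_tree <- function(w) {
  n <- nrow(w)
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  edges <- matrix(0L, nrow = 0, ncol = 2)
  for (e in seq_len(nrow(pairs))) {
    a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
    if (a != b) {
      parent[a] <- b
      edges <- rbind(edges, pairs[e, , drop = FALSE])
      if (nrow(edges) == n - 1L) break
    }
  }
  edges
}

# Direct tree edges away from root; returns list(parents, bfs_order).
orient_tree <- function(edges, n, root) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parents <- rep(list(integer(0)), n)
  seen <- logical(n)
  seen[root] <- TRUE
  queue <- root
  bfs <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    bfs <- c(bfs, v)
    nb <- sort(adj[[v]])           # ties: lower index first
    for (u in nb) if (!seen[u]) {
      seen[u] <- TRUE
      parents[[u]] <- v
      queue <- c(queue, u)
    }
  }
  list(parents = parents, bfs = bfs)
}

#' Tree-augmented naive Bayes structure
#'
#' Builds the maximum-weight spanning tree over attributes under CMI edge
#' weights (Kruskal; equal-weight ties broken by index pair), roots it, and
#' directs every arc away from the root, giving each non-root attribute
#' exactly one attribute parent.
#'
#' @param cmi Symmetric CMI matrix from [build_cmi_matrix()].
#' @param root Root attribute index; by convention the attribute most
#'   informative about the class (see [choose_root()]).
#' @return A `bn_structure` with `max_parents = 1`.
#' @export
learn_tan <- function(cmi, root = 1L) {
  n <- nrow(cmi)
  stopifnot(n >= 2L, root >= 1L, root <= n)
  edges <- max_spanning_tree(cmi)
  ot <- orient_tree(edges, n, root)
  bn_structure("tan", n, ot$parents, 1L, root = root, order = ot$bfs)
}

#' K-dependence Bayesian network structure
#'
#' Attributes are sorted by mutual information with the class, descending
#' (ties: lower original index first); the j-th attribute in that rigid order
#' takes as parents its `min(j-1, K)` predecessors with the highest CMI to it
#' (ties: earlier predecessor first).
#'
#' @param mi Vector of `MI(X_i;C)` from [mi_vector()].
#' @param cmi Symmetric CMI matrix.
#' @param k Dependence bound K >= 0.
#' @return A `bn_structure` with `max_parents = k`.
#' @export
learn_kdb <- function(mi, cmi, k) {
  n <- length(mi)
  stopifnot(k >= 0L, n >= 1L)
  sigma <- order(-mi, seq_len(n))
  parents <- rep(list(integer(0)), n)
  if (k > 0L && n >= 2L) {
    for (j in seq(2L, n)) {
      v <- sigma[j]
      preds <- sigma[seq_len(j - 1L)]
      take <- min(j - 1L, k)
      # rank predecessors by CMI descending, ties by position in sigma
      ord <- order(-cmi[preds, v], seq_along(preds))
      parents[[v]] <- sort(preds[ord[seq_len(take)]])
    }
  }
  bn_structure("kdb", n, parents, as.integer(k), root = sigma[1L],
               order = sigma)
}

#' Flexible K-dependence Bayesian network structure
#'
#' Stage 1 builds the CMI maximum-weight spanning tree exactly as
#' [learn_tan()], roots it at `root`, directs arcs outward, and records the
#' breadth-first order \eqn{\sigma} from the root. Stage 2 walks the
#' remaining attribute pairs in CMI-descending order (ties: lexicographically
#' smaller index pair) and, for a pair `(u, v)` with \eqn{\sigma(u) <
#' \sigma(v)}, adds the arc `u -> v` when `v` still has fewer than K parents.
#' Each added arc is the strongest relationship not already implicated in the
#' tree; orientation along \eqn{\sigma} makes acyclicity structural. Pairs
#' with zero CMI are never added in stage 2 (they would add parameters
#' without information).
#'
#' @param mi Vector of `MI(X_i;C)`.
#' @param cmi Symmetric CMI matrix.
#' @param k Dependence bound K >= 1.
#' @param root Root attribute; defaults to [choose_root()] of `mi`.
#' @return A `bn_structure` with `max_parents = k`.
#' @export
learn_fkbn <- function(mi, cmi, k, root = choose_root(mi)) {
  n <- nrow(cmi)
  stopifnot(k >= 1L, n >= 2L, length(mi) == n)
  edges <- max_spanning_tree(cmi)
  ot <- orient_tree(edges, n, root)
  parents <- ot$parents
  sigma_pos <- integer(n)
  sigma_pos[ot$bfs] <- seq_len(n)

  in_tree <- matrix(FALSE, n, n)
  in_tree[edges] <- TRUE
  in_tree[edges[, c(2, 1), drop = FALSE]] <- TRUE
  pairs <- which(upper.tri(cmi), arr.ind = TRUE)
  keep <- !in_tree[pairs]
  pairs <- pairs[keep, , drop = FALSE]
  ord <- order(-cmi[pairs], pairs[, 1], pairs[, 2])
  for (e in ord) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    if (cmi[i, j] <= 0) next
    if (sigma_pos[i] < sigma_pos[j]) { u <- i; v <- j } else { u <- j; v <- i }
    if (length(parents[[v]]) < k) parents[[v]] <- sort(c(parents[[v]], u))
  }
  bn_structure("fkbn", n, parents, as.integer(k), root = root,
               order = ot$bfs)
}

#' Choose the tree root
#'
#' Returns the attribute with maximal mutual information with the class
#' (ties: lowest index), so the most class-informative attribute is ancestral
#' in tree-based structures.
#'
#' @param mi Vector of `MI(X_i;C)`.
#' @return Attribute index.
#' @export
choose_root <- function(mi) {
  stopifnot(length(mi) >= 1L)
  which.max(mi)  # which.max already keeps the first (lowest-index) maximum
}

#' Learn a structure by algorithm tag
#'
#' Dispatcher used by the fitting and cross-validation paths.
#'
#' @param data A [discrete_dataset()].
#' @param algorithm One of `"nb"`, `"tan"`, `"kdb"`, `"fkbn"`.
#' @param k Dependence bound (ignored by `"nb"`/`"tan"`).
#' @return A `bn_structure`.
#' @export
learn_structure <- function(data, algorithm = c("nb", "tan", "kdb", "fkbn"),
                            k = 2L) {
  algorithm <- match.arg(algorithm)
  n <- data$n_attributes
  if (algorithm == "nb" || n < 2L) {
    s <- learn_nb(n)
    s$algorithm <- algorithm
    return(s)
  }
  if (algorithm == "tan") {
    return(learn_tan(build_cmi_matrix(data), root = choose_root(mi_vector(data))))
  }
  mi <- mi_vector(data)
  cmi <- build_cmi_matrix(data)
  if (algorithm == "kdb") return(learn_kdb(mi, cmi, k))
  if (k == 0L) {
    s <- learn_nb(n)
    s$algorithm <- "fkbn"
    return(s)
  }
  learn_fkbn(mi, cmi, k)
}

#' Write a structure to a text file
#'
#' Plain-text serialization (algorithm, K, root, order, per-attribute parent
#' lists) that [read_structure()] restores losslessly.
#'
#' @param structure A `bn_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  lines <- c(
    paste("algorithm", structure$algorithm),
    paste("k", structure$max_parents),
    paste("n", structure$n),
    paste("root", structure$root),
    paste("order", paste(structure$order, collapse = " ")),
    vapply(seq_len(structure$n), function(i)
      paste(c("parents", i, ":", structure$parents[[i]]), collapse = " "),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure written by [write_structure()]
#' @param path Path to a structure file.
#' @return A `bn_structure`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " +")
  get1 <- function(key) {
    hit <- which(vapply(kv, `[[`, character(1), 1L) == key)[1L]
    kv[[hit]][-1L]
  }
  n <- as.integer(get1("n"))
  parents <- rep(list(integer(0)), n)
  for (row in kv[vapply(kv, `[[`, character(1), 1L) == "parents"]) {
    i <- as.integer(row[2L])
    rest <- row[-(1:3)]
    parents[[i]] <- as.integer(rest[nzchar(rest)])
  }
  root_str <- get1("root")
  bn_structure(get1("algorithm"), n, parents,
               as.integer(get1("k")),
               root = if (identical(root_str, "NA")) NA_integer_ else
                 as.integer(root_str),
               order = as.integer(get1("order")))
}
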