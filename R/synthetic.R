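# Synthetic categorical data from planted K-dependence Bayesian networks.
# The generator exists so that every other module is testable without any
# external download: it emulates the *shapes* of clinical-registry extracts
# (tens of thousands of rows, ~20 attributes, 2-3 classes) and of small
# wide microarray tables (tens of rows, many attributes), not the marginal
# distributions of any real variable.

#' Specification of a planted-model generator
#'
#' @param n_attributes Number of predictive attributes.
#' @param domain_sizes Per-attribute domain sizes (recycled to length
#'   `n_attributes`).
#' @param n_classes Class domain size.
#' @param k Dependence bound of the planted structure.
#' @param sharpness Symmetric Dirichlet concentration for every conditional
#'   distribution; lower = sharper rows = stronger, more recoverable
#'   dependencies (0.1 is sharp, 1 is uniform over the simplex, large values
#'   give near-uniform rows and hence near-independence).
#' @param n_rows Number of instances to sample.
#' @param seed Integer seed; every draw derives from it.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_attributes = 20L, domain_sizes = 3L,
                           n_classes = 2L, k = 2L, sharpness = 0.1,
                           n_rows = 1000L, seed = 1L) {
  stopifnot(n_attributes >= 1L, all(domain_sizes >= 1L), n_classes >= 1L,
            k >= 0L, sharpness > 0, n_rows >= 0L)
  structure(list(n_attributes = as.integer(n_attributes),
                 domain_sizes = rep_len(as.integer(domain_sizes),
                                        n_attributes),
                 n_classes = as.integer(n_classes), k = as.integer(k),
                 sharpness = sharpness, n_rows = as.integer(n_rows),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# Uniform draw over all predecessor subsets of size <= k: pick the size with
# probability proportional to the number of subsets of that size, then a
# uniform subset of that size.
draw_parent_set <- function(preds, k) {
  kk <- min(k, length(preds))
  if (kk == 0L) return(integer(0))
  sizes <- 0:kk
  weights <- choose(length(preds), sizes)
  m <- sizes[sample.int(length(sizes), 1L, prob = weights)]
  if (m == 0L) return(integer(0))
  sort(preds[sample.int(length(preds), m)])
}

#' Draw a random planted structure
#'
#' Draws a uniformly random total order over attributes, then gives each
#' attribute a uniformly random subset of at most K of its predecessors as
#' parents. Deterministic given the spec's seed.
#'
#' @param spec A [generator_spec()].
#' @return A `bn_structure` (algorithm tag `"planted"`).
#' @export
random_structure <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_attributes
  sigma <- sample.int(n)
  parents <- rep(list(integer(0)), n)
  if (n >= 2L) for (j in seq(2L, n)) {
    v <- sigma[j]
    parents[[v]] <- draw_parent_set(sigma[seq_len(j - 1L)], spec$k)
  }
  bn_structure("planted", n, parents, max_parents = spec$k,
               root = sigma[1L], order = sigma)
}

rdirichlet1 <- function(d, conc) {
  g <- stats::rgamma(d, shape = conc)
  while (sum(g) == 0) g <- stats::rgamma(d, shape = conc)
  g / sum(g)
}

#' Draw random conditional probability tables for a planted structure
#'
#' The class marginal and every conditional row `P(x_i | pa_i, c)` are drawn
#' from a symmetric Dirichlet with the spec's concentration. Deterministic
#' given the spec's seed (offset so structure and parameters use distinct
#' streams).
#'
#' @param structure A planted `bn_structure` from [random_structure()].
#' @param spec The [generator_spec()].
#' @return An object of class `true_cpts`: `class_p` plus `cpt[[i]]` arrays
#'   with dim `(|dom_i|, parent domains..., n_classes)`; conditional rows
#'   (margin 1) each sum to 1.
#' @export
random_cpts <- function(structure, spec) {
  set.seed(spec$seed + 1L)
  n <- structure$n
  d <- spec$domain_sizes
  dc <- spec$n_classes
  class_p <- rdirichlet1(dc, spec$sharpness)
  cpt <- vector("list", n)
  for (i in seq_len(n)) {
    pa <- structure$parents[[i]]
    dims <- c(d[i], d[pa], dc)
    n_rows <- prod(dims[-1L])
    m <- vapply(seq_len(n_rows), function(r) rdirichlet1(d[i], spec$sharpness),
                numeric(d[i]))
    cpt[[i]] <- array(as.numeric(m), dim = dims)
  }
  structure(list(class_p = class_p, cpt = cpt, domain_sizes = d,
                 n_classes = dc), class = "true_cpts")
}

#' Ancestral sampling from a planted model
#'
#' Samples the class first, then each attribute in the planted topological
#' order conditioned on its sampled parents. Deterministic given `seed`.
#'
#' @param structure A planted `bn_structure`.
#' @param cpts Matching `true_cpts` from [random_cpts()].
#' @param n_rows Number of instances.
#' @param seed Integer seed.
#' @return A [discrete_dataset()] with domains `v1..v_d` per attribute and
#'   classes `c1..c_k`.
#' @export
sample_dataset <- function(structure, cpts, n_rows, seed = 1L) {
  set.seed(seed)
  n <- structure$n
  d <- cpts$domain_sizes
  dc <- cpts$n_classes
  n_rows <- as.integer(n_rows)
  cls <- if (n_rows > 0L)
    sample.int(dc, n_rows, replace = TRUE, prob = cpts$class_p) else integer(0)
  x <- matrix(0L, nrow = n_rows, ncol = n)
  topo <- structure$order
  if (n_rows > 0L) for (i in topo) {
    pa <- structure$parents[[i]]
    tab <- cpts$cpt[[i]]
    dims <- dim(tab)
    # linear index of the conditioning row for every instance
    row_idx <- rep.int(0L, n_rows)
    mult <- 1L
    for (s in seq_along(pa)) {
      row_idx <- row_idx + (x[, pa[s]] - 1L) * mult
      mult <- mult * dims[1L + s]
    }
    row_idx <- row_idx + (cls - 1L) * mult
    flat <- matrix(tab, nrow = dims[1L])
    u <- stats::runif(n_rows)
    for (r in unique(row_idx)) {
      sel <- row_idx == r
      p <- flat[, r + 1L]
      # clamp guards the u ~ 1 edge when cumsum(p) tops out below 1 in floats
      x[sel, i] <- pmin(findInterval(u[sel], cumsum(p), left.open = TRUE) + 1L,
                        d[i])
    }
  }
  domains <- lapply(seq_len(n), function(i) paste0("v", seq_len(d[i])))
  names(domains) <- paste0("X", seq_len(n))
  discrete_dataset(x, cls, domains, paste0("c", seq_len(dc)))
}

#' Score recovery of a planted structure as undirected adjacencies
#'
#' Fraction of the planted attribute-attribute arcs that appear in the
#' learned structure as an adjacency in either direction.
#'
#' @param planted,learned `bn_structure`s over the same attributes.
#' @return Real in `[0, 1]` (1 when the planted structure has no arcs).
#' @export
adjacency_recovery <- function(planted, learned) {
  pa_arcs <- structure_arcs(planted)
  if (nrow(pa_arcs) == 0L) return(1)
  la <- structure_arcs(learned)
  learned_und <- unique(rbind(la, la[, c(2, 1), drop = FALSE]))
  key <- function(m) paste(m[, 1], m[, 2])
  mean(key(pa_arcs) %in% key(learned_und))
}
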