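# Fixtures and independent oracles shared across the suite. Every oracle here
# is a deliberately naive re-derivation (plain loops, enumeration) kept
# separate from the implementation paths it checks.

# ---- dataset builders -------------------------------------------------------

# discrete_dataset from a plain integer matrix + class vector
make_dataset <- function(x, cls, n_class = max(cls)) {
  x <- as.matrix(x)
  domains <- lapply(seq_len(ncol(x)), function(a)
    paste0("v", seq_len(max(x[, a]))))
  names(domains) <- paste0("X", seq_len(ncol(x)))
  discrete_dataset(x, cls, domains, paste0("c", seq_len(n_class)))
}

# random small dataset for enumeration-scale oracle checks
random_small_dataset <- function(n_attr = 3, n_levels = 3, n_class = 2,
                                 n_rows = 30) {
  x <- matrix(sample.int(n_levels, n_rows * n_attr, replace = TRUE),
              nrow = n_rows)
  make_dataset(x, sample.int(n_class, n_rows, replace = TRUE), n_class)
}

# write a toy delimited file + schema, returning paths
write_toy_table <- function(df, kinds, dir = NULL, missing = "?") {
  if (is.null(dir)) {
    dir <- tempfile("toy")
    dir.create(dir)
  }
  cols <- lapply(seq_along(df), function(j)
    list(name = names(df)[j], kind = kinds[j], missing = missing))
  sch <- schema(cols)
  data_path <- file.path(dir, "data.csv")
  utils::write.table(df, data_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  schema_path <- file.path(dir, "schema.yml")
  write_schema(sch, schema_path)
  list(data = data_path, schema = schema_path, schema_obj = sch)
}

# ---- worked-example fixtures ------------------------------------------------

# the published 12-dataset x 4-algorithm rank matrix used as the
# rank-averaging worked example (6 large clinical sets with distinct ranks,
# 6 small wide sets all tied at 2.5)
example_rank_matrix <- function() {
  m <- rbind(
    c(4.0, 2.0, 2.0, 2.0),
    c(4.0, 3.0, 1.5, 1.5),
    c(4.0, 2.0, 2.0, 2.0),
    c(4.0, 1.5, 3.0, 1.5),
    c(4.0, 2.0, 2.0, 2.0),
    c(4.0, 3.0, 1.5, 1.5),
    matrix(2.5, 6, 4))
  dimnames(m) <- list(paste0("D", 1:12), c("NB", "TAN", "KDB", "FKBN"))
  m
}

# the four-attribute toy CMI weights used across the structure tests
toy_cmi <- function() {
  w <- matrix(0, 4, 4)
  set <- function(i, j, v) {
    w[i, j] <<- v
    w[j, i] <<- v
  }
  set(1, 4, 0.40); set(3, 4, 0.35); set(1, 3, 0.30)
  set(2, 3, 0.20); set(2, 4, 0.10); set(1, 2, 0.05)
  w
}

# ---- information-theory oracles ---------------------------------------------

oracle_mi <- function(data, i) {
  N <- nrow(data$x)
  total <- 0
  for (xi in seq_along(data$domains[[i]])) for (c in
      seq_along(data$class_domain)) {
    nxy <- sum(data$x[, i] == xi & data$class == c)
    if (nxy == 0) next
    nx <- sum(data$x[, i] == xi)
    nc <- sum(data$class == c)
    total <- total + nxy / N * log2((nxy / N) / ((nx / N) * (nc / N)))
  }
  total
}

oracle_cmi <- function(data, i, j) {
  N <- nrow(data$x)
  total <- 0
  for (xi in seq_along(data$domains[[i]]))
    for (xj in seq_along(data$domains[[j]]))
      for (c in seq_along(data$class_domain)) {
        nijc <- sum(data$x[, i] == xi & data$x[, j] == xj & data$class == c)
        if (nijc == 0) next
        nic <- sum(data$x[, i] == xi & data$class == c)
        njc <- sum(data$x[, j] == xj & data$class == c)
        nc <- sum(data$class == c)
        total <- total + nijc / N *
          log2((nc / N) * (nijc / N) / ((nic / N) * (njc / N)))
      }
  total
}

# ---- spanning-tree enumeration (Pruefer bijection) --------------------------

pruefer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, nrow = 0, ncol = 2)
  for (v in seq) {
    leaf <- which(degree == 1L)[1L]
    edges <- rbind(edges, c(min(leaf, v), max(leaf, v)))
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  rbind(edges, c(min(last), max(last)))
}

# maximum spanning-tree weight by exhaustive enumeration of all n^(n-2) trees
oracle_mst_weight <- function(w) {
  n <- nrow(w)
  if (n == 2) return(w[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    edges <- pruefer_to_edges(seqs[r, ], n)
    best <- max(best, sum(w[edges]))
  }
  best
}

tree_weight <- function(structure, w) {
  arcs <- structure_arcs(structure)
  sum(w[arcs])
}

# ---- MDL discretization oracle ----------------------------------------------

oracle_entropy <- function(y) {
  p <- table(y) / length(y)
  -sum(p * log2(p))
}

# independent recursive MDL discretization: brute force over boundary cuts
oracle_mdl_cuts <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  ux <- unique(x)
  if (length(ux) < 2) return(numeric(0))
  cands <- c()
  for (g in seq_len(length(ux) - 1)) {
    left <- sort(y[x == ux[g]])
    right <- sort(y[x == ux[g + 1]])
    if (!identical(as.character(left), as.character(right)) ||
        length(left) != length(right))
      cands <- c(cands, (ux[g] + ux[g + 1]) / 2)
  }
  if (length(cands) == 0) return(numeric(0))
  n <- length(x)
  gains <- sapply(cands, function(cut) {
    l <- y[x <= cut]; r <- y[x > cut]
    oracle_entropy(y) - length(l) / n * oracle_entropy(l) -
      length(r) / n * oracle_entropy(r)
  })
  best <- which.max(gains)
  cut <- cands[best]
  l <- y[x <= cut]; r <- y[x > cut]
  k <- length(unique(y)); k1 <- length(unique(l)); k2 <- length(unique(r))
  delta <- log2(3^k - 2) -
    (k * oracle_entropy(y) - k1 * oracle_entropy(l) - k2 * oracle_entropy(r))
  if (gains[best] <= log2(n - 1) / n + delta / n) return(numeric(0))
  c(oracle_mdl_cuts(x[x <= cut], l), cut, oracle_mdl_cuts(x[x > cut], r))
}

# run the package discretizer on one numeric column
fit_cuts <- function(x, y) {
  df <- data.frame(v = as.character(x), cls = as.character(y))
  rt <- raw_table(df, schema(list(list(name = "v", kind = "numeric"),
                                  list(name = "cls", kind = "class"))))
  fit_mdl_discretizer(rt)$cuts$v
}

# ---- classifier oracle ------------------------------------------------------

# brute-force posterior under naive Bayes with add-one-smoothed conditionals,
# computed straight from the data frame of codes (no log space, no caching)
oracle_nb_posterior <- function(data, inst) {
  dc <- length(data$class_domain)
  K <- nrow(data$x)
  post <- sapply(seq_len(dc), function(c) {
    p <- (sum(data$class == c) + 1) / (K + dc)
    for (i in seq_len(data$n_attributes)) {
      di <- length(data$domains[[i]])
      num <- sum(data$class == c & data$x[, i] == inst[i]) + 1
      den <- sum(data$class == c) + di
      p <- p * num / den
    }
    p
  })
  post / sum(post)
}

# ---- graph oracles ----------------------------------------------------------

# transitive closure by repeated boolean matrix product
oracle_reachable <- function(structure) {
  n <- structure$n
  A <- matrix(FALSE, n, n)
  arcs <- structure_arcs(structure)
  A[arcs] <- TRUE
  R <- A
  for (step in seq_len(n)) R <- R | (R %*% A > 0)
  R   # R[u, v]: directed path u -> v
}

# parse attribute arcs back out of DOT text
parse_dot_arcs <- function(dot) {
  lines <- strsplit(dot, "\n")[[1]]
  hits <- regmatches(lines,
    regexec("^  \"X(\\d+)\" -> \"X(\\d+)\"", lines))
  m <- do.call(rbind, lapply(hits[lengths(hits) == 3], function(h)
    as.integer(h[2:3])))
  if (is.null(m)) matrix(0L, 0, 2) else m[order(m[, 1], m[, 2]), ,
                                           drop = FALSE]
}
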