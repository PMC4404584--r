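# Laplace-smoothed parameter estimation and prediction. Base probability
# estimates follow the add-one pattern
#   P(c)            = (F(c) + 1) / (K + k)
#   P(c, x_i)       = (F(c, x_i) + 1) / (K_i + k_i)
#   P(c, x_i, x_j)  = (F(c, x_i, x_j) + 1) / (K_ij + k_ij)
# where F(.) is a training frequency, K_* the number of instances with the
# relevant variables known (all of them, after imputation) and k_* the size
# of the joint value space. Conditionals P(x_i | pa_i, c) are ratios of
# smoothed joints; with a shared denominator these renormalize exactly to
# (F(c, x_i, pa) + 1) / (F(c, pa) + |dom_i|). Parent sets larger than pairs
# use the same "+1 over (count + number-of-combinations)" pattern on the
# full combination space. Domain sizes come from the declared domains
# (including the reserved unseen level), not from observed combinations, so
# denominators do not depend on fold composition.

#' Count training frequencies for a structure
#'
#' Exact integer counts of every combination the structure's parent sets
#' need: class counts `F(c)`, and for each attribute the joint counts of
#' `(x_i, pa_i, c)` over the full declared value space (never-observed
#' combinations count 0).
#'
#' @param data A [discrete_dataset()].
#' @param structure A `bn_structure` over the same attributes.
#' @return An object of class `count_cache`: list with `class_counts`,
#'   `n_instances` (the number of training instances with known class), and
#'   `tables[[i]]`, an integer array with dim `(|dom_i|, parent domains...,
#'   |C|)`.
#' @export
count_frequencies <- function(data, structure) {
  stopifnot(inherits(data, "discrete_dataset"),
            structure$n == data$n_attributes)
  dc <- length(data$class_domain)
  tables <- vector("list", structure$n)
  for (i in seq_len(structure$n)) {
    pa <- structure$parents[[i]]
    dims <- c(length(data$domains[[i]]),
              vapply(pa, function(p) length(data$domains[[p]]), integer(1)),
              dc)
    code <- data$x[, i] - 1L
    mult <- dims[1L]
    if (length(pa)) for (s in seq_along(pa)) {
      code <- code + (data$x[, pa[s]] - 1L) * mult
      mult <- mult * dims[1L + s]
    }
    code <- code + (data$class - 1L) * mult
    tables[[i]] <- array(tabulate(code + 1L, nbins = prod(dims)), dim = dims)
  }
  structure(list(class_counts = tabulate(data$class, nbins = dc),
                 n_instances = nrow(data$x), tables = tables),
            class = "count_cache")
}

#' Fit Laplace-smoothed probability tables
#'
#' Class prior \eqn{\hat P(c) = (F(c)+1)/(K+k)}; per-attribute conditionals
#' are ratios of add-one-smoothed joints renormalized over the attribute's
#' declared domain, i.e. \eqn{\hat P(x_i | pa_i, c) = (F(c, x_i, pa_i) + 1) /
#' (F(c, pa_i) + |dom_i|)}. Every conditional row sums to 1 by construction,
#' and unseen value combinations (including the reserved unseen level) keep
#' nonzero mass.
#'
#' @param counts A `count_cache` from [count_frequencies()].
#' @param structure The `bn_structure` the counts were built for.
#' @param domains Attribute domain list (with `class_domain` attribute) or
#'   the originating [discrete_dataset()].
#' @return An object of class `cpt_set`: `log_prior` over classes and
#'   `log_cpt[[i]]` arrays shaped like the count tables.
#' @export
fit_cpts <- function(counts, structure, domains) {
  if (inherits(domains, "discrete_dataset")) {
    class_domain <- domains$class_domain
    domains <- domains$domains
  } else class_domain <- attr(domains, "class_domain")
  dc <- length(class_domain)
  prior <- (counts$class_counts + 1) / (counts$n_instances + dc)
  log_cpt <- vector("list", structure$n)
  for (i in seq_len(structure$n)) {
    tab <- counts$tables[[i]]
    di <- dim(tab)[1L]
    denom_margin <- apply(tab, seq_along(dim(tab))[-1L], sum)
    sm <- sweep(tab + 1, seq_along(dim(tab))[-1L], denom_margin + di, "/")
    log_cpt[[i]] <- log(sm)
  }
  structure(list(log_prior = log(prior), log_cpt = log_cpt,
                 class_domain = class_domain, domains = domains),
            class = "cpt_set")
}

#' Fit a complete classifier
#'
#' Convenience wrapper: learns (or accepts) a structure on the training data
#' and estimates its Laplace-smoothed tables.
#'
#' @param data A training [discrete_dataset()].
#' @param algorithm Algorithm tag or a ready `bn_structure`.
#' @param k Dependence bound for `"kdb"`/`"fkbn"`.
#' @return An object of class `bn_classifier` (structure + CPTs + domains).
#' @export
fit_classifier <- function(data, algorithm = "fkbn", k = 2L) {
  s <- if (inherits(algorithm, "bn_structure")) algorithm else
    learn_structure(data, algorithm, k)
  counts <- count_frequencies(data, s)
  cpts <- fit_cpts(counts, s, data)
  structure(list(structure = s, cpts = cpts, domains = data$domains,
                 class_domain = data$class_domain,
                 attr_names = data$attr_names),
            class = "bn_classifier")
}

#' @export
print.bn_classifier <- function(x, ...) {
  print(x$structure)
  cat("classes:", paste(x$class_domain, collapse = ", "), "\n")
  invisible(x)
}

instance_codes <- function(model, newdata) {
  if (inherits(newdata, "discrete_dataset")) {
    stopifnot(identical(lapply(newdata$domains, as.character),
                        lapply(model$domains, as.character)))
    newdata$x
  } else {
    x <- as.matrix(newdata)
    storage.mode(x) <- "integer"
    x
  }
}

#' Class posterior probabilities
#'
#' Evaluates, per instance and class, \eqn{\log \hat P(c) + \sum_i \log \hat
#' P(x_i | pa_i, c)} (log-space accumulation avoids underflow at tens of
#' attributes), then exponentiates and normalizes to a proper posterior.
#'
#' @param model A `bn_classifier`.
#' @param newdata A [discrete_dataset()] with the model's domains, or an
#'   integer code matrix.
#' @return Numeric matrix, rows = instances, columns = classes (named); each
#'   row sums to 1.
#' @export
posterior <- function(model, newdata) {
  x <- instance_codes(model, newdata)
  nr <- nrow(x)
  dc <- length(model$class_domain)
  s <- model$structure
  logp <- matrix(rep(model$cpts$log_prior, each = nr), nrow = nr, ncol = dc)
  for (c_idx in seq_len(dc)) {
    for (i in seq_len(s$n)) {
      pa <- s$parents[[i]]
      idx <- cbind(x[, i, drop = FALSE],
                   if (length(pa)) x[, pa, drop = FALSE],
                   rep.int(c_idx, nr))
      logp[, c_idx] <- logp[, c_idx] + model$cpts$log_cpt[[i]][idx]
    }
  }
  mx <- apply(logp, 1L, max)
  p <- exp(logp - mx)
  p <- p / rowSums(p)
  colnames(p) <- model$class_domain
  p
}

#' Predict class labels
#'
#' Argmax of the posterior; exact ties go to the class earlier in the class
#' domain order.
#'
#' @param object A `bn_classifier`.
#' @param newdata A [discrete_dataset()] or integer code matrix.
#' @param type `"label"` (default) for class labels, `"index"` for class
#'   indices.
#' @param ... Unused.
#' @return Character vector of labels (or integer indices).
#' @export
predict.bn_classifier <- function(object, newdata, type = c("label", "index"),
                                  ...) {
  type <- match.arg(type)
  p <- posterior(object, newdata)
  idx <- max.col(p, ties.method = "first")
  if (type == "index") idx else object$class_domain[idx]
}

#' Write a fitted classifier to a text file
#'
#' Structure, domains, and all log-probabilities at full precision; the file
#' round-trips to an identical predictor via [read_model()].
#'
#' @param model A `bn_classifier`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  s <- model$structure
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    paste("algorithm", s$algorithm),
    paste("k", s$max_parents),
    paste("n", s$n),
    paste("root", s$root),
    paste("order", paste(s$order, collapse = " ")),
    vapply(seq_len(s$n), function(i)
      paste(c("parents", i, ":", s$parents[[i]]), collapse = " "),
      character(1)),
    paste("class_domain", paste(model$class_domain, collapse = "\t"),
          sep = "\t"),
    vapply(seq_len(s$n), function(i)
      paste(c("domain", model$attr_names[i], model$domains[[i]]),
            collapse = "\t"), character(1)),
    paste("log_prior", num(model$cpts$log_prior)),
    vapply(seq_len(s$n), function(i)
      paste("log_cpt", i, num(model$cpts$log_cpt[[i]])), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a classifier written by [write_model()]
#' @param path Path to a model file.
#' @return A `bn_classifier`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  tag <- sub("[ \t].*", "", lines)
  pick <- function(key) lines[tag == key]
  after <- function(line) sub("^[^ \t]+[ \t]", "", line)
  n <- as.integer(after(pick("n")))
  parents <- rep(list(integer(0)), n)
  for (row in pick("parents")) {
    parts <- strsplit(row, " +")[[1]]
    i <- as.integer(parts[2L])
    rest <- parts[-(1:3)]
    parents[[i]] <- as.integer(rest[nzchar(rest)])
  }
  root_str <- after(pick("root"))
  s <- bn_structure(after(pick("algorithm")), n, parents,
                    as.integer(after(pick("k"))),
                    root = if (identical(root_str, "NA")) NA_integer_ else
                      as.integer(root_str),
                    order = as.integer(strsplit(after(pick("order")),
                                                " ")[[1]]))
  class_domain <- strsplit(after(pick("class_domain")), "\t")[[1]]
  domains <- vector("list", n)
  attr_names <- character(n)
  dom_lines <- pick("domain")
  for (i in seq_len(n)) {
    parts <- strsplit(dom_lines[i], "\t")[[1]]
    attr_names[i] <- parts[2L]
    domains[[i]] <- parts[-(1:2)]
  }
  names(domains) <- attr_names
  log_prior <- as.numeric(strsplit(after(pick("log_prior")), " ")[[1]])
  log_cpt <- vector("list", n)
  cpt_lines <- pick("log_cpt")
  for (row in cpt_lines) {
    parts <- strsplit(row, " +")[[1]]
    i <- as.integer(parts[2L])
    vals <- as.numeric(parts[-(1:2)])
    dims <- c(length(domains[[i]]),
              vapply(parents[[i]], function(p) length(domains[[p]]),
                     integer(1)),
              length(class_domain))
    log_cpt[[i]] <- array(vals, dim = dims)
  }
  cpts <- structure(list(log_prior = log_prior, log_cpt = log_cpt,
                         class_domain = class_domain, domains = domains),
                    class = "cpt_set")
  structure(list(structure = s, cpts = cpts, domains = domains,
                 class_domain = class_domain, attr_names = attr_names),
            class = "bn_classifier")
}
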