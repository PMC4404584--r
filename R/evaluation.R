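# Cross-validated zero-one loss and Friedman rank comparison across
# datasets, with an exact two-tailed binomial sign test deciding
# significance-based rank ties.

#' Zero-one loss
#'
#' \eqn{\xi(c,\hat c) = 1 - \delta(c,\hat c)}: the fraction of positions at
#' which prediction and truth disagree.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Real in `[0, 1]`.
#' @export
zero_one_loss <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (length(truth) == 0L) stop("empty label sequences")
  mean(truth != predicted)
}

# Stratified fold assignment: within each class, indices are shuffled by the
# seeded generator and dealt round-robin over folds.
stratified_folds <- function(class_labels, folds, seed) {
  assignment <- integer(length(class_labels))
  set.seed(seed)
  for (cl in unique(class_labels)) {
    idx <- which(class_labels == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Cross-validated zero-one loss
#'
#' Stratified k-fold cross-validation. Within every fold the full pipeline is
#' re-fitted on the training part only — imputation, MDL discretization,
#' structure, and Laplace tables — and zero-one loss is scored on the
#' held-out part, so held-out rows never inform any fitted statistic.
#'
#' @param raw A `raw_table` (or a [discrete_dataset()], converted via
#'   [as_raw_table()]).
#' @param algorithm `"nb"`, `"tan"`, `"kdb"`, or `"fkbn"`.
#' @param k Dependence bound for `"kdb"`/`"fkbn"`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed driving the fold assignment.
#' @return An object of class `cv_result`: `fold_losses`, `mean_loss`, `sd`
#'   (sample standard deviation across folds), and `correct`, the pooled
#'   per-instance correctness in original row order.
#' @export
cross_validate <- function(raw, algorithm = "fkbn", k = 2L, folds = 10L,
                           seed = 1L) {
  if (inherits(raw, "discrete_dataset")) raw <- as_raw_table(raw)
  stopifnot(inherits(raw, "raw_table"), folds >= 2L)
  nr <- nrow(raw$data)
  if (nr < folds) stop("fewer instances (", nr, ") than folds (", folds, ")")
  k <- switch(algorithm, nb = 0L, tan = 1L, as.integer(k))
  cls <- raw$data[[raw$schema$class_column]]
  fold_of <- stratified_folds(cls, folds, seed)
  fold_losses <- numeric(folds)
  correct <- logical(nr)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    train_cls <- cls[train_idx]
    if (!all(unique(cls) %in% train_cls))
      stop("training part of fold ", f, " lacks class label(s): ",
           paste(setdiff(unique(cls), train_cls), collapse = ", "),
           " (dataset too small or imbalanced for ", folds, " folds)")
    train <- raw_table(raw$data[train_idx, , drop = FALSE], raw$schema)
    test <- raw_table(raw$data[test_idx, , drop = FALSE], raw$schema)
    imp <- fit_imputation(train)
    disc <- fit_mdl_discretizer(train, imp)
    dtrain <- apply_preprocess(train, imp, disc)
    dtest <- apply_preprocess(test, imp, disc, domains = dtrain$domains)
    model <- fit_classifier(dtrain, algorithm, k)
    pred <- predict(model, dtest)
    truth <- test$data[[raw$schema$class_column]]
    fold_losses[f] <- zero_one_loss(truth, pred)
    correct[test_idx] <- pred == truth
  }
  structure(list(algorithm = algorithm, k = k, folds = folds, seed = seed,
                 fold_losses = fold_losses, mean_loss = mean(fold_losses),
                 sd = stats::sd(fold_losses), correct = correct),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s (K=%d): zero-one loss %.3f +/- %.3f over %d folds\n",
              x$algorithm, x$k, x$mean_loss, x$sd, x$folds))
  invisible(x)
}

#' Exact two-tailed binomial sign test
#'
#' Given the win counts of two classifiers over the instances where exactly
#' one of them is correct (ties already discarded), tests the hypothesis of
#' equal win probability 1/2: \eqn{p = \min(1,\; 2\,P[\mathrm{Bin}(m, 1/2)
#' \ge \max(w_a, w_b)])} with \eqn{m = w_a + w_b}. By convention `p = 1` when
#' `m = 0`.
#'
#' @param wins_a,wins_b Nonnegative win counts.
#' @return Two-tailed p-value in `(0, 1]`.
#' @export
sign_test <- function(wins_a, wins_b) {
  stopifnot(wins_a >= 0, wins_b >= 0)
  m <- wins_a + wins_b
  if (m == 0) return(1)
  hi <- max(wins_a, wins_b)
  min(1, 2 * stats::pbinom(hi - 1, m, 0.5, lower.tail = FALSE))
}

#' Pairwise win counts from cross-validation results
#'
#' For every ordered pair of classifiers, counts the pooled held-out
#' instances where the first is correct and the second wrong (double-correct
#' and double-wrong instances carry no sign information and are discarded by
#' the sign test).
#'
#' @param cv_results List of `cv_result`s for the same dataset, same folds.
#' @return Integer matrix `W` with `W[a, b]` = wins of `a` over `b`.
#' @export
pairwise_wins <- function(cv_results) {
  A <- length(cv_results)
  W <- matrix(0L, A, A)
  for (a in seq_len(A)) for (b in seq_len(A)) {
    if (a == b) next
    W[a, b] <- sum(cv_results[[a]]$correct & !cv_results[[b]]$correct)
  }
  W
}

#' Friedman ranks of algorithms across datasets
#'
#' Ranks the algorithms on each dataset by zero-one loss ascending (best =
#' rank 1) and averages ranks over datasets, \eqn{R_j = \frac1N \sum_i
#' r_i^j}. Tied algorithms share the average of the ranks they span. In
#' `"exact"` mode ties are exactly equal losses. In `"signtest"` mode
#' algorithms are grouped by the transitive closure of pairwise "not
#' significantly different" relations (two-tailed sign test p >= `alpha` on
#' the per-dataset win counts), and each group shares its average rank —
#' pairwise non-significance is not transitive, so the closure is what makes
#' the groups a partition.
#'
#' @param losses N-by-A numeric matrix of per-dataset zero-one losses
#'   (rows = datasets, columns = algorithms).
#' @param tie_mode `"exact"` or `"signtest"`.
#' @param tie_evidence For `"signtest"`: list of length N of A-by-A win-count
#'   matrices (see [pairwise_wins()]).
#' @param alpha Significance level for the sign test (default 0.05).
#' @return An object of class `rank_table`: `ranks` (N-by-A), `avg_ranks`
#'   (\eqn{R_j}), and `tie_mode`.
#' @export
friedman_rank <- function(losses, tie_mode = c("exact", "signtest"),
                          tie_evidence = NULL, alpha = 0.05) {
  tie_mode <- match.arg(tie_mode)
  losses <- as.matrix(losses)
  N <- nrow(losses); A <- ncol(losses)
  stopifnot(N >= 1L, A >= 2L, alpha > 0, alpha < 1)
  if (tie_mode == "signtest" &&
      (is.null(tie_evidence) || length(tie_evidence) != N))
    stop("signtest tie mode needs one win-count matrix per dataset")
  ranks <- matrix(0, N, A, dimnames = dimnames(losses))
  for (i in seq_len(N)) {
    base <- rank(losses[i, ], ties.method = "average")
    if (tie_mode == "signtest") {
      W <- tie_evidence[[i]]
      same <- matrix(FALSE, A, A)
      for (a in seq_len(A - 1L)) for (b in seq((a + 1L), A))
        same[a, b] <- same[b, a] <-
          sign_test(W[a, b], W[b, a]) >= alpha
      diag(same) <- TRUE
      comp <- transitive_components(same)
      for (g in unique(comp))
        ranks[i, comp == g] <- mean(base[comp == g])
    } else ranks[i, ] <- base
  }
  rank_table(ranks, tie_mode)
}

# Connected components of a symmetric logical adjacency matrix.
transitive_components <- function(adj) {
  A <- nrow(adj)
  comp <- integer(A)
  cur <- 0L
  for (v in seq_len(A)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Construct a rank table from per-dataset ranks
#'
#' @param ranks N-by-A matrix of per-dataset ranks (each row must sum to
#'   `A(A+1)/2`).
#' @param tie_mode Tag recording how ties were decided.
#' @return An object of class `rank_table` with the per-dataset ranks and
#'   the column averages \eqn{R_j}.
#' @export
rank_table <- function(ranks, tie_mode = "exact") {
  ranks <- as.matrix(ranks)
  A <- ncol(ranks)
  target <- A * (A + 1) / 2
  bad <- abs(rowSums(ranks) - target) > 1e-9
  if (any(bad))
    stop("rank row(s) do not sum to A(A+1)/2: ",
         paste(which(bad), collapse = ", "))
  structure(list(ranks = ranks, avg_ranks = colMeans(ranks),
                 tie_mode = tie_mode), class = "rank_table")
}

#' @export
print.rank_table <- function(x, digits = 2, ...) {
  out <- rbind(x$ranks, Average = x$avg_ranks)
  print(round(out, digits))
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with halves going up (`2.25 -> 2.3` at one digit), the
#' convention of most printed tables; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Read / write loss and rank matrices as delimited text
#'
#' Layout: datasets in rows, algorithms in columns, header row of algorithm
#' names, first column the dataset name.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_file <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = 1)
  if (any(!vapply(df, is.numeric, logical(1))))
    stop("non-numeric entries in matrix file ", path)
  as.matrix(df)
}

#' @rdname read_matrix_file
#' @param m Matrix to write.
#' @export
write_matrix_file <- function(m, path, sep = ",") {
  df <- data.frame(dataset = rownames(m) %||% paste0("D", seq_len(nrow(m))),
                   m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
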