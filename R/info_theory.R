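# Information-theoretic weights driving structure learning. All quantities
# are in bits (log base 2), estimated from unsmoothed maximum-likelihood
# frequencies; 0 * log(0/...) terms contribute 0. Laplace smoothing is
# reserved for the classifier's probability tables.

#' Mutual information between an attribute and the class
#'
#' \eqn{MI(X_i;C) = \sum_{x,c} P(x,c) \log_2 \frac{P(x,c)}{P(x)P(c)}}, from
#' empirical maximum-likelihood frequencies. Drives the attribute ordering of
#' the K-dependence learner and the choice of tree root.
#'
#' @param data A [discrete_dataset()].
#' @param i Attribute index (1-based).
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information <- function(data, i) {
  stopifnot(inherits(data, "discrete_dataset"),
            i >= 1L, i <= data$n_attributes)
  N <- nrow(data$x)
  if (N == 0L) stop("dataset is empty")
  di <- length(data$domains[[i]])
  dc <- length(data$class_domain)
  joint <- tabulate(data$x[, i] + di * (data$class - 1L), nbins = di * dc)
  # doubles: products of counts overflow 32-bit integers past ~46k rows
  joint <- matrix(as.numeric(joint), nrow = di, ncol = dc)
  mx <- rowSums(joint); mc <- colSums(joint)
  nz <- which(joint > 0, arr.ind = TRUE)
  v <- joint[nz]
  val <- sum(v / N * log2(v * N / (mx[nz[, 1]] * mc[nz[, 2]])))
  max(val, 0)
}

#' Mutual information of every attribute with the class
#'
#' @param data A [discrete_dataset()].
#' @return Numeric vector of length `n_attributes` (bits), named by attribute.
#' @export
mi_vector <- function(data) {
  v <- vapply(seq_len(data$n_attributes), function(i)
    mutual_information(data, i), numeric(1))
  names(v) <- data$attr_names
  v
}

#' Conditional mutual information of two attributes given the class
#'
#' \eqn{CMI(X_i;X_j|C) = \sum_{x_i,x_j,c} P(x_i,x_j,c) \log_2
#' \frac{P(c)P(x_i,x_j,c)}{P(x_i,c)P(x_j,c)}}, from maximum-likelihood
#' frequencies. Symmetric in `(i, j)`; the arc-weight currency of the
#' tree-augmented and K-dependence learners.
#'
#' @param data A [discrete_dataset()].
#' @param i,j Distinct attribute indices.
#' @return Nonnegative conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(data, i, j) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (i == j) stop("conditional mutual information requires i != j")
  N <- nrow(data$x)
  if (N == 0L) stop("dataset is empty")
  di <- length(data$domains[[i]])
  dj <- length(data$domains[[j]])
  dc <- length(data$class_domain)
  code <- data$x[, i] + di * (data$x[, j] - 1L) +
    di * dj * (data$class - 1L)
  joint <- array(as.numeric(tabulate(code, nbins = di * dj * dc)),
                 dim = c(di, dj, dc))
  n_c <- as.numeric(tabulate(data$class, nbins = dc))
  n_ic <- apply(joint, c(1, 3), sum)
  n_jc <- apply(joint, c(2, 3), sum)
  nz <- which(joint > 0, arr.ind = TRUE)
  v <- joint[nz]
  val <- sum(v / N * log2(n_c[nz[, 3]] * v /
                            (n_ic[nz[, c(1, 3)]] * n_jc[nz[, c(2, 3)]])))
  max(val, 0)
}

#' Conditional-mutual-information matrix over all attribute pairs
#'
#' Fills the symmetric n-by-n matrix of `CMI(X_i;X_j|C)` (bits); the diagonal
#' is stored as 0 and never read.
#'
#' @param data A [discrete_dataset()] with at least two attributes.
#' @return Symmetric numeric matrix with attribute-name dimnames.
#' @export
build_cmi_matrix <- function(data) {
  n <- data$n_attributes
  stopifnot(n >= 2L)
  m <- matrix(0, n, n, dimnames = list(data$attr_names, data$attr_names))
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    w <- conditional_mutual_information(data, i, j)
    m[i, j] <- w
    m[j, i] <- w
  }
  m
}

#' Write a CMI matrix as lower-triangular delimited text
#'
#' One row per attribute from the second onward; row `i` lists
#' `CMI(X_i;X_j|C)` for `j < i`, mirroring the conventional lower-triangular
#' presentation of the matrix.
#'
#' @param cmi Symmetric CMI matrix.
#' @param path Output path.
#' @param digits Significant digits to print.
#' @return Invisibly, `path`.
#' @export
write_cmi_matrix <- function(cmi, path, digits = 6) {
  n <- nrow(cmi)
  nms <- rownames(cmi) %||% paste0("X", seq_len(n))
  lines <- vapply(seq(2L, n), function(i)
    paste(c(nms[i], format(cmi[i, seq_len(i - 1L)], digits = digits,
                           trim = TRUE)), collapse = "\t"),
    character(1))
  writeLines(c(paste(c("", nms[seq_len(n - 1L)]), collapse = "\t"), lines),
             path)
  invisible(path)
}
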