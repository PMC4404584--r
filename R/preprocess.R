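# Reserved level appended to every categorical attribute domain so that
# test-time values never seen in training still receive Laplace mass.
UNSEEN_LEVEL <- "<unseen>"

#' Read a column schema
#'
#' A schema declares, for every column of a delimited data file, its name and
#' kind (`categorical`, `numeric`, or `class`) plus the tokens that mark a
#' missing value. Exactly one column must be declared `class`.
#'
#' The file is YAML of the form
#' \preformatted{
#' columns:
#'   - name: age
#'     kind: numeric
#'   - name: grade
#'     kind: categorical
#'   - name: outcome
#'     kind: class
#' missing: ["?", ""]
#' }
#' A per-column `missing` entry overrides the global list for that column.
#'
#' @param path Path to a YAML schema file.
#' @return An object of class `fkbn_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$columns) || length(spec$columns) == 0L)
    stop("schema declares no columns")
  global_missing <- as.character(spec$missing %||% "?")
  cols <- lapply(spec$columns, function(col) {
    if (is.null(col$name) || is.null(col$kind))
      stop("every schema column needs 'name' and 'kind'")
    kind <- match.arg(col$kind, c("categorical", "numeric", "class"))
    list(name = as.character(col$name), kind = kind,
         missing = as.character(col$missing %||% global_missing))
  })
  schema(cols)
}

#' Construct a schema in code
#'
#' @param columns List of per-column lists with fields `name`, `kind`
#'   (`categorical`/`numeric`/`class`) and optionally `missing` (character
#'   vector of marker tokens, default `"?"`).
#' @return An object of class `fkbn_schema`.
#' @export
schema <- function(columns) {
  columns <- lapply(columns, function(col) {
    col$missing <- as.character(col$missing %||% "?")
    col
  })
  names <- vapply(columns, `[[`, character(1), "name")
  kinds <- vapply(columns, `[[`, character(1), "kind")
  if (anyDuplicated(names)) stop("duplicate column names in schema")
  if (sum(kinds == "class") != 1L)
    stop("schema must declare exactly one class column")
  structure(list(columns = columns, names = names, kinds = kinds,
                 class_column = names[kinds == "class"]),
            class = "fkbn_schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited table against a schema
#'
#' Reads a header-ed delimited text file, checks the header against the
#' schema's declared columns, and normalizes every declared missing-value
#' marker to `NA`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema An `fkbn_schema`.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return An object of class `raw_table`: the character data frame plus its
#'   schema.
#' @export
read_table <- function(path, schema, sep = ",") {
  if (!file.exists(path)) stop("data file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "\"",
                          comment.char = "")
  if (!identical(colnames(df), schema$names)) {
    bad <- c(setdiff(colnames(df), schema$names),
             setdiff(schema$names, colnames(df)))
    if (length(bad) == 0L)
      stop("column order differs from schema: header is (",
           paste(colnames(df), collapse = ", "), ")")
    stop("header does not match schema; offending column(s): ",
         paste(unique(bad), collapse = ", "))
  }
  if (nrow(df) == 0L) stop("data file has no rows: ", path)
  for (j in seq_along(schema$columns))
    df[[j]][df[[j]] %in% schema$columns[[j]]$missing] <- NA_character_
  raw_table(df, schema)
}

#' Construct a raw table from a data frame
#'
#' @param df A data frame whose columns match the schema (values coerced to
#'   character; `NA` marks missing).
#' @param schema An `fkbn_schema`.
#' @return An object of class `raw_table`.
#' @export
raw_table <- function(df, schema) {
  stopifnot(inherits(schema, "fkbn_schema"))
  if (!identical(colnames(df), schema$names))
    stop("data frame columns do not match schema")
  df <- as.data.frame(lapply(df, as.character), check.names = FALSE,
                      stringsAsFactors = FALSE)
  if (any(is.na(df[[schema$class_column]])))
    stop("class column '", schema$class_column, "' contains missing values")
  structure(list(data = df, schema = schema), class = "raw_table")
}

#' @export
print.raw_table <- function(x, ...) {
  cat("raw_table:", nrow(x$data), "rows,", ncol(x$data), "columns (class: ",
      x$schema$class_column, ")\n", sep = " ")
  invisible(x)
}

#' Fit an imputation model on training rows
#'
#' Missing categorical values are later replaced by the column's training
#' mode (ties broken by first occurrence in file order); missing numeric
#' values by the training mean. The class column is never imputed.
#'
#' @param train A `raw_table` of training rows.
#' @return An object of class `imputation_model`.
#' @export
fit_imputation <- function(train) {
  stopifnot(inherits(train, "raw_table"))
  sch <- train$schema
  fills <- list()
  for (j in seq_along(sch$columns)) {
    col <- sch$columns[[j]]
    if (col$kind == "class") next
    v <- train$data[[j]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L)
      stop("column '", col$name, "' has no observed values; cannot impute")
    if (col$kind == "categorical") {
      # first-seen order: table() sorts, so count against unique() order
      levs <- unique(obs)
      counts <- tabulate(match(obs, levs), nbins = length(levs))
      fills[[col$name]] <- levs[which.max(counts)]
    } else {
      fills[[col$name]] <- mean(as.numeric(obs))
    }
  }
  structure(list(fills = fills, schema = sch), class = "imputation_model")
}

impute_table <- function(tab, imp) {
  df <- tab$data
  for (nm in names(imp$fills)) {
    v <- df[[nm]]
    if (anyNA(v)) {
      fill <- imp$fills[[nm]]
      df[[nm]][is.na(v)] <- as.character(fill)
    }
  }
  tab$data <- df
  tab
}

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

# Recursive entropy-minimizing split with the MDL stopping criterion, on one
# already-sorted numeric vector (x sorted ascending, y integer class codes).
mdl_split <- function(x, y, n_class_total) {
  n <- length(x)
  ux <- unique(x)           # x sorted, so ux ascending, groups contiguous
  if (length(ux) < 2L) return(numeric(0))
  grp <- match(x, ux)
  # class count vector per distinct value; candidate boundary iff adjacent
  # multisets differ
  cnt <- matrix(0L, nrow = length(ux), ncol = n_class_total)
  for (i in seq_len(n)) cnt[grp[i], y[i]] <- cnt[grp[i], y[i]] + 1L
  is_boundary <- vapply(seq_len(length(ux) - 1L), function(g)
    !identical(cnt[g, ], cnt[g + 1L, ]), logical(1))
  cand <- which(is_boundary)
  if (length(cand) == 0L) return(numeric(0))

  class_counts <- tabulate(y, nbins = n_class_total)
  ent_s <- entropy_bits(class_counts)
  k <- sum(class_counts > 0)

  cum <- apply(cnt, 2L, cumsum)           # cumulative class counts by group
  if (is.null(dim(cum))) cum <- matrix(cum, ncol = n_class_total)
  best_gain <- -Inf; best_g <- NA_integer_
  stats <- vector("list", length(cand))
  for (idx in seq_along(cand)) {
    g <- cand[idx]
    left <- cum[g, ]; right <- class_counts - left
    n1 <- sum(left); n2 <- n - n1
    e1 <- entropy_bits(left); e2 <- entropy_bits(right)
    gain <- ent_s - (n1 / n) * e1 - (n2 / n) * e2
    stats[[idx]] <- list(g = g, e1 = e1, e2 = e2,
                         k1 = sum(left > 0), k2 = sum(right > 0),
                         n1 = n1, gain = gain)
    if (gain > best_gain + 1e-12) { best_gain <- gain; best_g <- idx }
  }
  st <- stats[[best_g]]
  delta <- log2(3^k - 2) - (k * ent_s - st$k1 * st$e1 - st$k2 * st$e2)
  threshold <- log2(n - 1) / n + delta / n
  if (st$gain <= threshold) return(numeric(0))
  cut <- (ux[st$g] + ux[st$g + 1L]) / 2
  left_idx <- x <= cut
  c(mdl_split(x[left_idx], y[left_idx], n_class_total),
    cut,
    mdl_split(x[!left_idx], y[!left_idx], n_class_total))
}

#' Fit MDL (entropy-based) discretization cut points
#'
#' For each numeric column, recursively picks the class-entropy-minimizing
#' boundary cut and accepts it only when the information gain exceeds the
#' minimum-description-length threshold
#' \eqn{\log_2(N-1)/N + [\log_2(3^k-2) - (k\,Ent(S) - k_1 Ent(S_1) - k_2
#' Ent(S_2))]/N}, then recurses on the accepted halves. Candidate cuts are
#' midpoints between consecutive distinct sorted values whose adjacent class
#' multisets differ (boundary points). All entropies are in bits.
#'
#' @param train A `raw_table` of training rows.
#' @param imputation Optional `imputation_model` applied to the numeric
#'   columns first (means are defined on the numeric scale, so imputation
#'   precedes discretization).
#' @return An object of class `mdl_discretizer`: per numeric column a
#'   strictly increasing (possibly empty) vector of cut points.
#' @export
fit_mdl_discretizer <- function(train, imputation = NULL) {
  stopifnot(inherits(train, "raw_table"))
  if (!is.null(imputation)) train <- impute_table(train, imputation)
  sch <- train$schema
  cls <- train$data[[sch$class_column]]
  class_levels <- unique(cls)
  y <- match(cls, class_levels)
  cuts <- list()
  for (j in seq_along(sch$columns)) {
    col <- sch$columns[[j]]
    if (col$kind != "numeric") next
    v <- as.numeric(train$data[[j]])
    keep <- !is.na(v)
    if (!any(keep)) stop("numeric column '", col$name, "' is all-missing")
    ord <- order(v[keep])
    cuts[[col$name]] <- mdl_split(v[keep][ord], y[keep][ord],
                                  length(class_levels))
  }
  structure(list(cuts = cuts, schema = sch), class = "mdl_discretizer")
}

bin_labels <- function(cuts) {
  if (length(cuts) == 0L) return("(-Inf,Inf)")
  edges <- format(cuts, trim = TRUE, digits = 12)
  lo <- c("-Inf", edges)
  hi <- c(edges, "Inf")
  paste0("(", lo, ",", hi, ifelse(hi == "Inf", ")", "]"))
}

#' Apply fitted preprocessing models to a table
#'
#' Fills every missing value from the imputation model, bins numeric columns
#' with the fitted cut points (values beyond the training range fall into the
#' unbounded outer bins), and encodes categorical values against the training
#' domains. Categorical values never seen in training map to a reserved
#' `"<unseen>"` level that is part of every categorical domain. Domains are
#' fixed by `domains` (when preprocessing test rows) or recorded from the
#' training rows.
#'
#' @param table A `raw_table`.
#' @param imputation An `imputation_model` fitted on training rows.
#' @param discretizer An `mdl_discretizer` fitted on training rows.
#' @param domains Optional domain list from a training
#'   [discrete_dataset()] (use when transforming held-out rows so train and
#'   test share identical domains).
#' @return A [discrete_dataset()].
#' @export
apply_preprocess <- function(table, imputation, discretizer, domains = NULL) {
  stopifnot(inherits(table, "raw_table"))
  table <- impute_table(table, imputation)
  sch <- table$schema
  pred_idx <- which(sch$kinds != "class")
  attr_names <- sch$names[pred_idx]
  n <- length(pred_idx)
  nr <- nrow(table$data)

  doms <- vector("list", n)
  names(doms) <- attr_names
  x <- matrix(0L, nrow = nr, ncol = n, dimnames = list(NULL, attr_names))
  for (a in seq_len(n)) {
    col <- sch$columns[[pred_idx[a]]]
    v <- table$data[[pred_idx[a]]]
    if (col$kind == "numeric") {
      cuts <- discretizer$cuts[[col$name]]
      labs <- bin_labels(cuts)
      dom <- if (is.null(domains)) labs else domains[[col$name]]
      # right-closed bins: value z lands in bin 1 + #{cuts < z}
      code <- vapply(as.numeric(v), function(z) sum(z > cuts) + 1L,
                     integer(1))
      x[, a] <- code
      doms[[a]] <- dom
    } else {
      if (is.null(domains)) {
        dom <- c(unique(v), UNSEEN_LEVEL)
      } else dom <- domains[[col$name]]
      code <- match(v, dom)
      code[is.na(code)] <- match(UNSEEN_LEVEL, dom)
      x[, a] <- code
      doms[[a]] <- dom
    }
  }
  cls <- table$data[[sch$class_column]]
  class_dom <- if (is.null(domains)) unique(cls) else
    attr(domains, "class_domain")
  ccode <- match(cls, class_dom)
  if (anyNA(ccode))
    stop("class label(s) absent from training class domain: ",
         paste(unique(cls[is.na(ccode)]), collapse = ", "))
  attr(doms, "class_domain") <- class_dom
  discrete_dataset(x, ccode, doms, class_dom, attr_names)
}

#' Construct a discrete dataset
#'
#' The substrate of every computation in the package: instances over
#' finite-domain attributes plus a class variable, stored as integer codes
#' against fixed, ordered domains.
#'
#' @param x Integer matrix, rows = instances, columns = attributes; entry
#'   `x[r, a]` is the 1-based index of instance `r`'s value in `domains[[a]]`.
#' @param class_codes Integer vector of 1-based class indices.
#' @param domains List of character vectors, one ordered domain per attribute.
#' @param class_domain Character vector of class labels.
#' @param attr_names Attribute names (default taken from `domains`).
#' @return An object of class `discrete_dataset`.
#' @export
discrete_dataset <- function(x, class_codes, domains, class_domain,
                             attr_names = names(domains)) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(attr_names)) attr_names <- paste0("X", seq_len(ncol(x)))
  stopifnot(ncol(x) == length(domains),
            nrow(x) == length(class_codes))
  for (a in seq_len(ncol(x))) {
    v <- x[, a]
    if (length(v) && (min(v) < 1L || max(v) > length(domains[[a]])))
      stop("attribute ", attr_names[a], ": code outside declared domain")
  }
  if (length(class_codes) &&
      (min(class_codes) < 1L || max(class_codes) > length(class_domain)))
    stop("class code outside class domain")
  domains <- lapply(domains, as.character)
  names(domains) <- attr_names
  # keep the class domain attached so fitted train domains can encode test
  # tables (apply_preprocess reads it back)
  attr(domains, "class_domain") <- as.character(class_domain)
  structure(list(x = x, class = as.integer(class_codes), domains = domains,
                 class_domain = as.character(class_domain),
                 attr_names = attr_names,
                 n_attributes = ncol(x)),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("discrete_dataset:", nrow(x$x), "instances,", x$n_attributes,
      "attributes,", length(x$class_domain), "classes\n")
  invisible(x)
}

#' Number of instances in a discrete dataset
#' @param data A `discrete_dataset`.
#' @return Integer row count.
#' @export
n_instances <- function(data) nrow(data$x)

#' Convert a discrete dataset back to a raw table
#'
#' Decodes integer codes to their domain labels, producing an all-categorical
#' `raw_table` (with a matching generated schema). Useful for feeding
#' synthetic datasets to the cross-validation path, which re-fits
#' preprocessing per training fold.
#'
#' @param data A `discrete_dataset`.
#' @param class_name Name for the class column.
#' @return A `raw_table`.
#' @export
as_raw_table <- function(data, class_name = "class") {
  stopifnot(inherits(data, "discrete_dataset"))
  df <- as.data.frame(lapply(seq_len(data$n_attributes), function(a)
    data$domains[[a]][data$x[, a]]), col.names = data$attr_names,
    check.names = FALSE, stringsAsFactors = FALSE)
  df[[class_name]] <- data$class_domain[data$class]
  cols <- c(lapply(data$attr_names, function(nm)
    list(name = nm, kind = "categorical", missing = "?")),
    list(list(name = class_name, kind = "class", missing = "?")))
  raw_table(df, schema(cols))
}

#' Write a discrete dataset and its domains to text files
#'
#' Serializes the decoded table to delimited text and a sidecar YAML domain
#' file (ordered attribute domains, class domain, and any cut points used).
#'
#' @param data A `discrete_dataset`.
#' @param path Output path for the delimited table.
#' @param domains_path Output path for the sidecar domain file (default:
#'   `path` + `.domains.yml`).
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(data, path,
                          domains_path = paste0(path, ".domains.yml"),
                          sep = ",") {
  raw <- as_raw_table(data)
  utils::write.table(raw$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  yaml::write_yaml(list(attributes = data$domains,
                        class = as.list(data$class_domain)), domains_path)
  invisible(path)
}

#' Write a schema to YAML
#' @param schema An `fkbn_schema`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(list(columns = lapply(schema$columns, function(col)
    list(name = col$name, kind = col$kind,
         missing = as.list(col$missing)))), path)
  invisible(path)
}
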