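# Laplace-smoothed counting, conditional tables, and log-space prediction.

test_that("count cache stores exact frequencies for the structure", {
  x <- cbind(c(1, 1, 2, 2, 1, 2, 1, 1, 2, 1),
             c(1, 2, 1, 2, 1, 2, 2, 1, 1, 2))
  cls <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2)
  data <- make_dataset(x, cls)
  counts <- count_frequencies(data, learn_nb(2))
  expect_equal(counts$class_counts, c(6, 4))
  expect_equal(counts$n_instances, 10)
  # empty parent set: counts reduce to F(c, x_i)
  expect_equal(dim(counts$tables[[1]]), c(2L, 2L))
  expect_equal(counts$tables[[1]][1, 1], sum(x[, 1] == 1 & cls == 1))

  # with a parent, unobserved triples count zero
  s <- bn_structure("kdb", 2, list(integer(0), 1L), 1L)
  c2 <- count_frequencies(data, s)
  expect_equal(dim(c2$tables[[2]]), c(2L, 2L, 2L))
  expect_equal(sum(c2$tables[[2]]), 10)
  expect_equal(c2$tables[[2]][2, 2, 2],
               sum(x[, 2] == 2 & x[, 1] == 2 & cls == 2))
})

test_that("Laplace estimates follow the add-one pattern", {
  # class never observed: P(c) = (0 + 1) / (10 + 2) = 1/12
  data <- make_dataset(matrix(rep(1:2, 5), ncol = 1), rep(1, 10), n_class = 2)
  model <- fit_classifier(data, "nb")
  expect_equal(exp(model$cpts$log_prior), c(11 / 12, 1 / 12))

  # single class, binary attribute with counts (3, 1):
  # smoothed conditional = ((3+1)/(4+2), (1+1)/(4+2)) = (4/6, 2/6)
  d2 <- make_dataset(matrix(c(1, 1, 1, 2), ncol = 1), rep(1, 4), n_class = 1)
  m2 <- fit_classifier(d2, "nb")
  expect_equal(exp(m2$cpts$log_cpt[[1]][, 1]), c(4 / 6, 2 / 6))
})

test_that("conditional rows always sum to one", {
  set.seed(601)
  for (algo in c("nb", "tan", "kdb", "fkbn")) {
    data <- random_small_dataset(n_attr = 4, n_levels = 3, n_rows = 40)
    model <- fit_classifier(data, algo, k = 2)
    for (i in seq_len(4)) {
      tab <- exp(model$cpts$log_cpt[[i]])
      sums <- apply(tab, seq_along(dim(tab))[-1], sum)
      expect_true(all(abs(sums - 1) < 1e-10))
    }
    expect_equal(sum(exp(model$cpts$log_prior)), 1, tolerance = 1e-12)
  }
})

test_that("posterior equals brute-force Bayes evaluation on a toy", {
  set.seed(602)
  data <- random_small_dataset(n_attr = 3, n_levels = 2, n_class = 2,
                               n_rows = 6)
  model <- fit_classifier(data, "nb")
  p <- posterior(model, data)
  for (r in seq_len(6))
    expect_equal(unname(p[r, ]), oracle_nb_posterior(data, data$x[r, ]),
                 tolerance = 1e-10)
  expect_equal(unname(rowSums(p)), rep(1, 6), tolerance = 1e-12)

  # single-class model: posterior is identically 1
  d1 <- make_dataset(matrix(1:4, ncol = 1), rep(1, 4), n_class = 1)
  m1 <- fit_classifier(d1, "nb")
  expect_equal(unname(posterior(m1, d1)[, 1]), rep(1, 4))
})

test_that("prediction is the posterior argmax with first-class ties", {
  # both classes see values 1 and 2 equally often: posterior is (0.5, 0.5)
  # for every instance, so the tie rule must return the first class
  d_tie <- make_dataset(matrix(c(1, 2, 1, 2), ncol = 1), c(1, 1, 2, 2))
  m_tie <- fit_classifier(d_tie, "nb")
  p_tie <- posterior(m_tie, matrix(1L, 1, 1))
  expect_equal(unname(p_tie[1, 1]), unname(p_tie[1, 2]))
  expect_equal(predict(m_tie, matrix(1L, 1, 1)), "c1")

  # a clear majority class wins
  d_maj <- make_dataset(matrix(1, 6, 1), c(1, 2, 2, 2, 2, 2))
  expect_equal(predict(fit_classifier(d_maj, "nb"), matrix(1L, 1, 1)), "c2")
})

test_that("smoothed estimates approach ML frequencies as data replicate", {
  x <- matrix(c(1, 1, 1, 2), ncol = 1)
  cls <- c(1, 1, 2, 2)
  ml <- 2 / 2  # P(x=1 | c=1) ML = 1
  errs <- sapply(c(1, 10, 1000), function(m) {
    data <- make_dataset(x[rep(1:4, m), , drop = FALSE], rep(cls, m))
    model <- fit_classifier(data, "nb")
    abs(exp(model$cpts$log_cpt[[1]][1, 1]) - ml)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("log-space posterior equals direct product evaluation", {
  set.seed(603)
  data <- random_small_dataset(n_attr = 3, n_levels = 3, n_rows = 25)
  model <- fit_classifier(data, "kdb", k = 2)
  p_log <- posterior(model, data)
  # direct product from the stored tables, no log accumulation
  for (r in 1:5) {
    direct <- sapply(seq_along(data$class_domain), function(c_idx) {
      pr <- exp(model$cpts$log_prior[c_idx])
      for (i in 1:3) {
        idx <- c(data$x[r, i], data$x[r, model$structure$parents[[i]]], c_idx)
        pr <- pr * exp(model$cpts$log_cpt[[i]][matrix(idx, 1)])
      }
      pr
    })
    expect_equal(unname(p_log[r, ]), direct / sum(direct), tolerance = 1e-10)
  }
})

test_that("instances with the reserved unseen level get valid posteriors", {
  df <- data.frame(cat = c("a", "b", "a", "b"), cls = c("x", "x", "y", "y"))
  sch <- schema(list(list(name = "cat", kind = "categorical"),
                     list(name = "cls", kind = "class")))
  train <- raw_table(df, sch)
  imp <- fit_imputation(train)
  disc <- fit_mdl_discretizer(train, imp)
  dtrain <- apply_preprocess(train, imp, disc)
  model <- fit_classifier(dtrain, "nb")
  test <- raw_table(data.frame(cat = "z", cls = "x"), sch)
  dtest <- apply_preprocess(test, imp, disc, domains = dtrain$domains)
  p <- posterior(model, dtest)
  expect_false(any(is.na(p)))
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("model files round-trip to an identical predictor", {
  set.seed(604)
  data <- random_small_dataset(n_attr = 4, n_levels = 3, n_rows = 50)
  model <- fit_classifier(data, "fkbn", k = 2)
  path <- tempfile(fileext = ".txt")
  write_model(model, path)
  model2 <- read_model(path)
  expect_equal(model2$structure, model$structure)
  expect_equal(posterior(model2, data), posterior(model, data))
  expect_identical(predict(model2, data), predict(model, data))
})
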