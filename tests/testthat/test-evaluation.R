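# Zero-one loss, stratified cross-validation, the exact sign test, and
# Friedman rank aggregation in both tie modes.

test_that("zero-one loss counts disagreements", {
  expect_equal(zero_one_loss(c("a", "b"), c("a", "b")), 0)
  expect_equal(zero_one_loss(c("a", "b"), c("b", "a")), 1)
  expect_equal(zero_one_loss(c("a", "b", "a", "b"), c("a", "a", "b", "b")),
               0.5)
  expect_error(zero_one_loss(c("a", "b"), "a"), "equal length")
})

test_that("sign test matches closed forms and brute-force summation", {
  expect_equal(sign_test(5, 5), 1)
  expect_equal(sign_test(10, 0), 2 * (1 / 2)^10)
  expect_equal(sign_test(0, 0), 1)

  # brute force over both tails for every split with m <= 25
  for (m in 1:25) for (wa in 0:m) {
    wb <- m - wa
    hi <- max(wa, wb)
    brute <- min(1, 2 * sum(stats::dbinom(hi:m, m, 0.5)))
    expect_equal(sign_test(wa, wb), brute, tolerance = 1e-12)
  }
})

test_that("exact-mode Friedman ranks order by loss with average-rank ties", {
  rt <- friedman_rank(matrix(c(0.1, 0.2, 0.3), 1))
  expect_equal(unname(rt$ranks[1, ]), c(1, 2, 3))

  rt2 <- friedman_rank(matrix(c(0.2, 0.1, 0.2, 0.4), 1))
  expect_equal(unname(rt2$ranks[1, ]), c(2.5, 1, 2.5, 4))

  # averages over datasets
  losses <- rbind(c(0.3, 0.1, 0.2), c(0.1, 0.2, 0.3))
  rt3 <- friedman_rank(losses)
  expect_equal(unname(rt3$avg_ranks), c(2, 1.5, 2.5))
})

test_that("signtest-mode ties group by transitive non-significance", {
  # distinct losses but no pairwise evidence of difference: all share 2.5
  W <- matrix(2L, 4, 4); diag(W) <- 0L
  rt <- friedman_rank(matrix(c(0.166, 0.164, 0.162, 0.19), 1),
                      tie_mode = "signtest", tie_evidence = list(W))
  expect_equal(unname(rt$ranks[1, ]), rep(2.5, 4))

  # one algorithm decisively worse (20 losses, 0 wins vs everyone):
  # it takes rank 4 alone, the rest share (1+2+3)/3 = 2
  W2 <- matrix(2L, 4, 4); diag(W2) <- 0L
  W2[1, 2:4] <- 0L; W2[2:4, 1] <- 20L
  rt2 <- friedman_rank(matrix(c(0.9, 0.2, 0.21, 0.22), 1),
                       tie_mode = "signtest", tie_evidence = list(W2))
  expect_equal(unname(rt2$ranks[1, ]), c(4, 2, 2, 2))

  # transitivity: A~B and B~C significant A!=C still merge into one group
  W3 <- matrix(0L, 3, 3)
  W3[1, 3] <- 20L; W3[3, 1] <- 0L      # A beats C decisively
  W3[1, 2] <- 3L; W3[2, 1] <- 2L       # A ~ B
  W3[2, 3] <- 3L; W3[3, 2] <- 2L       # B ~ C
  rt3 <- friedman_rank(matrix(c(0.1, 0.2, 0.3), 1), tie_mode = "signtest",
                       tie_evidence = list(W3))
  expect_equal(unname(rt3$ranks[1, ]), rep(2, 3))

  expect_error(friedman_rank(matrix(0.1, 1, 3), tie_mode = "signtest"),
               "win-count")
})

test_that("rank rows conserve A(A+1)/2 and permute with the columns", {
  set.seed(701)
  for (rep in 1:20) {
    A <- sample(2:6, 1); N <- sample(1:5, 1)
    losses <- matrix(stats::runif(N * A), N, A)
    losses[sample(length(losses), 3, replace = TRUE)] <- 0.5  # force ties
    rt <- friedman_rank(losses)
    expect_equal(unname(rowSums(rt$ranks)), rep(A * (A + 1) / 2, N))

    perm <- sample.int(A)
    rt_p <- friedman_rank(losses[, perm, drop = FALSE])
    expect_equal(unname(rt_p$ranks), unname(rt$ranks[, perm, drop = FALSE]))

    # signtest mode conserves the row sum too
    W <- lapply(seq_len(N), function(i) {
      m <- matrix(sample(0:8, A * A, replace = TRUE), A, A); diag(m) <- 0L; m
    })
    rt_s <- friedman_rank(losses, tie_mode = "signtest", tie_evidence = W)
    expect_equal(unname(rowSums(rt_s$ranks)), rep(A * (A + 1) / 2, N))
  }
})

test_that("lowering a loss never worsens that algorithm's exact-mode rank", {
  set.seed(702)
  for (rep in 1:15) {
    losses <- matrix(stats::runif(4), 1, 4)
    rt <- friedman_rank(losses)
    j <- sample.int(4, 1)
    better <- losses
    better[1, j] <- better[1, j] * 0.5
    rt2 <- friedman_rank(better)
    expect_lte(rt2$ranks[1, j], rt$ranks[1, j])
  }
})

test_that("pairwise win counting discards double-correct/double-wrong", {
  ra <- list(correct = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  rb <- list(correct = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  W <- pairwise_wins(list(ra, rb))
  expect_equal(W[1, 2], 2L)   # instances 2 and 5
  expect_equal(W[2, 1], 1L)   # instance 3
})

test_that("cross-validation is deterministic, stratified, and leak-free", {
  set.seed(703)
  spec <- generator_spec(n_attributes = 5, domain_sizes = 3, n_classes = 2,
                         k = 1, sharpness = 0.5, n_rows = 150, seed = 31)
  planted <- random_structure(spec)
  cpts <- random_cpts(planted, spec)
  raw <- as_raw_table(sample_dataset(planted, cpts, 150, seed = 32))

  r1 <- cross_validate(raw, "nb", folds = 5, seed = 9)
  r2 <- cross_validate(raw, "nb", folds = 5, seed = 9)
  expect_identical(r1$fold_losses, r2$fold_losses)
  expect_identical(r1$correct, r2$correct)
  expect_length(r1$fold_losses, 5)
  expect_true(all(r1$fold_losses >= 0 & r1$fold_losses <= 1))
  expect_equal(r1$mean_loss, mean(r1$fold_losses))

  # a different seed reshuffles folds
  r3 <- cross_validate(raw, "nb", folds = 5, seed = 10)
  expect_false(identical(r1$fold_losses, r3$fold_losses))

  # a class with a single instance cannot survive 5-fold training splits
  df <- data.frame(f = letters[1:10],
                   cls = c(rep("x", 9), "y"))
  tiny <- raw_table(df, schema(list(list(name = "f", kind = "categorical"),
                                    list(name = "cls", kind = "class"))))
  expect_error(cross_validate(tiny, "nb", folds = 5, seed = 1), "lacks")
})

test_that("perfectly separable data yields zero cross-validated loss", {
  df <- data.frame(f = rep(c("p", "q"), each = 25),
                   cls = rep(c("x", "y"), each = 25))
  sch <- schema(list(list(name = "f", kind = "categorical"),
                     list(name = "cls", kind = "class")))
  for (algo in c("nb", "fkbn")) {
    r <- cross_validate(raw_table(df, sch), algo, k = 2, folds = 10, seed = 4)
    expect_equal(r$mean_loss, 0)
    expect_equal(r$sd, 0)
  }
})

test_that("pure-noise attributes give loss near the minority rate", {
  # class marginal 70/30, attributes carry no signal: NB converges to the
  # majority rule, whose risk is 0.30
  set.seed(704)
  losses <- sapply(1:3, function(s) {
    n <- 600
    df <- data.frame(a = sample(letters[1:3], n, TRUE),
                     b = sample(letters[1:3], n, TRUE),
                     cls = rep(c("maj", "min"), times = c(0.7 * n, 0.3 * n)))
    cross_validate(raw_table(df, schema(list(
      list(name = "a", kind = "categorical"),
      list(name = "b", kind = "categorical"),
      list(name = "cls", kind = "class")))), "nb", folds = 10,
      seed = s)$mean_loss
  })
  se <- sqrt(0.3 * 0.7 / 600)
  expect_lt(abs(mean(losses) - 0.30), 3 * se)
})

test_that("loss/rank matrices round-trip through delimited text", {
  m <- example_rank_matrix()
  path <- tempfile(fileext = ".csv")
  write_matrix_file(m, path)
  expect_equal(read_matrix_file(path), m)
})
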