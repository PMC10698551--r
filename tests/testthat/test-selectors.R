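two_blob_data <- function(n = 60, p = 10, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n)
  X[y == "b", 1] <- X[y == "b", 1] + sep
  X[y == "b", 2] <- X[y == "b", 2] + sep
  list(X = X, y = y)
}

test_that("the selector bank has 15 uniquely named members", {
  bank <- selector_bank()
  expect_length(bank, 15L)
  expect_false(anyDuplicated(names(bank)) > 0)
  expect_true(all(c("MCFS", "UDFS", "trace_ratio") %in% names(bank)))
  expect_error(run_selector("nope", matrix(1:4, 2)), "unknown selector")
})

test_that("trace-ratio selection matches the exhaustive subset oracle", {
  for (s in 1:4) {
    set.seed(400 + s)
    n <- 30; p <- 8; k <- 3
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * p), n)
    X[y == "b", 1:2] <- X[y == "b", 1:2] + rnorm(2, sd = 2)
    res <- trace_ratio_select(X, y, k)
    oracle <- oracle_trace_ratio_best(X, y, k)
    achieved <- sum(oracle$a[res$selected]) / sum(oracle$b[res$selected])
    expect_equal(achieved, oracle$ratio, tolerance = 1e-8)
    expect_equal(res$lambda, achieved, tolerance = 1e-6)
  }
})

test_that("trace-ratio handles separable and degenerate cases", {
  set.seed(5)
  n <- 20
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 5, sd = 1), n)
  # feature 3: between-class variance, zero within-class variance
  X[, 3] <- ifelse(y == "a", 0, 1)
  res <- trace_ratio_select(X, y, 1)
  expect_equal(res$selected, 3L)
  # all features identical -> first k by tie-break
  Xsame <- matrix(rep(rnorm(n), 5), n)
  res2 <- trace_ratio_select(Xsame, y, 3)
  expect_equal(res2$selected, 1:3)
  # k = p: lambda equals the global Fisher ratio
  res3 <- trace_ratio_select(X, y, 5)
  sc <- radfuse:::scatter_diagonals(X, y)
  expect_equal(res3$lambda, sum(sc$between) / sum(sc$within),
               tolerance = 1e-8)
  expect_error(trace_ratio_select(Xsame * 0, y, 2), "within-class scatter")
})

test_that("MCFS recovers cluster-informative features", {
  bd <- two_blob_data(n = 60, p = 10, sep = 4, seed = 6)
  res <- mcfs_select(scale(bd$X), k = 2, n_clusters = 3, seed = 1)
  expect_setequal(res$selected, c(1L, 2L))
  expect_error(mcfs_select(bd$X, 2, n_clusters = 60), "n_clusters")
  # duplicate columns tie-break by index
  Xd <- cbind(bd$X[, 1], bd$X[, 1], bd$X[, 1])
  resd <- mcfs_select(scale(Xd), k = 2, n_clusters = 2, seed = 1)
  expect_equal(resd$scores[1], resd$scores[2])
  expect_equal(resd$selected, c(1L, 2L))
})

test_that("UDFS decreases its objective and recovers informative features", {
  hits <- vapply(1:20, function(s) {
    bd <- two_blob_data(n = 44, p = 10, sep = 4, seed = 600 + s)
    res <- udfs_select(scale(bd$X), k = 3, gamma = 0.1, seed = s,
                       n_comp = 2)
    expect_true(all(diff(res$objective) <= 1e-8))
    sum(c(1, 2) %in% res$selected)
  }, numeric(1))
  expect_gte(sum(hits == 2), 18)
  # infinite regularization collapses every score
  res_inf <- udfs_select(matrix(rnorm(30), 10), k = 2, gamma = Inf)
  expect_true(all(res_inf$scores == 0))
  expect_equal(res_inf$selected, 1:2)
})

test_that("fisher scoring matches the direct formula and ranking", {
  bd <- two_blob_data(seed = 8)
  res <- run_selector("fisher_score", bd$X, bd$y, k = 5, seed = 1)
  Xs <- scale(bd$X)
  direct <- vapply(seq_len(ncol(Xs)), function(j) {
    num <- 0; den <- 0
    for (cl in unique(bd$y)) {
      idx <- bd$y == cl
      num <- num + sum(idx) * (mean(Xs[idx, j]) - mean(Xs[, j]))^2
      den <- den + sum((Xs[idx, j] - mean(Xs[idx, j]))^2)
    }
    num / den
  }, numeric(1))
  expect_equal(order(-res$scores), order(-direct))
})

test_that("selectors are deterministic and scale-invariant", {
  bd <- two_blob_data(seed = 9)
  scales <- runif(10, 0.1, 50)
  shifts <- rnorm(10, sd = 10)
  X2 <- sweep(sweep(bd$X, 2, scales, `*`), 2, shifts, `+`)
  for (nm in setdiff(names(selector_bank()), "variance")) {
    r1 <- run_selector(nm, bd$X, bd$y, k = 4, seed = 11)
    r1b <- run_selector(nm, bd$X, bd$y, k = 4, seed = 11)
    expect_identical(r1[c("scores", "selected")],
                     r1b[c("scores", "selected")])
    r2 <- run_selector(nm, X2, bd$y, k = 4, seed = 11)
    expect_equal(r1$selected, r2$selected,
                 label = paste("selected set of", nm))
  }
})

test_that("the variance selector scores a constant matrix as zero", {
  X <- matrix(5, 20, 4)
  res <- run_selector("variance", X, NULL, k = 2, seed = 1)
  expect_true(all(res$scores == 0))
  expect_equal(res$selected, 1:2)
})
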