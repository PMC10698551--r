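make_views <- function(n = 60, p = 4, S = 3, seed = 1, effect = 1) {
  set.seed(seed)
  y <- rep(c("neg", "pos"), length.out = n)
  v <- lapply(seq_len(S), function(s) {
    m <- matrix(rnorm(n * p), n)
    m[y == "pos", 1] <- m[y == "pos", 1] + effect / s
    colnames(m) <- paste0("f", seq_len(p))
    m
  })
  names(v) <- c("ADC", "DWI600", "T2WI", "DCE1", "DCE2")[seq_len(S)]
  list(views = v, y = y)
}

test_that("binary tasks retain one discriminant dimension per feature", {
  mv <- make_views()
  ft <- fusion_fit(mv$views, mv$y)
  expect_equal(ft$r, 1L)
  fused <- predict(ft, mv$views)
  expect_equal(dim(fused), c(60L, 4L))
  expect_equal(colnames(fused), paste0("f", 1:4))
})

test_that("fused training features have unit between-class scatter", {
  mv <- make_views(n = 80, p = 5, S = 3, seed = 2)
  for (strategy in c("featurewise", "viewlevel")) {
    ft <- fusion_fit(mv$views, mv$y, strategy = strategy)
    fused <- predict(ft, mv$views)
    for (j in seq_len(ncol(fused)))
      expect_equal(between_scatter_1d(fused[, j], mv$y), 1,
                   tolerance = 1e-8)
  }
})

test_that("two identical views fuse to a rescaling of the single view", {
  mv <- make_views(n = 50, p = 3, S = 1, seed = 3)
  v2 <- list(ADC = mv$views[[1]], DWI600 = mv$views[[1]])
  ft <- fusion_fit(v2, mv$y)
  fused <- predict(ft, v2)
  for (j in 1:3) {
    r <- suppressWarnings(stats::cor(fused[, j], mv$views[[1]][, j]))
    expect_equal(abs(r), 1, tolerance = 1e-8)
  }
})

test_that("applying a transform is deterministic, idempotent and row-equivariant", {
  mv <- make_views(seed = 4)
  ft <- fusion_fit(mv$views, mv$y)
  f1 <- predict(ft, mv$views)
  expect_identical(f1, predict(ft, mv$views))
  # single held-out lesion: no batch dependence
  one <- lapply(mv$views, function(v) v[5, , drop = FALSE])
  expect_equal(unname(predict(ft, one)), unname(f1[5, , drop = FALSE]))
  # permuted rows in -> permuted rows out
  perm <- sample(nrow(f1))
  fp <- predict(ft, lapply(mv$views, function(v) v[perm, , drop = FALSE]))
  expect_equal(unname(fp), unname(f1[perm, , drop = FALSE]))
})

test_that("the fitted transform depends on training rows only", {
  mv <- make_views(n = 80, seed = 5)
  tr <- 1:60
  fit1 <- fusion_fit(lapply(mv$views, function(v) v[tr, , drop = FALSE]),
                     mv$y[tr])
  # mangle the held-out rows entirely; the fit must not change
  views2 <- lapply(mv$views, function(v) { v[61:80, ] <- 999; v })
  fit2 <- fusion_fit(lapply(views2, function(v) v[tr, , drop = FALSE]),
                     mv$y[tr])
  expect_identical(fit1, fit2)
})

test_that("degenerate inputs are refused with a clear condition", {
  mv <- make_views()
  expect_error(fusion_fit(mv$views[1], mv$y), "at least 2 views")
  expect_error(fusion_fit(mv$views, rep("one", 60)), "at least 2 classes")
  same <- lapply(mv$views, function(v) { v[] <- rep(v[1, ], each = 60); v })
  expect_error(fusion_fit(same, mv$y), "between-class scatter")
})

test_that("viewlevel alignment strengthens within-class cross-view correlation", {
  mv <- make_views(n = 100, p = 6, S = 2, seed = 6, effect = 1.5)
  ft <- fusion_fit(mv$views, mv$y, strategy = "viewlevel")
  Z <- lapply(seq_along(mv$views), function(i) {
    s <- ft$std[[i]]
    sweep(sweep(mv$views[[i]], 2, s$mean), 2, s$sd, `/`) %*%
      ft$proj[[i]]
  })
  st <- ft$steps[[1]]
  mean_wc_cor <- function(A, B) {
    vals <- c()
    for (k in unique(mv$y)) {
      idx <- mv$y == k
      for (d in seq_len(min(ncol(A), ncol(B))))
        vals <- c(vals, stats::cor(A[idx, d], B[idx, d]))
    }
    mean(abs(vals))
  }
  before <- mean_wc_cor(Z[[1]], Z[[2]])
  after <- mean_wc_cor(Z[[1]] %*% st$u, Z[[2]] %*% st$v)
  expect_gte(after, before - 1e-12)
})

test_that("channel combinations enumerate deterministically", {
  expect_length(enumerate_combinations(c("a", "b", "c", "d")), 11L)
  expect_length(enumerate_combinations(c("a", "b")), 1L)
  expect_length(enumerate_combinations(c("a", "b", "c")), 4L)
  cmb <- enumerate_combinations(c("w", "x", "y", "z"))
  expect_equal(cmb[[1]], c("w", "x"))
  expect_equal(cmb[[11]], c("w", "x", "y", "z"))
  expect_error(enumerate_combinations(c("a", "a", "b")), "duplicate")
})

test_that("serialized transforms round-trip their configuration", {
  mv <- make_views(seed = 7)
  ft <- fusion_fit(mv$views, mv$y)
  path <- tempfile(fileext = ".json")
  write_fusion_json(ft, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$strategy, "featurewise")
  expect_equal(unlist(back$channels), ft$channels)
  unlink(path)
})
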