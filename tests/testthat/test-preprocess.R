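test_that("constant volumes normalize to the range midpoint", {
  v <- array(5, c(4, 4, 4))
  m <- array(TRUE, c(4, 4, 4))
  pp <- preprocess(v, m, iso_config(), spacing = c(1, 1, 1))
  expect_true(all(pp$volume == 127.5))
})

test_that("a volume already at target spacing is only renormalized", {
  set.seed(1)
  v <- array(runif(64, 10, 20), c(4, 4, 4))
  m <- array(TRUE, c(4, 4, 4))
  pp <- preprocess(v, m, iso_config(), spacing = c(1, 1, 1))
  expect_identical(dim(pp$volume), dim(v))
  # monotone affine map onto [0, 255]
  expect_equal(range(pp$volume), c(0, 255))
  expect_equal(stats::cor(as.vector(v), as.vector(pp$volume)), 1)
})

test_that("resampling grid arithmetic follows ceil(extent / spacing)", {
  v <- array(1:8, c(2, 2, 2))
  m <- array(TRUE, c(2, 2, 2))
  pp <- preprocess(v, m, iso_config(), spacing = c(2, 2, 2))
  # extent 4 mm per axis at 1 mm target -> 4 voxels per axis
  expect_identical(dim(pp$volume), c(4L, 4L, 4L))
  expect_identical(dim(pp$mask), c(4L, 4L, 4L))
})

test_that("a vanishing mask raises an error naming the lesion", {
  v <- array(runif(64), c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  cfg <- preprocess_config(target_spacing = c(4, 4, 4), n_bins = 8)
  expect_error(preprocess(v, m, cfg, spacing = c(1, 1, 1),
                          lesion_id = "L0042"),
               "L0042")
})

test_that("discretization puts the upper edge in the last bin", {
  v <- array(0, c(2, 2, 1)); v[, , 1] <- c(0, 1, 2, 3)
  m <- array(TRUE, c(2, 2, 1))
  g <- radfuse:::discretize_mask(v, m, 2L)
  expect_equal(sort(unique(as.vector(g))), c(1L, 2L))
  expect_equal(g[2, 2, 1], 2L)   # maximum maps into bin 2, not bin 3
  # constant region -> single bin
  g2 <- radfuse:::discretize_mask(array(7, c(2, 2, 1)), m, 8L)
  expect_true(all(g2 == 1L))
})
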