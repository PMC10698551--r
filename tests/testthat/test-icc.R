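test_that("identical non-constant ratings give ICC 1", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_two_rater(x, x), 1)
  expect_equal(icc_two_rater(x, x, model = "ICC3"), 1)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  set.seed(21)
  for (i in 1:5) {
    a <- rnorm(30)
    b <- a + rnorm(30, sd = 0.5) + 0.3   # noise + systematic offset
    expect_equal(icc_two_rater(a, b), oracle_icc21_aov(a, b),
                 tolerance = 1e-10)
  }
  # a constant offset penalizes absolute agreement but not consistency
  a <- rnorm(50)
  expect_lt(icc_two_rater(a, a + 1), 1)
  expect_equal(icc_two_rater(a, a + 1, model = "ICC3"), 1, tolerance = 1e-9)
})

test_that("independent raters give near-zero ICC", {
  iccs <- vapply(1:10, function(s) {
    set.seed(300 + s)
    icc_two_rater(rnorm(200), rnorm(200))
  }, numeric(1))
  expect_true(all(abs(iccs) < 0.15))
})

test_that("degenerate and invalid inputs are handled", {
  expect_true(is.na(icc_two_rater(rep(1, 5), rep(1, 5))))
  expect_error(icc_two_rater(1:2, 1:2), "at least 3")
  expect_error(icc_two_rater(1:5, 1:4), "different lesions")
  expect_error(icc_two_rater(c(1, 2, NA), c(1, 2, 3)), "non-finite")
})

make_rater_tables <- function(n = 40, noise = 0, seed = 1) {
  spec <- cohort_spec(n_per_class = c("HR+" = n / 2, HEBC = n / 4,
                                      TNBC = n / 4),
                      test_size = n / 4, seed = seed)
  ta <- generate_cohort(spec, channels = "ADC")$ADC
  tb <- ta
  if (noise > 0) {
    set.seed(seed + 1)
    fm <- feature_matrix(tb)
    fm <- fm + matrix(rnorm(length(fm), sd = noise * apply(fm, 2, sd)),
                      nrow(fm))
    tb[, colnames(fm)] <- fm
  }
  list(a = ta, b = tb)
}

test_that("feature filtering retains exactly the reliable features", {
  tt <- make_rater_tables(40)
  res <- filter_features(tt$a, tt$b)
  expect_equal(nrow(res$report), 109L)
  expect_true(all(res$report$retained))
  expect_equal(ncol(res$table), 2 + 109)
  # replace one feature by rater-independent noise -> dropped
  tb2 <- tt$b
  set.seed(5)
  tb2$glcm_Contrast <- rnorm(nrow(tb2))
  res2 <- filter_features(tt$a, tb2)
  expect_false(res2$report$retained[res2$report$feature == "glcm_Contrast"])
  expect_true(sum(!res2$report$retained) == 1)
  # threshold 1: only bit-identical columns survive
  res3 <- filter_features(tt$a, tb2, threshold = 1)
  expect_equal(sum(res3$report$retained), 108L)
  # mismatched registries are refused
  ta_sub <- tt$a[, -3]
  class(ta_sub) <- class(tt$a)
  expect_error(filter_features(ta_sub, tt$b), "registries")
})

test_that("ICC recovers the generative reliability at n = 500", {
  # a = s + e1, b = s + e2 with var(s) = 1, var(e) chosen per target ICC
  for (target in c(0.5, 0.8)) {
    est <- vapply(1:4, function(seed) {
      set.seed(800 + seed)
      n <- 500
      s <- rnorm(n)
      ve <- (1 - target) / target
      icc_two_rater(s + rnorm(n, sd = sqrt(ve)), s + rnorm(n, sd = sqrt(ve)))
    }, numeric(1))
    expect_lt(abs(mean(est) - target), 0.05)
  }
})
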