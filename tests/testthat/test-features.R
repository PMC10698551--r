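test_that("the default registry has 109 features split 19/15/75", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 109L)
  counts <- table(reg$family)
  expect_equal(as.integer(counts[c("intensity", "morphology", "texture")]),
               c(19L, 15L, 75L))
  expect_false(anyDuplicated(reg$name) > 0)
  needed <- c("shape_SphericalDisproportion", "shape_MinorAxisLength",
              "shape_Sphericity", "glcm_Correlation", "glcm_Imc2",
              "firstorder_Entropy", "firstorder_MeanAbsoluteDeviation",
              "firstorder_Uniformity", "glcm_ClusterTendency",
              "firstorder_RobustMeanAbsoluteDeviation",
              "firstorder_90Percentile", "firstorder_RootMeanSquared")
  expect_true(all(needed %in% reg$name))
})

test_that("constant-intensity regions give entropy 0 and uniformity 1", {
  v <- array(3, c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
  is <- make_image_set(list(ADC = v), m)
  fv <- extract_features(is, feature_registry("firstorder"), iso_config())
  expect_equal(fv$ADC$values[["firstorder_Entropy"]], 0)
  expect_equal(fv$ADC$values[["firstorder_Uniformity"]], 1)
})

test_that("cube morphology matches the closed forms", {
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  is <- make_image_set(list(ADC = array(stats::runif(216), c(6, 6, 6))), m)
  fv <- extract_features(is, feature_registry("shape"), iso_config())
  v <- fv$ADC$values
  expect_equal(v[["shape_Sphericity"]], (36 * pi)^(1 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(v[["shape_Sphericity"]] * v[["shape_SphericalDisproportion"]],
               1, tolerance = 1e-12)
  expect_equal(v[["shape_VoxelVolume"]], 64)
  expect_equal(v[["shape_SurfaceArea"]], 96)
})

test_that("a two-level stripe has GLCM correlation -1 along its normal", {
  d <- c(8, 8, 8)
  v <- array(rep(c(0, 1), length.out = d[1]), dim = d)  # varies along x
  g <- array(NA_integer_, d)
  g[] <- oracle_discretize(as.vector(v), 2)
  feats <- radfuse:::glcm_feature_values(
    radfuse:::glcm_counts(g, c(1L, 0L, 0L), 2L) /
      sum(radfuse:::glcm_counts(g, c(1L, 0L, 0L), 2L)))
  expect_equal(unname(feats["Correlation"]), -1, tolerance = 1e-12)
})

test_that("percentiles interpolate linearly between order statistics", {
  vals <- as.numeric(1:10)
  fo <- radfuse:::firstorder_features(vals, oracle_discretize(vals, 32), 1)
  expect_equal(fo[["firstorder_90Percentile"]], 9.1)
  expect_equal(fo[["firstorder_10Percentile"]], 1.9)
})

test_that("GLCM features match the brute-force co-occurrence oracle", {
  for (s in 1:3) {
    set.seed(100 + s)
    d <- c(8, 8, 8)
    v <- array(stats::rnorm(prod(d)), d)
    m <- array(stats::runif(prod(d)) < 0.7, d)
    m[4, 4, 4] <- TRUE
    is <- make_image_set(list(ADC = v), m)
    fv <- extract_features(is, feature_registry("glcm"), iso_config(8))
    pp <- preprocess(v, m, iso_config(8), spacing = c(1, 1, 1))
    g <- array(NA_integer_, d)
    g[pp$mask] <- oracle_discretize(pp$volume[pp$mask], 8)
    oracle <- oracle_glcm_features(oracle_glcm_P(g, 8))
    expect_equal(fv$ADC$values[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("aggregated features are invariant under axis permutations", {
  set.seed(11)
  d <- c(7, 7, 7)
  v <- array(stats::rnorm(prod(d)), d)
  m <- array(stats::runif(prod(d)) < 0.75, d)
  reg <- feature_registry(c("firstorder", "glcm", "glrlm", "glszm",
                            "ngtdm"))
  f1 <- extract_features(make_image_set(list(ADC = v), m), reg,
                         iso_config(6))$ADC$values
  vp <- aperm(v, c(2, 3, 1)); mp <- aperm(m, c(2, 3, 1))
  f2 <- extract_features(make_image_set(list(ADC = vp), mp), reg,
                         iso_config(6))$ADC$values
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("features are invariant to affine rescaling of raw intensities", {
  set.seed(12)
  d <- c(7, 7, 7)
  v <- array(stats::rnorm(prod(d)), d)
  m <- array(stats::runif(prod(d)) < 0.75, d)
  reg <- feature_registry()
  f1 <- extract_features(make_image_set(list(ADC = v), m), reg,
                         iso_config(6))$ADC$values
  f2 <- extract_features(make_image_set(list(ADC = 3.7 * v + 11), m), reg,
                         iso_config(6))$ADC$values
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("tiny masks and unknown channels are rejected", {
  v <- array(1:27, c(3, 3, 3))
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_error(extract_features(make_image_set(list(ADC = v), m),
                                feature_registry("firstorder"),
                                iso_config()),
               "fewer than 2")
  m[1, 1, 1] <- TRUE
  expect_error(extract_features(make_image_set(list(XX = v), m),
                                feature_registry("firstorder"),
                                iso_config()),
               "unknown channel")
})

test_that("feature tables are assembled in sorted registry order", {
  reg <- feature_registry("firstorder")
  m <- array(TRUE, c(3, 3, 3))
  mk <- function(id, seed) {
    set.seed(seed)
    v <- array(stats::rnorm(27), c(3, 3, 3))
    extract_features(make_image_set(list(ADC = v), m, id = id), reg,
                     iso_config())$ADC
  }
  vecs <- list(mk("b", 2), mk("a", 3), mk("c", 4))
  labels <- c(a = "HR+", b = "TNBC", c = "HEBC")
  tab <- table_from_vectors(vecs, labels)
  expect_s3_class(tab, "feature_table")
  expect_equal(tab$lesion_id, c("a", "b", "c"))
  expect_equal(tab$class, c("HR+", "TNBC", "HEBC"))
  expect_equal(colnames(tab)[-(1:2)], reg$name)
  expect_error(table_from_vectors(c(vecs, vecs[1]), labels), "duplicate")
  expect_error(table_from_vectors(vecs, labels[-1]), "missing class label")
  empty <- table_from_vectors(list(), labels)
  expect_equal(nrow(empty), 0L)
})
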