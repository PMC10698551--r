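test_that("default cohort spec reproduces the study's class structure", {
  spec <- cohort_spec()
  expect_equal(sum(spec$n_per_class), 466L)
  expect_equal(unname(attr(spec, "names_n")), c(336L, 76L, 54L))
  expect_equal(spec$test_size, 129L)
  tabs <- generate_cohort(spec, channels = c("ADC", "DWI600"))
  for (tb in tabs) {
    expect_equal(nrow(tb), 466L)
    expect_equal(as.integer(table(tb$class)[c("HR+", "HEBC", "TNBC")]),
                 c(336L, 76L, 54L))
    expect_equal(ncol(tb), 2 + 109)
    expect_false(anyNA(tb))
  }
})

test_that("generation is byte-identical for a fixed seed", {
  spec <- cohort_spec(n_per_class = c("HR+" = 20L, HEBC = 8L, TNBC = 8L),
                      test_size = 9L, seed = 424242L)
  t1 <- generate_cohort(spec, channels = c("ADC", "T2WI"))
  t2 <- generate_cohort(spec, channels = c("ADC", "T2WI"))
  expect_identical(t1, t2)
  l1 <- generate_lesion(spec, "L0003", "TNBC", channels = "ADC")
  l2 <- generate_lesion(spec, "L0003", "TNBC", channels = "ADC")
  expect_identical(l1, l2)
})

test_that("images mode produces coherent lesion sets", {
  spec <- cohort_spec(n_per_class = c("HR+" = 2L, HEBC = 2L, TNBC = 2L),
                      test_size = 2L, seed = 7L)
  les <- generate_cohort(spec, mode = "images",
                         channels = c("ADC", "DCE1"))
  expect_length(les, 6L)
  for (l in les) {
    expect_s3_class(l, "lesion_image_set")
    expect_gt(sum(l$mask), 0)
    for (v in l$channels) expect_identical(dim(v), dim(l$mask))
  }
  expect_error(generate_cohort(spec, channels = "BOGUS"), "unknown channel")
})

test_that("stratified split reproduces 337/129 and stays within one lesion", {
  labels <- rep(c("HR+", "HEBC", "TNBC"), c(336, 76, 54))
  sp <- split_cohort(labels, 129, seed = 3)
  expect_length(sp$train_ids, 337L)
  expect_length(sp$test_ids, 129L)
  expect_setequal(c(sp$train_ids, sp$test_ids), seq_along(labels))
  frac <- 129 / 466
  for (cl in unique(labels)) {
    n_cl <- sum(labels == cl)
    in_test <- sum(labels[sp$test_ids] == cl)
    expect_lte(abs(in_test - n_cl * frac), 1)
  }
  expect_identical(sp, split_cohort(labels, 129, seed = 3))
  expect_error(split_cohort(labels, 0, seed = 1), "positive")
  expect_error(split_cohort(rep("HR+", 10), 3, seed = 1), "two classes")
  expect_error(split_cohort(c("a", rep("b", 9)), 3, seed = 1),
               "at least 2 members")
})

test_that("rater-pair perturbation behaves at both extremes", {
  m <- ball_mask(20)
  rp0 <- make_rater_pair(m, 0, seed = 1)
  expect_identical(rp0$mask_a, rp0$mask_b)
  rp1 <- make_rater_pair(m, 1, seed = 1)
  dice <- 2 * sum(rp1$mask_a & rp1$mask_b) /
    (sum(rp1$mask_a) + sum(rp1$mask_b))
  expect_gt(dice, 0.8)
  expect_false(identical(rp1$mask_a, rp1$mask_b))
  expect_error(make_rater_pair(array(FALSE, c(3, 3, 3)), 1, seed = 1),
               "empty")
})

test_that("TNBC lesions carry lower ADC intensity entropy than non-TNBC", {
  # feature-table route: 20 independent cohorts
  ok <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_per_class = c("HR+" = 60L, HEBC = 20L,
                                        TNBC = 30L),
                        test_size = 20L, seed = 9000L + s)
    tb <- generate_cohort(spec, channels = "ADC")$ADC
    mean(tb$firstorder_Entropy[tb$class == "TNBC"]) <
      mean(tb$firstorder_Entropy[tb$class != "TNBC"])
  }, logical(1))
  expect_gte(sum(ok), 19)
})

test_that("extracted ADC entropy shows the TNBC direction in images mode", {
  reg <- feature_registry("firstorder")
  ok <- vapply(1:2, function(s) {
    spec <- cohort_spec(n_per_class = c("HR+" = 25L, HEBC = 5L,
                                        TNBC = 20L),
                        test_size = 10L, seed = 1700L + s)
    les <- generate_cohort(spec, mode = "images", channels = "ADC")
    ent <- vapply(les, function(l)
      extract_features(l, reg)$ADC$values[["firstorder_Entropy"]],
      numeric(1))
    cls <- vapply(les, function(l) l$class_label, character(1))
    mean(ent[cls == "TNBC"]) < mean(ent[cls != "TNBC"])
  }, logical(1))
  expect_true(all(ok))
})

test_that("TNBC median mask diameter matches the cohort description", {
  spec <- cohort_spec(seed = 20260925L)
  d <- vapply(1:40, function(i) {
    l <- generate_lesion(spec, sprintf("DT%03d", i), "TNBC",
                         channels = character(0))
    pts <- radfuse:::boundary_points(l$mask, l$voxel_spacing)
    radfuse:::max_pairwise_dist(pts)
  }, numeric(1))
  expect_gt(stats::median(d), 26 * 0.8)
  expect_lt(stats::median(d), 26 * 1.2)
})
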