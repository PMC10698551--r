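#' Two-rater intraclass correlation coefficient
#'
#' ICC for a two-rater, single-measurement reliability design, computed from
#' the two-way ANOVA mean-squares decomposition. The default model is
#' ICC(2,1) -- two-way random effects, absolute agreement, single rater --
#' so a systematic delineation bias between raters lowers the coefficient.
#' ICC(3,1) (consistency) is available as an alternative.
#'
#' @param values_a,values_b one measurement per lesion from each rater;
#'   equal lengths >= 3, finite.
#' @param model "ICC2" (absolute agreement, default) or "ICC3" (consistency).
#' @return a single ICC value, or `NA` when the total variance is zero
#'   (undefined reliability; treated downstream as "not retained").
#' @export
icc_two_rater <- function(values_a, values_b, model = c("ICC2", "ICC3")) {
  model <- match.arg(model)
  n <- length(values_a)
  if (length(values_b) != n) stop_radfuse("raters measured different lesions")
  if (n < 3) stop_radfuse("need at least 3 lesions")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop_radfuse("non-finite feature values")
  x <- cbind(values_a, values_b)
  k <- 2
  grand <- mean(x)
  if (sum((x - grand)^2) <= 0) return(NA_real_)
  rm <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  mse <- sum((x - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + grand)^2) /
    ((n - 1) * (k - 1))
  if (model == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Filter a feature table by inter-rater reliability
#'
#' Computes the per-feature two-rater ICC between two delineations of the
#' same lesions and keeps the features whose ICC exceeds the threshold
#' (strictly; undefined ICCs are never retained). At the degenerate
#' threshold of 1 only perfect-agreement features survive.
#'
#' @param table_a,table_b `feature_table`s from the two raters; identical
#'   lesions and feature registry.
#' @param threshold retention threshold (default 0.75).
#' @param model passed to [icc_two_rater()].
#' @return list with `table` (the filtered `table_a`) and `report`, a data
#'   frame with columns `feature`, `icc`, `retained` covering every feature.
#' @export
filter_features <- function(table_a, table_b, threshold = 0.75,
                            model = "ICC2") {
  fa <- feature_matrix(table_a); fb <- feature_matrix(table_b)
  if (!identical(colnames(fa), colnames(fb)))
    stop_radfuse("feature registries of the two raters differ")
  if (!identical(table_a$lesion_id, table_b$lesion_id))
    stop_radfuse("the two raters cover different lesions")
  icc <- vapply(seq_len(ncol(fa)), function(j)
    icc_two_rater(fa[, j], fb[, j], model = model), numeric(1))
  perfect <- vapply(seq_len(ncol(fa)), function(j)
    isTRUE(all.equal(fa[, j], fb[, j])) &&
      stats::var(fa[, j]) > 0, logical(1))
  retained <- !is.na(icc) & (icc > threshold | (threshold >= 1 & perfect))
  report <- data.frame(feature = colnames(fa), icc = icc,
                       retained = retained, stringsAsFactors = FALSE)
  keep <- c("lesion_id", "class", colnames(fa)[retained])
  out <- table_a[, intersect(keep, colnames(table_a)), drop = FALSE]
  attr(out, "channel") <- attr(table_a, "channel")
  class(out) <- class(table_a)
  list(table = out, report = report)
}

#' Write an ICC report to CSV
#' @param report data frame from [filter_features()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_icc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
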