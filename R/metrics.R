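#' Area under the ROC curve via the rank statistic
#'
#' Mann-Whitney formulation with midranks, so ties contribute 1/2; equals
#' the proportion of positive/negative pairs ordered correctly.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels two-level factor; second level is the positive class,
#'   or a logical/0-1 vector of positives.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.factor(labels)) labels == levels(labels)[2] else labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_radfuse("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Threshold metrics at P(positive) >= 0.5.
threshold_metrics <- function(prob, labels, threshold = 0.5) {
  pos <- labels == levels(labels)[2]
  pred <- prob >= threshold
  c(acc = mean(pred == pos),
    sen = if (any(pos)) mean(pred[pos]) else NA_real_,
    spe = if (any(!pos)) mean(!pred[!pos]) else NA_real_)
}

#' Paired Wilcoxon signed-rank test
#'
#' Classic convention: zero differences are dropped; ranks of |differences|
#' use midranks. For n <= 25 retained pairs the two-sided p-value is exact,
#' computed from the full null distribution of the positive-rank sum over
#' all sign assignments (dynamic-programming enumeration, valid under
#' ties); beyond that, a normal approximation with tie correction is used.
#' If every difference is zero, p = 1 by convention.
#'
#' @param a,b paired measurements (equal lengths >= 5).
#' @param model_a,model_b identifiers carried into the result.
#' @return object of class `comparison_result`: list with
#'   `wilcoxon_statistic` (positive-rank sum V), `p_value`, `n_effective`,
#'   `method`.
#' @examples
#' wilcoxon_paired(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))$p_value
#' # exact: 2 / 2^6 = 0.03125
#' @export
wilcoxon_paired <- function(a, b, model_a = "a", model_b = "b") {
  if (length(a) != length(b)) stop_radfuse("paired vectors differ in length")
  if (length(a) < 5) stop_radfuse("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(model_a = model_a, model_b = model_b,
                          wilcoxon_statistic = 0, p_value = 1,
                          n_effective = 0L, method = "degenerate"),
                     class = "comparison_result"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # doubled midranks are integers; DP over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    v2 <- round(2 * V)
    p_le <- sum(counts[seq_len(v2 + 1)]) / 2^n
    p_ge <- sum(counts[(v2 + 1):(total + 1)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_tie_corrected"
  }
  structure(list(model_a = model_a, model_b = model_b,
                 wilcoxon_statistic = V, p_value = p,
                 n_effective = as.integer(n), method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$model_a, " vs ", x$model_b, ": V = ",
      x$wilcoxon_statistic, ", p = ", signif(x$p_value, 4), " (", x$method,
      ", n = ", x$n_effective, ")\n", sep = "")
  invisible(x)
}
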