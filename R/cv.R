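#' Stratified fold assignment
#'
#' Round-robin assignment of shuffled within-class indices, so per-fold
#' class counts differ by at most one from proportional allocation.
#'
#' @param y class labels (factor or character).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold id per observation.
#' @export
stratified_folds <- function(y, n_folds = 10, seed = 0L) {
  y <- as.character(y)
  tab <- table(y)
  if (any(tab < n_folds))
    stop_radfuse("class '", names(tab)[which.min(tab)],
                 "' has fewer members (", min(tab), ") than folds (",
                 n_folds, ")")
  folds <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Evaluate a bank of (selector x classifier) models under one fold layout.
# `fold_data(train_idx, test_idx)` returns list(train=, test=) feature
# matrices; selectors are fitted inside each training fold only.
cv_bank_engine <- function(fold_data, y, selectors, classifiers,
                           n_folds = 10, seed = 0L,
                           k_select = NULL) {
  stopifnot(is.factor(y), nlevels(y) == 2)
  folds <- stratified_folds(y, n_folds, seed)
  per_model <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    dat <- fold_data(tr, te)
    k_eff <- if (is.null(k_select)) min(20, ncol(dat$train)) else
      min(k_select, ncol(dat$train))
    for (sname in names(selectors)) {
      sres <- run_selector(selectors[[sname]], dat$train, y[tr],
                           k = k_eff,
                           seed = derive_seed(seed, paste0("sel:", sname,
                                                           ":f", f)))
      cols <- sres$selected
      Xtr <- dat$train[, cols, drop = FALSE]
      Xte <- dat$test[, cols, drop = FALSE]
      for (cname in classifiers) {
        fit <- fit_classifier(cname, Xtr, y[tr],
                              seed = derive_seed(seed, paste0("clf:", cname,
                                                              ":f", f)))
        prob <- predict_prob(fit, Xte)
        key <- paste(sname, cname, sep = "+")
        m <- threshold_metrics(prob, y[te])
        row <- data.frame(fold = f, auc = auc_rank(prob, y[te]),
                          acc = m["acc"], sen = m["sen"], spe = m["spe"])
        per_model[[key]] <- rbind(per_model[[key]], row)
        attr(per_model[[key]], "selected") <-
          c(attr(per_model[[key]], "selected") %||% character(0),
            colnames(dat$train)[cols])
      }
    }
  }
  lapply(per_model, function(df) {
    structure(list(auc = mean(df$auc), acc = mean(df$acc),
                   sen = mean(df$sen), spe = mean(df$spe),
                   per_fold = df[, c("fold", "auc", "acc", "sen", "spe")],
                   n_folds = n_folds,
                   selected = attr(df, "selected")),
              class = "cv_result")
  })
}

#' Cross-validate one base model
#'
#' Stratified k-fold cross-validation of a (feature selector, classifier)
#' pair. The selector is fitted inside each training fold only (no
#' information from held-out folds reaches selection or fitting); AUC is the
#' tie-corrected rank statistic, and ACC/SEN/SPE are taken at the 0.5
#' probability threshold, then averaged across folds.
#'
#' @param model list with `selector` (name or `selector_spec`), `classifier`
#'   (name from [classifier_bank()]) and optionally `k_select`.
#' @param X feature matrix.
#' @param y two-level factor (second level = positive class).
#' @param n_folds folds (default 10).
#' @param seed integer seed.
#' @return a `cv_result`: mean `auc`, `acc`, `sen`, `spe` plus `per_fold`.
#' @export
cross_validate <- function(model, X, y, n_folds = 10, seed = 0L) {
  X <- as.matrix(X)
  sel <- model$selector
  if (is.character(sel)) sel <- selector_bank()[[sel]]
  if (is.null(sel)) stop_radfuse("unknown selector in model spec")
  res <- cv_bank_engine(function(tr, te)
    list(train = X[tr, , drop = FALSE], test = X[te, , drop = FALSE]),
    y, stats::setNames(list(sel), sel$name), model$classifier,
    n_folds = n_folds, seed = seed, k_select = model$k_select)
  out <- res[[1]]
  out$model <- paste(sel$name, model$classifier, sep = "+")
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", if (!is.null(x$model)) x$model else "", ": AUC ",
      round(x$auc, 3), ", ACC ", round(x$acc, 3), ", SEN ",
      round(x$sen, 3), ", SPE ", round(x$spe, 3), " (", x$n_folds,
      " folds)\n", sep = "")
  invisible(x)
}
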