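#' Binary labels for the three receptor-status tasks
#'
#' \describe{
#' \item{HRposVsHRneg}{positive = hormone-receptor negative (HEBC or TNBC,
#'   the minority event); negative = HR+.}
#' \item{TNBCvsHEBC}{restricted to TNBC and HEBC lesions; positive = TNBC.}
#' \item{TNBCvsNonTNBC}{positive = TNBC; negative = everything else.}
#' }
#' Re-applying the mapping to its own output is idempotent.
#'
#' @param labels cohort class labels.
#' @param task one of the three task names.
#' @return list with `idx` (kept row indices) and `y`, a two-level factor
#'   whose second level is the positive class.
#' @export
binary_task_labels <- function(labels,
                               task = c("HRposVsHRneg", "TNBCvsHEBC",
                                        "TNBCvsNonTNBC")) {
  task <- match.arg(task)
  labels <- as.character(labels)
  if (task == "HRposVsHRneg") {
    idx <- seq_along(labels)
    y <- ifelse(labels == "HR+", "HR+", "HR-")
    lev <- c("HR+", "HR-")
  } else if (task == "TNBCvsHEBC") {
    idx <- which(labels %in% c("TNBC", "HEBC"))
    y <- labels[idx]
    lev <- c("HEBC", "TNBC")
  } else {
    idx <- seq_along(labels)
    y <- ifelse(labels == "TNBC", "TNBC", "nonTNBC")
    lev <- c("nonTNBC", "TNBC")
  }
  y <- factor(y, levels = lev)
  if (any(table(y) == 0))
    stop_radfuse("task ", task, " has an empty arm")
  list(idx = idx, y = y, task = task)
}

#' Rank MRI sequences by their best cross-validated base model
#'
#' For every channel, evaluates the full (selector x classifier) bank under
#' stratified cross-validation on the task's binary labels and records the
#' maximum-AUC base model. The returned table is sorted by AUC, with ties
#' broken by ACC and then channel name, so ranking is deterministic.
#'
#' @param tables named list of per-channel `feature_table`s.
#' @param task task name (see [binary_task_labels()]).
#' @param selectors named list of selector specs (default the full
#'   15-member bank).
#' @param classifiers character vector of classifier names (default the
#'   10-member bank).
#' @param n_folds folds (default 10).
#' @param seed integer seed.
#' @param k_select features per selector (default min(20, p)).
#' @return data frame of class `ranking_table` (channel, auc, acc, sen, spe,
#'   selector, classifier), with attributes `all_results` and
#'   `n_evaluations`.
#' @export
rank_sequences <- function(tables, task, selectors = selector_bank(),
                           classifiers = classifier_bank(), n_folds = 10,
                           seed = 0L, k_select = NULL) {
  if (length(tables) < 2) stop_radfuse("need at least 2 channels to rank")
  if (any(vapply(tables, nrow, integer(1)) == 0))
    stop_radfuse("empty feature table")
  rows <- list()
  all_results <- list()
  for (ch in names(tables)) {
    bt <- binary_task_labels(tables[[ch]]$class, task)
    X <- feature_matrix(tables[[ch]])[bt$idx, , drop = FALSE]
    res <- cv_bank_engine(function(tr, te)
      list(train = X[tr, , drop = FALSE], test = X[te, , drop = FALSE]),
      bt$y, selectors, classifiers, n_folds = n_folds,
      # one shared stream: identical fold layout across channels makes
      # per-channel AUCs comparable and ties between identical channels exact
      seed = derive_seed(seed, "rank"), k_select = k_select)
    all_results[[ch]] <- res
    aucs <- vapply(res, `[[`, numeric(1), "auc")
    accs <- vapply(res, `[[`, numeric(1), "acc")
    best <- order(-aucs, -accs, names(res))[1]
    parts <- strsplit(names(res)[best], "+", fixed = TRUE)[[1]]
    rows[[ch]] <- data.frame(channel = ch, auc = aucs[best],
                             acc = accs[best],
                             sen = res[[best]]$sen, spe = res[[best]]$spe,
                             selector = parts[1], classifier = parts[2],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, -out$acc, out$channel), ]
  rownames(out) <- NULL
  attr(out, "all_results") <- all_results
  attr(out, "n_evaluations") <- length(tables) * length(selectors) *
    length(classifiers)
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Search fused-sequence models over the top-ranked channels
#'
#' Takes the top `top_k` channels of a ranking, enumerates every combination
#' of two or more of them, and for each combination evaluates the full base
#' model bank on fused features. The fusion transform is fitted inside each
#' training fold (the leakage-safe default; set `fusion_per_fold = FALSE`
#' to fit it once on all supplied rows). The winning model maximizes AUC
#' with ties broken by ACC, then smaller combination, then name.
#'
#' @param tables named list of per-channel `feature_table`s.
#' @param ranking a `ranking_table` from [rank_sequences()].
#' @param task task name.
#' @param selectors,classifiers the base-model bank.
#' @param n_folds,seed,k_select as in [rank_sequences()].
#' @param strategy,combination passed to [fusion_fit()].
#' @param top_k number of top channels to fuse (default 4, giving 11
#'   combinations).
#' @param fusion_per_fold fit fusion inside each CV training fold (default).
#' @return list with `best` (combination, selector, classifier, cv_result),
#'   `per_combination` data frame, and `n_evaluations`.
#' @export
rff_search <- function(tables, ranking, task, selectors = selector_bank(),
                       classifiers = classifier_bank(), n_folds = 10,
                       seed = 0L, k_select = NULL,
                       strategy = "featurewise", combination = "sum",
                       top_k = 4, fusion_per_fold = TRUE) {
  if (nrow(ranking) < top_k)
    stop_radfuse("ranking has fewer than ", top_k, " channels")
  top <- ranking$channel[seq_len(top_k)]
  combos <- enumerate_combinations(top)
  bt <- binary_task_labels(tables[[top[1]]]$class, task)
  views_all <- lapply(tables[top], function(tb)
    feature_matrix(tb)[bt$idx, , drop = FALSE])
  rows <- list()
  best <- NULL
  for (ci in seq_along(combos)) {
    cmb <- combos[[ci]]
    views <- views_all[cmb]
    fd <- if (fusion_per_fold) {
      function(tr, te) {
        ft <- fusion_fit(lapply(views, function(v) v[tr, , drop = FALSE]),
                         bt$y[tr], strategy = strategy,
                         combination = combination)
        list(train = predict(ft, lapply(views, function(v)
               v[tr, , drop = FALSE])),
             test = predict(ft, lapply(views, function(v)
               v[te, , drop = FALSE])))
      }
    } else {
      ft_all <- fusion_fit(views, bt$y, strategy = strategy,
                           combination = combination)
      fused <- predict(ft_all, views)
      function(tr, te) list(train = fused[tr, , drop = FALSE],
                            test = fused[te, , drop = FALSE])
    }
    res <- cv_bank_engine(fd, bt$y, selectors, classifiers,
                          n_folds = n_folds,
                          seed = derive_seed(seed, paste0("rff:",
                            paste(cmb, collapse = "_"))),
                          k_select = k_select)
    for (key in names(res)) {
      parts <- strsplit(key, "+", fixed = TRUE)[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        combination = paste(cmb, collapse = "+"), size = length(cmb),
        selector = parts[1], classifier = parts[2],
        auc = res[[key]]$auc, acc = res[[key]]$acc,
        sen = res[[key]]$sen, spe = res[[key]]$spe,
        stringsAsFactors = FALSE)
      cand <- list(combination = cmb, selector = parts[1],
                   classifier = parts[2], cv = res[[key]])
      if (is.null(best) || better_model(cand, best)) best <- cand
    }
  }
  per_comb <- do.call(rbind, rows)
  list(best = best, per_combination = per_comb,
       n_evaluations = length(combos) * length(selectors) *
         length(classifiers))
}

# argmax tie-break: AUC, then ACC, then smaller combination, then names.
better_model <- function(a, b) {
  if (a$cv$auc != b$cv$auc) return(a$cv$auc > b$cv$auc)
  if (a$cv$acc != b$cv$acc) return(a$cv$acc > b$cv$acc)
  la <- length(a$combination); lb <- length(b$combination)
  if (la != lb) return(la < lb)
  ka <- paste(paste(a$combination, collapse = "+"), a$selector, a$classifier)
  kb <- paste(paste(b$combination, collapse = "+"), b$selector, b$classifier)
  ka < kb
}

#' Evaluate the optimal single-sequence and fused models on held-out data
#'
#' Refits both final models on the full training cohort and evaluates each
#' once on the held-out test cohort. Training-cohort performance is reported
#' in both conventions: pooled cross-validation on the training cohort and
#' refit-on-train (resubstitution). Overlapping lesion ids between train and
#' test are refused (leakage guard).
#'
#' @param rss list: `channel`, `selector`, `classifier`, optional `k_select`.
#' @param rff list: `channels`, `selector`, `classifier`, optional
#'   `strategy`, `combination`, `k_select`.
#' @param train_tables,test_tables named per-channel `feature_table` lists.
#' @param task task name.
#' @param n_folds,seed as elsewhere.
#' @return list with `rss` and `rff` reports (train_cv, train_refit, test
#'   metric vectors) and `comparison`, the paired fold-wise Wilcoxon test.
#' @export
evaluate_holdout <- function(rss, rff, train_tables, test_tables, task,
                             n_folds = 10, seed = 0L) {
  ids_tr <- train_tables[[1]]$lesion_id
  ids_te <- test_tables[[1]]$lesion_id
  if (length(intersect(ids_tr, ids_te)))
    stop_radfuse("train and test cohorts share lesion ids (leakage)")
  bt_tr <- binary_task_labels(train_tables[[1]]$class, task)
  bt_te <- binary_task_labels(test_tables[[1]]$class, task)
  if (nlevels(droplevels(bt_te$y)) < 2)
    stop_radfuse("test cohort has a single class")
  eval_model <- function(Xtr, Xte, spec) {
    k <- spec$k_select %||% min(20, ncol(Xtr))
    sres <- run_selector(spec$selector, Xtr, bt_tr$y, k = k,
                         seed = derive_seed(seed, "holdout_sel"))
    fit <- fit_classifier(spec$classifier,
                          Xtr[, sres$selected, drop = FALSE], bt_tr$y,
                          seed = derive_seed(seed, "holdout_clf"))
    score <- function(X, y) {
      pr <- predict_prob(fit, X[, sres$selected, drop = FALSE])
      m <- threshold_metrics(pr, y)
      c(auc = auc_rank(pr, y), m)
    }
    list(train_refit = score(Xtr, bt_tr$y), test = score(Xte, bt_te$y))
  }
  # single-sequence model
  Xtr_s <- feature_matrix(train_tables[[rss$channel]])[bt_tr$idx, ,
                                                       drop = FALSE]
  Xte_s <- feature_matrix(test_tables[[rss$channel]])[bt_te$idx, ,
                                                      drop = FALSE]
  rss_rep <- eval_model(Xtr_s, Xte_s, rss)
  rss_cv <- cross_validate(list(selector = rss$selector,
                                classifier = rss$classifier,
                                k_select = rss$k_select),
                           Xtr_s, bt_tr$y, n_folds = n_folds, seed = seed)
  # fused model
  vtr <- lapply(train_tables[rff$channels], function(tb)
    feature_matrix(tb)[bt_tr$idx, , drop = FALSE])
  vte <- lapply(test_tables[rff$channels], function(tb)
    feature_matrix(tb)[bt_te$idx, , drop = FALSE])
  ft <- fusion_fit(vtr, bt_tr$y, strategy = rff$strategy %||% "featurewise",
                   combination = rff$combination %||% "sum")
  Ftr <- predict(ft, vtr); Fte <- predict(ft, vte)
  rff_rep <- eval_model(Ftr, Fte, rff)
  rff_cv_res <- rff_cv_on_train(vtr, bt_tr$y, rff, n_folds, seed)
  cmp <- wilcoxon_paired(rff_cv_res$per_fold$auc, rss_cv$per_fold$auc,
                         model_a = "R_FF", model_b = "Rss")
  list(rss = c(rss_rep, list(train_cv = rss_cv)),
       rff = c(rff_rep, list(train_cv = rff_cv_res)),
       comparison = cmp)
}

rff_cv_on_train <- function(views, y, rff, n_folds, seed) {
  sel <- rff$selector
  if (is.character(sel)) sel <- selector_bank()[[sel]]
  res <- cv_bank_engine(function(tr, te) {
    ft <- fusion_fit(lapply(views, function(v) v[tr, , drop = FALSE]), y[tr],
                     strategy = rff$strategy %||% "featurewise",
                     combination = rff$combination %||% "sum")
    list(train = predict(ft, lapply(views, function(v)
           v[tr, , drop = FALSE])),
         test = predict(ft, lapply(views, function(v)
           v[te, , drop = FALSE])))
  }, y, stats::setNames(list(sel), sel$name), rff$classifier,
  n_folds = n_folds, seed = seed, k_select = rff$k_select)
  res[[1]]
}

#' Per-feature class-contrast summary of a fused feature matrix
#'
#' For each top-ranked fused feature: a rank-sum p-value between the two
#' classes, the threshold defined as the mean of the two class means, and
#' the percentage of lesions of each class below/above that threshold.
#' When base-model results are supplied, features are ranked by how often
#' they were selected across base models with AUC above `auc_min`
#' (default 0.6); otherwise by p-value.
#'
#' @param X fused feature matrix with column names.
#' @param y two-level factor.
#' @param top_k number of features to summarize (default 5).
#' @param model_results optional list of `cv_result`s (with `$selected`
#'   feature-name multisets and `$auc`).
#' @param auc_min AUC cutoff for counting selections.
#' @return data frame: feature, frequency, p_value, mean_threshold, and
#'   below/above percentages for the negative and positive class.
#' @export
table3_summary <- function(X, y, top_k = 5, model_results = NULL,
                           auc_min = 0.6) {
  stopifnot(is.factor(y), nlevels(y) == 2)
  if (any(table(y) == 0)) stop_radfuse("empty class")
  X <- as.matrix(X)
  freq <- NULL
  if (!is.null(model_results)) {
    good <- Filter(function(r) r$auc > auc_min, model_results)
    tab <- table(unlist(lapply(good, `[[`, "selected")))
    freq <- stats::setNames(rep(0, ncol(X)), colnames(X))
    freq[names(tab)[names(tab) %in% names(freq)]] <-
      tab[names(tab) %in% names(freq)]
    ord <- order(-freq, seq_along(freq))
  } else {
    pv <- vapply(seq_len(ncol(X)), function(j)
      suppressWarnings(stats::wilcox.test(X[y == levels(y)[1], j],
                                          X[y == levels(y)[2], j],
                                          exact = FALSE)$p.value),
      numeric(1))
    ord <- order(pv, seq_len(ncol(X)))
  }
  take <- ord[seq_len(min(top_k, ncol(X)))]
  neg <- levels(y)[1]; pos <- levels(y)[2]
  rows <- lapply(take, function(j) {
    x <- X[, j]
    m_neg <- mean(x[y == neg]); m_pos <- mean(x[y == pos])
    thr <- (m_neg + m_pos) / 2
    p <- suppressWarnings(stats::wilcox.test(x[y == neg], x[y == pos],
                                             exact = FALSE)$p.value)
    data.frame(feature = colnames(X)[j],
               frequency = if (is.null(freq)) NA_real_ else freq[j],
               p_value = p, mean_threshold = thr,
               below_neg = 100 * mean(x[y == neg] < thr),
               above_neg = 100 * mean(x[y == neg] >= thr),
               below_pos = 100 * mean(x[y == pos] < thr),
               above_pos = 100 * mean(x[y == pos] >= thr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "classes") <- c(negative = neg, positive = pos)
  out
}
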