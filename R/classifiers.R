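# Classifier bank: 10 members with fixed defaults behind a uniform
# fit/predict-probability interface. `y` must be a two-level factor; the
# second level is the positive class and predictions are P(positive).

#' Names of the classifier bank
#'
#' Logistic regression plus nine conventional companions (linear
#' discriminant, k-NN, Gaussian naive Bayes, decision tree, random forest,
#' linear and RBF SVM, gradient-boosted stumps, ridge). The list is a
#' documented configuration default; any subset can be passed to the
#' evaluation functions.
#' @return character vector of length 10.
#' @examples
#' length(classifier_bank())  # 10
#' @export
classifier_bank <- function() {
  c("logistic", "lda", "knn", "naive_bayes", "decision_tree",
    "random_forest", "svm_linear", "svm_rbf", "gbm_stumps", "ridge")
}

fit_classifier <- function(name, X, y, seed = 0L) {
  stopifnot(is.factor(y), nlevels(y) == 2)
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  model <- with_seed(seed, switch(name,
    logistic = suppressWarnings(stats::glm.fit(cbind(1, X),
      as.numeric(y) - 1, family = stats::binomial())),
    lda = tryCatch(MASS::lda(X, grouping = y),
                   error = function(e) list(fallback = mean(y == levels(y)[2]))),
    knn = list(X = X, y = y, k = 5),
    naive_bayes = e1071::naiveBayes(X, y),
    decision_tree = rpart::rpart(y ~ ., data = data.frame(y = y, X),
      method = "class", control = rpart::rpart.control(cp = 0.01,
        minsplit = 10)),
    random_forest = randomForest::randomForest(X, y, ntree = 100),
    svm_linear = svm_safe(X, y, "linear"),
    svm_rbf = svm_safe(X, y, "radial"),
    gbm_stumps = xgboost::xgb.train(
      params = list(max_depth = 1, eta = 0.3,
                    objective = "binary:logistic", nthread = 1),
      xgboost::xgb.DMatrix(X, label = as.numeric(y) - 1), nrounds = 50),
    ridge = glmnet::glmnet(cbind(X, 0), y, family = "binomial",
      alpha = 0, lambda = 0.1),
    stop_radfuse("unknown classifier: ", name)))
  structure(list(name = name, model = model, levels = levels(y),
                 p = ncol(X)), class = "radfuse_classifier")
}

svm_safe <- function(X, y, kernel) {
  tryCatch(e1071::svm(X, y, kernel = kernel, probability = TRUE,
                      cost = 1, scale = apply(X, 2, stats::sd) > 0),
           error = function(e) list(fallback = mean(y == levels(y)[2])))
}

predict_prob <- function(fit, X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  m <- fit$model
  pos <- fit$levels[2]
  if (is.list(m) && !is.null(m$fallback)) return(rep(m$fallback, nrow(X)))
  switch(fit$name,
    logistic = {
      eta <- drop(cbind(1, X) %*% ifelse(is.na(m$coefficients), 0,
                                         m$coefficients))
      stats::plogis(eta)
    },
    lda = stats::predict(m, X)$posterior[, pos],
    knn = {
      pr <- class::knn(m$X, X, m$y, k = min(m$k, nrow(m$X)), prob = TRUE)
      pw <- attr(pr, "prob")
      ifelse(pr == pos, pw, 1 - pw)
    },
    naive_bayes = stats::predict(m, X, type = "raw")[, pos],
    decision_tree = stats::predict(m, data.frame(X), type = "prob")[, pos],
    random_forest = stats::predict(m, X, type = "prob")[, pos],
    svm_linear = ,
    svm_rbf = {
      pr <- stats::predict(m, X, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    gbm_stumps = stats::predict(m, X),
    ridge = drop(stats::predict(m, cbind(X, 0), type = "response")),
    stop_radfuse("unknown classifier: ", fit$name))
}
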