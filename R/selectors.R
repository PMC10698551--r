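# Feature-selection bank: 15 methods behind one interface. The three
# methods studied in depth (trace_ratio, MCFS, UDFS) get full
# implementations; the remainder are standard filter/embedded/wrapper
# selectors. Every selector returns per-feature scores; the selected set is
# the top-k by score with deterministic ties broken by lower index.

top_k_by_score <- function(scores, k) {
  k <- min(k, length(scores))
  order(-scores, seq_along(scores))[seq_len(k)]
}

selection_result <- function(name, scores, k, seed) {
  structure(list(name = name, scores = as.numeric(scores),
                 selected = top_k_by_score(scores, k),
                 k = as.integer(min(k, length(scores))),
                 seed = as.integer(seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$name, ": top ", x$k, " of ",
      length(x$scores), " features\n", sep = "")
  invisible(x)
}

# Between/within scatter diagonals (Fisher style), shared by several
# selectors.
scatter_diagonals <- function(X, y) {
  y <- as.character(y)
  mu <- colMeans(X)
  a <- numeric(ncol(X)); b <- numeric(ncol(X))
  for (k in unique(y)) {
    idx <- y == k
    mk <- colMeans(X[idx, , drop = FALSE])
    a <- a + sum(idx) * (mk - mu)^2
    b <- b + colSums(sweep(X[idx, , drop = FALSE], 2, mk)^2)
  }
  list(between = a, within = b)
}

#' Trace-ratio feature selection
#'
#' Iterative maximization of the trace ratio sum(a_S)/sum(b_S) over k-subsets
#' S, with a and b the diagonals of the Fisher between- and within-class
#' scatter. Starting from lambda = 0, the top-k features by a_j - lambda b_j
#' are selected and lambda updated to their ratio until |change| < 1e-8 (at
#' most 100 iterations); the lambda sequence is monotone non-decreasing,
#' which is asserted on every run.
#'
#' @param X numeric matrix (lesions x features).
#' @param y class labels (>= 2 per class).
#' @param k number of features to select.
#' @param seed integer (unused randomness; kept for interface uniformity).
#' @return a `selection_result`.
#' @export
trace_ratio_select <- function(X, y, k, seed = 0L) {
  sc <- scatter_diagonals(X, y)
  if (all(sc$within <= 0))
    stop_radfuse("within-class scatter is zero for every feature")
  lambda <- 0
  sel <- NULL
  for (it in seq_len(100)) {
    score <- sc$between - lambda * sc$within
    sel <- top_k_by_score(score, k)
    denom <- sum(sc$within[sel])
    lam_new <- if (denom > 0) sum(sc$between[sel]) / denom
               else sum(sc$between[sel]) / 1e-12
    if (lam_new < lambda - 1e-9)
      stop_radfuse("trace-ratio objective decreased; numerical failure")
    conv <- abs(lam_new - lambda) < 1e-8
    lambda <- lam_new
    if (conv) break
  }
  score <- sc$between - lambda * sc$within
  res <- selection_result("trace_ratio", score, k, seed)
  res$selected <- sel[order(-score[sel], sel)]
  res$lambda <- lambda
  res
}

# Symmetric kNN heat-kernel affinity; bandwidth = median pairwise distance.
knn_affinity <- function(X, k_nn = 5) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  k_nn <- min(k_nn, n - 1)
  sigma <- stats::median(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ], seq_len(n))[2:(k_nn + 1)]
    W[i, nb] <- exp(-D[i, nb]^2 / (2 * sigma^2))
  }
  pmax(W, t(W))
}

graph_components <- function(W) {
  n <- nrow(W)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(W[i, ] > 0)
      m <- min(comp[c(i, nb)])
      if (any(comp[c(i, nb)] != m)) { comp[c(i, nb)] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Multi-cluster feature selection (MCFS)
#'
#' Builds a symmetric k-nearest-neighbour heat-kernel graph, takes the
#' bottom non-trivial eigenvectors of its normalized Laplacian as a spectral
#' embedding of the cluster structure, reconstructs each eigenvector from
#' the features by an L1-penalized linear regression (lasso path, read off
#' where k features are active), and scores every feature by its maximum
#' absolute coefficient across eigenvectors.
#'
#' @param X numeric matrix.
#' @param k number of features to select.
#' @param n_clusters embedding dimension (2 <= n_clusters < n).
#' @param seed integer seed.
#' @param k_nn graph neighbourhood size.
#' @return a `selection_result`.
#' @export
mcfs_select <- function(X, k, n_clusters = 5, seed = 0L, k_nn = 5) {
  n <- nrow(X)
  if (n_clusters >= n) stop_radfuse("n_clusters must be < n")
  if (n_clusters < 2) stop_radfuse("n_clusters must be >= 2")
  W <- knn_affinity(X, k_nn)
  comp <- graph_components(W)
  n_comp <- max(comp)
  if (n_comp > 1)
    warning("kNN graph has ", n_comp,
            " connected components; using component-wise Laplacian")
  d <- pmax(rowSums(W), 1e-12)
  Ln <- diag(n) - sweep(sweep(W, 1, sqrt(d), `/`), 2, sqrt(d), `/`)
  eg <- eigen((Ln + t(Ln)) / 2, symmetric = TRUE)
  ord <- order(eg$values)
  # skip one trivial eigenvector per connected component
  take <- ord[(n_comp + 1):min(n_comp + n_clusters, n)]
  E <- eg$vectors[, take, drop = FALSE]
  scores <- with_seed(seed, {
    s <- numeric(ncol(X))
    for (j in seq_len(ncol(E))) {
      fit <- glmnet::glmnet(X, E[, j], family = "gaussian",
                            standardize = TRUE, intercept = TRUE,
                            nlambda = 100)
      # deepest point on the path with at most k active features:
      # least-shrunk coefficients for a k-sparse reconstruction
      ok <- which(fit$df <= min(k, ncol(X)))
      pick <- if (length(ok)) max(ok) else 1L
      cf <- abs(as.numeric(fit$beta[, pick]))
      s <- pmax(s, cf)
    }
    # identical columns are interchangeable for the path; give them the
    # group-mean score so ties resolve by the documented index rule
    dup_groups <- split(seq_len(ncol(X)),
                        apply(X, 2, function(col) paste(signif(col, 12),
                                                        collapse = ",")))
    for (g in dup_groups)
      if (length(g) > 1) s[g] <- mean(s[g])
    s
  })
  selection_result("MCFS", scores, k, seed)
}

#' Unsupervised discriminative feature selection (UDFS)
#'
#' L2,1-norm regularized discriminative analysis: minimizes
#' trace(W' M W) + gamma * ||W||_{2,1} over orthonormal W, with M built from
#' the local total scatter of k-nearest-neighbour patches. Solved by
#' iterative reweighting (eigenvectors of M + gamma D, D from current row
#' norms); the objective is checked to be non-increasing each iteration and
#' iteration stops at relative change < 1e-6 or 200 rounds. Features are
#' scored by the row norms of W. The limit gamma = Inf collapses all row
#' norms to zero, leaving the deterministic index tie-break.
#'
#' @param X numeric matrix.
#' @param k number of features to select.
#' @param gamma regularization weight (default 0.1).
#' @param seed integer seed.
#' @param n_comp number of discriminative directions (default 4).
#' @param k_nn local neighbourhood size.
#' @return a `selection_result` (with the objective trace in `$objective`).
#' @export
udfs_select <- function(X, k, gamma = 0.1, seed = 0L, n_comp = 4,
                        k_nn = 5) {
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop_radfuse("UDFS needs at least 3 samples")
  if (!is.finite(gamma))
    return(selection_result("UDFS", numeric(p), k, seed))
  n_comp <- min(n_comp, p, n - 1)
  k_nn <- min(k_nn, n - 1)
  D <- as.matrix(stats::dist(X))
  M <- matrix(0, n, n)
  lam <- 1e-3
  for (i in seq_len(n)) {
    nb <- c(i, order(D[i, ], seq_len(n))[2:(k_nn + 1)])
    m <- length(nb)
    H <- diag(m) - 1 / m
    Xi <- X[nb, , drop = FALSE]
    Bi <- H %*% solve(H %*% Xi %*% t(Xi) %*% H + lam * diag(m)) %*% H
    M[nb, nb] <- M[nb, nb] + Bi
  }
  Mt <- crossprod(X, M %*% X)
  Mt <- (Mt + t(Mt)) / 2
  d_w <- rep(0.5, p)
  obj_prev <- Inf
  objective <- numeric(0)
  Wm <- NULL
  for (it in seq_len(200)) {
    A <- Mt + gamma * diag(d_w, p)
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    idx <- order(eg$values)[seq_len(n_comp)]
    Wm <- eg$vectors[, idx, drop = FALSE]
    rn <- sqrt(rowSums(Wm^2))
    obj <- sum(diag(crossprod(Wm, Mt %*% Wm))) + gamma * sum(rn)
    if (!is.finite(obj)) stop_radfuse("UDFS objective is non-finite")
    if (obj > obj_prev + 1e-8)
      stop_radfuse("UDFS objective increased; numerical failure")
    objective <- c(objective, obj)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) < 1e-6 * max(abs(obj_prev), 1e-12)) break
    obj_prev <- obj
    d_w <- 1 / (2 * pmax(rn, 1e-8))
  }
  res <- selection_result("UDFS", sqrt(rowSums(Wm^2)), k, seed)
  res$objective <- objective
  res
}

# ---- remaining bank members ------------------------------------------------

variance_select <- function(X, y, k, seed)
  selection_result("variance", apply(X, 2, stats::var), k, seed)

fisher_select <- function(X, y, k, seed) {
  sc <- scatter_diagonals(X, y)
  selection_result("fisher_score", sc$between / pmax(sc$within, 1e-12),
                   k, seed)
}

tscore_select <- function(X, y, k, seed) {
  y <- as.character(y)
  cls <- sort(unique(y))
  s <- if (length(cls) == 2) {
    a <- X[y == cls[1], , drop = FALSE]; b <- X[y == cls[2], , drop = FALSE]
    se <- sqrt(apply(a, 2, stats::var) / nrow(a) +
                 apply(b, 2, stats::var) / nrow(b))
    abs(colMeans(a) - colMeans(b)) / pmax(se, 1e-12)
  } else {
    sc <- scatter_diagonals(X, y)
    (sc$between / max(length(cls) - 1, 1)) /
      pmax(sc$within / max(nrow(X) - length(cls), 1), 1e-12)
  }
  selection_result("t_score", s, k, seed)
}

gini_impurity <- function(y) 1 - sum((table(y) / length(y))^2)

gini_select <- function(X, y, k, seed) {
  base <- gini_impurity(y)
  s <- apply(X, 2, function(x) {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = 11), type = 7))
    if (length(br) < 2) return(0)
    b <- cut(x, br, include.lowest = TRUE)
    base - sum(vapply(split(y, b), function(g)
      length(g) / length(y) * gini_impurity(g), numeric(1)))
  })
  selection_result("gini_index", s, k, seed)
}

relieff_select <- function(X, y, k, seed, k_nn = 5, m = 100) {
  y <- as.character(y)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(x) max(x) - min(x))
  rng[rng <= 0] <- 1
  D <- as.matrix(stats::dist(X))
  idx <- with_seed(seed, sample(n, min(m, n)))
  s <- numeric(p)
  pri <- table(y) / n
  for (i in idx) {
    for (cl in names(pri)) {
      pool <- setdiff(which(y == cl), i)
      if (!length(pool)) next
      nb <- pool[order(D[i, pool], pool)][seq_len(min(k_nn, length(pool)))]
      diffs <- colMeans(abs(sweep(X[nb, , drop = FALSE], 2, X[i, ])) /
                          rep(rng, each = length(nb)))
      if (cl == y[i]) s <- s - diffs / length(idx)
      else s <- s + (pri[[cl]] / (1 - pri[[y[i]]])) * diffs / length(idx)
    }
  }
  selection_result("ReliefF", s, k, seed)
}

disc_bins <- function(x, nb = 5) {
  br <- unique(stats::quantile(x, seq(0, 1, length.out = nb + 1), type = 7))
  if (length(br) < 2) return(factor(rep(1, length(x))))
  cut(x, br, include.lowest = TRUE)
}

mutual_info <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  sum(tab * safe_log2(tab / outer(pa, pb)), na.rm = TRUE)
}

mrmr_select <- function(X, y, k, seed) {
  p <- ncol(X)
  disc <- lapply(seq_len(p), function(j) disc_bins(X[, j]))
  rel <- vapply(disc, function(d) mutual_info(d, y), numeric(1))
  k_eff <- min(k, p)
  sel <- integer(0)
  red <- numeric(p)
  scores <- numeric(p)
  for (step in seq_len(k_eff)) {
    crit <- rel - if (length(sel)) red / length(sel) else 0
    crit[sel] <- -Inf
    pick <- top_k_by_score(crit, 1)[1]
    sel <- c(sel, pick)
    scores[pick] <- k_eff - step + 1
    if (step < k_eff)
      red <- red + vapply(disc, function(d) mutual_info(d, disc[[pick]]),
                          numeric(1))
  }
  res <- selection_result("mRMR", scores, k, seed)
  res$selected <- sel
  res
}

laplacian_select <- function(X, y, k, seed, k_nn = 5) {
  W <- knn_affinity(X, k_nn)
  d <- rowSums(W)
  s <- apply(X, 2, function(f) {
    ft <- f - sum(f * d) / sum(d)
    den <- sum(d * ft^2)
    if (den <= 0) return(-Inf)
    num <- sum(W * outer(ft, ft, function(a, b) (a - b)^2)) / 2
    -num / den
  })
  s[!is.finite(s)] <- min(s[is.finite(s)], 0) - 1
  selection_result("laplacian_score", s, k, seed)
}

spec_select <- function(X, y, k, seed, k_nn = 5) {
  W <- knn_affinity(X, k_nn)
  d <- pmax(rowSums(W), 1e-12)
  Ln <- diag(nrow(W)) - sweep(sweep(W, 1, sqrt(d), `/`), 2, sqrt(d), `/`)
  s <- apply(X, 2, function(f) {
    fh <- sqrt(d) * f
    nf <- sqrt(sum(fh^2))
    if (nf <= 0) return(-Inf)
    fh <- fh / nf
    -drop(crossprod(fh, Ln %*% fh))
  })
  s[!is.finite(s)] <- min(s[is.finite(s)], 0) - 1
  selection_result("SPEC", s, k, seed)
}

chisq_select <- function(X, y, k, seed) {
  s <- apply(X, 2, function(x) {
    b <- disc_bins(x)
    if (nlevels(droplevels(b)) < 2) return(0)
    suppressWarnings(stats::chisq.test(table(b, y))$statistic)
  })
  selection_result("chi_square", s, k, seed)
}

cfs_select <- function(X, y, k, seed) {
  yn <- as.numeric(factor(y))
  p <- ncol(X)
  rel <- abs(suppressWarnings(stats::cor(X, yn)))
  rel[!is.finite(rel)] <- 0
  cc <- abs(suppressWarnings(stats::cor(X)))
  cc[!is.finite(cc)] <- 0
  sel <- integer(0); scores <- numeric(p)
  k_eff <- min(k, p)
  for (step in seq_len(k_eff)) {
    crit <- rel - if (length(sel))
      rowMeans(cc[, sel, drop = FALSE]) else 0
    crit[sel] <- -Inf
    pick <- top_k_by_score(crit, 1)[1]
    sel <- c(sel, pick); scores[pick] <- k_eff - step + 1
  }
  res <- selection_result("cfs", scores, k, seed)
  res$selected <- sel
  res
}

l1_logistic_select <- function(X, y, k, seed) {
  yf <- factor(y)
  s <- with_seed(seed, {
    fit <- glmnet::glmnet(X, yf, family = if (nlevels(yf) == 2)
      "binomial" else "multinomial", standardize = TRUE, nlambda = 100)
    beta <- if (nlevels(yf) == 2) abs(as.matrix(fit$beta)) else
      Reduce(`+`, lapply(fit$beta, function(b) abs(as.matrix(b))))
    # earlier path entry (larger lambda) = stronger feature
    entry <- apply(beta, 1, function(b) {
      w <- which(b > 0)
      if (!length(w)) 0 else ncol(beta) - w[1] + 1
    })
    entry + apply(beta, 1, max) * 1e-6
  })
  selection_result("l1_logistic", s, k, seed)
}

rfe_select <- function(X, y, k, seed) {
  yn <- as.numeric(factor(y)) - 1
  p <- ncol(X)
  alive <- seq_len(p)
  scores <- numeric(p)
  round <- 0
  Xs <- scale(X)
  Xs[!is.finite(Xs)] <- 0
  while (length(alive) > 1) {
    round <- round + 1
    cf <- tryCatch({
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Xs[, alive,
        drop = FALSE]), yn, family = stats::binomial()))
      abs(fit$coefficients[-1])
    }, error = function(e) rep(0, length(alive)))
    cf[!is.finite(cf)] <- 0
    ndrop <- max(1L, floor(length(alive) * 0.1))
    drop_idx <- order(cf, seq_along(cf))[seq_len(ndrop)]
    scores[alive[drop_idx]] <- round + cf[drop_idx] * 1e-9
    alive <- alive[-drop_idx]
  }
  scores[alive] <- round + 1
  selection_result("rfe_linear", scores, k, seed)
}

#' The feature-selection bank
#'
#' Fifteen selector specifications spanning filter, embedded and wrapper
#' families. MCFS, UDFS and trace_ratio are always present; the remaining
#' twelve are a documented configuration default and can be replaced by
#' passing a different list wherever a bank is accepted.
#'
#' @return named list of `selector_spec` objects (name, requires_labels,
#'   hyperparameters).
#' @examples
#' length(selector_bank())  # 15
#' @export
selector_bank <- function() {
  mk <- function(name, requires_labels, ...)
    structure(list(name = name, requires_labels = requires_labels,
                   hyperparameters = list(...)), class = "selector_spec")
  list(
    trace_ratio = mk("trace_ratio", TRUE),
    MCFS = mk("MCFS", FALSE, n_clusters = 5),
    UDFS = mk("UDFS", FALSE, gamma = 0.1),
    variance = mk("variance", FALSE),
    fisher_score = mk("fisher_score", TRUE),
    t_score = mk("t_score", TRUE),
    gini_index = mk("gini_index", TRUE),
    ReliefF = mk("ReliefF", TRUE),
    mRMR = mk("mRMR", TRUE),
    laplacian_score = mk("laplacian_score", FALSE),
    SPEC = mk("SPEC", FALSE),
    chi_square = mk("chi_square", TRUE),
    cfs = mk("cfs", TRUE),
    l1_logistic = mk("l1_logistic", TRUE),
    rfe_linear = mk("rfe_linear", TRUE)
  )
}

#' Run one selector from the bank
#'
#' Dispatches a `selector_spec` on a feature matrix. Inputs are standardized
#' per feature before selection (except for the variance selector, whose
#' score is the raw variance), making every standardizing selector invariant
#' to per-feature affine rescaling. Unsupervised selectors ignore `y`; all
#' selectors are deterministic given `seed`.
#'
#' @param spec a `selector_spec` from [selector_bank()], or its name.
#' @param X numeric matrix (lesions x features).
#' @param y class labels (may be NULL for unsupervised selectors).
#' @param k number of features to select; default `min(20, ncol(X))`.
#' @param seed integer seed.
#' @return a `selection_result`.
#' @export
run_selector <- function(spec, X, y = NULL, k = min(20, ncol(X)),
                         seed = 0L) {
  if (is.character(spec)) {
    bank <- selector_bank()
    if (!spec %in% names(bank)) stop_radfuse("unknown selector: ", spec)
    spec <- bank[[spec]]
  }
  stopifnot(inherits(spec, "selector_spec"))
  X <- as.matrix(X)
  if (spec$requires_labels && is.null(y))
    stop_radfuse("selector ", spec$name, " requires labels")
  hp <- spec$hyperparameters
  if (spec$name != "variance") {
    Xs <- scale(X)
    Xs[, apply(X, 2, stats::sd) == 0] <- 0
    Xs[!is.finite(Xs)] <- 0
  } else Xs <- X
  switch(spec$name,
    trace_ratio = trace_ratio_select(Xs, y, k, seed),
    MCFS = mcfs_select(Xs, k, n_clusters = hp$n_clusters %||% 5,
                       seed = seed),
    UDFS = udfs_select(Xs, k, gamma = hp$gamma %||% 0.1, seed = seed),
    variance = variance_select(Xs, y, k, seed),
    fisher_score = fisher_select(Xs, y, k, seed),
    t_score = tscore_select(Xs, y, k, seed),
    gini_index = gini_select(Xs, y, k, seed),
    ReliefF = relieff_select(Xs, y, k, seed),
    mRMR = mrmr_select(Xs, y, k, seed),
    laplacian_score = laplacian_select(Xs, y, k, seed),
    SPEC = spec_select(Xs, y, k, seed),
    chi_square = chisq_select(Xs, y, k, seed),
    cfs = cfs_select(Xs, y, k, seed),
    l1_logistic = l1_logistic_select(Xs, y, k, seed),
    rfe_linear = rfe_select(Xs, y, k, seed),
    stop_radfuse("unknown selector: ", spec$name))
}
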