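#' Fit a class-structure-aware multi-sequence fusion transform
#'
#' Learns a supervised mapping from a set of per-sequence (per-"view")
#' feature matrices to a single fused feature matrix, eliminating
#' between-class correlations (the between-class scatter of the fused
#' training features is whitened to the identity) while preserving the
#' within-class structure that carries complementary signal across
#' sequences.
#'
#' Two strategies are provided:
#' \describe{
#' \item{featurewise (default)}{For each feature index j, the values of
#'   feature j across the S views form an S-vector per lesion. The S x S
#'   between-class scatter of these vectors is eigendecomposed; the top
#'   c - 1 eigenvectors (c = number of classes), scaled by the inverse
#'   square root of their eigenvalues, define the projection. For binary
#'   tasks this maps S values to one fused value per feature (e.g. a
#'   feature observed on 10 sequences collapses to dimension 1), so the
#'   fused matrix keeps the original n x p shape.}
#' \item{viewlevel}{Each whole view matrix is whitened against its
#'   between-class scatter and reduced to r <= c - 1 discriminant
#'   dimensions; view pairs are then aligned by the SVD of their pooled
#'   within-class cross-covariance and folded in sequentially with the
#'   chosen combination rule (`sum` keeps dimensionality, `concatenate`
#'   stacks aligned dimensions).}
#' }
#'
#' Eigenvalues below 1e-10 of the largest are treated as null directions;
#' a feature whose between-class scatter is entirely null falls back to an
#' equal-weight average of the views. The transform is fitted exclusively
#' on the rows passed here (training data); apply it to held-out data with
#' [predict.fusion_transform()].
#'
#' @param views named list of numeric matrices (lesions x features), equal
#'   shapes and identical column names, rows aligned across views.
#' @param labels class label per lesion (2 or more classes, each with at
#'   least 2 lesions).
#' @param strategy "featurewise" or "viewlevel".
#' @param combination "sum" or "concatenate" (viewlevel only).
#' @return object of class `fusion_transform`.
#' @examples
#' n <- 40
#' y <- rep(c("a", "b"), each = n / 2)
#' v <- list(ADC = matrix(rnorm(n * 3), n), DWI600 = matrix(rnorm(n * 3), n))
#' colnames(v$ADC) <- colnames(v$DWI600) <- c("f1", "f2", "f3")
#' ft <- fusion_fit(v, y)
#' dim(predict(ft, v))
#' @export
fusion_fit <- function(views, labels,
                       strategy = c("featurewise", "viewlevel"),
                       combination = c("sum", "concatenate")) {
  strategy <- match.arg(strategy)
  combination <- match.arg(combination)
  if (!is.list(views) || length(views) < 2)
    stop_radfuse("fusion needs at least 2 views")
  if (is.null(names(views)) || anyDuplicated(names(views)))
    stop_radfuse("views must be uniquely named")
  p <- ncol(views[[1]]); n <- nrow(views[[1]])
  fn <- colnames(views[[1]])
  for (v in views)
    if (!identical(dim(v), c(n, p)) || !identical(colnames(v), fn))
      stop_radfuse("all views must share shape and feature names")
  labels <- as.character(labels)
  if (length(labels) != n) stop_radfuse("labels must match view rows")
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop_radfuse("fusion needs at least 2 classes")
  if (any(table(labels) < 2))
    stop_radfuse("every class needs at least 2 training lesions")
  std <- lapply(views, function(v) {
    mu <- colMeans(v); sd <- apply(v, 2, stats::sd)
    sd[sd <= 0 | !is.finite(sd)] <- 1
    list(mean = mu, sd = sd)
  })
  Z <- mapply(function(v, s) sweep(sweep(v, 2, s$mean), 2, s$sd, `/`),
              views, std, SIMPLIFY = FALSE)
  obj <- list(strategy = strategy, combination = combination,
              channels = names(views), feature_names = fn,
              classes = cls, std = std, n_train = n)
  if (strategy == "featurewise") {
    S <- length(views)
    W <- array(0, dim = c(S, length(cls) - 1, p),
               dimnames = list(names(views), NULL, fn))
    rks <- integer(p)
    for (j in seq_len(p)) {
      M <- vapply(Z, function(z) z[, j], numeric(n))   # n x S
      wj <- whiten_between(M, labels)
      rks[j] <- wj$rank
      if (wj$rank == 0) {
        W[, 1, j] <- 1 / S
      } else {
        W[, seq_len(wj$rank), j] <- wj$W
      }
    }
    if (all(rks == 0))
      stop_radfuse("between-class scatter numerically zero: ",
                   "classes are identical across all features")
    obj$W <- W
    obj$rank <- rks
    obj$r <- length(cls) - 1
  } else {
    r <- length(cls) - 1
    proj <- list(); Ts <- list()
    for (v in names(views)) {
      wv <- whiten_between(Z[[v]], labels)
      if (wv$rank == 0)
        stop_radfuse("between-class scatter numerically zero in view ", v)
      proj[[v]] <- wv$W
      Ts[[v]] <- Z[[v]] %*% wv$W
    }
    steps <- list()
    F <- Ts[[1]]
    for (k in 2:length(views)) {
      Tv <- Ts[[k]]
      Cw <- within_cross_cov(F, Tv, labels)
      sv <- svd(Cw)
      m <- min(ncol(F), ncol(Tv))
      Fa <- F %*% sv$u; Ta <- Tv %*% sv$v
      F <- if (combination == "sum")
        Fa[, seq_len(m), drop = FALSE] + Ta[, seq_len(m), drop = FALSE]
      else cbind(Fa, Ta)
      steps[[k - 1]] <- list(u = sv$u, v = sv$v, m = m)
    }
    obj$proj <- proj
    obj$steps <- steps
    obj$r <- r
  }
  class(obj) <- "fusion_transform"
  obj
}

# Whiten the between-class scatter of X (n x d): returns W (d x rank) with
# t(W) %*% Sb %*% W = I on the retained top min(c-1, rank) directions.
whiten_between <- function(X, labels) {
  n <- nrow(X)
  cls <- sort(unique(labels))
  mu <- colMeans(X)
  Sb <- matrix(0, ncol(X), ncol(X))
  for (k in cls) {
    idx <- labels == k
    d <- colMeans(X[idx, , drop = FALSE]) - mu
    Sb <- Sb + (sum(idx) / n) * tcrossprod(d)
  }
  eg <- eigen(Sb, symmetric = TRUE)
  cutoff <- 1e-10 * max(eg$values, 0)
  keep <- which(eg$values > cutoff & eg$values > 0)
  keep <- keep[seq_len(min(length(keep), length(cls) - 1))]
  if (length(keep) == 0) return(list(W = NULL, rank = 0L))
  W <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), length(keep))
  list(W = W, rank = length(keep))
}

# Pooled within-class cross-covariance between two representations.
within_cross_cov <- function(A, B, labels) {
  out <- matrix(0, ncol(A), ncol(B))
  for (k in unique(labels)) {
    idx <- labels == k
    Ac <- scale(A[idx, , drop = FALSE], scale = FALSE)
    Bc <- scale(B[idx, , drop = FALSE], scale = FALSE)
    out <- out + crossprod(Ac, Bc)
  }
  out / nrow(A)
}

#' Apply a fitted fusion transform to new data
#'
#' Standardizes each view with the training statistics stored in the
#' transform and applies the fitted projections. Deterministic, row-wise
#' (a single held-out lesion gets the same fused values as part of any
#' batch), and never refitted on the supplied data.
#'
#' @param object a `fusion_transform`.
#' @param views named list of matrices matching the fitted channels and
#'   feature names.
#' @param ... unused.
#' @return fused numeric matrix (one column per feature for binary
#'   featurewise fusion).
#' @export
predict.fusion_transform <- function(object, views, ...) {
  miss <- setdiff(object$channels, names(views))
  if (length(miss))
    stop_radfuse("missing fitted channel(s): ", paste(miss, collapse = ", "))
  views <- views[object$channels]
  for (v in views)
    if (!identical(colnames(v), object$feature_names))
      stop_radfuse("feature names do not match the fitted transform")
  Z <- mapply(function(v, s) sweep(sweep(v, 2, s$mean), 2, s$sd, `/`),
              views, object$std, SIMPLIFY = FALSE)
  n <- nrow(Z[[1]])
  p <- length(object$feature_names)
  if (object$strategy == "featurewise") {
    r <- object$r
    cols <- list()
    for (j in seq_len(p)) {
      M <- vapply(Z, function(z) z[, j], numeric(n))
      if (n == 1) M <- matrix(M, nrow = 1)
      rk <- max(object$rank[j], 1L)
      f <- M %*% object$W[, seq_len(rk), j, drop = TRUE]
      cols[[j]] <- matrix(f, nrow = n)
    }
    out <- do.call(cbind, cols)
    colnames(out) <- if (object$r == 1 || all(object$rank <= 1))
      object$feature_names
    else unlist(lapply(seq_len(p), function(j)
      paste0(object$feature_names[j], "_d",
             seq_len(max(object$rank[j], 1L)))))
    out
  } else {
    Ts <- lapply(object$channels, function(v) Z[[v]] %*% object$proj[[v]])
    F <- Ts[[1]]
    for (k in 2:length(Ts)) {
      st <- object$steps[[k - 1]]
      Fa <- F %*% st$u; Ta <- Ts[[k]] %*% st$v
      F <- if (object$combination == "sum")
        Fa[, seq_len(st$m), drop = FALSE] + Ta[, seq_len(st$m), drop = FALSE]
      else cbind(Fa, Ta)
    }
    colnames(F) <- paste0("fused_d", seq_len(ncol(F)))
    F
  }
}

#' @export
print.fusion_transform <- function(x, ...) {
  cat("<fusion_transform> ", x$strategy, " fusion of ",
      length(x$channels), " views (", paste(x$channels, collapse = " + "),
      "), ", length(x$feature_names), " features, classes: ",
      paste(x$classes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Enumerate fusable channel combinations
#'
#' All subsets of size `min_size` up to all channels, ordered by size then
#' lexicographically by channel rank (input order). The canonical top-4
#' input yields the 11 combinations of two, three or four sequences.
#'
#' @param top_sequences character vector of channels, best first.
#' @param min_size smallest subset size (default 2).
#' @return list of character vectors.
#' @examples
#' length(enumerate_combinations(c("ADC", "DWI600", "T2WI", "DCE2")))  # 11
#' @export
enumerate_combinations <- function(top_sequences, min_size = 2) {
  if (anyDuplicated(top_sequences))
    stop_radfuse("duplicate channels in top_sequences")
  k <- length(top_sequences)
  if (k < min_size) stop_radfuse("need at least ", min_size, " channels")
  out <- list()
  for (s in min_size:k) {
    cmb <- utils::combn(seq_len(k), s)
    for (i in seq_len(ncol(cmb)))
      out[[length(out) + 1]] <- top_sequences[cmb[, i]]
  }
  out
}

#' Serialize a fusion transform to JSON
#' @param object a `fusion_transform`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fusion_json <- function(object, path) {
  ser <- list(strategy = object$strategy, combination = object$combination,
              channels = object$channels,
              feature_names = object$feature_names,
              classes = object$classes,
              std = object$std, n_train = object$n_train)
  if (object$strategy == "featurewise") {
    ser$W <- apply(object$W, 3, identity, simplify = FALSE)
    ser$rank <- object$rank
  } else {
    ser$proj <- object$proj
    ser$steps <- object$steps
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
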