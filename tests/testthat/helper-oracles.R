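# Independent brute-force oracles. Everything here is written from the
# definitions with plain loops, sharing no code with the package internals.

# -- discretization (same fixed-bin-count convention, written separately) --
oracle_discretize <- function(vals, nb) {
  r <- range(vals)
  if (r[2] - r[1] <= 0) return(rep(1L, length(vals)))
  b <- floor(nb * (vals - r[1]) / (r[2] - r[1])) + 1L
  pmin(b, nb)
}

# -- brute-force merged symmetric GLCM probability matrix ------------------
oracle_glcm_P <- function(g, nb) {
  d <- dim(g)
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  C <- matrix(0, nb, nb)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- g[x, y, z]
    if (is.na(a)) next
    for (o in offs) {
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      b <- g[x2, y2, z2]
      if (is.na(b)) next
      C[a, b] <- C[a, b] + 1
      C[b, a] <- C[b, a] + 1
    }
  }
  C / sum(C)
}

# -- the 24 GLCM features, naive double loops over grey levels -------------
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P)
  mu <- 0; for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0; for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  lg <- function(x) if (x > 0) log2(x) else 0
  autoc <- cp <- cs <- ct <- contrast <- id <- idm <- idmn <- idn <- 0
  je <- jent <- iv <- ss <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    autoc <- autoc + i * j * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    contrast <- contrast + (i - j)^2 * p
    id <- id + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    je <- je + p^2
    jent <- jent - p * lg(p)
    if (i != j) iv <- iv + p / (i - j)^2
    ss <- ss + (i - mu)^2 * p
    hxy1 <- hxy1 - p * lg(px[i] * px[j])
    hxy2 <- hxy2 - px[i] * px[j] * lg(px[i] * px[j])
  }
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  dent <- 0; for (k in 0:(ng - 1)) dent <- dent - pd[k + 1] * lg(pd[k + 1])
  dvar <- 0; for (k in 0:(ng - 1)) dvar <- dvar + (k - da)^2 * pd[k + 1]
  sa <- 0; sent <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * ps[k - 1]
    sent <- sent - ps[k - 1] * lg(ps[k - 1])
  }
  hx <- 0; for (i in 1:ng) hx <- hx - px[i] * lg(px[i])
  imc1 <- if (hx > 0) (jent - hxy1) / hx else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - jent)), 0))
  keep <- which(px > 0)
  mcc <- if (length(keep) < 2) 1 else {
    m <- length(keep)
    Q <- matrix(0, m, m)
    for (ii in 1:m) for (jj in 1:m) {
      acc <- 0
      for (kk in 1:m)
        acc <- acc + P[keep[ii], keep[kk]] * P[keep[jj], keep[kk]] /
          (px[keep[ii]] * px[keep[kk]])
      Q[ii, jj] <- acc
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(glcm_Autocorrelation = autoc, glcm_ClusterProminence = cp,
    glcm_ClusterShade = cs, glcm_ClusterTendency = ct,
    glcm_Contrast = contrast,
    glcm_Correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    glcm_DifferenceAverage = da, glcm_DifferenceEntropy = dent,
    glcm_DifferenceVariance = dvar, glcm_Id = id, glcm_Idm = idm,
    glcm_Idmn = idmn, glcm_Idn = idn, glcm_Imc1 = imc1, glcm_Imc2 = imc2,
    glcm_InverseVariance = iv, glcm_JointAverage = mu, glcm_JointEnergy = je,
    glcm_JointEntropy = jent, glcm_MaximumProbability = max(P),
    glcm_SumAverage = sa, glcm_SumEntropy = sent, glcm_SumSquares = ss,
    glcm_MCC = mcc)
}

# -- AUC as the all-pairs comparison statistic -----------------------------
oracle_auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# -- exact Wilcoxon signed-rank p by full sign-assignment enumeration ------
oracle_wilcoxon_exact <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  vals <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vals[m + 1] <- sum(r[signs == 1])
  }
  p_le <- mean(vals <= V); p_ge <- mean(vals >= V)
  min(1, 2 * min(p_le, p_ge))
}

# -- ICC(2,1) from an aov mean-squares decomposition -----------------------
oracle_icc21_aov <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# -- exhaustive trace-ratio maximization -----------------------------------
oracle_trace_ratio_best <- function(X, y, k) {
  p <- ncol(X)
  classes <- unique(y)
  mu <- colMeans(X)
  a <- numeric(p); b <- numeric(p)
  for (cl in classes) {
    sub <- X[y == cl, , drop = FALSE]
    mk <- colMeans(sub)
    a <- a + nrow(sub) * (mk - mu)^2
    for (j in 1:p) b[j] <- b[j] + sum((sub[, j] - mk[j])^2)
  }
  best <- -Inf; best_set <- NULL
  for (cmb in utils::combn(p, k, simplify = FALSE)) {
    denom <- sum(b[cmb])
    ratio <- if (denom > 0) sum(a[cmb]) / denom else Inf
    if (ratio > best) { best <- ratio; best_set <- cmb }
  }
  list(ratio = best, set = best_set, a = a, b = b)
}

# -- fixture builders ------------------------------------------------------
make_image_set <- function(vols, mask, spacing = c(1, 1, 1),
                           id = "fx1", class = "HR+") {
  structure(list(lesion_id = id, class_label = class, channels = vols,
                 mask = mask, voxel_spacing = spacing),
            class = "lesion_image_set")
}

ball_mask <- function(r, pad = 2) {
  d <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  co <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  array((co$x - ctr)^2 + (co$y - ctr)^2 + (co$z - ctr)^2 <= r^2,
        dim = c(d, d, d))
}

iso_config <- function(n_bins = 8)
  preprocess_config(target_spacing = c(1, 1, 1), n_bins = n_bins)

# weighted between-class scatter of a fused column
between_scatter_1d <- function(x, y) {
  mu <- mean(x)
  s <- 0
  for (k in unique(y))
    s <- s + (sum(y == k) / length(y)) * (mean(x[y == k]) - mu)^2
  s
}
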