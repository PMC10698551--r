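# Texture features on the fixed-bin-count discretized volume (integer grey
# levels 1..ng inside the mask, NA outside). GLCM/GLRLM aggregate over the
# 13 unique 3D directions at Chebyshev distance 1; GLCM additionally
# contributes 14 per-direction-variance variants.

safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

# Co-occurrence counts for one offset, symmetrized (counts both (i,j) and
# (j,i)); returns ng x ng matrix.
glcm_counts <- function(g, off, ng) {
  nb <- shift3d(g, -off, fill = NA)
  ok <- !is.na(g) & !is.na(nb)
  if (!any(ok)) return(matrix(0, ng, ng))
  idx <- (g[ok] - 1L) * ng + nb[ok]
  cnt <- tabulate(idx, nbins = ng * ng)
  m <- matrix(cnt, ng, ng, byrow = TRUE)
  m + t(m)
}

# The 24 direction-merged GLCM features from a normalized symmetric P.
glcm_feature_values <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)                      # symmetric: px == py
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  # difference and sum marginals
  dvals <- 0:(ng - 1)
  pd <- vapply(dvals, function(k) sum(P[abs(i - j) == k]), numeric(1))
  svals <- 2:(2 * ng)
  ps <- vapply(svals, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(dvals * pd)
  hxy <- -sum(P * safe_log2(P))
  hx <- -sum(px * safe_log2(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(P * safe_log2(pxpy))
  hxy2 <- -sum(pxpy * safe_log2(pxpy))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  autoc <- sum(i * j * P)
  corr <- if (sig2 > 0) (autoc - mu^2) / sig2 else 1
  offd <- i != j
  # maximal correlation coefficient on present grey levels
  keep <- px > 0
  mcc <- if (sum(keep) < 2) 1 else {
    Pp <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]
    Q <- matrix(0, sum(keep), sum(keep))
    for (k in seq_len(sum(keep)))
      Q <- Q + outer(Pp[, k] / pxk, Pp[, k]) / pxk[k]
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }
  c(Autocorrelation = autoc,
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * safe_log2(pd)),
    DifferenceVariance = sum((dvals - da)^2 * pd),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (any(offd)) sum(P[offd] / (i[offd] - j[offd])^2)
                      else 0,
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    SumAverage = sum(svals * ps),
    SumEntropy = -sum(ps * safe_log2(ps)),
    SumSquares = sig2,
    MCC = mcc)
}

glcm_all_features <- function(g, ng, want_merged = TRUE, want_dir = TRUE) {
  offs <- glcm_offsets()
  counts <- lapply(seq_len(nrow(offs)),
                   function(k) glcm_counts(g, as.integer(offs[k, ]), ng))
  merged <- Reduce(`+`, counts)
  out <- numeric(0)
  if (want_merged) {
    P <- merged / max(sum(merged), 1)
    v <- glcm_feature_values(P)
    names(v) <- paste0("glcm_", names(v))
    out <- c(out, v)
  }
  if (want_dir) {
    base <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
              "ClusterTendency", "Contrast", "Correlation",
              "DifferenceAverage", "DifferenceEntropy", "Id", "Idm",
              "JointEnergy", "JointEntropy", "MaximumProbability",
              "SumEntropy")
    per_dir <- vapply(counts, function(cm) {
      s <- sum(cm)
      if (s == 0) return(rep(NA_real_, length(base)))
      glcm_feature_values(cm / s)[base]
    }, numeric(length(base)))
    dv <- apply(per_dir, 1, function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 2) return(0)
      mean((x - mean(x))^2)
    })
    names(dv) <- paste0("glcm_", base, "DirectionalVariance")
    out <- c(out, dv)
  }
  out
}

# Run-length matrix merged over the 13 directions. Returns ng x Lmax counts.
glrlm_matrix <- function(g, ng) {
  d <- dim(g)
  n <- prod(d)
  coords <- arrayInd(seq_len(n), d)
  gv <- as.vector(g)
  offs <- glcm_offsets()
  R <- matrix(0, ng, max(d))
  for (k in seq_len(nrow(offs))) {
    o <- as.integer(offs[k, ])
    S <- sum(o^2)
    t_along <- coords %*% o
    key <- coords * S - tcrossprod(t_along, o)   # constant along each line
    key <- sweep(key, 2, apply(key, 2, min))
    A2 <- max(key[, 2]) + 1; A3 <- max(key[, 3]) + 1
    kk <- key[, 1] * A2 * A3 + key[, 2] * A3 + key[, 3]
    ord <- order(kk, t_along)
    gs <- gv[ord]; ks <- kk[ord]
    nn <- length(gs)
    newrun <- c(TRUE, ks[-1] != ks[-nn] |
                  xor(is.na(gs[-1]), is.na(gs[-nn])) |
                  (!is.na(gs[-1]) & !is.na(gs[-nn]) & gs[-1] != gs[-nn]))
    starts <- which(newrun)
    lens <- diff(c(starts, nn + 1))
    grays <- gs[starts]
    keep <- !is.na(grays)
    if (!any(keep)) next
    acc <- tapply(rep(1, sum(keep)),
                  list(factor(grays[keep], levels = seq_len(ng)),
                       factor(lens[keep], levels = seq_len(ncol(R)))),
                  sum, default = 0)
    R <- R + acc
  }
  R
}

glrlm_features <- function(g, ng, n_voxels) {
  R <- glrlm_matrix(g, ng)
  Nr <- sum(R)
  lv <- seq_len(ncol(R)); gvv <- seq_len(nrow(R))
  rg <- rowSums(R); rl <- colSums(R)
  p <- R / Nr
  mu_g <- sum(gvv * rowSums(p)); mu_l <- sum(lv * colSums(p))
  c(glrlm_ShortRunEmphasis = sum(t(R) / lv^2) / Nr,
    glrlm_LongRunEmphasis = sum(t(R) * lv^2) / Nr,
    glrlm_GrayLevelNonUniformity = sum(rg^2) / Nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(rg^2) / Nr^2,
    glrlm_RunLengthNonUniformity = sum(rl^2) / Nr,
    glrlm_RunLengthNonUniformityNormalized = sum(rl^2) / Nr^2,
    glrlm_RunPercentage = Nr / (n_voxels * 13),
    glrlm_GrayLevelVariance = sum((gvv - mu_g)^2 * rowSums(p)),
    glrlm_RunVariance = sum((lv - mu_l)^2 * colSums(p)),
    glrlm_RunEntropy = -sum(p * safe_log2(p)),
    glrlm_LowGrayLevelRunEmphasis = sum(R / gvv^2) / Nr,
    glrlm_HighGrayLevelRunEmphasis = sum(R * gvv^2) / Nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum((R / gvv^2) %*% diag(1 / lv^2,
      ncol(R))) / Nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum((R * gvv^2) %*% diag(1 / lv^2,
      ncol(R))) / Nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum((R / gvv^2) %*% diag(lv^2,
      ncol(R))) / Nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum((R * gvv^2) %*% diag(lv^2,
      ncol(R))) / Nr)
}

# 26-connected equal-grey zones via iterative min-label propagation.
glszm_zones <- function(g) {
  mask <- !is.na(g)
  lab <- array(0, dim = dim(g))
  lab[mask] <- seq_len(sum(mask))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- as.matrix(offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ])
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      o <- as.integer(offs[k, ])
      sh <- shift3d(lab, o, fill = 0)
      shg <- shift3d(g, o, fill = NA)
      upd <- mask & !is.na(shg) & shg == g & sh > 0 & sh < lab
      if (any(upd)) { lab[upd] <- sh[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  sizes <- table(lab[mask])
  zone_gray <- g[match(as.integer(names(sizes)), lab)]
  data.frame(gray = as.integer(zone_gray), size = as.integer(sizes))
}

glszm_features <- function(g, ng, n_voxels) {
  z <- glszm_zones(g)
  Nz <- nrow(z)
  smax <- max(z$size)
  Z <- tapply(rep(1, Nz), list(factor(z$gray, levels = seq_len(ng)),
                               factor(z$size, levels = seq_len(smax))),
              sum, default = 0)
  sv <- seq_len(smax); gvv <- seq_len(ng)
  zg <- rowSums(Z); zs <- colSums(Z)
  p <- Z / Nz
  mu_g <- sum(gvv * rowSums(p)); mu_s <- sum(sv * colSums(p))
  c(glszm_SmallAreaEmphasis = sum(t(Z) / sv^2) / Nz,
    glszm_LargeAreaEmphasis = sum(t(Z) * sv^2) / Nz,
    glszm_GrayLevelNonUniformity = sum(zg^2) / Nz,
    glszm_GrayLevelNonUniformityNormalized = sum(zg^2) / Nz^2,
    glszm_SizeZoneNonUniformity = sum(zs^2) / Nz,
    glszm_SizeZoneNonUniformityNormalized = sum(zs^2) / Nz^2,
    glszm_ZonePercentage = Nz / n_voxels,
    glszm_GrayLevelVariance = sum((gvv - mu_g)^2 * rowSums(p)),
    glszm_ZoneVariance = sum((sv - mu_s)^2 * colSums(p)),
    glszm_ZoneEntropy = -sum(p * safe_log2(p)),
    glszm_LowGrayLevelZoneEmphasis = sum(Z / gvv^2) / Nz,
    glszm_HighGrayLevelZoneEmphasis = sum(Z * gvv^2) / Nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum((Z / gvv^2) %*%
      diag(1 / sv^2, smax)) / Nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum((Z * gvv^2) %*%
      diag(1 / sv^2, smax)) / Nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum((Z / gvv^2) %*%
      diag(sv^2, smax)) / Nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum((Z * gvv^2) %*%
      diag(sv^2, smax)) / Nz)
}

ngtdm_features <- function(g, ng) {
  mask <- !is.na(g)
  gz <- g; gz[!mask] <- 0L
  ssum <- array(0, dim = dim(g)); cnt <- array(0, dim = dim(g))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- as.matrix(offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ])
  for (k in seq_len(nrow(offs))) {
    o <- as.integer(offs[k, ])
    ssum <- ssum + shift3d(gz, o, fill = 0)
    cnt <- cnt + shift3d(mask * 1L, o, fill = 0)
  }
  use <- mask & cnt > 0
  A <- ssum[use] / cnt[use]
  gu <- g[use]
  N <- length(gu)
  s_i <- vapply(seq_len(ng), function(lvl) sum(abs(lvl - A[gu == lvl])),
                numeric(1))
  n_i <- tabulate(gu, nbins = ng)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  ngp <- length(pres)
  pij <- outer(p_i[pres], p_i[pres])
  dij2 <- outer(pres, pres, function(a, b) (a - b)^2)
  contrast <- if (ngp > 1)
    sum(pij * dij2) / (ngp * (ngp - 1)) * sum(s_i) / N else 0
  denb <- sum(abs(outer(pres * p_i[pres], pres * p_i[pres], `-`)))
  busy <- if (denb > 0) sum(p_i * s_i) / denb else 0
  cplx <- if (N > 0) {
    m <- outer(pres, pres, function(a, b) abs(a - b)) *
      (outer(p_i[pres] * s_i[pres], rep(1, ngp)) +
         outer(rep(1, ngp), p_i[pres] * s_i[pres])) /
      (outer(p_i[pres], p_i[pres], `+`))
    sum(m) / N
  } else 0
  dens <- sum(s_i)
  strength <- if (dens > 0)
    sum((outer(p_i[pres], p_i[pres], `+`)) * dij2) / dens else 0
  coars <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  c(ngtdm_Coarseness = coars, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busy, ngtdm_Complexity = cplx,
    ngtdm_Strength = strength)
}
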