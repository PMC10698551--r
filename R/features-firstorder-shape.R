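# First-order (intensity histogram) features on normalized in-mask values.
# Entropy and Uniformity are computed on the fixed-bin-count discretization;
# all other statistics on the continuous values. Moments use the population
# (1/N) convention; percentiles use linear interpolation between order
# statistics.
firstorder_features <- function(values, gray_levels, voxel_volume_mm3) {
  n <- length(values)
  p <- tabulate(gray_levels, nbins = max(gray_levels))
  p <- p[p > 0] / n
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  robust <- values[values >= q[1] & values <= q[5]]
  sk <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((values - mu)^4) / m2^2 else 0
  c(firstorder_Energy = sum(values^2),
    firstorder_TotalEnergy = voxel_volume_mm3 * sum(values^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(values),
    `firstorder_10Percentile` = q[1],
    `firstorder_90Percentile` = q[5],
    firstorder_Maximum = max(values),
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(values) - min(values),
    firstorder_MeanAbsoluteDeviation = mean(abs(values - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      mean(abs(robust - mean(robust))),
    firstorder_RootMeanSquared = sqrt(mean(values^2)),
    firstorder_StandardDeviation = sqrt(m2),
    firstorder_Skewness = sk,
    firstorder_Kurtosis = ku,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

# Exposed-face surface area (sum of mask faces not shared with a mask
# neighbour), in mm^2. This voxel-face convention makes a cube of side L
# have area 6 L^2 exactly.
voxel_surface_area <- function(mask, spacing) {
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[a] <- s
      nb <- shift3d(mask, off, fill = FALSE)
      area <- area + sum(mask & !nb) * face[a]
    }
  }
  area
}

# Largest pairwise distance among boundary-voxel centres, memory-chunked.
max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- 0
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[s:e, , drop = FALSE] %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

boundary_points <- function(mask, spacing) {
  surf <- mask & !erode6(mask)
  idx <- which(surf, arr.ind = TRUE)
  sweep(idx, 2, spacing, `*`)
}

# Morphology features from the (resampled) mask; channel-independent.
shape_features <- function(mask, spacing) {
  n <- sum(mask)
  vol <- n * prod(spacing)
  area <- voxel_surface_area(mask, spacing)
  sph <- (36 * pi)^(1 / 3) * vol^(2 / 3) / area
  pts <- boundary_points(mask, spacing)
  max3d <- max_pairwise_dist(pts)
  plane_diam <- function(keep_axes, split_axis) {
    ids <- unique(pts[, split_axis])
    best <- 0
    for (v in ids) {
      sub <- pts[pts[, split_axis] == v, keep_axes, drop = FALSE]
      best <- max(best, max_pairwise_dist(sub))
    }
    best
  }
  idx <- which(mask, arr.ind = TRUE)
  phys <- sweep(idx, 2, spacing, `*`)
  cv <- stats::cov(phys) * (n - 1) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  c(shape_VoxelVolume = vol,
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = area / vol,
    shape_Sphericity = sph,
    shape_SphericalDisproportion = 1 / sph,
    shape_Compactness2 = sph^3,
    shape_Maximum3DDiameter = max3d,
    shape_Maximum2DDiameterSlice = plane_diam(c(1, 2), 3),
    shape_Maximum2DDiameterColumn = plane_diam(c(1, 3), 2),
    shape_Maximum2DDiameterRow = plane_diam(c(2, 3), 1),
    shape_MajorAxisLength = 4 * sqrt(ev[1]),
    shape_MinorAxisLength = 4 * sqrt(ev[2]),
    shape_LeastAxisLength = 4 * sqrt(ev[3]),
    shape_Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    shape_Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}
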