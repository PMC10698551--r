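#' Preprocessing configuration
#'
#' Holds the resampling and intensity-normalization conventions applied
#' before feature extraction: target voxel spacing 1.096 x 1.096 x 1.2 mm,
#' min-max intensity normalization to 0-255, and a 32-level fixed-bin-count
#' discretization for texture features.
#'
#' @param target_spacing numeric length 3, mm.
#' @param intensity_range numeric length 2, output intensity range.
#' @param n_bins number of grey levels for texture discretization (>= 2).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(1.096, 1.096, 1.2),
                              intensity_range = c(0, 255),
                              n_bins = 32L) {
  stopifnot(length(target_spacing) == 3, all(target_spacing > 0),
            length(intensity_range) == 2,
            intensity_range[1] < intensity_range[2], n_bins >= 2)
  structure(list(target_spacing = target_spacing,
                 intensity_range = intensity_range,
                 n_bins = as.integer(n_bins)),
            class = "preprocess_config")
}

# Trilinear (volume) / nearest-neighbour (mask) resampling with half-voxel
# centre alignment; output grid shape = ceil(physical extent / new spacing).
resample3d <- function(arr, spacing_in, spacing_out, method = c("linear",
                                                                "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  extent <- d * spacing_in
  d_out <- pmax(as.integer(ceiling(extent / spacing_out - 1e-9)), 1L)
  # centre of output voxel i at (i - 0.5) * spacing_out; map to input
  # fractional voxel index (centres at integers 1..d)
  ax <- lapply(1:3, function(a)
    ((seq_len(d_out[a]) - 0.5) * spacing_out[a]) / spacing_in[a] + 0.5)
  if (method == "nearest") {
    ix <- lapply(1:3, function(a) pmin(pmax(round(ax[[a]]), 1L), d[a]))
    return(arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(ax[[a]]), 1L), d[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
  fr <- lapply(1:3, function(a) pmin(pmax(ax[[a]] - lo[[a]], 0), 1))
  out <- array(0, dim = d_out)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
    w <- outer(outer(wx, wy), wz)
    ixx <- if (cx == 0) lo[[1]] else hi[[1]]
    iyy <- if (cy == 0) lo[[2]] else hi[[2]]
    izz <- if (cz == 0) lo[[3]] else hi[[3]]
    out <- out + w * arr[ixx, iyy, izz, drop = FALSE]
  }
  out
}

#' Resample and intensity-normalize a volume/mask pair
#'
#' Resamples the intensity volume (trilinear) and mask (nearest neighbour)
#' to the configured target spacing, then min-max maps intensities over the
#' whole volume onto the configured range (default 0-255). A zero-intensity
#' range maps the whole volume to the range midpoint.
#'
#' @param volume 3D numeric array.
#' @param mask logical/0-1 3D array, same dimensions.
#' @param config a [preprocess_config()].
#' @param spacing input voxel spacing (mm); default assumes the volume is
#'   already on the target grid.
#' @param lesion_id used in error messages when the mask vanishes.
#' @return list with `volume` (normalized), `mask` (logical) and `spacing`.
#' @export
preprocess <- function(volume, mask, config = preprocess_config(),
                       spacing = config$target_spacing,
                       lesion_id = "lesion") {
  stopifnot(identical(dim(volume), dim(mask)))
  if (!isTRUE(all.equal(spacing, config$target_spacing,
                        tolerance = 1e-9))) {
    volume <- resample3d(volume, spacing, config$target_spacing, "linear")
    mask <- resample3d((mask != 0) * 1L, spacing, config$target_spacing,
                       "nearest") != 0
  } else {
    mask <- mask != 0
  }
  if (!any(mask))
    stop_radfuse("mask of ", lesion_id, " vanished after resampling")
  r <- range(volume)
  lo <- config$intensity_range[1]; hi <- config$intensity_range[2]
  if (r[2] - r[1] <= 0) {
    volume[] <- (lo + hi) / 2
  } else {
    volume <- lo + (volume - r[1]) / (r[2] - r[1]) * (hi - lo)
  }
  list(volume = volume, mask = mask, spacing = config$target_spacing)
}

# Fixed-bin-count discretization of in-mask intensities to 1..n_bins;
# the upper edge maps into the last bin, constant regions into bin 1.
discretize_mask <- function(volume, mask, n_bins) {
  vals <- volume[mask]
  r <- range(vals)
  g <- array(NA_integer_, dim = dim(volume))
  if (r[2] - r[1] <= 0) {
    g[mask] <- 1L
  } else {
    b <- floor(n_bins * (vals - r[1]) / (r[2] - r[1])) + 1L
    g[mask] <- pmin(b, n_bins)
  }
  g
}
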