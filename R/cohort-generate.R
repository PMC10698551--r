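#' Generate a synthetic lesion cohort
#'
#' Produces either per-channel radiomics feature tables (`mode = "features"`)
#' or voxel-level lesion image sets (`mode = "images"`) with the class
#' structure described by a [cohort_spec()]. Both modes draw every random
#' quantity from streams derived from `spec$seed`, so repeated calls with the
#' same spec are identical.
#'
#' In images mode each lesion is a superellipsoid blob whose boundary is
#' perturbed by a smooth Gaussian random field scaled by the class
#' irregularity, on a grid at the standard 1.096 x 1.096 x 1.2 mm spacing;
#' channel intensities are correlated Gaussian random fields passed through a
#' class/channel-specific peaedness transform so that, e.g., the ADC channel
#' of triple-negative lesions has a more concentrated intensity histogram
#' (lower entropy, lower mean absolute deviation).
#'
#' In features mode the per-channel 109-feature tables are synthesized
#' directly from the same latent layout: shape features derive from the
#' class-dependent size/irregularity latents and are identical across
#' channels; intensity/texture features carry the class-conditional mean
#' shifts of `spec$channel_effects`, with the signal features of each channel
#' sharing a channel-private noise factor.
#'
#' @param spec a [cohort_spec()].
#' @param mode "features" or "images".
#' @param channels channels to generate (default all ten).
#' @return features mode: named list of `feature_table` data frames, one per
#'   channel; images mode: list of `lesion_image_set` objects.
#' @examples
#' tabs <- generate_cohort(cohort_spec(n_per_class =
#'   c("HR+" = 20L, HEBC = 8L, TNBC = 8L), test_size = 9L),
#'   channels = c("ADC", "DWI600"))
#' nrow(tabs$ADC)
#' @export
generate_cohort <- function(spec, mode = c("features", "images"),
                            channels = channel_names()) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  bad <- setdiff(channels, channel_names())
  if (length(bad)) stop_radfuse("unknown channels: ", paste(bad, collapse = ", "))
  classes <- rep(spec$class_names, spec$n_per_class)
  ids <- sprintf("L%04d", seq_along(classes))
  if (mode == "features") {
    generate_feature_tables(spec, ids, classes, channels)
  } else {
    lapply(seq_along(ids), function(i)
      generate_lesion(spec, ids[i], classes[i], channels))
  }
}

# ---- features mode ---------------------------------------------------------

feature_scale_map <- function(names) {
  special <- list(
    firstorder_Entropy = c(3.2, 0.6), firstorder_Uniformity = c(0.18, 0.05),
    firstorder_MeanAbsoluteDeviation = c(18, 4),
    firstorder_RobustMeanAbsoluteDeviation = c(12, 3),
    firstorder_90Percentile = c(180, 25), firstorder_RootMeanSquared = c(120, 20),
    glcm_Correlation = c(0.55, 0.12), glcm_Imc2 = c(0.75, 0.1),
    glcm_ClusterTendency = c(14, 4), glcm_Contrast = c(8, 2.5),
    glcm_JointEntropy = c(6.5, 0.9))
  t(vapply(names, function(nm) {
    if (!is.null(special[[nm]])) return(special[[nm]])
    h <- 0
    for (ch in utf8ToInt(nm)) h <- (h * 131 + ch) %% 99991
    ctr <- 0.5 + (h %% 997) / 10   # deterministic plausible magnitude
    c(ctr, 0.2 * ctr)
  }, numeric(2)))
}

shape_feature_matrix <- function(spec, classes, n) {
  s <- stats::rlnorm(n, log(spec$size_median_mm[classes]),
                     spec$size_sdlog[classes])
  ir <- pmin(pmax(spec$shape_irregularity[classes] +
                    stats::rnorm(n, 0, 0.20), 0.02), 0.95)
  jig <- function(sd = 0.12) exp(stats::rnorm(n, 0, sd))
  a <- s / 2
  b <- a * (1 - 0.15 * ir) * jig()
  c3 <- a * (1 - 0.25 * ir) * jig()
  vol <- 4 * pi / 3 * a * b * c3 * jig()
  area <- 4 * pi * ((a * b)^1.6 + (a * c3)^1.6 + (b * c3)^1.6)^(1 / 1.6) /
    3^(1 / 1.6) * (1 + 0.8 * ir) * jig()
  sph <- (36 * pi)^(1 / 3) * vol^(2 / 3) / area
  out <- cbind(
    shape_VoxelVolume = vol, shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = area / vol, shape_Sphericity = sph,
    shape_SphericalDisproportion = 1 / sph, shape_Compactness2 = sph^3,
    shape_Maximum3DDiameter = 2 * a * (1 + 0.1 * ir) * jig(0.03),
    shape_Maximum2DDiameterSlice = 2 * pmax(a, b) * jig(0.03),
    shape_Maximum2DDiameterColumn = 2 * pmax(a, c3) * jig(0.03),
    shape_Maximum2DDiameterRow = 2 * pmax(b, c3) * jig(0.03),
    shape_MajorAxisLength = 1.79 * a * jig(0.02),
    shape_MinorAxisLength = 1.79 * b * jig(0.02),
    shape_LeastAxisLength = 1.79 * c3 * jig(0.02),
    shape_Elongation = b / a, shape_Flatness = c3 / a)
  out
}

generate_feature_tables <- function(spec, ids, classes, channels) {
  reg <- feature_registry()
  n <- length(ids)
  shape_mat <- with_seed(derive_seed(spec$seed, "shape"),
                         shape_feature_matrix(spec, classes, n))
  sets <- signal_sets()
  nonshape <- reg$name[reg$group != "shape"]
  scales <- feature_scale_map(nonshape)
  eff <- spec$channel_effects
  out <- lapply(channels, function(ch) {
    vals <- with_seed(derive_seed(spec$seed, paste0("feat:", ch)), {
      u_ent <- stats::rnorm(n); u_tex <- stats::rnorm(n); u_bg <- stats::rnorm(n)
      z <- matrix(stats::rnorm(n * length(nonshape), 0, 0.6), n,
                  dimnames = list(NULL, nonshape))
      # channel-wide background correlation for non-signal features
      insig <- !(nonshape %in% unlist(lapply(sets, `[[`, "feature")))
      z[, insig] <- z[, insig] * sqrt(0.75 / 0.36) + 0.5 * u_bg
      for (set_name in names(sets)) {
        set <- sets[[set_name]]
        u <- if (set_name == "ENT") u_ent else u_tex
        shift <- numeric(n)
        rows <- eff[eff$channel == ch & eff$set == set_name, , drop = FALSE]
        for (k in seq_len(nrow(rows)))
          shift[classes == rows$class[k]] <- shift[classes == rows$class[k]] +
            rows$shift[k]
        for (j in seq_len(nrow(set))) {
          f <- set$feature[j]
          z[, f] <- set$sign[j] * (shift + 0.8 * u) + z[, f]
        }
      }
      sweep(sweep(z, 2, scales[, 2], `*`), 2, scales[, 1], `+`)
    })
    full <- cbind(as.data.frame(vals), as.data.frame(shape_mat))
    full <- full[, reg$name]
    tab <- cbind(data.frame(lesion_id = ids, class = classes,
                            stringsAsFactors = FALSE), full)
    attr(tab, "channel") <- ch
    class(tab) <- c("feature_table", "data.frame")
    tab
  })
  names(out) <- channels
  out
}

# ---- images mode -----------------------------------------------------------

# Smooth zero-mean unit-variance Gaussian random field via FFT convolution
# of white noise with a Gaussian kernel (periodic boundary).
grf3 <- function(dims, corlen) {
  w <- array(stats::rnorm(prod(dims)), dim = dims)
  k <- lapply(dims, function(d) {
    x <- c(0:(d %/% 2), -((d - d %/% 2 - 1):1))
    if (length(x) != d) x <- x[seq_len(d)]
    x
  })
  kern <- exp(-(outer(outer(k[[1]]^2, k[[2]]^2, `+`), k[[3]]^2, `+`)) /
                (2 * corlen^2))
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(kern), inverse = TRUE)) /
    prod(dims)
  (sm - mean(sm)) / stats::sd(sm)
}

image_texture_params <- function(spec, class, channel) {
  eff <- spec$channel_effects
  ent <- sum(eff$shift[eff$class == class & eff$channel == channel &
                         eff$set == "ENT"])
  tex <- sum(eff$shift[eff$class == class & eff$channel == channel &
                         eff$set == "TEX"])
  list(peak = min(max(0.3 - 0.9 * ent, 0.05), 2),
       corlen = 2.5 + 1.5 * abs(tex))
}

#' Generate one synthetic lesion image set
#'
#' @param spec a [cohort_spec()].
#' @param lesion_id identifier; also seeds this lesion's random stream.
#' @param class one of `spec$class_names`.
#' @param channels channel volumes to synthesize.
#' @return a `lesion_image_set`: list with `lesion_id`, `class_label`,
#'   `channels` (named list of 3D arrays), `mask` (logical 3D array) and
#'   `voxel_spacing` in mm.
#' @export
generate_lesion <- function(spec, lesion_id, class,
                            channels = channel_names()) {
  stopifnot(class %in% spec$class_names)
  spacing <- c(1.096, 1.096, 1.2)
  lseed <- derive_seed(spec$seed, paste0("lesion:", lesion_id))
  geo <- with_seed(lseed, {
    s <- stats::rlnorm(1, log(spec$size_median_mm[class]),
                       spec$size_sdlog[class])
    s <- min(max(s, 8), 70)
    ir <- min(max(spec$shape_irregularity[class] + stats::rnorm(1, 0, 0.20),
                  0.02), 0.95)
    dims <- pmax(ceiling((s * 1.5 + 8) / spacing), 12L)
    ctr <- (dims + 1) / 2
    axes <- c(1, (1 - 0.15 * ir) * exp(stats::rnorm(1, 0, 0.05)),
              (1 - 0.25 * ir) * exp(stats::rnorm(1, 0, 0.05)))
    # calibrated shrink so the median mask max-diameter matches s: the
    # voxelized surface adds ~3% and positive boundary bumps near the tips
    # add ~1.06 * irregularity * amplitude (fit over 280 lesions)
    amp <- 0.35
    a <- (s / 2) / (1.03 + 1.06 * ir * amp)
    xs <- (seq_len(dims[1]) - ctr[1]) * spacing[1]
    ys <- (seq_len(dims[2]) - ctr[2]) * spacing[2]
    zs <- (seq_len(dims[3]) - ctr[3]) * spacing[3]
    p <- 2.5
    u <- (outer(outer(abs(xs / (a * axes[1]))^p,
                      abs(ys / (a * axes[2]))^p, `+`),
                abs(zs / (a * axes[3]))^p, `+`))^(1 / p)
    g <- grf3(dims, corlen = max(2, s / 3 / mean(spacing)))
    mask <- u <= 1 + ir * amp * g
    if (!any(mask)) mask <- u <= 1
    mask <- largest_component(mask)
    list(mask = mask, dims = dims)
  })
  vols <- lapply(channels, function(ch) {
    par <- image_texture_params(spec, class, ch)
    with_seed(derive_seed(lseed, paste0("ch:", ch)), {
      z <- grf3(geo$dims, par$corlen)
      tx <- exp(par$peak * z)
      bg <- abs(stats::rnorm(prod(geo$dims), 0, 0.02))
      v <- array(bg, dim = geo$dims)
      v[geo$mask] <- 0.1 + tx[geo$mask]
      v
    })
  })
  names(vols) <- channels
  structure(list(lesion_id = lesion_id, class_label = class,
                 channels = vols, mask = geo$mask, voxel_spacing = spacing),
            class = "lesion_image_set")
}

#' @export
print.lesion_image_set <- function(x, ...) {
  cat("<lesion_image_set> ", x$lesion_id, " (", x$class_label, "), grid ",
      paste(dim(x$mask), collapse = "x"), ", ", sum(x$mask),
      " mask voxels, channels: ", paste(names(x$channels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Largest 6-connected component of a logical array (frontier BFS flood
# fill on linear indices; one visit per voxel).
largest_component <- function(mask) {
  d <- dim(mask)
  visited <- array(FALSE, dim = d)
  strides <- c(1L, d[1], d[1] * d[2])
  lin <- function(co) (co[, 3] - 1L) * strides[3] +
    (co[, 2] - 1L) * strides[2] + co[, 1]
  best <- integer(0)
  todo <- which(mask & !visited)
  while (length(todo)) {
    comp <- integer(0)
    frontier <- todo[1]
    visited[frontier] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      co <- arrayInd(frontier, d)
      nb <- integer(0)
      for (a in 1:3) for (s in c(-1L, 1L)) {
        co2 <- co
        co2[, a] <- co2[, a] + s
        ok <- co2[, a] >= 1L & co2[, a] <= d[a]
        if (any(ok)) nb <- c(nb, lin(co2[ok, , drop = FALSE]))
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
    todo <- which(mask & !visited)
  }
  out <- array(FALSE, dim = d)
  out[best] <- TRUE
  out
}

dilate6 <- function(mask) {
  out <- mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out | shift3d(mask, off, fill = FALSE)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out & shift3d(mask, off, fill = FALSE)
  out
}

#' Simulate a second rater's delineation of a mask
#'
#' Perturbs the boundary of a binary mask by a stated physical magnitude:
#' within the band between the k-fold erosion and k-fold dilation of the
#' mask (k = perturbation in voxels), voxels are included where a smooth
#' random field is positive. A zero perturbation returns the input mask
#' unchanged, so inter-rater reliability testing can span the full agreement
#' range.
#'
#' @param mask logical 3D array, nonempty.
#' @param perturbation_mm boundary perturbation magnitude (mm).
#' @param seed integer seed for the perturbation field.
#' @param voxel_spacing mm per voxel along each axis.
#' @return list of class `rater_pair` with `mask_a`, `mask_b`,
#'   `perturbation_mm`.
#' @export
make_rater_pair <- function(mask, perturbation_mm, seed,
                            voxel_spacing = c(1, 1, 1)) {
  if (!any(mask)) stop_radfuse("mask is empty")
  k <- round(perturbation_mm / min(voxel_spacing))
  if (k <= 0) {
    mask_b <- mask
  } else {
    d <- mask; e <- mask
    for (i in seq_len(k)) { d <- dilate6(d); e <- erode6(e) }
    g <- with_seed(derive_seed(seed, "rater"), grf3(dim(mask), corlen = 3))
    mask_b <- e | (d & !e & g > 0)
    if (!any(mask_b))
      stop_radfuse("perturbation of ", perturbation_mm,
                   " mm leaves an empty mask")
  }
  structure(list(mask_a = mask, mask_b = mask_b,
                 perturbation_mm = perturbation_mm), class = "rater_pair")
}

#' Stratified train/test split
#'
#' Splits lesion indices into train and test sets with per-class test counts
#' allocated by largest remainder, so every class's test fraction is within
#' one lesion of the global fraction. With the default 466-lesion cohort and
#' `test_size = 129` this reproduces a 337/129 partition.
#'
#' @param labels class label per lesion.
#' @param test_size number of held-out lesions.
#' @param seed integer seed.
#' @param allow_zero_test permit `test_size = 0` (everything in train).
#' @return list with integer vectors `train_ids` and `test_ids` (indices
#'   into `labels`).
#' @export
split_cohort <- function(labels, test_size, seed, allow_zero_test = FALSE) {
  n <- length(labels)
  if (test_size >= n) stop_radfuse("test_size must be < number of lesions")
  if (test_size <= 0 && !allow_zero_test)
    stop_radfuse("test_size must be positive")
  tab <- table(labels)
  if (length(tab) < 2) stop_radfuse("need at least two classes to stratify")
  if (any(tab < 2)) stop_radfuse("every class needs at least 2 members")
  quota <- as.numeric(tab) * test_size / n
  base <- floor(quota)
  rem <- test_size - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), -as.numeric(tab), names(tab))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  test_ids <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(seq_along(tab), function(g) {
      idx <- which(labels == names(tab)[g])
      if (base[g] == 0) return(integer(0))
      sample(idx, base[g])
    }))
  })
  test_ids <- sort(test_ids)
  list(train_ids = setdiff(seq_len(n), test_ids), test_ids = test_ids)
}

#' Write an images-mode cohort to NIfTI files
#'
#' One `.nii.gz` per channel per lesion plus the mask, and a JSON manifest
#' recording lesion ids, classes and voxel spacing. Requires the RNifti
#' package.
#'
#' @param lesions list of `lesion_image_set` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort_nifti <- function(lesions, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_radfuse("RNifti is required to write NIfTI output")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (les in lesions) {
    for (ch in names(les$channels)) {
      img <- RNifti::asNifti(les$channels[[ch]],
                             pixdim = les$voxel_spacing)
      RNifti::writeNifti(img, file.path(dir,
        sprintf("%s_%s.nii.gz", les$lesion_id, ch)))
    }
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(les$mask),
                                             dim = dim(les$mask)),
                                       pixdim = les$voxel_spacing),
                       file.path(dir, sprintf("%s_mask.nii.gz",
                                              les$lesion_id)))
    manifest[[les$lesion_id]] <- list(class = les$class_label,
                                      spacing = les$voxel_spacing)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
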