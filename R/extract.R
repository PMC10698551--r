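#' Extract radiomics features from a lesion image set
#'
#' Preprocesses each channel volume (resampling to the target spacing and
#' 0-255 normalization) and computes the registry's features. Morphology
#' features are computed once from the mask and repeated for every channel
#' (geometry is channel-independent after co-registration); intensity and
#' texture features are computed per channel, texture on the fixed-bin-count
#' discretization inside the mask with GLCM/GLRLM aggregated symmetrically
#' over the 13 unique 3D direction offsets at distance 1.
#'
#' @param image_set a `lesion_image_set` (see [generate_lesion()]).
#' @param registry a [feature_registry()]; subsetting it restricts which
#'   feature groups are computed.
#' @param config a [preprocess_config()].
#' @return named list (per channel) of `feature_vector` objects: lists with
#'   `lesion_id`, `channel` and the named numeric `values`.
#' @export
extract_features <- function(image_set, registry = feature_registry(),
                             config = preprocess_config()) {
  stopifnot(inherits(image_set, "lesion_image_set"))
  chs <- names(image_set$channels)
  bad <- setdiff(chs, channel_names())
  if (length(bad))
    stop_radfuse("unknown channel(s): ", paste(bad, collapse = ", "))
  groups <- unique(registry$group)
  pp_first <- preprocess(image_set$channels[[1]], image_set$mask, config,
                         spacing = image_set$voxel_spacing,
                         lesion_id = image_set$lesion_id)
  mask <- pp_first$mask
  if (sum(mask) < 2)
    stop_radfuse("mask of ", image_set$lesion_id, " has fewer than 2 voxels")
  spacing <- config$target_spacing
  shape_vals <- if ("shape" %in% groups) shape_features(mask, spacing)
  bb <- mask_bbox(mask, margin = 1L)
  mask_c <- crop_bbox(mask, bb)
  out <- lapply(seq_along(chs), function(k) {
    pp <- if (k == 1) pp_first else
      preprocess(image_set$channels[[k]], image_set$mask, config,
                 spacing = image_set$voxel_spacing,
                 lesion_id = image_set$lesion_id)
    vol <- crop_bbox(pp$volume, bb)
    vals <- vol[mask_c]
    g <- discretize_mask(vol, mask_c, config$n_bins)
    ng <- config$n_bins
    feats <- numeric(0)
    if ("firstorder" %in% groups)
      feats <- c(feats, firstorder_features(vals, g[mask_c], prod(spacing)))
    if (!is.null(shape_vals)) feats <- c(feats, shape_vals)
    if (any(c("glcm", "glcmdir") %in% groups))
      feats <- c(feats, glcm_all_features(g, ng,
                                          want_merged = "glcm" %in% groups,
                                          want_dir = "glcmdir" %in% groups))
    if ("glrlm" %in% groups)
      feats <- c(feats, glrlm_features(g, ng, sum(mask_c)))
    if ("glszm" %in% groups)
      feats <- c(feats, glszm_features(g, ng, sum(mask_c)))
    if ("ngtdm" %in% groups)
      feats <- c(feats, ngtdm_features(g, ng))
    missing <- setdiff(registry$name, names(feats))
    if (length(missing))
      stop_radfuse("features not computed: ", paste(missing, collapse = ", "))
    structure(list(lesion_id = image_set$lesion_id, channel = chs[k],
                   values = feats[registry$name]),
              class = "feature_vector")
  })
  names(out) <- chs
  out
}

#' Assemble feature vectors into a per-channel feature table
#'
#' @param vectors list of `feature_vector` objects from one channel.
#' @param labels named vector mapping lesion_id to class label.
#' @return a `feature_table` data frame: rows sorted by lesion id, columns
#'   `lesion_id`, `class`, then the registry features in registry order.
#' @export
table_from_vectors <- function(vectors, labels) {
  stopifnot(length(vectors) > 0 || is.list(vectors))
  if (length(vectors) == 0) {
    tab <- data.frame(lesion_id = character(0), class = character(0))
    class(tab) <- c("feature_table", "data.frame")
    return(tab)
  }
  ids <- vapply(vectors, function(v) v$lesion_id, character(1))
  if (anyDuplicated(ids))
    stop_radfuse("duplicate lesion_id: ", ids[duplicated(ids)][1])
  chans <- unique(vapply(vectors, function(v) v$channel, character(1)))
  if (length(chans) != 1)
    stop_radfuse("vectors span multiple channels: ",
                 paste(chans, collapse = ", "))
  nm <- names(vectors[[1]]$values)
  mats <- t(vapply(vectors, function(v) {
    if (!identical(names(v$values), nm))
      stop_radfuse("inconsistent feature registries across vectors")
    v$values
  }, numeric(length(nm))))
  miss <- setdiff(ids, names(labels))
  if (length(miss))
    stop_radfuse("missing class label for: ", paste(miss, collapse = ", "))
  ord <- order(ids)
  tab <- cbind(data.frame(lesion_id = ids[ord],
                          class = unname(labels[ids[ord]]),
                          stringsAsFactors = FALSE),
               as.data.frame(mats[ord, , drop = FALSE]))
  rownames(tab) <- NULL
  attr(tab, "channel") <- chans
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# Numeric feature matrix of a feature_table (drops id/class columns).
feature_matrix <- function(tab) {
  as.matrix(tab[, setdiff(colnames(tab), c("lesion_id", "class")),
                drop = FALSE])
}
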