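#' Radiomics feature registry
#'
#' The default registry enumerates the 109 features extracted per lesion per
#' sequence: 19 intensity (first-order) features, 15 morphology (shape)
#' features computed from the mask, and 75 texture features. The texture
#' family comprises 24 direction-merged grey-level co-occurrence matrix
#' (GLCM) features, 14 per-direction-variance GLCM variants (the variance of
#' a base GLCM feature across the 13 unique 3D directions), 16 grey-level
#' run-length matrix (GLRLM) features, 16 grey-level size-zone matrix
#' (GLSZM) features and 5 neighbourhood grey-tone difference matrix (NGTDM)
#' features. Feature definitions follow the usual IBSI conventions; the
#' exact texture membership is a package configuration, controllable through
#' the `groups` argument.
#'
#' @param groups character vector of feature groups to include; default all.
#' @return An object of class `feature_registry`: a data frame with columns
#'   `name`, `family` (intensity/morphology/texture) and `group`.
#' @examples
#' reg <- feature_registry()
#' table(reg$family)
#' @export
feature_registry <- function(groups = c("firstorder", "shape", "glcm",
                                        "glcmdir", "glrlm", "glszm",
                                        "ngtdm")) {
  groups <- match.arg(groups, several.ok = TRUE)
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
          "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "StandardDeviation", "Skewness", "Kurtosis",
          "Variance", "Uniformity")
  sh <- c("VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
          "SphericalDisproportion", "Compactness2", "Maximum3DDiameter",
          "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
          "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
          "LeastAxisLength", "Elongation", "Flatness")
  glcm <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
            "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
            "JointAverage", "JointEnergy", "JointEntropy",
            "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares",
            "MCC")
  glcmdir <- paste0(c("Autocorrelation", "ClusterProminence", "ClusterShade",
                      "ClusterTendency", "Contrast", "Correlation",
                      "DifferenceAverage", "DifferenceEntropy", "Id", "Idm",
                      "JointEnergy", "JointEntropy", "MaximumProbability",
                      "SumEntropy"), "DirectionalVariance")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
             "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
             "ZoneEntropy", "LowGrayLevelZoneEmphasis",
             "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
             "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
             "LargeAreaHighGrayLevelEmphasis")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

  blocks <- list(
    firstorder = data.frame(name = paste0("firstorder_", fo),
                            family = "intensity", group = "firstorder"),
    shape = data.frame(name = paste0("shape_", sh),
                       family = "morphology", group = "shape"),
    glcm = data.frame(name = paste0("glcm_", glcm),
                      family = "texture", group = "glcm"),
    glcmdir = data.frame(name = paste0("glcm_", glcmdir),
                         family = "texture", group = "glcmdir"),
    glrlm = data.frame(name = paste0("glrlm_", glrlm),
                       family = "texture", group = "glrlm"),
    glszm = data.frame(name = paste0("glszm_", glszm),
                       family = "texture", group = "glszm"),
    ngtdm = data.frame(name = paste0("ngtdm_", ngtdm),
                       family = "texture", group = "ngtdm")
  )
  reg <- do.call(rbind, blocks[groups])
  rownames(reg) <- NULL
  stopifnot(!anyDuplicated(reg$name))
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

#' @export
print.feature_registry <- function(x, ...) {
  cat("<feature_registry> ", nrow(x), " features (",
      paste(sprintf("%s: %d", names(table(x$family)), table(x$family)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Names of the MRI sequence channels handled by the pipeline
#'
#' T2-weighted, two diffusion weightings (b = 600 and 800 s/mm^2), the
#' ADC map derived from them, and six dynamic contrast-enhanced phases.
#' @return character vector of length 10.
#' @export
channel_names <- function() {
  c("T2WI", "DWI600", "DWI800", "ADC",
    "DCE1", "DCE2", "DCE3", "DCE4", "DCE5", "DCE6")
}
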