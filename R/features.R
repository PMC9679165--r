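# Feature registry and combinators. The 11 base features are accepted as
# per-vertex inputs (precomputed surface overlays); curvature features are
# derived from the principal curvatures k1, k2 by the combinators below.

#' The 11 base feature names, in canonical order
#'
#' Cortical thickness, grey-white contrast, mean curvature, sulcal depth,
#' intrinsic (Gaussian) curvature, FLAIR intensity sampled at 25/50/75%
#' of the cortical thickness, at the grey-white boundary, and 0.5 mm and
#' 1 mm subcortically.
#'
#' @return character vector of length 11.
#' @export
fcdFeatures <- function() {
  c("thickness", "gw_contrast", "mean_curv", "sulcal_depth",
    "intrinsic_curv", "flair_gm_25", "flair_gm_50", "flair_gm_75",
    "flair_wm_boundary", "flair_wm_0.5mm", "flair_wm_1mm")
}

#' FLAIR-derived feature names
#' @return character vector of length 6 (subset of [fcdFeatures()]).
#' @export
flairFeatures <- function() fcdFeatures()[6:11]

#' T1-derived feature names (available in all subjects)
#' @return character vector of length 5.
#' @export
t1Features <- function() fcdFeatures()[1:5]

#' Intrinsic (Gaussian) curvature from principal curvatures
#'
#' The product `k1 * k2` per vertex (units 1/mm^2); elevated values index
#' abnormal cortical folding.
#'
#' @param k1,k2 numeric per-vertex principal curvatures (1/mm).
#' @return numeric per-vertex field.
#' @examples
#' intrinsicCurvature(0.1, 0.1) # sphere of radius 10 mm -> 0.01
#' @export
intrinsicCurvature <- function(k1, k2) {
  stopifnot(length(k1) == length(k2))
  k1 * k2
}

#' Mean curvature from principal curvatures
#'
#' `(k1 + k2) / 2` per vertex (units 1/mm). A literal reciprocal reading
#' (`1 / mean(k1, k2)`) is available behind `reciprocal = TRUE` but is
#' dimensionally a radius, not a curvature; the default is the standard
#' definition.
#'
#' @param k1,k2 numeric per-vertex principal curvatures (1/mm).
#' @param reciprocal return `2 / (k1 + k2)` instead.
#' @return numeric per-vertex field.
#' @export
meanCurvature <- function(k1, k2, reciprocal = FALSE) {
  stopifnot(length(k1) == length(k2))
  m <- (k1 + k2) / 2
  if (reciprocal) 1 / m else m
}

#' Default per-feature smoothing kernels (FWHM, mm)
#'
#' Mean curvature and sulcal depth are smoothed with a 5 mm kernel;
#' thickness, grey-white contrast and all FLAIR intensities with 10 mm;
#' intrinsic curvature with 20 mm so that folding-pattern abnormalities
#' are stable across adjacent gyri and sulci.
#'
#' @return named numeric vector, one kernel per feature.
#' @export
defaultSmoothingPolicy <- function() {
  p <- c(thickness = 10, gw_contrast = 10, mean_curv = 5, sulcal_depth = 5,
         intrinsic_curv = 20, flair_gm_25 = 10, flair_gm_50 = 10,
         flair_gm_75 = 10, flair_wm_boundary = 10, "flair_wm_0.5mm" = 10,
         "flair_wm_1mm" = 10)
  p[fcdFeatures()]
}

#' Apply the smoothing policy to the raw feature set
#'
#' Smooths each base feature of every subject/hemisphere with its policy
#' kernel via [gaussianSmooth()]; missing (FLAIR-unavailable) values stay
#' missing. Provenance is updated.
#'
#' @param store a [CohortFeatureStore-class] with a "raw" feature set.
#' @param policy named kernel map as from [defaultSmoothingPolicy()].
#' @param fwhm kernel sizes are FWHM (default) or sigma.
#' @return the store with its "raw" set smoothed.
#' @export
applySmoothing <- function(store, policy = defaultSmoothingPolicy(),
                           fwhm = TRUE) {
  unknown <- setdiff(names(policy), fcdFeatures())
  if (length(unknown)) {
    stop("unknown feature(s) in smoothing policy: ",
         paste(unknown, collapse = ", "))
  }
  arr <- featureSet(store, "raw")
  meshes <- list(store@template@left, store@template@right)
  for (f in names(policy)) {
    fi <- match(f, fcdFeatures())
    for (h in 1:2) {
      m <- meshes[[h]]
      W <- smoothingWeights(m, policy[[f]], fwhm)
      x <- arr[, h, fi, , drop = TRUE]
      x <- as.matrix(x)
      na <- is.na(x)
      x[na] <- 0
      sm <- gaussianSmooth(m, x, policy[[f]], fwhm, weights = W)
      sm[na] <- NA_real_
      arr[, h, fi, ] <- sm
    }
  }
  store@featureSets[["raw"]] <- arr
  store@provenance <- c(store@provenance,
                        sprintf("smoothed:%s", paste(policy, collapse = "/")))
  store
}
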