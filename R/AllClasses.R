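#' @import methods
NULL

#' Triangle surface mesh
#'
#' A triangulated surface with an optional cortex mask. All vertex indices
#' are 1-based. Vertices flagged `FALSE` in `cortexMask` stand for the
#' medial wall / non-cortical surface and are excluded from geodesic
#' neighbourhoods, smoothing, normalization statistics and clustering.
#'
#' @slot vertices numeric matrix (n x 3), coordinates in mm.
#' @slot triangles integer matrix (m x 3) of vertex indices.
#' @slot cortexMask logical vector of length n; `FALSE` = medial wall.
#' @export
setClass("SurfaceMesh",
  representation(
    vertices = "matrix",
    triangles = "matrix",
    cortexMask = "logical"
  )
)

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices
  tr <- object@triangles
  msg <- character()
  if (ncol(v) != 3L) msg <- c(msg, "vertices must be an n x 3 matrix")
  if (ncol(tr) != 3L) msg <- c(msg, "triangles must be an m x 3 matrix")
  if (length(object@cortexMask) != nrow(v)) {
    msg <- c(msg, "cortexMask length must equal the vertex count")
  }
  if (any(tr < 1L) || any(tr > nrow(v))) {
    msg <- c(msg, "triangle indices out of range")
  }
  if (any(tr[, 1] == tr[, 2] | tr[, 1] == tr[, 3] | tr[, 2] == tr[, 3])) {
    msg <- c(msg, "degenerate triangle (repeated vertex)")
  }
  key <- apply(tr, 1L, function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(key)) msg <- c(msg, "duplicate (non-manifold) triangles")
  if (length(msg)) msg else TRUE
})

#' Construct a SurfaceMesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param triangles m x 3 matrix of 1-based vertex indices.
#' @param cortexMask logical per-vertex mask; default all cortex.
#' @return A [SurfaceMesh-class] object.
#' @examples
#' m <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                  rbind(c(1L, 2L, 3L)))
#' nVertices(m)
#' @export
SurfaceMesh <- function(vertices, triangles,
                        cortexMask = rep(TRUE, nrow(vertices))) {
  mode(triangles) <- "integer"
  new("SurfaceMesh", vertices = as.matrix(vertices),
      triangles = as.matrix(triangles), cortexMask = cortexMask)
}

#' Bilaterally symmetric template surface
#'
#' Two mirrored hemisphere meshes with identity vertex correspondence
#' (vertex i on the left corresponds to vertex i on the right), the
#' geometric substrate for interhemispheric asymmetry features.
#'
#' @slot left,right [SurfaceMesh-class] hemispheres.
#' @export
setClass("SymmetricTemplate",
  representation(left = "SurfaceMesh", right = "SurfaceMesh")
)

setValidity("SymmetricTemplate", function(object) {
  msg <- character()
  if (nrow(object@left@vertices) != nrow(object@right@vertices)) {
    msg <- c(msg, "hemispheres must have equal vertex counts")
  }
  if (nrow(object@left@triangles) != nrow(object@right@triangles)) {
    msg <- c(msg, "hemispheres must have equal triangle counts")
  }
  if (!identical(object@left@cortexMask, object@right@cortexMask)) {
    msg <- c(msg, "corresponding cortex masks must be identical")
  }
  if (length(msg)) msg else TRUE
})

#' Lesion annotation with geodesic border zones
#'
#' Per-patient lesion mask on one hemisphere plus the 0-20 mm and
#' 20-40 mm geodesic border rings and the training-exclusion set
#' (mask plus both rings). Rings absorb the uncertainty of manually
#' delineated lesion borders.
#'
#' @slot hemi "lh" or "rh".
#' @slot mask,ring20,ring40,exclusion logical per-vertex fields.
#' @export
setClass("LesionAnnotation",
  representation(
    hemi = "character",
    mask = "logical",
    ring20 = "logical",
    ring40 = "logical",
    exclusion = "logical"
  )
)

setValidity("LesionAnnotation", function(object) {
  msg <- character()
  if (!object@hemi %in% c("lh", "rh")) msg <- c(msg, "hemi must be lh or rh")
  n <- length(object@mask)
  if (length(object@ring20) != n || length(object@ring40) != n ||
      length(object@exclusion) != n) {
    msg <- c(msg, "mask and rings must have equal length")
  }
  if (!any(object@mask)) msg <- c(msg, "lesion mask must be non-empty")
  if (any(object@mask & object@ring20) || any(object@mask & object@ring40) ||
      any(object@ring20 & object@ring40)) {
    msg <- c(msg, "mask, ring20 and ring40 must be pairwise disjoint")
  }
  if (!identical(object@exclusion, object@mask | object@ring20 | object@ring40)) {
    msg <- c(msg, "exclusion must equal mask | ring20 | ring40")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort feature store
#'
#' The pipeline's central container: subject demographics, the per-vertex
#' feature arrays of every processing stage, per-patient lesion
#' annotations, and a provenance log of applied stages.
#'
#' Each feature set is a 4-D array indexed \[vertex, hemisphere, feature,
#' subject\], hemispheres ordered (lh, rh), features in [fcdFeatures()]
#' registry order. FLAIR-derived features are `NA` for subjects without a
#' FLAIR scan until classifier-input assembly imputes them.
#'
#' @slot template [SymmetricTemplate-class].
#' @slot subjects data.frame of demographics (one row per subject).
#' @slot featureSets named list of 4-D arrays.
#' @slot lesions named list of [LesionAnnotation-class] (patients only).
#' @slot provenance character log of applied processing stages.
#' @export
setClass("CohortFeatureStore",
  representation(
    template = "SymmetricTemplate",
    subjects = "data.frame",
    featureSets = "list",
    lesions = "list",
    provenance = "character"
  )
)

setValidity("CohortFeatureStore", function(object) {
  msg <- character()
  need <- c("subject_id", "group", "site_id", "scanner", "age", "sex",
            "flair_available")
  miss <- setdiff(need, names(object@subjects))
  if (length(miss)) {
    msg <- c(msg, paste("subjects table missing columns:",
                        paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(object@subjects$subject_id)) {
      msg <- c(msg, "duplicate subject_id")
    }
    if (!all(object@subjects$group %in% c("patient", "control"))) {
      msg <- c(msg, "group must be patient or control")
    }
    if (any(object@subjects$age < 3)) msg <- c(msg, "ages must be >= 3 years")
    if (any(names(object@lesions) %in%
            object@subjects$subject_id[object@subjects$group == "control"])) {
      msg <- c(msg, "controls must not carry lesion annotations")
    }
  }
  nv <- nrow(object@template@left@vertices)
  for (nm in names(object@featureSets)) {
    d <- dim(object@featureSets[[nm]])
    if (length(d) != 4L || d[1] != nv || d[2] != 2L) {
      msg <- c(msg, sprintf(
        "feature set '%s' must be [vertex=%d, hemi=2, feature, subject]",
        nm, nv))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Subject-level train/test split with cross-validation folds
#'
#' @slot trainIds,testIds character subject ids.
#' @slot folds named integer vector (1..nFolds) over the train ids.
#' @export
setClass("CohortSplit",
  representation(trainIds = "character", testIds = "character",
                 folds = "integer")
)

setValidity("CohortSplit", function(object) {
  msg <- character()
  if (length(intersect(object@trainIds, object@testIds))) {
    msg <- c(msg, "train and test ids must be disjoint")
  }
  if (!setequal(names(object@folds), object@trainIds)) {
    msg <- c(msg, "folds must be assigned to exactly the train ids")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted ComBat harmonization model
#'
#' Parametric empirical-Bayes location/scale harmonization across sites,
#' preserving modelled covariates (age, sex, disease status). The model
#' can later be applied to a previously unseen site with the reference
#' parameters frozen.
#'
#' @slot batchVar column of the demographics table used as batch.
#' @slot covariates covariate names entering the design.
#' @slot sites site roster the model was fit on.
#' @slot blocks internal per-block parameter lists (T1 vs FLAIR columns).
#' @slot eb logical; empirical-Bayes shrinkage applied.
#' @export
setClass("ComBatModel",
  representation(batchVar = "character", covariates = "character",
                 sites = "character", blocks = "list", eb = "logical")
)

#' Trained MLP ensemble with decision threshold
#'
#' Ensemble of fold x initialization multilayer perceptrons; the ensemble
#' prediction is the arithmetic mean of member probabilities, thresholded
#' at the Dice-optimal `threshold`.
#'
#' @slot members list of trained member networks.
#' @slot networkSpec list describing the architecture.
#' @slot threshold Dice-optimal decision threshold in (0, 1).
#' @slot provenance list: fold/seed grid, config hash, training log.
#' @export
setClass("EnsembleModel",
  representation(members = "list", networkSpec = "list",
                 threshold = "numeric", provenance = "list")
)

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@members) < 1L) msg <- c(msg, "ensemble needs >= 1 member")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1) {
    msg <- c(msg, "threshold must be a single value in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})
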