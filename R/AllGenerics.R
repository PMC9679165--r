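#' @rdname SurfaceMesh-class
#' @param x a SurfaceMesh, SymmetricTemplate or CohortFeatureStore.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("cortexMask", function(x) standardGeneric("cortexMask"))

#' @rdname CohortFeatureStore-class
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @rdname CohortFeatureStore-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname CohortFeatureStore-class
#' @export
setGeneric("template", function(x) standardGeneric("template"))

#' @rdname CohortFeatureStore-class
#' @param name feature-set name, e.g. "raw", "combat", "normalized".
#' @export
setGeneric("featureSet", function(x, name) standardGeneric("featureSet"))

#' @rdname CohortFeatureStore-class
#' @param value replacement 4-D array.
#' @export
setGeneric("featureSet<-", function(x, name, value) {
  standardGeneric("featureSet<-")
})

#' @rdname CohortFeatureStore-class
#' @export
setGeneric("featureSetNames", function(x) standardGeneric("featureSetNames"))

#' @rdname CohortFeatureStore-class
#' @param subjectId a subject identifier.
#' @export
setGeneric("lesionAnnotation", function(x, subjectId) {
  standardGeneric("lesionAnnotation")
})

#' @rdname CohortFeatureStore-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
setMethod("nVertices", "SymmetricTemplate", function(x) nrow(x@left@vertices))
setMethod("nVertices", "CohortFeatureStore", function(x) nVertices(x@template))
setMethod("cortexMask", "SurfaceMesh", function(x) x@cortexMask)
setMethod("cortexMask", "SymmetricTemplate", function(x) x@left@cortexMask)

setMethod("subjectTable", "CohortFeatureStore", function(x) x@subjects)
setMethod("subjectIds", "CohortFeatureStore", function(x) x@subjects$subject_id)
setMethod("template", "CohortFeatureStore", function(x) x@template)
setMethod("featureSet", "CohortFeatureStore", function(x, name) {
  if (!name %in% names(x@featureSets)) {
    stop(sprintf("feature set '%s' not present (have: %s)", name,
                 paste(names(x@featureSets), collapse = ", ")))
  }
  x@featureSets[[name]]
})
setMethod("featureSet<-", "CohortFeatureStore", function(x, name, value) {
  x@featureSets[[name]] <- value
  validObject(x)
  x
})
setMethod("featureSetNames", "CohortFeatureStore", function(x) {
  names(x@featureSets)
})
setMethod("lesionAnnotation", "CohortFeatureStore", function(x, subjectId) {
  x@lesions[[subjectId]]
})
setMethod("provenance", "CohortFeatureStore", function(x) x@provenance)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles (%d cortex)\n",
              nrow(object@vertices), nrow(object@triangles),
              sum(object@cortexMask)))
})

setMethod("show", "SymmetricTemplate", function(object) {
  cat(sprintf(
    "SymmetricTemplate: 2 x %d vertices (%d cortex per hemisphere)\n",
    nVertices(object), sum(object@left@cortexMask)))
})

setMethod("show", "CohortFeatureStore", function(object) {
  tab <- table(object@subjects$group)
  cat(sprintf(
    "CohortFeatureStore: %d subjects (%d patients, %d controls), %d sites\n",
    nrow(object@subjects), sum(object@subjects$group == "patient"),
    sum(object@subjects$group == "control"),
    length(unique(object@subjects$site_id))))
  cat(sprintf("  template: 2 x %d vertices\n", nVertices(object)))
  cat(sprintf("  feature sets: %s\n",
              paste(names(object@featureSets), collapse = ", ")))
  cat(sprintf("  provenance: %s\n",
              paste(object@provenance, collapse = " -> ")))
  invisible(tab)
})

setMethod("show", "ComBatModel", function(object) {
  cat(sprintf(
    "ComBatModel: batch '%s' over %d sites; covariates: %s; EB: %s\n",
    object@batchVar, length(object@sites),
    paste(object@covariates, collapse = ", "), object@eb))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf(
    "EnsembleModel: %d members (%d folds x %d inits), threshold %.2f\n",
    length(object@members),
    length(unique(object@provenance$grid$fold)),
    length(unique(object@provenance$grid$init)), object@threshold))
})

setMethod("show", "CohortSplit", function(object) {
  cat(sprintf("CohortSplit: %d train / %d test, %d folds\n",
              length(object@trainIds), length(object@testIds),
              length(unique(object@folds))))
})

setMethod("show", "LesionAnnotation", function(object) {
  cat(sprintf(
    "LesionAnnotation (%s): %d mask, %d ring20, %d ring40 vertices\n",
    object@hemi, sum(object@mask), sum(object@ring20), sum(object@ring40)))
})
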