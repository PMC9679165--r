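# Three-stage normalization: (1) intrasubject z-scoring to absorb
# interindividual distribution shifts (age/sex-related), (2)
# interhemispheric asymmetry on the symmetric template, (3) per-vertex
# z-scoring by healthy-control statistics to absorb normal interregional
# variability. Outputs are the "normalized" (stages 1+3) and "asymmetry"
# (stages 1+2+3) feature sets.

#' Per-vertex healthy-control reference statistics
#'
#' Mean and SD per (stage, feature, hemisphere, vertex), computed from
#' healthy controls only -- by default the train-cohort controls so the
#' reference can be reused for test subjects without leakage.
#'
#' @slot mu,sd named lists ("zscore", "asym_raw") of \[vertex, hemi,
#'   feature\] arrays.
#' @slot nControls number of controls used.
#' @export
setClass("ControlReference",
  representation(mu = "list", sd = "list", nControls = "integer")
)

setMethod("show", "ControlReference", function(object) {
  cat(sprintf("ControlReference from %d controls (stages: %s)\n",
              object@nControls, paste(names(object@mu), collapse = ", ")))
})

#' Stage 1: intrasubject z-scoring
#'
#' Per subject and feature, z-scores the values over all cortex vertices
#' of both hemispheres; afterwards every subject-feature map has mean 0
#' and SD 1. Stored as feature set "zscore". Medial-wall vertices carry 0
#' and are excluded from the statistics.
#'
#' @param store a [CohortFeatureStore-class] with a "combat" set.
#' @param set input feature set (default "combat").
#' @return the store with a "zscore" feature set.
#' @export
intrasubjectZscore <- function(store, set = "combat") {
  if ("zscore" %in% names(store@featureSets)) {
    stop("intrasubject z-scoring already ran; refusing to double-normalize")
  }
  arr <- featureSet(store, set)
  cortex <- cortexMask(store@template)
  out <- arr
  d <- dim(arr)
  for (si in seq_len(d[4])) {
    for (fi in seq_len(d[3])) {
      x <- arr[, , fi, si]
      v <- x[cortex, ]
      if (all(is.na(v))) next
      m <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        stop(sprintf(
          "zero within-subject variance for subject %s, feature %s",
          store@subjects$subject_id[si], fcdFeatures()[fi]))
      }
      out[, , fi, si] <- (x - m) / s
    }
  }
  out[!cortex, , , ] <- 0
  store@featureSets[["zscore"]] <- out
  store@provenance <- c(store@provenance, "zscore")
  store
}

#' Stage 2: interhemispheric asymmetry
#'
#' Exploits the template's vertex correspondence: the left asymmetry map
#' is left minus right, the right map right minus left, so
#' `asym_lh[v] == -asym_rh[v]` exactly. Stored as feature set "asym_raw".
#'
#' @param store a [CohortFeatureStore-class] with a "zscore" set.
#' @param set input feature set (default "zscore").
#' @return the store with an "asym_raw" feature set.
#' @export
interhemisphericAsymmetry <- function(store, set = "zscore") {
  if ("asym_raw" %in% names(store@featureSets)) {
    stop("asymmetry stage already ran; refusing to double-normalize")
  }
  arr <- featureSet(store, set)
  out <- arr
  out[, 1, , ] <- arr[, 1, , ] - arr[, 2, , ]
  out[, 2, , ] <- arr[, 2, , ] - arr[, 1, , ]
  store@featureSets[["asym_raw"]] <- out
  store@provenance <- c(store@provenance, "asymmetry")
  store
}

#' Build the healthy-control reference
#'
#' @param store a [CohortFeatureStore-class] after stages 1 and 2.
#' @param controlIds controls to use (default: all controls in the
#'   store; pass the train-cohort controls to avoid test leakage).
#' @param sdFloor lower bound on the control SD (z-units) protecting
#'   near-constant vertices from division blow-ups.
#' @return a [ControlReference-class].
#' @export
buildControlReference <- function(store, controlIds = NULL, sdFloor = 1e-3) {
  subj <- store@subjects
  if (is.null(controlIds)) {
    controlIds <- subj$subject_id[subj$group == "control"]
  }
  bad <- setdiff(controlIds, subj$subject_id[subj$group == "control"])
  if (length(bad)) {
    stop("reference must be built from controls only; not controls: ",
         paste(bad, collapse = ", "))
  }
  idx <- match(controlIds, subj$subject_id)
  if (length(idx) < 2L) stop("need >= 2 controls for a reference")
  mu <- list(); sdl <- list()
  for (set in c("zscore", "asym_raw")) {
    arr <- featureSet(store, set)[, , , idx, drop = FALSE]
    d <- dim(arr)
    m <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
    k <- rowSums(!is.na(m))
    mrow <- rowMeans(m, na.rm = TRUE)
    s <- sqrt(pmax(rowSums(m^2, na.rm = TRUE) - k * mrow^2, 0) /
                pmax(k - 1, 1))
    s[k < 2 | !is.finite(s) | s < sdFloor] <- sdFloor
    mrow[k == 0] <- 0
    mu[[set]] <- array(mrow, dim = d[1:3])
    sdl[[set]] <- array(s, dim = d[1:3])
  }
  new("ControlReference", mu = mu, sd = sdl,
      nControls = length(idx))
}

#' Stage 3: per-vertex normalization by healthy controls
#'
#' z-scores the stage-1 and stage-2 outputs by the control mean and SD at
#' each vertex, producing the final "normalized" and "asymmetry" feature
#' sets consumed by the classifier.
#'
#' @param store a [CohortFeatureStore-class] after stages 1 and 2.
#' @param reference a [ControlReference-class] built at the same stages.
#' @return the store with "normalized" and "asymmetry" feature sets.
#' @export
controlNormalize <- function(store, reference) {
  if ("normalized" %in% names(store@featureSets)) {
    stop("control normalization already ran; refusing to double-normalize")
  }
  cortex <- cortexMask(store@template)
  nv <- nVertices(store@template)
  if (dim(reference@mu$zscore)[1] != nv) {
    stop("reference/template vertex-count mismatch")
  }
  n <- nrow(store@subjects)
  outNames <- c(zscore = "normalized", asym_raw = "asymmetry")
  for (set in names(outNames)) {
    arr <- featureSet(store, set)
    mu <- reference@mu[[set]]
    s <- reference@sd[[set]]
    out <- arr
    for (si in seq_len(n)) {
      out[, , , si] <- (arr[, , , si] - mu) / s
    }
    out[!cortex, , , ] <- 0
    store@featureSets[[outNames[[set]]]] <- out
  }
  store@provenance <- c(store@provenance,
                        sprintf("control-normalized(n=%d)",
                                reference@nControls))
  store
}
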