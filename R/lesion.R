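# Lesion-mask hygiene and border-zone construction. Manual lesion masks
# are drawn conservatively and their borders are uncertain; geodesic
# border rings (0-20 and 20-40 mm) around each mask absorb that
# uncertainty and are excluded from classifier training.

#' Morphological closing of a lesion mask
#'
#' Fills small defects by `nIter` one-ring dilations followed by `nIter`
#' one-ring erosions on the vertex graph (the structuring element is the
#' one-ring vertex neighbourhood).
#'
#' @param mask logical per-vertex mask.
#' @param mesh a [SurfaceMesh-class].
#' @param nIter dilation/erosion iterations (default 5).
#' @return closed logical mask (always a superset of the input interior).
#' @export
fillMaskDefects <- function(mask, mesh, nIter = 5) {
  stopifnot(length(mask) == nVertices(mesh))
  if (!any(mask)) stop("mask must be non-empty")
  adj <- buildAdjacency(mesh)
  dilate <- function(m) {
    out <- m
    out[unique(unlist(adj[m], use.names = FALSE))] <- TRUE
    out
  }
  erode <- function(m) {
    keep <- vapply(seq_along(m), function(v) {
      m[v] && all(m[adj[[v]]])
    }, logical(1))
    keep
  }
  m <- mask
  for (k in seq_len(nIter)) m <- dilate(m)
  for (k in seq_len(nIter)) m <- erode(m)
  m
}

#' Build 20/40 mm geodesic border zones around a lesion mask
#'
#' Ring20 holds vertices with geodesic distance to the mask in (0, 20]
#' mm, ring40 in (20, 40] mm; the exclusion set (mask plus both rings) is
#' what all training-label logic must honour.
#'
#' @param mask logical per-vertex lesion mask.
#' @param mesh the hemisphere [SurfaceMesh-class].
#' @param hemi "lh" or "rh".
#' @param innerMm,outerMm ring radii (mm), defaults 20 and 40.
#' @return a [LesionAnnotation-class].
#' @export
makeBorderZones <- function(mask, mesh, hemi = "lh", innerMm = 20,
                            outerMm = 40) {
  stopifnot(length(mask) == nVertices(mesh))
  if (!any(mask)) stop("mask must be non-empty")
  if (all(mask[mesh@cortexMask])) {
    stop("mask covers the whole hemisphere; no border zones exist")
  }
  d <- geodesicDistance(mesh, which(mask))
  ring20 <- !is.na(d) & d > 0 & d <= innerMm & !mask
  ring40 <- !is.na(d) & d > innerMm & d <= outerMm & !mask
  new("LesionAnnotation", hemi = hemi, mask = mask,
      ring20 = ring20, ring40 = ring40,
      exclusion = mask | ring20 | ring40)
}

#' Interrater mask overlap with an optional border zone
#'
#' Fraction of mask B captured by mask A after dilating A geodesically by
#' `borderMm` (0 gives the plain fraction of B inside A), plus a binary
#' any-overlap flag. The symmetrized mean (averaging both directions) is
#' also reported because the directionality of "fraction mask overlap" is
#' a convention.
#'
#' @param maskA,maskB logical per-vertex masks on the same hemisphere.
#' @param mesh the hemisphere [SurfaceMesh-class].
#' @param borderMm geodesic dilation of the first mask (mm).
#' @return list with `fraction`, `anyOverlap`, and `fractionSym`.
#' @export
interraterOverlap <- function(maskA, maskB, mesh, borderMm = 0) {
  if (!any(maskA) || !any(maskB)) stop("masks must be non-empty")
  dilA <- .dilateGeodesic(maskA, mesh, borderMm)
  dilB <- .dilateGeodesic(maskB, mesh, borderMm)
  list(fraction = sum(maskB & dilA) / sum(maskB),
       anyOverlap = any(maskB & dilA),
       fractionSym = mean(c(sum(maskB & dilA) / sum(maskB),
                            sum(maskA & dilB) / sum(maskA))))
}

#' @keywords internal
.dilateGeodesic <- function(mask, mesh, borderMm) {
  if (borderMm <= 0) return(mask)
  d <- geodesicDistance(mesh, which(mask))
  out <- !is.na(d) & d <= borderMm
  out | mask
}
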