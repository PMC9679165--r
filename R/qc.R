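# Automated quality control: subjects whose features are extreme in many
# cortical regions (artefact signature) are flagged and excluded. The
# regional statistic is the mean feature value over each region of a
# cortical parcellation; a feature is an outlier for a subject if it
# deviates by more than 2.7 cohort SDs in more than 10 non-lesional
# regions, and a subject is excluded with >= 2 such features (T1-only)
# or >= 3 (FLAIR available).

#' Geodesic Voronoi parcellation of the template
#'
#' A Desikan-Killiany stand-in: farthest-point sampling places
#' `nRegions` seeds on the left cortex and each cortex vertex is assigned
#' to its geodesically nearest seed; the parcellation is mirrored to the
#' right hemisphere through the vertex correspondence. Deterministic.
#'
#' @param tpl a [SymmetricTemplate-class].
#' @param nRegions regions per hemisphere (default 34).
#' @return integer per-vertex region labels (1..nRegions, `NA` off
#'   cortex), identical for both hemispheres; regions on the two
#'   hemispheres are treated as distinct in QC.
#' @export
makeParcellation <- function(tpl, nRegions = 34) {
  mesh <- tpl@left
  cortex <- which(mesh@cortexMask)
  if (nRegions > length(cortex)) stop("more regions than cortex vertices")
  seeds <- cortex[1]
  dmin <- geodesicDistance(mesh, seeds)
  while (length(seeds) < nRegions) {
    cand <- cortex[which.max(dmin[cortex])]
    seeds <- c(seeds, cand)
    dmin <- pmin(dmin, geodesicDistance(mesh, cand), na.rm = TRUE)
  }
  g <- .cortexGraph(mesh)
  D <- igraph::distances(g, v = seeds, to = cortex, algorithm = "dijkstra")
  lab <- rep(NA_integer_, nVertices(mesh))
  lab[cortex] <- apply(D, 2L, which.min)
  lab
}

#' Regional mean features per subject
#'
#' @param store a [CohortFeatureStore-class].
#' @param parcellation labels from [makeParcellation()].
#' @param set feature set to summarize (default "raw").
#' @return array \[subject, feature, region\] where regions enumerate
#'   (lh, rh) x parcel; for patients, regions containing lesion-mask
#'   vertices are `NA` (lesional regions are excluded from QC).
#' @export
regionalSummaries <- function(store, parcellation, set = "raw") {
  arr <- featureSet(store, set)
  nR <- max(parcellation, na.rm = TRUE)
  n <- nrow(store@subjects)
  nf <- dim(arr)[3]
  out <- array(NA_real_, dim = c(n, nf, 2L * nR),
               dimnames = list(store@subjects$subject_id, fcdFeatures(),
                               c(paste0("lh_", seq_len(nR)),
                                 paste0("rh_", seq_len(nR)))))
  regIdx <- split(which(!is.na(parcellation)),
                  parcellation[!is.na(parcellation)])
  for (h in 1:2) {
    for (r in seq_len(nR)) {
      v <- regIdx[[r]]
      block <- arr[v, h, , , drop = FALSE]
      out[, , (h - 1L) * nR + r] <-
        t(colMeans(array(block, dim = c(length(v), nf, n)), na.rm = TRUE))
    }
  }
  for (sid in names(store@lesions)) {
    ann <- store@lesions[[sid]]
    h <- match(ann@hemi, c("lh", "rh"))
    les <- unique(stats::na.omit(parcellation[ann@mask]))
    if (length(les)) out[sid, , (h - 1L) * nR + les] <- NA_real_
  }
  out
}

#' Detect outlier features per subject
#'
#' A feature is an outlier for a subject iff its regional mean deviates
#' from the cohort mean of that region by more than `sdThreshold` cohort
#' SDs in strictly more than `regionThreshold` non-lesional regions.
#' Cohort statistics include the candidate subject.
#'
#' @param store a [CohortFeatureStore-class].
#' @param parcellation labels from [makeParcellation()].
#' @param sdThreshold deviation threshold in cohort SDs (default 2.7).
#' @param regionThreshold region count that must be exceeded (default 10).
#' @return named list: per subject, the character vector of outlier
#'   features (possibly empty).
#' @export
detectOutlierFeatures <- function(store, parcellation, sdThreshold = 2.7,
                                  regionThreshold = 10) {
  nR <- max(parcellation, na.rm = TRUE)
  if (nR < 12) {
    stop("parcellation has fewer than 12 regions; the >10-region rule ",
         "cannot fire meaningfully")
  }
  reg <- regionalSummaries(store, parcellation)
  mu <- apply(reg, c(2, 3), mean, na.rm = TRUE)
  s <- apply(reg, c(2, 3), stats::sd, na.rm = TRUE)
  n <- dim(reg)[1]
  extreme <- abs(reg - rep(mu, each = n)) > sdThreshold * rep(s, each = n)
  counts <- apply(extreme, c(1, 2), sum, na.rm = TRUE)
  ids <- store@subjects$subject_id
  res <- lapply(seq_len(n), function(i) {
    names(which(counts[i, ] > regionThreshold))
  })
  names(res) <- ids
  res
}

#' Flag outlier subjects for exclusion
#'
#' @param outlierFeatures result of [detectOutlierFeatures()].
#' @param flairAvailable named logical vector (or the store's subjects
#'   table is used when a store is given).
#' @return data.frame with subject_id, n_outlier_features, threshold and
#'   excluded flag.
#' @export
flagOutlierSubjects <- function(outlierFeatures, flairAvailable) {
  if (is(flairAvailable, "CohortFeatureStore")) {
    flairAvailable <- stats::setNames(
      flairAvailable@subjects$flair_available,
      flairAvailable@subjects$subject_id)
  }
  ids <- names(outlierFeatures)
  nOut <- lengths(outlierFeatures)
  thr <- ifelse(flairAvailable[ids], 3L, 2L)
  data.frame(subject_id = ids,
             n_outlier_features = as.integer(nOut),
             threshold = thr,
             excluded = nOut >= thr,
             row.names = NULL)
}
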