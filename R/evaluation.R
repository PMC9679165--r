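# Cluster formation and cohort-level evaluation: predicted vertices are
# grouped into spatially connected clusters, clusters under 100 vertices
# (~0.5 cm^2, disproportionately false positives) are filtered, and the
# cohort metrics are sensitivity (cluster overlaps the lesion mask),
# sensitivity+ (mask or its 20 mm border zone), specificity (controls
# with zero clusters) and cluster-count summaries. A permutation logistic
# regression relates detection to demographic/clinical factors.

#' Form predicted clusters from a thresholded prediction
#'
#' Connected components per hemisphere (a cluster never spans
#' hemispheres: the mesh has no interhemispheric edges); components
#' smaller than `minSize` vertices are filtered out; the rest are sorted
#' by size, largest first.
#'
#' @param pred boolean \[vertex x hemi\] matrix (columns lh, rh), e.g.
#'   from [predictSubject()].
#' @param tpl a [SymmetricTemplate-class].
#' @param prob optional probability matrix for cluster mean probability.
#' @param minSize minimum cluster size in vertices (default 100).
#' @return list of clusters, each a list with hemi, vertices, size and
#'   meanProb.
#' @export
formClusters <- function(pred, tpl, prob = NULL, minSize = 100) {
  meshes <- list(lh = tpl@left, rh = tpl@right)
  clusters <- list()
  for (h in c("lh", "rh")) {
    cc <- connectedComponents(meshes[[h]], pred[, h])
    for (lab in seq_along(cc$sizes)) {
      if (cc$sizes[lab] < minSize) next
      v <- which(!is.na(cc$labels) & cc$labels == lab)
      clusters[[length(clusters) + 1L]] <- list(
        hemi = h, vertices = v, size = length(v),
        meanProb = if (is.null(prob)) NA_real_ else mean(prob[v, h]))
    }
  }
  if (length(clusters) > 1L) {
    clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "size"),
                               decreasing = TRUE)]
  }
  clusters
}

#' Cohort-level detection metrics
#'
#' A patient counts as detected if any predicted cluster shares at least
#' one vertex with the lesion mask (sensitivity), or with the mask or
#' its 20 mm border ring (sensitivity+); specificity is the fraction of
#' controls with zero post-filter clusters. Cluster counts are
#' summarized as median (IQR).
#'
#' @param clustersBySubject named list: per subject, output of
#'   [formClusters()].
#' @param store the [CohortFeatureStore-class] carrying group labels and
#'   lesion annotations.
#' @return list with `sensitivity`, `sensitivityPlus`, `specificity`,
#'   `clusterCounts` (per-group median/IQR) and the per-subject
#'   `detectionTable`.
#' @export
computeMetrics <- function(clustersBySubject, store) {
  subj <- store@subjects
  rows <- lapply(names(clustersBySubject), function(sid) {
    i <- match(sid, subj$subject_id)
    if (is.na(i)) stop("subject has clusters but no group label: ", sid)
    cl <- clustersBySubject[[sid]]
    ann <- store@lesions[[sid]]
    det <- detPlus <- NA
    if (subj$group[i] == "patient") {
      if (is.null(ann)) stop("patient without lesion annotation: ", sid)
      hit <- vapply(cl, function(x) {
        x$hemi == ann@hemi && any(ann@mask[x$vertices])
      }, logical(1))
      hitPlus <- vapply(cl, function(x) {
        x$hemi == ann@hemi && any((ann@mask | ann@ring20)[x$vertices])
      }, logical(1))
      det <- any(hit)
      detPlus <- any(hitPlus)
    }
    data.frame(subject_id = sid, group = subj$group[i],
               nClusters = length(cl), detected = det,
               detectedPlus = detPlus)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$subject_id), , drop = FALSE]
  rownames(tab) <- NULL
  pat <- tab[tab$group == "patient", , drop = FALSE]
  ctl <- tab[tab$group == "control", , drop = FALSE]
  counts <- list(
    patients = if (nrow(pat)) .medIqr(pat$nClusters) else NULL,
    controls = if (nrow(ctl)) .medIqr(ctl$nClusters) else NULL)
  list(
    sensitivity = if (nrow(pat)) mean(pat$detected) else NA_real_,
    sensitivityPlus = if (nrow(pat)) mean(pat$detectedPlus) else NA_real_,
    specificity = if (nrow(ctl)) mean(ctl$nClusters == 0) else NA_real_,
    clusterCounts = counts,
    detectionTable = tab)
}

#' Permutation logistic regression of detection factors
#'
#' Fits `detected ~ factors` by IRLS (binomial GLM) and assesses each
#' coefficient against a permutation null built by shuffling the
#' detection outcome (`p = (1 + #(|beta_perm| >= |beta_obs|)) /
#' (1 + nPerm)`, two-sided); Benjamini-Hochberg controls the FDR across
#' factors.
#'
#' @param detectionTable data.frame with a logical/0-1 `detected` column
#'   and the factor columns.
#' @param factors factor column names to test.
#' @param nPerm number of permutations (default 1000).
#' @param q FDR level for the BH decisions (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return data.frame per factor: beta, pPerm, pBH, significant, plus a
#'   `converged` attribute; separation is flagged with a warning.
#' @export
detectionFactorRegression <- function(detectionTable, factors,
                                      nPerm = 1000, q = 0.05, seed = 1L) {
  y <- as.integer(detectionTable$detected)
  X <- stats::model.matrix(
    stats::reformulate(factors), data = detectionTable)
  fitCoef <- function(yy) {
    fit <- suppressWarnings(stats::glm.fit(X, yy,
                                           family = stats::binomial()))
    structure(fit$coefficients[-1L], converged = fit$converged,
              sep = any(abs(fit$coefficients[-1L]) > 15))
  }
  obs <- fitCoef(y)
  if (!attr(obs, "converged") || attr(obs, "sep")) {
    warning("possible separation / non-convergence; coefficients flagged")
  }
  set.seed(seed)
  exceed <- numeric(length(obs))
  for (b in seq_len(nPerm)) {
    bperm <- fitCoef(sample(y))
    exceed <- exceed + (abs(bperm) >= abs(obs))
  }
  pPerm <- (1 + exceed) / (1 + nPerm)
  pBH <- stats::p.adjust(pPerm, method = "BH")
  data.frame(factor = names(obs), beta = as.numeric(obs),
             pPerm = pPerm, pBH = pBH, significant = pBH < q,
             row.names = NULL)
}
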