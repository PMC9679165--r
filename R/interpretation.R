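# Interpretability: integrated-gradients saliency for the ensemble,
# lesion phenotyping by low-dimensional embedding + Gaussian mixture,
# and structured per-patient reports.

#' Integrated gradients attribution
#'
#' Right-Riemann approximation of the path integral of the model's
#' input gradients from the zero baseline to `x`:
#' `IG_i = x_i * (1/m) * sum_k dF/dx_i((k/m) x)`. For an ensemble the
#' attribution is the mean of member attributions. Satisfies the
#' completeness axiom `sum(IG) ~ F(x) - F(0)` as `m` grows, and
#' attributes exactly `w * x` for a linear model at any `m`.
#'
#' @param model an [EnsembleModel-class] or a single member network.
#' @param x input vector (33 features).
#' @param m number of Riemann steps (default 256).
#' @param output attribute the probability (default) or the raw logit.
#' @return list with `attributions` (named numeric), `completeness`
#'   (absolute residual vs `F(x) - F(0)`), `fx`, `f0`.
#' @export
integratedGradients <- function(model, x, m = 256,
                                output = c("prob", "logit")) {
  if (m < 1) stop("m must be >= 1")
  output <- match.arg(output)
  members <- if (is(model, "EnsembleModel")) model@members else list(model)
  x <- as.numeric(x)
  steps <- (seq_len(m) / m)
  Xpath <- outer(steps, x)
  att <- rep(0, length(x))
  fx <- f0 <- 0
  val <- function(net, xi) {
    p <- .forward(net, matrix(xi, 1, length(x)))
    if (output == "logit") stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
    else p
  }
  for (net in members) {
    g <- .inputGradient(net, Xpath, output = output)
    att <- att + colMeans(g) * x
    fx <- fx + val(net, x)
    f0 <- f0 + val(net, rep(0, length(x)))
  }
  k <- length(members)
  att <- att / k; fx <- fx / k; f0 <- f0 / k
  names(att) <- names(x)
  list(attributions = att, completeness = abs(sum(att) - (fx - f0)),
       fx = fx, f0 = f0)
}

#' Mean feature summaries over lesion (or pseudo-lesion) vertex sets
#'
#' For each patient lesion mask, the mean of the normalized and
#' asymmetry features over the mask; for each control, a size-matched
#' geodesic pseudo-lesion at a random cortical location (sizes matched
#' within 10% to the patient lesions, cycled).
#'
#' @param store a [CohortFeatureStore-class] after normalization.
#' @param includeControls sample matched control pseudo-lesions.
#' @param seed RNG seed for control sampling.
#' @return data.frame: one row per lesion/pseudo-lesion with subject_id,
#'   group, hemi, size and mean `normalized.*` / `asymmetry.*` features.
#' @export
lesionFeatureSummary <- function(store, includeControls = TRUE, seed = 1L) {
  subj <- store@subjects
  meshes <- list(lh = store@template@left, rh = store@template@right)
  summarize <- function(sid, hemi, v) {
    if (length(v) == 0L) stop("empty vertex set for ", sid)
    h <- match(hemi, c("lh", "rh"))
    rowFor <- function(set) {
      m <- colMeans(featureSet(store, set)[v, h, ,
                    match(sid, subj$subject_id), drop = FALSE],
                    na.rm = TRUE, dims = 1)
      stats::setNames(as.numeric(m), paste(set, fcdFeatures(), sep = "."))
    }
    c(rowFor("normalized"), rowFor("asymmetry"))
  }
  rows <- list()
  sizes <- integer()
  for (sid in names(store@lesions)) {
    ann <- store@lesions[[sid]]
    v <- which(ann@mask)
    sizes <- c(sizes, length(v))
    rows[[sid]] <- c(list(subject_id = sid, group = "patient",
                          hemi = ann@hemi, size = length(v)),
                     as.list(summarize(sid, ann@hemi, v)))
  }
  if (includeControls && length(sizes)) {
    set.seed(seed)
    ctlIds <- subj$subject_id[subj$group == "control"]
    target <- rep_len(sizes, length(ctlIds))
    for (k in seq_along(ctlIds)) {
      sid <- ctlIds[k]
      hemi <- if (stats::runif(1) < 0.5) "lh" else "rh"
      v <- .matchedDisc(meshes[[hemi]], target[k])
      rows[[sid]] <- c(list(subject_id = sid, group = "control",
                            hemi = hemi, size = length(v)),
                       as.list(summarize(sid, hemi, v)))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

# geodesic disc with vertex count within 10% of target (grown by
# distance rank from a random cortex seed)
#' @keywords internal
.matchedDisc <- function(mesh, targetSize) {
  seedV <- sample(which(mesh@cortexMask), 1)
  d <- geodesicDistance(mesh, seedV)
  ord <- order(d, na.last = NA)
  n <- min(targetSize, length(ord))
  ord[seq_len(n)]
}

#' Embed lesion summaries and cluster into phenotype groups
#'
#' 2-D embedding of the T1-derived feature summaries (available in all
#' subjects) for display, plus a K-component Gaussian mixture assigning
#' each lesion to a phenotype group; assignment is the argmax
#' responsibility. The mixture is fitted on the standardized summary
#' features themselves rather than on the 2-D coordinates: the linear
#' embedding used here can collapse directions that separate groups,
#' whereas a nonlinear embedding would have preserved them. Deterministic
#' under `seed`.
#'
#' @param summaries output of [lesionFeatureSummary()] (patients rows are
#'   clustered; control rows, if present, are embedded alongside).
#' @param K mixture components (default 3).
#' @param seed RNG seed.
#' @param patientsOnly cluster patient lesions only (default TRUE).
#' @return the input data.frame plus columns `embed1`, `embed2`, `phenotype`.
#' @export
embedAndCluster <- function(summaries, K = 3, seed = 1L,
                            patientsOnly = TRUE) {
  cols <- paste("normalized", t1Features(), sep = ".")
  sel <- if (patientsOnly) summaries$group == "patient" else
    rep(TRUE, nrow(summaries))
  if (sum(sel) < 5 * K) stop("need at least 5*K lesions to cluster")
  X <- as.matrix(summaries[, cols])
  if (all(apply(X[sel, ], 2, stats::sd) < 1e-12)) {
    stop("degenerate summaries: all points identical")
  }
  set.seed(seed)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  emb <- pc$x[, 1:2, drop = FALSE]
  # fix the sign convention so the embedding is reproducible
  for (j in 1:2) if (emb[which.max(abs(emb[, j])), j] < 0) {
    emb[, j] <- -emb[, j]
  }
  Xs <- scale(X)
  gmm <- Mclust(Xs[sel, , drop = FALSE], G = K, verbose = FALSE)
  out <- summaries
  out$embed1 <- emb[, 1]
  out$embed2 <- emb[, 2]
  out$phenotype <- NA_integer_
  out$phenotype[sel] <- gmm$classification
  out
}

#' Per-patient interpretable report
#'
#' For each predicted cluster: hemisphere, size, cortical location (the
#' modal parcellation region), the 33 mean input feature values over the
#' cluster, integrated-gradients saliency per feature (positive values
#' drive the "lesion" prediction) and the completeness residual.
#'
#' @param model an [EnsembleModel-class].
#' @param store a [CohortFeatureStore-class] after normalization.
#' @param subjectId subject to report on.
#' @param parcellation optional labels from [makeParcellation()].
#' @param m integrated-gradients steps (default 256).
#' @param minSize cluster size filter (default 100).
#' @return list of class "fcdPatientReport" with subject metadata and a
#'   `clusters` list; serializable to JSON via [writeReportJson()].
#' @export
patientReport <- function(model, store, subjectId, parcellation = NULL,
                          m = 256, minSize = 100) {
  pr <- predictSubject(model, store, subjectId)
  cl <- formClusters(pr$pred, store@template, pr$prob, minSize = minSize)
  featNames <- paste(rep(c("combat", "normalized", "asymmetry"),
                         each = 11), fcdFeatures(), sep = ".")
  clusters <- lapply(seq_along(cl), function(k) {
    x <- assembleClassifierInput(store, subjectId, cl[[k]]$hemi)
    xbar <- colMeans(x[cl[[k]]$vertices, , drop = FALSE])
    ig <- integratedGradients(model, xbar, m = m)
    region <- if (is.null(parcellation)) NA_integer_ else {
      labs <- parcellation[cl[[k]]$vertices]
      as.integer(names(sort(table(labs), decreasing = TRUE))[1])
    }
    list(id = k, hemi = cl[[k]]$hemi, size = cl[[k]]$size,
         region = region, meanProb = cl[[k]]$meanProb,
         meanFeatures = stats::setNames(as.numeric(xbar), featNames),
         saliency = stats::setNames(as.numeric(ig$attributions),
                                    featNames),
         completenessResidual = ig$completeness)
  })
  out <- list(subject_id = subjectId,
              threshold = model@threshold,
              nClusters = length(clusters),
              message = if (length(clusters) == 0)
                "no clusters detected" else NULL,
              clusters = clusters)
  class(out) <- "fcdPatientReport"
  out
}

#' Serialize / read a patient report as JSON
#'
#' @param report an "fcdPatientReport" from [patientReport()].
#' @param path output JSON path.
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeReportJson
#' @export
readReportJson <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = FALSE)
  class(out) <- "fcdPatientReport"
  out
}

#' Render a patient report
#'
#' Bar chart of the 33 mean feature values for the largest predicted
#' cluster, coloured by integrated-gradients saliency (red = drives the
#' lesion prediction), plus a textual cluster table.
#'
#' @param report an "fcdPatientReport".
#' @param path optional PNG path; plots to the active device if `NULL`.
#' @export
plotPatientReport <- function(report, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 700, res = 110)
    on.exit(grDevices::dev.off())
  }
  if (report$nClusters == 0) {
    graphics::plot.new()
    graphics::title(main = sprintf("%s: no clusters detected",
                                   report$subject_id))
    return(invisible(NULL))
  }
  cl <- report$clusters[[1]]
  sal <- unlist(cl$saliency)
  mv <- unlist(cl$meanFeatures)
  colScale <- grDevices::colorRampPalette(c("navy", "grey90", "firebrick"))
  colIdx <- cut(sal, breaks = seq(-max(abs(sal)) - 1e-12,
                                  max(abs(sal)) + 1e-12, length.out = 65),
                labels = FALSE)
  op <- graphics::par(mar = c(10, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::barplot(mv, names.arg = names(mv), las = 2,
                    col = colScale(64)[colIdx], cex.names = 0.55,
                    ylab = "mean feature value (z)",
                    main = sprintf(
                      "%s cluster 1 (%s, %d vertices) - saliency colour",
                      report$subject_id, cl$hemi, cl$size))
  invisible(NULL)
}
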