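# Cohort persistence, demographics IO, cohort splitting and assembly of
# the 33-feature classifier input.

.SCHEMA_VERSION <- 2L

#' Write / read a cohort container
#'
#' The cohort container is a single versioned RDS file holding the
#' template, demographics, all feature sets, lesion annotations and the
#' provenance log. The round trip is lossless (exact array equality).
#'
#' @param store a [CohortFeatureStore-class].
#' @param path file path.
#' @return `writeCohort` returns `path` invisibly; `readCohort` returns
#'   the [CohortFeatureStore-class].
#' @export
writeCohort <- function(store, path) {
  validObject(store)
  payload <- list(
    schema_version = .SCHEMA_VERSION,
    template = store@template,
    subjects = store@subjects,
    featureSets = store@featureSets,
    lesions = store@lesions,
    provenance = store@provenance)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort container not found: ", path)
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$schema_version)) {
    stop("not a cohort container (no schema version)")
  }
  if (payload$schema_version != .SCHEMA_VERSION) {
    stop(sprintf("schema version mismatch: container %s, package %s",
                 payload$schema_version, .SCHEMA_VERSION))
  }
  if (is.null(payload$subjects)) {
    stop("cohort container is missing the demographics table")
  }
  nv <- nVertices(payload$template)
  for (nm in names(payload$featureSets)) {
    if (dim(payload$featureSets[[nm]])[1] != nv) {
      stop("vertex-count mismatch between feature set '", nm,
           "' and the template")
    }
  }
  new("CohortFeatureStore", template = payload$template,
      subjects = payload$subjects, featureSets = payload$featureSets,
      lesions = payload$lesions, provenance = payload$provenance)
}

#' Demographics CSV import/export
#'
#' One row per subject with the Subject fields (subject_id, group,
#' site_id, scanner, age, sex, flair_available, optional clinical
#' columns).
#'
#' @param store a [CohortFeatureStore-class].
#' @param path CSV path.
#' @export
writeDemographics <- function(store, path) {
  utils::write.csv(store@subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDemographics
#' @return data.frame of demographics.
#' @export
readDemographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "site_id", "scanner", "age", "sex",
            "flair_available")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("demographics CSV missing columns: ", paste(miss, collapse = ", "))
  }
  df$flair_available <- as.logical(df$flair_available)
  df
}

#' Split a cohort into train/test with cross-validation folds
#'
#' Subject-level split (never vertex-level), stratified by site and
#' group so patient/control ratios are preserved; folds are a random
#' near-equal partition of the train subjects. Deterministic under
#' `seed`.
#'
#' @param store a [CohortFeatureStore-class].
#' @param trainFraction fraction of subjects assigned to train.
#' @param nFolds number of cross-validation folds.
#' @param seed RNG seed.
#' @return a [CohortSplit-class].
#' @export
splitCohort <- function(store, trainFraction = 0.5, nFolds = 10, seed = 1L) {
  subj <- store@subjects
  set.seed(seed)
  trainIds <- character()
  for (strat in split(subj$subject_id,
                      interaction(subj$site_id, subj$group, drop = TRUE))) {
    k <- round(length(strat) * trainFraction)
    trainIds <- c(trainIds, sample(strat, k))
  }
  testIds <- setdiff(subj$subject_id, trainIds)
  nPat <- sum(subj$group[subj$subject_id %in% trainIds] == "patient")
  if (nPat < nFolds) {
    stop(sprintf("fewer train patients (%d) than folds (%d)", nPat, nFolds))
  }
  shuffled <- sample(trainIds)
  folds <- stats::setNames(rep_len(seq_len(nFolds), length(shuffled)),
                           shuffled)
  new("CohortSplit", trainIds = sort(trainIds), testIds = sort(testIds),
      folds = folds[sort(trainIds)])
}

#' Assemble the 33-feature classifier input for one hemisphere
#'
#' Ordered concatenation `[11 ComBat | 11 normalized | 11 asymmetry]`
#' features (registry order within each block). Missing FLAIR entries are
#' imputed with 0 -- the control mean in z-units -- so a single network
#' serves T1-only and T1+FLAIR subjects. Medial-wall vertices carry 0.
#'
#' @param store a [CohortFeatureStore-class] after harmonization and
#'   normalization.
#' @param subjectId subject identifier.
#' @param hemi "lh" or "rh".
#' @return numeric matrix (vertices x 33) with named columns.
#' @export
assembleClassifierInput <- function(store, subjectId, hemi) {
  need <- c("combat", "normalized", "asymmetry")
  miss <- setdiff(need, names(store@featureSets))
  if (length(miss)) {
    stop("feature set(s) not yet computed: ", paste(miss, collapse = ", "),
         " (run harmonization/normalization first)")
  }
  h <- match(hemi, c("lh", "rh"))
  si <- match(subjectId, store@subjects$subject_id)
  if (is.na(si)) stop("unknown subject: ", subjectId)
  blocks <- lapply(need, function(nm) {
    m <- store@featureSets[[nm]][, h, , si]
    colnames(m) <- paste(nm, fcdFeatures(), sep = ".")
    m
  })
  x <- do.call(cbind, blocks)
  x[is.na(x)] <- 0
  x[!cortexMask(store@template), ] <- 0
  x
}
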