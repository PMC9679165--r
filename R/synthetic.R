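# Synthetic multi-site cohort generator. Emulates the statistical
# structure the pipeline assumes -- smooth per-vertex feature maps with
# age/sex effects, per-site additive/multiplicative scanner shifts,
# variable FLAIR availability, and contiguous geodesic lesions realizing
# three feature archetypes -- so that every downstream stage is testable
# without clinical data.

#' Synthetic cohort configuration
#'
#' Defaults define the package's reference study conditions: a 3-site
#' cohort with mixed 1.5 T / 3 T scanners, 70% FLAIR availability, smooth
#' spatially correlated per-vertex noise (15 mm FWHM), and lesions of
#' 33-45 mm geodesic radius realizing three archetypes (archetype "group1"
#' at 2 control-SD effect size).
#'
#' @param nSites number of sites.
#' @param patientsPerSite,controlsPerSite subjects per site (recycled).
#' @param scanners per-site field-strength labels ("1.5T"/"3T").
#' @param flairFraction fraction of each site's subjects with FLAIR.
#' @param subdivisionLevel icosphere subdivision level of the template.
#' @param radius,centerOffset,capFraction template geometry, see
#'   [makeTemplate()].
#' @param radiusRange lesion geodesic radius range (mm). Chosen so that
#'   planted lesion masks (~160-295 vertices at the default template
#'   resolution) sit well above the evaluation's fixed 100-vertex
#'   cluster filter, mirroring the clinical regime where the ~0.5 cm^2
#'   filter is an order of magnitude below typical lesion extent;
#'   Dice-thresholded prediction cores cover only part of a mask, so
#'   masks near the filter size are structurally undetectable.
#' @param archetypeWeights sampling weights of the three lesion archetypes.
#' @param effectScale multiplier on all archetype effect sizes.
#' @param siteAdditiveSd SD (in control-SD units) of random per-site
#'   additive feature shifts; ignored if `siteAdditive` is given.
#' @param siteScaleRange range of random per-site multiplicative noise
#'   scales; ignored if `siteScale` is given.
#' @param siteAdditive optional nSites x 11 matrix of additive shifts in
#'   control-SD units (planted-parameter tests).
#' @param siteScale optional nSites x 11 matrix of noise scales.
#' @param ageRange,sexP age uniform range (years) and P(male).
#' @param noiseFwhm FWHM (mm) of the spatial correlation of the noise.
#' @param seed RNG seed; same seed and config give a bit-identical cohort.
#' @return a validated config list of class "SyntheticConfig".
#' @export
syntheticConfig <- function(nSites = 3,
                            patientsPerSite = 20,
                            controlsPerSite = 20,
                            scanners = rep(c("3T", "1.5T"),
                                           length.out = nSites),
                            flairFraction = 0.7,
                            subdivisionLevel = 4,
                            radius = 65, centerOffset = 70,
                            capFraction = 0.9,
                            radiusRange = c(33, 45),
                            archetypeWeights = c(group1 = 0.4, group2 = 0.3,
                                                 group3 = 0.3),
                            effectScale = 1,
                            siteAdditiveSd = 0.25,
                            siteScaleRange = c(0.85, 1.15),
                            siteAdditive = NULL,
                            siteScale = NULL,
                            ageRange = c(3, 60), sexP = 0.5,
                            noiseFwhm = 15,
                            seed = 1L) {
  cfg <- list(
    nSites = as.integer(nSites),
    patientsPerSite = rep_len(as.integer(patientsPerSite), nSites),
    controlsPerSite = rep_len(as.integer(controlsPerSite), nSites),
    scanners = rep_len(scanners, nSites),
    flairFraction = flairFraction,
    subdivisionLevel = as.integer(subdivisionLevel),
    radius = radius, centerOffset = centerOffset,
    capFraction = capFraction,
    radiusRange = radiusRange,
    archetypeWeights = archetypeWeights / sum(archetypeWeights),
    effectScale = effectScale,
    siteAdditiveSd = siteAdditiveSd,
    siteScaleRange = siteScaleRange,
    siteAdditive = siteAdditive,
    siteScale = siteScale,
    ageRange = ageRange, sexP = sexP,
    noiseFwhm = noiseFwhm,
    seed = as.integer(seed))
  stopifnot(cfg$nSites >= 1, all(cfg$patientsPerSite >= 0),
            all(cfg$controlsPerSite >= 0), all(cfg$radiusRange > 0),
            cfg$flairFraction >= 0, cfg$flairFraction <= 1,
            all(cfg$scanners %in% c("1.5T", "3T")),
            is.null(cfg$siteScale) || all(cfg$siteScale > 0),
            cfg$ageRange[1] >= 3)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# noise SDs of the directly generated fields (feature units)
.fieldSigma <- c(thickness = 0.25, gw_contrast = 0.06, sulcal_depth = 1.0,
                 k1 = 0.05, k2 = 0.05,
                 flair_gm_25 = 0.07, flair_gm_50 = 0.07, flair_gm_75 = 0.07,
                 flair_wm_boundary = 0.07, "flair_wm_0.5mm" = 0.07,
                 "flair_wm_1mm" = 0.07)

# age slopes (units/year) and sex offsets (units, male - female)
.ageSlopes <- c(thickness = -0.010, sulcal_depth = 0.005)
.sexOffsets <- c(thickness = 0.05)

#' Archetype feature offsets (control-SD units)
#'
#' The three lesion archetypes: "group1" (increased intrinsic curvature
#' and thickness, decreased grey-white contrast, increased white-matter
#' FLAIR, deeper sulci), "group2" (increased intrinsic curvature,
#' decreased grey-white contrast and decreased intracortical FLAIR) and
#' "group3" (heterogeneous, all offsets under 0.5 SD, largely overlapping
#' healthy cortex).
#'
#' @return 3 x 11 numeric matrix (archetype x feature).
#' @export
lesionArchetypes <- function() {
  f <- fcdFeatures()
  a <- matrix(0, 3, length(f), dimnames = list(
    c("group1", "group2", "group3"), f))
  a["group1", c("thickness", "intrinsic_curv")] <- 2.0
  a["group1", "gw_contrast"] <- -2.0
  a["group1", c("flair_wm_0.5mm", "flair_wm_1mm")] <- 2.0
  a["group1", "flair_wm_boundary"] <- 1.0
  a["group1", "sulcal_depth"] <- 1.0
  a["group2", "intrinsic_curv"] <- 1.5
  a["group2", "gw_contrast"] <- -1.5
  a["group2", c("flair_gm_25", "flair_gm_50", "flair_gm_75")] <- -1.5
  a["group3", "thickness"] <- 0.4
  a["group3", "intrinsic_curv"] <- 0.3
  a["group3", "gw_contrast"] <- -0.3
  a["group3", "flair_gm_50"] <- -0.2
  a
}

# smooth deterministic mean maps on unit-sphere coordinates (x taken as
# |x| so that mirrored hemispheres share identical maps)
#' @keywords internal
.meanMaps <- function(u) {
  ux <- abs(u[, 1]); uy <- u[, 2]; uz <- u[, 3]
  s1 <- sin(3 * uz + 1); s2 <- cos(2 * uy); s3 <- sin(2 * ux)
  fold <- sin(4 * uy) * cos(4 * uz)
  cbind(
    thickness = 2.7 + 0.15 * s1 + 0.10 * s2,
    gw_contrast = 1.25 + 0.04 * s2 + 0.03 * s3,
    sulcal_depth = 1.2 * fold,
    k1 = 0.15 + 0.08 * sin(5 * uz) * cos(4 * uy),
    k2 = -0.02 + 0.05 * cos(5 * uz + 1),
    flair_gm_25 = 1.10 + 0.03 * s1,
    flair_gm_50 = 1.05 + 0.03 * s2,
    flair_gm_75 = 1.00 + 0.03 * s3,
    flair_wm_boundary = 0.92 + 0.02 * s1,
    "flair_wm_0.5mm" = 0.88 + 0.02 * s2,
    "flair_wm_1mm" = 0.85 + 0.02 * s3)
}

#' Simulate a synthetic multi-site cohort
#'
#' Generates demographics, per-vertex features and planted lesions per
#' the configuration. Per subject and generated field, vertex values are
#' `mu_v + age * slope + sex * offset + site_additive + eps * sigma *
#' site_scale` with `eps` a smooth (15 mm FWHM) spatially correlated unit-
#' variance field. Mean and intrinsic curvature are derived from generated
#' principal curvature fields k1, k2 through the feature combinators.
#' Patient lesions are geodesic discs grown from a random cortex seed on a
#' fair-coin hemisphere, with archetype offsets (in control-SD units)
#' added inside, and carry full 20/40 mm border-zone annotations.
#'
#' @param config a [syntheticConfig()].
#' @param template optional prebuilt [SymmetricTemplate-class] (must match
#'   the config geometry); built from the config if `NULL`.
#' @return list with elements `store` (a [CohortFeatureStore-class]) and
#'   `truth` (planted parameters: site effects, per-feature control SD,
#'   archetype/seed/radius per lesion).
#' @export
simulateCohort <- function(config = syntheticConfig(), template = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(template)) {
    template <- makeTemplate(config$subdivisionLevel, config$radius,
                             config$centerOffset, config$capFraction)
  }
  if (max(config$radiusRange) > pi * config$radius) {
    stop("lesion radius exceeds the hemisphere extent")
  }
  set.seed(config$seed)
  nv <- nVertices(template)
  cortex <- cortexMask(template)
  feats <- fcdFeatures()
  nf <- length(feats)
  meshes <- list(lh = template@left, rh = template@right)

  # demographics ------------------------------------------------------
  nPerSite <- config$patientsPerSite + config$controlsPerSite
  n <- sum(nPerSite)
  siteId <- rep(sprintf("site%d", seq_len(config$nSites)), nPerSite)
  group <- unlist(lapply(seq_len(config$nSites), function(s) {
    c(rep("patient", config$patientsPerSite[s]),
      rep("control", config$controlsPerSite[s]))
  }))
  subjects <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = group,
    site_id = siteId,
    scanner = rep(config$scanners, nPerSite),
    age = round(stats::runif(n, config$ageRange[1], config$ageRange[2]), 1),
    sex = ifelse(stats::runif(n) < config$sexP, "M", "F"),
    flair_available = stats::runif(n) < config$flairFraction,
    stringsAsFactors = FALSE)

  # planted site effects (control-SD units for additive shifts) --------
  fieldNames <- colnames(.meanMaps(matrix(0, 1, 3)))
  siteAdd <- config$siteAdditive
  if (is.null(siteAdd)) {
    siteAdd <- matrix(stats::rnorm(config$nSites * nf, 0,
                                   config$siteAdditiveSd),
                      config$nSites, nf)
  }
  siteScale <- config$siteScale
  if (is.null(siteScale)) {
    siteScale <- matrix(stats::runif(config$nSites * nf,
                                     config$siteScaleRange[1],
                                     config$siteScaleRange[2]),
                        config$nSites, nf)
  }
  dimnames(siteAdd) <- dimnames(siteScale) <-
    list(sprintf("site%d", seq_len(config$nSites)), feats)

  # smooth unit-variance noise machinery ------------------------------
  Wn <- lapply(meshes, smoothingWeights, kernelMm = config$noiseFwhm)
  rowNorm <- lapply(Wn, function(W) {
    r <- sqrt(Matrix::rowSums(W^2))
    r[r == 0] <- 1
    r
  })
  smoothNoise <- function(hemi, k) {
    z <- matrix(stats::rnorm(nv * k), nv, k)
    as.matrix(Wn[[hemi]] %*% z) / rowNorm[[hemi]]
  }

  # per-hemisphere mean maps (identical across hemispheres by mirror
  # symmetry; computed once on the left)
  uL <- sweep(template@left@vertices,
              2, c(-config$centerOffset, 0, 0)) / config$radius
  mu <- .meanMaps(uL)
  nField <- length(fieldNames)

  # generate clean fields, derive curvatures, apply site effects ------
  arr <- array(NA_real_, dim = c(nv, 2, nf, n),
               dimnames = list(NULL, c("lh", "rh"), feats,
                               subjects$subject_id))
  sexNum <- as.integer(subjects$sex == "M")
  siteIdx <- match(subjects$site_id, rownames(siteAdd))
  cleanNoise <- vector("list", 2)
  for (h in 1:2) {
    eps <- smoothNoise(h, nField * n)
    dim(eps) <- c(nv, nField, n)
    dimnames(eps) <- list(NULL, fieldNames, subjects$subject_id)
    cleanNoise[[h]] <- eps
  }
  sigmaScaled <- .fieldSigma[fieldNames]
  for (i in seq_len(n)) {
    agec <- subjects$age[i]
    for (h in 1:2) {
      fields <- mu
      for (fn in names(.ageSlopes)) {
        fields[, fn] <- fields[, fn] + .ageSlopes[[fn]] * agec
      }
      for (fn in names(.sexOffsets)) {
        fields[, fn] <- fields[, fn] + .sexOffsets[[fn]] * sexNum[i]
      }
      noise <- sweep(cleanNoise[[h]][, , i], 2, sigmaScaled, `*`)
      raw <- fields + noise
      out <- cbind(
        thickness = raw[, "thickness"],
        gw_contrast = raw[, "gw_contrast"],
        mean_curv = meanCurvature(raw[, "k1"], raw[, "k2"]),
        sulcal_depth = raw[, "sulcal_depth"],
        intrinsic_curv = intrinsicCurvature(raw[, "k1"], raw[, "k2"]),
        raw[, flairFeatures(), drop = FALSE])
      ctr <- cbind(
        thickness = fields[, "thickness"],
        gw_contrast = fields[, "gw_contrast"],
        mean_curv = meanCurvature(fields[, "k1"], fields[, "k2"]),
        sulcal_depth = fields[, "sulcal_depth"],
        intrinsic_curv = intrinsicCurvature(fields[, "k1"], fields[, "k2"]),
        fields[, flairFeatures(), drop = FALSE])
      # multiplicative site effect scales the stochastic deviation only;
      # the additive shift is applied below in control-SD units
      s <- siteIdx[i]
      arr[, h, , i] <- ctr + sweep(out - ctr, 2, siteScale[s, feats], `*`)
    }
  }

  # empirical per-feature control SD (pooled over vertices/hemispheres),
  # the unit for additive site shifts and archetype effect sizes
  ctrlIdx <- which(subjects$group == "control")
  sigmaEmp <- vapply(seq_len(nf), function(fi) {
    x <- arr[cortex, , fi, ctrlIdx]
    mu_v <- apply(x, c(1, 2), mean)
    stats::sd(sweep(x, c(1, 2), mu_v))
  }, numeric(1))
  names(sigmaEmp) <- feats

  # additive site shifts, expressed in control-SD units
  for (i in seq_len(n)) {
    s <- siteIdx[i]
    shift <- siteAdd[s, ] * sigmaEmp
    arr[, , , i] <- arr[, , , i] +
      rep(shift, each = nv * 2)
  }

  # FLAIR availability ------------------------------------------------
  arr[, , flairFeatures(), !subjects$flair_available] <- NA_real_
  # medial wall carries 0
  arr[!cortex, , , ] <- 0

  # planted lesions ----------------------------------------------------
  lesions <- list()
  truthLesions <- NULL
  archOffsets <- lesionArchetypes() * config$effectScale
  patIdx <- which(subjects$group == "patient")
  cortexIdx <- which(cortex)
  for (i in patIdx) {
    hemi <- if (stats::runif(1) < 0.5) "lh" else "rh"
    h <- match(hemi, c("lh", "rh"))
    seedV <- sample(cortexIdx, 1)
    radius <- stats::runif(1, config$radiusRange[1], config$radiusRange[2])
    arch <- sample(rownames(archOffsets), 1,
                   prob = config$archetypeWeights)
    d <- geodesicDistance(meshes[[hemi]], seedV)
    mask <- !is.na(d) & d <= radius
    off <- archOffsets[arch, ] * sigmaEmp
    for (fi in seq_len(nf)) {
      if (off[fi] != 0) {
        arr[mask, h, fi, i] <- arr[mask, h, fi, i] + off[fi]
      }
    }
    sid <- subjects$subject_id[i]
    lesions[[sid]] <- makeBorderZones(mask, meshes[[hemi]], hemi = hemi)
    truthLesions <- rbind(truthLesions, data.frame(
      subject_id = sid, hemi = hemi, seed_vertex = seedV,
      radius_mm = radius, archetype = arch, n_vertices = sum(mask)))
  }
  subjects$lesion_hemi <- NA_character_
  subjects$lesion_hemi[patIdx] <- truthLesions$hemi

  store <- new("CohortFeatureStore",
               template = template,
               subjects = subjects,
               featureSets = list(raw = arr),
               lesions = lesions,
               provenance = sprintf("synthetic(seed=%d)", config$seed))
  list(store = store,
       truth = list(siteAdditive = siteAdd, siteScale = siteScale,
                    sigmaControl = sigmaEmp, lesions = truthLesions,
                    config = config))
}
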