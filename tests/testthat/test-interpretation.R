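# Integrated gradients, lesion phenotyping and patient reports.

test_that("integrated gradients vanish at the zero baseline input", {
  mod <- miniModel()
  ig <- integratedGradients(mod, rep(0, 33), m = 16)
  expect_equal(unname(ig$attributions), rep(0, 33))
  expect_equal(ig$completeness, 0, tolerance = 1e-12)
})

test_that("integrated gradients are exact for a linear logit at any m", {
  # no hidden layers: the logit is w.x + b, whose path integral is w*x
  spec <- networkSpec(inputDim = 6, hidden = integer(0), inputDropout = 0)
  net <- fcdetect:::.initNet(spec, seed = 5)
  w <- as.numeric(net$W[[1]])
  x <- c(0.5, -1, 2, 0, 0.3, -0.7)
  for (m in c(1, 3, 64)) {
    ig <- integratedGradients(net, x, m = m, output = "logit")
    expect_equal(unname(ig$attributions), w * x, tolerance = 1e-10)
    expect_lt(ig$completeness, 1e-10)
  }
  # a feature that is zero in the input gets zero attribution
  expect_equal(unname(ig$attributions[4]), 0)
})

test_that("completeness residual is under 1% for trained networks at
           m = 256", {
  mod <- miniModel()
  store <- miniNormalized()
  set.seed(9)
  for (sid in sample(subjectIds(store), 3)) {
    x <- assembleClassifierInput(store, sid, "lh")
    xbar <- colMeans(x[cortexMask(template(store)), ])
    ig <- integratedGradients(mod, xbar, m = 256)
    expect_lt(ig$completeness,
              max(0.01 * abs(ig$fx - ig$f0), 1e-6))
  }
})

test_that("lesion feature summaries recover planted effects and match
           control sizes", {
  store <- miniNormalized()
  summ <- lesionFeatureSummary(store, seed = 2)
  pats <- summ[summ$group == "patient", ]
  ctls <- summ[summ$group == "control", ]
  # archetype-1 thickness (+2 SD) visible in the normalized means
  expect_gt(mean(pats$normalized.thickness), 1.0)
  expect_lt(mean(abs(ctls$normalized.thickness)), 0.5)
  # pseudo-lesions size-matched within 10%
  expect_true(all(abs(ctls$size - rep_len(pats$size, nrow(ctls))) /
                    rep_len(pats$size, nrow(ctls)) <= 0.1))
})

test_that("whole-cortex control summaries are near zero", {
  store <- miniNormalized()
  subj <- store@subjects
  ctl <- subj$subject_id[subj$group == "control"][1]
  cortex <- which(cortexMask(template(store)))
  z <- featureSet(store, "normalized")
  m <- mean(z[cortex, , "thickness", match(ctl, subj$subject_id)])
  expect_lt(abs(m), 0.25)
})

test_that("phenotype clustering recovers three planted archetypes", {
  cfg <- syntheticConfig(nSites = 1, patientsPerSite = 60,
                         controlsPerSite = 20, subdivisionLevel = 3,
                         radiusRange = c(25, 35),
                         archetypeWeights = c(1, 1, 1) / 3,
                         siteAdditive = matrix(0, 1, 11),
                         siteScale = matrix(1, 1, 11), seed = 17)
  sim <- simulateCohort(cfg)
  store <- intrasubjectZscore(sim$store, set = "raw")
  store <- interhemisphericAsymmetry(store)
  store <- controlNormalize(store, buildControlReference(store))
  summ <- lesionFeatureSummary(store, includeControls = FALSE)
  out <- embedAndCluster(summ, K = 3, seed = 4)
  truthArch <- sim$truth$lesions$archetype[
    match(out$subject_id[out$group == "patient"],
          sim$truth$lesions$subject_id)]
  ari <- mclust::adjustedRandIndex(out$phenotype[out$group == "patient"],
                                   truthArch)
  expect_gt(ari, 0.8)
  # determinism and the K = 1 degenerate case
  out2 <- embedAndCluster(summ, K = 3, seed = 4)
  expect_identical(out$phenotype, out2$phenotype)
  one <- embedAndCluster(summ, K = 1, seed = 4)
  expect_true(all(one$phenotype[one$group == "patient"] == 1))
})

test_that("patient reports list clusters with aligned saliency and
           round-trip via JSON", {
  mod <- miniModel()
  store <- miniNormalized()
  sp <- miniSplit()
  parc <- makeParcellation(template(store), nRegions = 16)
  subj <- store@subjects
  pats <- intersect(sp@testIds, subj$subject_id[subj$group == "patient"])
  found <- FALSE
  for (sid in pats) {
    repp <- patientReport(mod, store, sid, parcellation = parc,
                          m = 128, minSize = 5)
    if (repp$nClusters == 0) next
    found <- TRUE
    cl <- repp$clusters[[1]]
    expect_length(cl$meanFeatures, 33)
    expect_length(cl$saliency, 33)
    expect_lt(cl$completenessResidual, 0.02)
    # planted thickness effect should be among the top positive saliencies
    thickCols <- grep("\\.thickness$", names(cl$saliency))
    top3 <- order(cl$saliency, decreasing = TRUE)[1:3]
    expect_true(any(top3 %in% thickCols))
    path <- withr::local_tempfile(fileext = ".json")
    writeReportJson(repp, path)
    back <- readReportJson(path)
    expect_equal(back$subject_id, repp$subject_id)
    expect_equal(back$nClusters, repp$nClusters)
    expect_equal(unlist(back$clusters[[1]]$saliency),
                 unname(cl$saliency), tolerance = 1e-12)
    break
  }
  expect_true(found)
})

test_that("subjects without suprathreshold clusters report that fact", {
  mod <- miniModel()
  store <- miniNormalized()
  subj <- store@subjects
  ctl <- subj$subject_id[subj$group == "control"][1]
  repp <- patientReport(mod, store, ctl, minSize = 1e6)
  expect_equal(repp$nClusters, 0)
  expect_match(repp$message, "no clusters")
  path <- withr::local_tempfile(fileext = ".png")
  plotPatientReport(repp, path)
  expect_true(file.exists(path))
})
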