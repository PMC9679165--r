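# Shared fixtures, built in code once per test run and memoized.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small 2-site cohort on a level-2 template (162 vertices/hemisphere)
miniSim <- function() fixture("miniSim", function() {
  simulateCohort(syntheticConfig(
    nSites = 2, patientsPerSite = 8, controlsPerSite = 8,
    subdivisionLevel = 2, radiusRange = c(22, 32),
    archetypeWeights = c(group1 = 1, group2 = 0, group3 = 0), seed = 42))
})

# the same cohort taken through combat + three-stage normalization
miniNormalized <- function() fixture("miniNormalized", function() {
  store <- fitComBat(miniSim()$store)$store
  store <- interhemisphericAsymmetry(intrasubjectZscore(store))
  ref <- buildControlReference(store)
  controlNormalize(store, ref)
})

miniSplit <- function() fixture("miniSplit", function() {
  splitCohort(miniNormalized(), trainFraction = 0.5, nFolds = 2, seed = 3)
})

miniData <- function() fixture("miniData", function() {
  prepareSubjectData(miniNormalized(), miniSplit()@trainIds)
})

# a small but functioning ensemble (2 folds x 2 inits, short training)
miniModel <- function() fixture("miniModel", function() {
  trainEnsemble(miniNormalized(), miniSplit(),
                trainingConfig(epochs = 8, nLesional = 400,
                               nNonlesional = 400, batchSize = 500),
                nInits = 2, seed = 9, data = miniData())
})

miniTrainingConfig <- function() {
  trainingConfig(epochs = 8, nLesional = 400, nNonlesional = 400,
                 batchSize = 500)
}

# cohort with planted site effects for parameter-recovery checks
combatSim <- function() fixture("combatSim", function() {
  shifts <- matrix(0, 3, 11)
  shifts[1, ] <- 1.0; shifts[2, ] <- 0; shifts[3, ] <- -1.0
  scales <- matrix(1, 3, 11)
  scales[1, ] <- 0.7; scales[3, ] <- 1.4
  simulateCohort(syntheticConfig(
    nSites = 3, patientsPerSite = 25, controlsPerSite = 25,
    subdivisionLevel = 2, siteAdditive = shifts, siteScale = scales,
    flairFraction = 1, seed = 77))
})

siteMeanSpread <- function(arr, subj, feature) {
  vapply(unique(subj$site_id), function(s) {
    mean(arr[, , feature, subj$site_id == s])
  }, numeric(1))
}

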