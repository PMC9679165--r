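# ComBat harmonization: identity on a single site, removal of planted
# site effects, covariate preservation, the non-EB standardization
# oracle, an sva cross-check, and frozen-reference new-site mode.

test_that("single-site harmonization is the identity", {
  cfg <- syntheticConfig(nSites = 1, patientsPerSite = 4,
                         controlsPerSite = 4, subdivisionLevel = 1,
                         radiusRange = c(20, 25), seed = 2)
  sim <- simulateCohort(cfg)
  res <- suppressMessages(fitComBat(sim$store))
  expect_equal(featureSet(res$store, "combat"),
               featureSet(sim$store, "raw"), tolerance = 1e-6)
})

test_that("planted site shifts are removed >=90% and the age slope
           survives", {
  sim <- combatSim()
  res <- fitComBat(sim$store)
  subj <- sim$store@subjects
  cortex <- cortexMask(template(sim$store))
  rawSpread <- siteMeanSpread(featureSet(sim$store, "raw")[cortex, , , ,
                                                           drop = FALSE],
                              subj, "thickness")
  harmSpread <- siteMeanSpread(featureSet(res$store, "combat")[cortex, , , ,
                                                               drop = FALSE],
                               subj, "thickness")
  expect_lt(diff(range(harmSpread)), 0.1 * diff(range(rawSpread)))

  # planted age slope (-0.010 mm/yr on thickness) preserved within 10%
  harm <- featureSet(res$store, "combat")
  subjMean <- colMeans(matrix(harm[cortex, , "thickness", ],
                              ncol = nrow(subj)))
  slope <- coef(lm(subjMean ~ subj$age))[2]
  expect_equal(as.numeric(slope), -0.010, tolerance = 0.10)
})

test_that("without EB, harmonization equals the direct location/scale
           standardization oracle", {
  sim <- combatSim()
  res <- fitComBat(sim$store, eb = FALSE)
  subj <- sim$store@subjects
  arr <- featureSet(sim$store, "raw")
  harm <- featureSet(res$store, "combat")
  # oracle: per column, OLS with site dummies + covariates, then
  # remove each site's residual location/scale directly
  cortex <- which(cortexMask(template(sim$store)))
  set.seed(4)
  for (k in 1:20) {
    v <- sample(cortex, 1); h <- sample(1:2, 1); f <- sample(1:11, 1)
    y <- arr[v, h, f, ]
    X <- cbind(model.matrix(~ 0 + factor(subj$site_id)), subj$age,
               as.numeric(subj$sex == "M"),
               as.numeric(subj$group == "patient"))
    B <- solve(crossprod(X), crossprod(X, y))
    ns <- table(subj$site_id)
    alpha <- sum(ns / length(y) * B[1:3])
    fitted <- X %*% B
    sigma <- sqrt(mean((y - fitted)^2))
    stand <- alpha + X[, 4:6, drop = FALSE] %*% B[4:6]
    z <- (y - stand) / sigma
    for (s in unique(subj$site_id)) {
      zi <- z[subj$site_id == s]
      z[subj$site_id == s] <- (zi - mean(zi)) / sd(zi)
    }
    expect_equal(as.numeric(harm[v, h, f, ]),
                 as.numeric(z * sigma + stand), tolerance = 1e-6)
  }
})

test_that("authored ComBat matches sva::ComBat on a complete matrix", {
  skip_if_not_installed("sva")
  sim <- combatSim()
  subj <- sim$store@subjects
  arr <- featureSet(sim$store, "raw")
  cortex <- which(cortexMask(template(sim$store)))[1:40]
  Y <- t(sapply(cortex, function(v) arr[v, 1, "thickness", ]))
  mod <- model.matrix(~ age + I(sex == "M") + I(group == "patient"),
                      data = subj)
  ref <- suppressMessages(
    sva::ComBat(dat = Y, batch = subj$site_id, mod = mod))
  mine <- fcdetect:::.combatFitBlock(
    t(Y), factor(subj$site_id),
    fcdetect:::.covDesign(subj, c("age", "sex", "group")), eb = TRUE)
  expect_equal(as.numeric(t(mine$harmonized)), as.numeric(ref),
               tolerance = 1e-4)
})

test_that("grand mean is preserved at the fitted alpha + X beta", {
  sim <- combatSim()
  res <- fitComBat(sim$store, eb = FALSE)
  blk <- res$model@blocks$t1
  subj <- sim$store@subjects
  Xcov <- fcdetect:::.covDesign(subj, res$model@covariates)
  Y <- fcdetect:::.flattenSet(featureSet(res$store, "combat"),
                              blk$featIdx, seq_len(nrow(subj)))
  pred <- matrix(blk$alpha, nrow(Y), ncol(Y), byrow = TRUE) +
    Xcov %*% blk$betaCov
  keep <- !blk$skip
  expect_lt(max(abs(colMeans(Y)[keep] - colMeans(pred)[keep])), 1e-6)
})

test_that("new-site harmonization removes a planted shift and nulls are
           untouched", {
  sim <- combatSim()
  fitted <- fitComBat(sim$store)
  # null new site: same generating distribution, no shift
  mkNew <- function(shiftSd) {
    shifts <- matrix(shiftSd, 1, 11)
    s <- simulateCohort(syntheticConfig(
      nSites = 1, patientsPerSite = 0, controlsPerSite = 20,
      subdivisionLevel = 2, siteAdditive = shifts,
      siteScale = matrix(1, 1, 11), flairFraction = 1, seed = 99))
    s$store@subjects$site_id <- "site_new"
    list(store = s$store, sigma = s$truth$sigmaControl)
  }
  nullSite <- mkNew(0)
  h0 <- harmonizeNewSite(fitted$model, nullSite$store)
  cortex <- cortexMask(template(nullSite$store))
  sigma <- as.numeric(nullSite$sigma["thickness"])
  delta <- featureSet(h0, "combat")[cortex, , "thickness", ] -
    featureSet(nullSite$store, "raw")[cortex, , "thickness", ]
  expect_lt(abs(mean(delta)) / sigma, 0.05)
  expect_lt(mean(abs(delta)) / sigma, 0.25)  # EB noise floor at n = 20

  shifted <- mkNew(0.8)
  h1 <- harmonizeNewSite(fitted$model, shifted$store)
  refMean <- mean(featureSet(fitted$store, "combat")[cortex, ,
                                                     "thickness", ])
  newMean <- mean(featureSet(h1, "combat")[cortex, , "thickness", ])
  # planted +0.8 SD shift removed to within 0.1 SD of the reference
  expect_lt(abs(newMean - refMean) / sigma, 0.1)
})

test_that("new-site harmonization is idempotent (EB disabled)", {
  sim <- combatSim()
  fitted <- fitComBat(sim$store, eb = FALSE)
  new1 <- simulateCohort(syntheticConfig(
    nSites = 1, patientsPerSite = 0, controlsPerSite = 10,
    subdivisionLevel = 2, siteAdditive = matrix(0.5, 1, 11),
    siteScale = matrix(1.2, 1, 11), flairFraction = 1, seed = 55))$store
  new1@subjects$site_id <- "siteX"
  h1 <- harmonizeNewSite(fitted$model, new1)
  again <- h1
  again@featureSets <- list(raw = featureSet(h1, "combat"))
  h2 <- harmonizeNewSite(fitted$model, again)
  expect_equal(featureSet(h2, "combat"), featureSet(h1, "combat"),
               tolerance = 1e-6)
})

test_that("site rosters and degenerate sites are rejected", {
  sim <- combatSim()
  fitted <- fitComBat(sim$store)
  expect_error(harmonizeNewSite(fitted$model, sim$store), "reference")
  one <- sim$store
  keep <- c(which(one@subjects$site_id == "site1"),
            which(one@subjects$site_id == "site2")[1])
  one@subjects <- one@subjects[keep, ]
  one@featureSets$raw <- one@featureSets$raw[, , , keep, drop = FALSE]
  expect_error(fitComBat(one), ">= 2 subjects")
})
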