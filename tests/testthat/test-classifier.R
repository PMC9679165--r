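# Focal loss, gradients, vertex sampling, threshold optimization and
# ensemble contracts.

test_that("focal loss reduces to cross-entropy at gamma = 0, alpha = 1", {
  set.seed(1)
  p <- runif(1e4, 0.001, 0.999)
  y <- rbinom(1e4, 1, 0.5)
  bce <- -ifelse(y == 1, log(p), log(1 - p))
  expect_lt(max(abs(focalLoss(p, y, gamma = 0, alpha = 1,
                              reduce = FALSE) - bce)), 1e-12)
})

test_that("focal loss matches the closed form and is monotone in p_t", {
  # hand evaluation: y=1, p=0.9, gamma=2, alpha=1
  expect_equal(focalLoss(0.9, 1, gamma = 2, alpha = 1),
               -(0.1)^2 * log(0.9), tolerance = 1e-9)
  expect_equal(focalLoss(0.9, 1, gamma = 2, alpha = 1), 1.0536052e-3,
               tolerance = 1e-6)
  grid <- seq(0.02, 0.98, by = 0.02)
  for (g in c(0, 1, 2, 5)) {
    l <- focalLoss(grid, rep(1, length(grid)), gamma = g, alpha = 0.5,
                   reduce = FALSE)
    expect_true(all(diff(l) < 0))  # decreasing as p_t grows
  }
})

test_that("focal loss clips degenerate probabilities", {
  expect_true(is.finite(focalLoss(0, 1, 2, 0.5)))
  expect_true(is.finite(focalLoss(1, 0, 2, 0.5)))
})

test_that("analytic focal-loss and network gradients match numerical
           differentiation", {
  set.seed(2)
  p <- runif(20, 0.05, 0.95)
  y <- rbinom(20, 1, 0.5)
  eps <- 1e-6
  for (g in c(0, 2)) {
    ana <- fcdetect:::.focalLossGradP(p, y, g, 0.5)
    num <- vapply(seq_along(p), function(i) {
      ph <- p; pl <- p
      ph[i] <- p[i] + eps; pl[i] <- p[i] - eps
      (focalLoss(ph, y, g, 0.5) - focalLoss(pl, y, g, 0.5)) / (2 * eps)
    }, numeric(1))
    expect_equal(ana, num, tolerance = 1e-5)
  }

  # weight gradients against central differences
  spec <- networkSpec(inputDim = 5, hidden = c(4, 3), inputDropout = 0)
  net <- fcdetect:::.initNet(spec, seed = 3)
  X <- matrix(rnorm(40), 8, 5)
  yy <- rbinom(8, 1, 0.5)
  bw <- fcdetect:::.backward(net, X, yy, gamma = 2, alpha = 0.5)
  for (l in 1:3) {
    i <- 1; j <- 1
    fplus <- net; fplus$W[[l]][i, j] <- fplus$W[[l]][i, j] + eps
    fminus <- net; fminus$W[[l]][i, j] <- fminus$W[[l]][i, j] - eps
    num <- (focalLoss(fcdetect:::.forward(fplus, X), yy, 2, 0.5) -
              focalLoss(fcdetect:::.forward(fminus, X), yy, 2, 0.5)) /
      (2 * eps)
    expect_equal(bw$gW[[l]][i, j], num, tolerance = 1e-4)
  }
})

test_that("vertex sampling honours counts, masks and the exclusion set", {
  data <- miniData()
  cfg <- trainingConfig()
  pats <- names(data)[vapply(data, function(d) d$group == "patient",
                             logical(1))]
  d <- data[[pats[1]]]
  set.seed(5)
  s <- sampleTrainingVertices(d, cfg)
  expect_length(s$lesional, 2000)
  expect_length(s$nonlesional, 2000)
  expect_true(all(d$label[s$lesional]))
  expect_false(any(d$exclusion[s$nonlesional]))
  expect_false(any(d$label[s$nonlesional]))

  # pools larger than the request are sampled without replacement
  big <- d
  big$label <- rep(FALSE, length(big$label))
  big$label[1:250] <- TRUE
  big$exclusion <- rep(FALSE, length(big$exclusion))
  cfgSmall <- trainingConfig(nLesional = 200, nNonlesional = 50)
  set.seed(7)
  s2 <- sampleTrainingVertices(big, cfgSmall)
  expect_length(unique(s2$lesional), 200)
  set.seed(7)
  s3 <- sampleTrainingVertices(big, cfgSmall)
  expect_identical(s2, s3)  # reproducible under seed

  ctl <- data[[setdiff(names(data), pats)[1]]]
  sc <- sampleTrainingVertices(ctl, cfg)
  expect_length(sc$lesional, 0)
  expect_length(sc$nonlesional, 2000)

  empty <- d
  empty$label <- rep(FALSE, length(empty$label))
  empty$group <- "patient"
  expect_error(sampleTrainingVertices(empty, cfg), "empty lesion mask")
})

test_that("threshold optimization maximizes pooled Dice with smallest-t
           ties", {
  # perfectly separated: any t in (0.1, 0.9] has Dice 1 -> returns 0.11
  p <- c(rep(0.9, 50), rep(0.1, 200))
  y <- c(rep(1, 50), rep(0, 200))
  expect_equal(optimizeThreshold(p, y), 0.11)
  expect_error(optimizeThreshold(runif(10), rep(0, 10)), "positive")

  set.seed(8)
  p <- runif(500); y <- rbinom(500, 1, 0.3)
  t1 <- optimizeThreshold(p, y)
  # brute-force grid oracle
  dice <- sapply(seq(0.01, 0.99, 0.01), function(t) {
    tp <- sum(p >= t & y == 1)
    2 * tp / (2 * tp + sum(p >= t & y == 0) + sum(p < t & y == 1))
  })
  expect_equal(t1, seq(0.01, 0.99, 0.01)[which.max(dice)])
})

test_that("training is deterministic under a fixed seed", {
  data <- miniData()
  sp <- miniSplit()
  cfg <- trainingConfig(epochs = 2, nLesional = 100, nNonlesional = 100,
                        batchSize = 200)
  a <- trainFold(data, sp@folds, 1, cfg, seed = 4)
  b <- trainFold(data, sp@folds, 1, cfg, seed = 4)
  expect_identical(a$net$W, b$net$W)
  expect_identical(a$log, b$log)
  expect_equal(unname(a$audit["violations"]), 0)
  expect_gt(unname(a$audit["checked"]), 0)
})

test_that("the ensemble is the arithmetic mean of its members", {
  mod <- miniModel()
  expect_length(mod@members, 4)  # 2 folds x 2 inits
  store <- miniNormalized()
  sid <- subjectIds(store)[1]
  x <- assembleClassifierInput(store, sid, "lh")
  manual <- rowMeans(vapply(mod@members,
                            function(m) fcdetect:::.forward(m, x),
                            numeric(nrow(x))))
  pr <- predictSubject(mod, store, sid)
  cortex <- cortexMask(template(store))
  expect_equal(pr$prob[cortex, "lh"], manual[cortex], tolerance = 1e-12)
  # inference is deterministic (dropout off)
  pr2 <- predictSubject(mod, store, sid)
  expect_identical(pr$prob, pr2$prob)
})

test_that("ensemble log-loss is no worse than the mean member log-loss", {
  mod <- miniModel()
  store <- miniNormalized()
  sp <- miniSplit()
  data <- prepareSubjectData(store, sp@testIds[1:4])
  X <- do.call(rbind, lapply(data, `[[`, "x"))
  y <- unlist(lapply(data, `[[`, "label"))
  memberP <- vapply(mod@members, function(m) fcdetect:::.forward(m, X),
                    numeric(nrow(X)))
  ll <- function(p) mean(-ifelse(y == 1, log(pmax(p, 1e-12)),
                                 log(pmax(1 - p, 1e-12))))
  expect_lte(ll(rowMeans(memberP)), mean(apply(memberP, 2, ll)) + 1e-12)
})

test_that("provenance hash changes iff the config changes", {
  c1 <- trainingConfig()
  c2 <- trainingConfig()
  c3 <- trainingConfig(gamma = 3)
  expect_identical(fcdetect:::.hashConfig(c1), fcdetect:::.hashConfig(c2))
  expect_false(identical(fcdetect:::.hashConfig(c1),
                         fcdetect:::.hashConfig(c3)))
})

test_that("strong planted lesions separate vertices (high validation
           AUC)", {
  mod <- miniModel()
  ok <- !is.na(mod@provenance$valSummary$valAUC)
  expect_gt(mean(mod@provenance$valSummary$valAUC[ok]), 0.85)
})
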