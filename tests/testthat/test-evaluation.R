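# Cluster formation/filtering, cohort metrics and the permutation
# logistic regression.

test_that("the cluster size filter has exact boundary behaviour", {
  tpl <- makeTemplate(3, centerOffset = 0)  # 642 vertices/hemisphere
  mesh <- tpl@left
  d <- geodesicDistance(mesh, which(mesh@cortexMask)[1])
  ord <- order(d, na.last = NA)
  pred <- matrix(FALSE, nVertices(tpl), 2,
                 dimnames = list(NULL, c("lh", "rh")))
  pred[ord[1:99], 1] <- TRUE
  expect_length(formClusters(pred, tpl), 0)
  pred[ord[1:100], 1] <- TRUE
  cl <- formClusters(pred, tpl)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 100)
  # empty prediction
  expect_length(formClusters(pred & FALSE, tpl), 0)
})

test_that("multi-blob predictions match the flood-fill + filter oracle", {
  tpl <- makeTemplate(2, centerOffset = 0)
  set.seed(10)
  pred <- matrix(runif(2 * nVertices(tpl)) < 0.35, nVertices(tpl), 2,
                 dimnames = list(NULL, c("lh", "rh")))
  pred[!cortexMask(tpl), ] <- FALSE
  cl <- formClusters(pred, tpl, minSize = 5)
  expected <- list()
  for (h in 1:2) {
    mesh <- if (h == 1) tpl@left else tpl@right
    or <- floodFillOracle(mesh, pred[, h])
    for (lab in seq_along(or$sizes)) {
      if (or$sizes[lab] >= 5) {
        expected[[length(expected) + 1]] <-
          sort(which(!is.na(or$labels) & or$labels == lab))
      }
    }
  }
  got <- lapply(cl, function(x) sort(x$vertices))
  expect_setequal(got, expected)
  # sorted by size, descending
  sizes <- vapply(cl, `[[`, numeric(1), "size")
  expect_true(all(diff(sizes) <= 0))
})

# tiny cohort whose detections we can enumerate by hand
toyMetricSetup <- function() {
  sim <- miniSim()
  store <- sim$store
  subj <- store@subjects
  pats <- subj$subject_id[subj$group == "patient"][1:3]
  ctls <- subj$subject_id[subj$group == "control"][1:3]
  tpl <- template(store)
  mk <- function(vertices, hemi) list(hemi = hemi,
                                      vertices = vertices,
                                      size = length(vertices),
                                      meanProb = 0.9)
  ann1 <- store@lesions[[pats[1]]]
  ann2 <- store@lesions[[pats[2]]]
  ann3 <- store@lesions[[pats[3]]]
  clusters <- list()
  # patient 1: cluster overlapping the mask -> detected both ways
  clusters[[pats[1]]] <- list(mk(which(ann1@mask), ann1@hemi))
  # patient 2: cluster only in ring20 -> sensitivity+ only
  clusters[[pats[2]]] <- list(mk(which(ann2@ring20)[1:3], ann2@hemi))
  # patient 3: cluster on the wrong hemisphere -> miss
  clusters[[pats[3]]] <- list(mk(which(ann3@mask),
                                 setdiff(c("lh", "rh"), ann3@hemi)))
  # controls: one with a cluster, two clean
  clusters[[ctls[1]]] <- list(mk(1:30, "lh"))
  clusters[[ctls[2]]] <- list()
  clusters[[ctls[3]]] <- list()
  list(store = store, clusters = clusters, pats = pats, ctls = ctls)
}

test_that("cohort metrics match the hand-computed contingency", {
  ts <- toyMetricSetup()
  met <- computeMetrics(ts$clusters, ts$store)
  expect_equal(met$sensitivity, 1 / 3)
  expect_equal(met$sensitivityPlus, 2 / 3)
  expect_equal(met$specificity, 2 / 3)
  expect_true(met$sensitivityPlus >= met$sensitivity)
  tab <- met$detectionTable
  expect_false(tab$detected[tab$subject_id == ts$pats[2]])
  expect_true(tab$detectedPlus[tab$subject_id == ts$pats[2]])
})

test_that("metrics are invariant to subject ordering", {
  ts <- toyMetricSetup()
  met1 <- computeMetrics(ts$clusters, ts$store)
  met2 <- computeMetrics(rev(ts$clusters), ts$store)
  expect_equal(met1$sensitivity, met2$sensitivity)
  expect_equal(met1$detectionTable, met2$detectionTable)
})

test_that("lowering the size filter never lowers sensitivity nor raises
           specificity", {
  mod <- miniModel()
  store <- miniNormalized()
  sp <- miniSplit()
  preds <- lapply(sp@testIds, function(sid) predictSubject(mod, store, sid))
  names(preds) <- sp@testIds
  prev <- NULL
  for (ms in c(20, 10, 5, 2)) {
    clusters <- lapply(preds, function(pr) {
      formClusters(pr$pred, template(store), pr$prob, minSize = ms)
    })
    met <- computeMetrics(clusters, store)
    if (!is.null(prev)) {
      expect_gte(met$sensitivity, prev$sensitivity)
      expect_lte(met$specificity, prev$specificity)
    }
    expect_gte(met$sensitivityPlus, met$sensitivity)
    prev <- met
  }
})

test_that("a deterministic predictor attains the minimal permutation p", {
  set.seed(3)
  n <- 40
  tab <- data.frame(detected = rep(c(TRUE, FALSE), each = n / 2),
                    x = rep(c(1, 0), each = n / 2) +
                      rnorm(n, sd = 0.01),
                    z = rnorm(n))
  res <- suppressWarnings(
    detectionFactorRegression(tab, c("x", "z"), nPerm = 99, seed = 1))
  expect_equal(res$pPerm[res$factor == "x"], 1 / (1 + 99))
})

test_that("IRLS coefficients match a direct likelihood maximization", {
  tab <- data.frame(detected = c(1, 0, 1, 1, 0, 0),
                    a = c(0.2, -1.1, 0.9, -0.4, 0.3, -1.5),
                    b = c(1, 0, 1, 0, 1, 0))
  res <- detectionFactorRegression(tab, c("a", "b"), nPerm = 9, seed = 1)
  X <- cbind(1, tab$a, tab$b)
  nll <- function(beta) {
    eta <- X %*% beta
    -sum(tab$detected * eta - log(1 + exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(res$beta, opt$par[2:3], tolerance = 1e-5)
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(12)
  rejections <- 0L
  nSim <- 60
  for (s in seq_len(nSim)) {
    tab <- data.frame(detected = rbinom(40, 1, 0.5), x = rnorm(40))
    res <- suppressWarnings(
      detectionFactorRegression(tab, "x", nPerm = 79, seed = s))
    rejections <- rejections + (res$pPerm < 0.05)
  }
  expect_lte(rejections / nSim, 0.12)
})
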