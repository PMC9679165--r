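# Training orchestration: class-balanced per-epoch vertex sampling,
# per-fold training with early stopping, the fold x initialization
# ensemble, Dice-optimal decision threshold, and ensemble prediction.

#' Training configuration
#'
#' Per-patient per-epoch sampling is 2000 lesional and 2000 non-lesional
#' vertices (lesional vertices are drawn with replacement only when the
#' mask is smaller than the request); controls contribute 2000
#' non-lesional vertices each. The non-lesional pool always excludes the
#' 0-40 mm border-zone exclusion set.
#'
#' @param nLesional,nNonlesional per-patient draws per epoch.
#' @param gamma,alpha focal-loss parameters (see [focalLoss()]).
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param patience early-stopping patience on validation loss.
#' @param includeControls controls as non-lesional examples.
#' @return config list of class "TrainingConfig".
#' @export
trainingConfig <- function(nLesional = 2000, nNonlesional = 2000,
                           gamma = 2, alpha = 0.5, epochs = 100,
                           lr = 1e-3, batchSize = 1000, patience = 10,
                           includeControls = TRUE) {
  stopifnot(nLesional > 0, nNonlesional > 0, gamma >= 0,
            alpha > 0, alpha <= 1, epochs >= 1)
  cfg <- list(nLesional = as.integer(nLesional),
              nNonlesional = as.integer(nNonlesional),
              gamma = gamma, alpha = alpha, epochs = as.integer(epochs),
              lr = lr, batchSize = as.integer(batchSize),
              patience = as.integer(patience),
              includeControls = includeControls)
  class(cfg) <- "TrainingConfig"
  cfg
}

#' Per-subject training matrices
#'
#' Assembles, for each listed subject, the stacked (lh then rh) 33-column
#' input matrix plus label, exclusion and cortex masks. Labels are the
#' lesion mask; the exclusion mask is the 0-40 mm border-zone set.
#'
#' @param store a [CohortFeatureStore-class] after normalization.
#' @param ids subject ids (default: all).
#' @return named list of per-subject lists (x, label, exclusion, cortex,
#'   group).
#' @export
prepareSubjectData <- function(store, ids = subjectIds(store)) {
  cortex <- rep(cortexMask(store@template), 2L)
  nv <- nVertices(store@template)
  out <- lapply(ids, function(sid) {
    x <- rbind(assembleClassifierInput(store, sid, "lh"),
               assembleClassifierInput(store, sid, "rh"))
    lab <- excl <- rep(FALSE, 2L * nv)
    ann <- store@lesions[[sid]]
    if (!is.null(ann)) {
      off <- if (ann@hemi == "lh") 0L else nv
      lab[off + which(ann@mask)] <- TRUE
      excl[off + which(ann@exclusion)] <- TRUE
    }
    grp <- store@subjects$group[match(sid, store@subjects$subject_id)]
    list(x = x, label = lab, exclusion = excl, cortex = cortex,
         group = grp)
  })
  names(out) <- ids
  out
}

#' Sample training vertices for one subject
#'
#' Patients yield `nLesional` lesional draws (with replacement iff the
#' mask is smaller than the request) and `nNonlesional` non-lesional
#' draws from the pool outside the 0-40 mm exclusion set; controls yield
#' `nNonlesional` non-lesional draws.
#'
#' @param subjectData one element of [prepareSubjectData()].
#' @param config a [trainingConfig()].
#' @return list with integer `lesional` and `nonlesional` row indices.
#' @export
sampleTrainingVertices <- function(subjectData, config) {
  nonPool <- which(!subjectData$label & !subjectData$exclusion &
                     subjectData$cortex)
  drawFrom <- function(pool, k) {
    if (length(pool) == 0L) stop("empty sampling pool")
    pool[sample.int(length(pool), k, replace = length(pool) < k)]
  }
  if (subjectData$group == "patient") {
    lesPool <- which(subjectData$label)
    if (length(lesPool) == 0L) stop("patient with an empty lesion mask")
    list(lesional = drawFrom(lesPool, config$nLesional),
         nonlesional = drawFrom(nonPool, config$nNonlesional))
  } else {
    list(lesional = integer(),
         nonlesional = drawFrom(nonPool, config$nNonlesional))
  }
}

#' Train one cross-validation fold
#'
#' Trains a network on the fold's training subjects only, resampling
#' vertices each epoch, with early stopping on the validation-fold focal
#' loss. Deterministic under (foldId, seed). Every epoch the sampled
#' non-lesional indices are audited against the exclusion contract.
#'
#' @param data output of [prepareSubjectData()] for the train cohort.
#' @param folds named fold assignment (from a [CohortSplit-class]).
#' @param foldId validation fold.
#' @param config a [trainingConfig()].
#' @param seed RNG seed.
#' @param spec a [networkSpec()].
#' @return list: `net` (best weights), `valLoss`, `valAUC`, `log`,
#'   `audit` (exclusion-contract counters).
#' @export
trainFold <- function(data, folds, foldId, config = trainingConfig(),
                      seed = 1L, spec = networkSpec()) {
  trainIds <- names(folds)[folds != foldId]
  valIds <- names(folds)[folds == foldId]
  useIds <- if (config$includeControls) trainIds else
    trainIds[vapply(data[trainIds], function(d) d$group == "patient",
                    logical(1))]
  net <- .initNet(spec, .deriveSeed(seed, 1L))
  adam <- .adamInit(net)
  # validation pool: cortex vertices outside the border rings; the mask
  # itself stays in (it carries the positive labels)
  valKeep <- lapply(data[valIds], function(d) {
    (d$cortex & !d$exclusion) | d$label
  })
  valX <- do.call(rbind, Map(function(d, k) d$x[k, , drop = FALSE],
                             data[valIds], valKeep))
  valY <- unlist(Map(function(d, k) d$label[k], data[valIds], valKeep),
                 use.names = FALSE)
  best <- list(loss = Inf, net = net, epoch = 0L)
  log <- NULL
  auditChecked <- 0L
  auditViolations <- 0L
  for (epoch in seq_len(config$epochs)) {
    set.seed(.deriveSeed(seed, 1000L + epoch))
    parts <- lapply(useIds, function(sid) {
      s <- sampleTrainingVertices(data[[sid]], config)
      idx <- c(s$lesional, s$nonlesional)
      auditChecked <<- auditChecked + length(s$nonlesional)
      auditViolations <<- auditViolations +
        sum(data[[sid]]$exclusion[s$nonlesional])
      list(x = data[[sid]]$x[idx, , drop = FALSE],
           y = rep(c(1L, 0L), c(length(s$lesional),
                                length(s$nonlesional))))
    })
    Xall <- do.call(rbind, lapply(parts, `[[`, "x"))
    yall <- unlist(lapply(parts, `[[`, "y"), use.names = FALSE)
    ord <- sample.int(nrow(Xall))
    Xall <- Xall[ord, , drop = FALSE]
    yall <- yall[ord]
    nB <- ceiling(nrow(Xall) / config$batchSize)
    epochLoss <- 0
    for (b in seq_len(nB)) {
      sel <- ((b - 1L) * config$batchSize + 1L):min(b * config$batchSize,
                                                    nrow(Xall))
      Xb <- Xall[sel, , drop = FALSE]
      yb <- yall[sel]
      dropMask <- matrix(stats::runif(length(Xb)) >=
                           spec$inputDropout, nrow(Xb), ncol(Xb)) * 1
      bw <- .backward(net, Xb, yb, config$gamma, config$alpha, dropMask)
      if (!is.finite(bw$loss)) {
        stop(sprintf("training diverged (non-finite loss, epoch %d)",
                     epoch))
      }
      st <- .adamStep(net, bw, adam, lr = config$lr)
      net <- st$net
      adam <- st$state
      epochLoss <- epochLoss + bw$loss * length(sel)
    }
    epochLoss <- epochLoss / nrow(Xall)
    vp <- .forward(net, valX)
    vLoss <- focalLoss(vp, valY, config$gamma, config$alpha)
    log <- rbind(log, data.frame(epoch = epoch, trainLoss = epochLoss,
                                 valLoss = vLoss))
    if (vLoss < best$loss) best <- list(loss = vLoss, net = net,
                                        epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  valAUC <- if (any(valY) && !all(valY)) {
    .aucRank(.forward(best$net, valX), valY)
  } else NA_real_
  if (auditViolations > 0L) {
    stop("exclusion-zone vertices leaked into training batches")
  }
  list(net = best$net, valLoss = best$loss, valAUC = valAUC, log = log,
       foldId = foldId, seed = seed,
       audit = c(checked = auditChecked, violations = auditViolations))
}

#' Train the cross-validated ensemble
#'
#' Trains one network per (fold, initialization) cell, combines all
#' members into an ensemble whose prediction is the mean member
#' probability, and sets the decision threshold by Dice on the train
#' cohort. Any failing member aborts the ensemble.
#'
#' @param store a [CohortFeatureStore-class] after normalization.
#' @param split a [CohortSplit-class].
#' @param config a [trainingConfig()].
#' @param nInits random initializations per fold (default 5; 10 folds x
#'   5 gives the full 50-member ensemble).
#' @param seed base RNG seed.
#' @param spec a [networkSpec()].
#' @param data optional precomputed [prepareSubjectData()] for the train
#'   cohort.
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(store, split, config = trainingConfig(),
                          nInits = 5, seed = 1L, spec = networkSpec(),
                          data = NULL) {
  foldIds <- sort(unique(split@folds))
  if (is.null(data)) data <- prepareSubjectData(store, split@trainIds)
  grid <- expand.grid(fold = foldIds, init = seq_len(nInits))
  members <- vector("list", nrow(grid))
  valSummary <- NULL
  for (k in seq_len(nrow(grid))) {
    fit <- trainFold(data, split@folds, grid$fold[k], config,
                     seed = .deriveSeed(seed, grid$fold[k] * 100L +
                                          grid$init[k]),
                     spec = spec)
    members[[k]] <- fit$net
    valSummary <- rbind(valSummary, data.frame(
      fold = grid$fold[k], init = grid$init[k], valLoss = fit$valLoss,
      valAUC = fit$valAUC))
  }
  # Dice-optimal threshold on the train-cohort patients, border zones
  # omitted from the labels
  patIds <- split@trainIds[vapply(data[split@trainIds],
                                  function(d) d$group == "patient",
                                  logical(1))]
  probs <- list(); labs <- list()
  for (sid in patIds) {
    d <- data[[sid]]
    keep <- d$cortex & !d$exclusion | d$label
    p <- rowMeans(vapply(members, function(m) .forward(m, d$x),
                         numeric(nrow(d$x))))
    probs[[sid]] <- p[keep]
    labs[[sid]] <- d$label[keep]
  }
  thr <- optimizeThreshold(unlist(probs, use.names = FALSE),
                           unlist(labs, use.names = FALSE))
  new("EnsembleModel", members = members, networkSpec = spec,
      threshold = thr,
      provenance = list(grid = grid, seed = seed,
                        configHash = .hashConfig(config),
                        config = config, valSummary = valSummary,
                        thresholdData = "train-cohort patients"))
}

#' Dice-optimal decision threshold
#'
#' Scans the grid 0.01, 0.02, ..., 0.99 and returns the threshold
#' maximizing the pooled vertex Dice score `2TP / (2TP + FP + FN)`;
#' ties resolve to the smallest threshold.
#'
#' @param predictions vertex probabilities.
#' @param labels 0/1 lesion labels.
#' @param perSubject optional list-of-vectors form to average Dice per
#'   subject instead of pooling (not the default).
#' @return the optimal threshold.
#' @export
optimizeThreshold <- function(predictions, labels, perSubject = NULL) {
  if (!any(labels == 1)) stop("no positive labels; cannot optimize Dice")
  grid <- seq(0.01, 0.99, by = 0.01)
  dice <- vapply(grid, function(t) {
    pred <- predictions >= t
    tp <- sum(pred & labels == 1)
    2 * tp / (2 * tp + sum(pred & labels == 0) + sum(!pred & labels == 1))
  }, numeric(1))
  grid[which.max(dice)]
}

#' Predict lesional probability for one subject
#'
#' Mean member probability per vertex on both hemispheres (dropout
#' disabled), plus the thresholded boolean field.
#'
#' @param model an [EnsembleModel-class].
#' @param store a [CohortFeatureStore-class] normalized with the
#'   training-time ComBat model and control reference.
#' @param subjectId subject to predict.
#' @return list with `prob` and `pred` (each a \[vertex x hemi\] matrix
#'   with columns lh, rh) and `threshold`.
#' @export
predictSubject <- function(model, store, subjectId) {
  nv <- nVertices(store@template)
  cortex <- cortexMask(store@template)
  prob <- matrix(0, nv, 2, dimnames = list(NULL, c("lh", "rh")))
  for (h in c("lh", "rh")) {
    x <- assembleClassifierInput(store, subjectId, h)
    p <- rowMeans(vapply(model@members, function(m) .forward(m, x),
                         numeric(nv)))
    p[!cortex] <- 0
    prob[, h] <- p
  }
  list(prob = prob, pred = prob >= model@threshold & cortex,
       threshold = model@threshold)
}
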