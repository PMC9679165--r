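# Parametric empirical-Bayes ComBat harmonization of vertex-wise features
# across sites, retaining biological covariates (age, sex, disease
# status), plus frozen-reference harmonization of a previously unseen
# site. The estimator follows the standard location/scale model: per
# (feature, vertex) column, y = alpha + X beta + gamma_site +
# delta_site * eps; site effects are EB-shrunk toward parametric priors
# (normal for locations, inverse-gamma for scales) and removed.

#' @keywords internal
.covDesign <- function(subjects, covariates) {
  cols <- lapply(covariates, function(cv) {
    x <- subjects[[cv]]
    if (is.null(x)) stop("covariate not in demographics: ", cv)
    if (cv == "sex") as.numeric(x == "M")
    else if (cv == "group") as.numeric(x == "patient")
    else if (is.numeric(x)) x
    else stop("unsupported covariate type: ", cv)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

#' @keywords internal
.apriorf <- function(deltaHat) {
  m <- mean(deltaHat); s2 <- stats::var(deltaHat)
  (2 * s2 + m^2) / s2
}

#' @keywords internal
.bpriorf <- function(deltaHat) {
  m <- mean(deltaHat); s2 <- stats::var(deltaHat)
  (m * s2 + m^3) / s2
}

# EB iteration for one batch (vectorized over columns)
#' @keywords internal
.itSol <- function(Zs, gHat, dHat, gBar, t2, a, b, conv = 1e-4) {
  nb <- nrow(Zs)
  gOld <- gHat; dOld <- dHat
  change <- 1
  while (change > conv) {
    gNew <- (nb * t2 * gHat + dOld * gBar) / (nb * t2 + dOld)
    sum2 <- colSums(sweep(Zs, 2, gNew)^2)
    dNew <- (b + 0.5 * sum2) / (nb / 2 + a - 1)
    change <- max(abs(gNew - gOld) / abs(gOld + 1e-12),
                  abs(dNew - dOld) / dOld)
    gOld <- gNew; dOld <- dNew
  }
  list(gammaStar = gOld, deltaStar = dOld)
}

# core fit on a complete data matrix Y (subjects x columns)
#' @keywords internal
.combatFitBlock <- function(Y, batch, Xcov, eb = TRUE) {
  batch <- droplevels(factor(batch))
  nb <- table(batch)
  if (any(nb < 2)) {
    stop("every site needs >= 2 subjects (have: ",
         paste(sprintf("%s=%d", names(nb), nb), collapse = ", "), ")")
  }
  n <- nrow(Y)
  Xb <- stats::model.matrix(~ 0 + batch)
  design <- cbind(Xb, Xcov)
  if (qr(design)$rank < ncol(design)) {
    stop("covariates are collinear with the site indicators")
  }
  B <- solve(crossprod(design), crossprod(design, Y))
  S <- nlevels(batch)
  alpha <- as.numeric(crossprod(as.numeric(nb) / n, B[seq_len(S), , drop = FALSE]))
  betaCov <- B[-seq_len(S), , drop = FALSE]
  resid <- Y - design %*% B
  varPooled <- colMeans(resid^2)
  skip <- varPooled < 1e-12
  varPooled[skip] <- 1
  standMean <- matrix(alpha, n, ncol(Y), byrow = TRUE)
  if (ncol(Xcov)) standMean <- standMean + Xcov %*% betaCov
  Z <- (Y - standMean) / matrix(sqrt(varPooled), n, ncol(Y), byrow = TRUE)
  gammaHat <- deltaHat <- matrix(0, S, ncol(Y))
  for (s in seq_len(S)) {
    Zs <- Z[batch == levels(batch)[s], , drop = FALSE]
    gammaHat[s, ] <- colMeans(Zs)
    deltaHat[s, ] <- .colVars(Zs)
  }
  deltaHat[, skip] <- 1
  priors <- list()
  if (eb && S >= 1) {
    gammaStar <- deltaStar <- matrix(0, S, ncol(Y))
    for (s in seq_len(S)) {
      gBar <- mean(gammaHat[s, !skip]); t2 <- stats::var(gammaHat[s, !skip])
      a <- .apriorf(deltaHat[s, !skip]); b <- .bpriorf(deltaHat[s, !skip])
      Zs <- Z[batch == levels(batch)[s], , drop = FALSE]
      sol <- .itSol(Zs, gammaHat[s, ], deltaHat[s, ], gBar, t2, a, b)
      gammaStar[s, ] <- sol$gammaStar
      deltaStar[s, ] <- sol$deltaStar
      priors[[levels(batch)[s]]] <- list(gammaBar = gBar, tau2 = t2,
                                         aPrior = a, bPrior = b)
    }
  } else {
    gammaStar <- gammaHat
    deltaStar <- deltaHat
  }
  deltaStar[, skip] <- 1
  gammaStar[, skip] <- 0
  harmAdj <- (Z - gammaStar[as.integer(batch), , drop = FALSE]) /
    sqrt(deltaStar[as.integer(batch), , drop = FALSE])
  out <- harmAdj * matrix(sqrt(varPooled), n, ncol(Y), byrow = TRUE) +
    standMean
  out[, skip] <- Y[, skip]
  list(model = list(alpha = alpha, betaCov = betaCov,
                    varPooled = varPooled, gammaStar = gammaStar,
                    deltaStar = deltaStar, priors = priors,
                    batchLevels = levels(batch), skip = skip),
       harmonized = out)
}

#' @keywords internal
.flattenSet <- function(arr, featIdx, subjIdx) {
  x <- arr[, , featIdx, subjIdx, drop = FALSE]
  d <- dim(x)
  t(matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4]))
}

#' @keywords internal
.unflattenInto <- function(arr, Y, featIdx, subjIdx) {
  d <- c(dim(arr)[1:2], length(featIdx), length(subjIdx))
  arr[, , featIdx, subjIdx] <- array(t(Y), dim = d)
  arr
}

#' Fit ComBat harmonization across sites
#'
#' Fits the parametric EB ComBat model per (feature, vertex) column on
#' the "raw" feature set and stores the harmonized values as feature set
#' "combat". T1-derived columns are fit on all subjects; FLAIR-derived
#' columns on FLAIR-available subjects only. With a single site the model
#' is the identity (there is no batch effect to remove).
#'
#' @param store a [CohortFeatureStore-class].
#' @param batchVar demographics column used as batch (default site_id;
#'   set to a site-by-scanner interaction column when both vary).
#' @param covariates biological covariates to retain.
#' @param eb apply empirical-Bayes shrinkage (disable for testing against
#'   the direct location/scale standardization).
#' @return list with `store` (the input store plus a "combat" feature
#'   set) and `model` (a [ComBatModel-class]).
#' @export
fitComBat <- function(store, batchVar = "site_id",
                      covariates = c("age", "sex", "group"), eb = TRUE) {
  subj <- store@subjects
  batch <- subj[[batchVar]]
  if (is.null(batch)) stop("batch variable not in demographics: ", batchVar)
  arr <- featureSet(store, "raw")
  sites <- sort(unique(batch))
  feats <- fcdFeatures()
  t1Idx <- match(t1Features(), feats)
  flairIdx <- match(flairFeatures(), feats)
  out <- arr
  blocks <- list()
  if (length(sites) == 1L) {
    message("single site: ComBat is the identity, no batch effect to remove")
    model <- new("ComBatModel", batchVar = batchVar,
                 covariates = covariates, sites = as.character(sites),
                 blocks = list(), eb = eb)
    store@featureSets[["combat"]] <- arr
    store@provenance <- c(store@provenance, "combat(identity)")
    return(list(store = store, model = model))
  }
  Xcov <- .covDesign(subj, covariates)
  allIdx <- seq_len(nrow(subj))
  fl <- which(subj$flair_available)
  blockDefs <- list(t1 = list(feat = t1Idx, subj = allIdx))
  if (length(fl) >= 2L) {
    blockDefs$flair <- list(feat = flairIdx, subj = fl)
  }
  for (nm in names(blockDefs)) {
    bd <- blockDefs[[nm]]
    Y <- .flattenSet(arr, bd$feat, bd$subj)
    fit <- .combatFitBlock(Y, batch[bd$subj], Xcov[bd$subj, , drop = FALSE],
                           eb = eb)
    out <- .unflattenInto(out, fit$harmonized, bd$feat, bd$subj)
    blocks[[nm]] <- c(fit$model, list(featIdx = bd$feat))
  }
  model <- new("ComBatModel", batchVar = batchVar, covariates = covariates,
               sites = as.character(sites), blocks = blocks, eb = eb)
  store@featureSets[["combat"]] <- out
  store@provenance <- c(store@provenance, sprintf("combat(%s)", batchVar))
  list(store = store, model = model)
}

#' Harmonize a new site against a fitted reference model
#'
#' Reference intercepts, covariate effects and pooled standardization are
#' held frozen; only the new site's location/scale effects are estimated
#' (with EB shrinkage) and removed. Applying the adjustment twice is a
#' fixed point: an already-harmonized site has location ~0 and scale ~1,
#' so the second pass is a no-op up to EB shrinkage noise.
#'
#' @param model a [ComBatModel-class] fit on the reference cohort.
#' @param newStore a [CohortFeatureStore-class] with a "raw" set whose
#'   sites are disjoint from the model's roster.
#' @return `newStore` with a "combat" feature set added.
#' @export
harmonizeNewSite <- function(model, newStore) {
  subj <- newStore@subjects
  batch <- subj[[model@batchVar]]
  overlap <- intersect(unique(batch), model@sites)
  if (length(overlap)) {
    stop("new-site cohort contains reference sites: ",
         paste(overlap, collapse = ", "))
  }
  nb <- table(batch)
  if (any(nb < 2)) stop("new site needs >= 2 subjects for a scale estimate")
  arr <- featureSet(newStore, "raw")
  out <- arr
  Xcov <- .covDesign(subj, model@covariates)
  fl <- which(subj$flair_available)
  for (nm in names(model@blocks)) {
    blk <- model@blocks[[nm]]
    sIdx <- if (nm == "flair") fl else seq_len(nrow(subj))
    if (length(sIdx) < 2L) next
    Y <- .flattenSet(arr, blk$featIdx, sIdx)
    n <- nrow(Y)
    standMean <- matrix(blk$alpha, n, ncol(Y), byrow = TRUE)
    if (ncol(Xcov)) {
      standMean <- standMean + Xcov[sIdx, , drop = FALSE] %*% blk$betaCov
    }
    Z <- (Y - standMean) / matrix(sqrt(blk$varPooled), n, ncol(Y),
                                  byrow = TRUE)
    bfac <- droplevels(factor(batch[sIdx]))
    gammaStar <- deltaStar <- matrix(0, nlevels(bfac), ncol(Y))
    for (s in seq_len(nlevels(bfac))) {
      Zs <- Z[bfac == levels(bfac)[s], , drop = FALSE]
      gHat <- colMeans(Zs)
      dHat <- .colVars(Zs)
      dHat[blk$skip] <- 1
      if (model@eb) {
        ok <- !blk$skip
        gBar <- mean(gHat[ok]); t2 <- stats::var(gHat[ok])
        a <- .apriorf(dHat[ok]); b <- .bpriorf(dHat[ok])
        sol <- .itSol(Zs, gHat, dHat, gBar, t2, a, b)
        gammaStar[s, ] <- sol$gammaStar
        deltaStar[s, ] <- sol$deltaStar
      } else {
        gammaStar[s, ] <- gHat
        deltaStar[s, ] <- dHat
      }
    }
    deltaStar[, blk$skip] <- 1
    gammaStar[, blk$skip] <- 0
    adj <- (Z - gammaStar[as.integer(bfac), , drop = FALSE]) /
      sqrt(deltaStar[as.integer(bfac), , drop = FALSE])
    Yh <- adj * matrix(sqrt(blk$varPooled), n, ncol(Y), byrow = TRUE) +
      standMean
    Yh[, blk$skip] <- Y[, blk$skip]
    out <- .unflattenInto(out, Yh, blk$featIdx, sIdx)
  }
  newStore@featureSets[["combat"]] <- out
  newStore@provenance <- c(newStore@provenance, "combat(new-site)")
  newStore
}
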