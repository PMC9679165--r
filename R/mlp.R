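# Multilayer perceptron for vertex-wise lesion probability, written on
# base matrix operations: 33 inputs -> 40 -> 10 -> 1 logistic output,
# dropout 0.4 on the input layer, focal loss, Adam updates. Gradients
# (both for the weights and with respect to the input, as needed by
# integrated gradients) come from explicit backpropagation.

#' Default network architecture
#'
#' @param inputDim input features (default 33).
#' @param hidden hidden layer widths (default c(40, 10)).
#' @param inputDropout dropout rate on the input layer (default 0.4).
#' @return list describing the architecture.
#' @export
networkSpec <- function(inputDim = 33, hidden = c(40, 10),
                        inputDropout = 0.4) {
  list(inputDim = inputDim, hidden = hidden, inputDropout = inputDropout)
}

#' @keywords internal
.initNet <- function(spec, seed) {
  set.seed(seed)
  dims <- c(spec$inputDim, spec$hidden, 1L)
  net <- list(spec = spec, W = list(), b = list())
  for (l in seq_len(length(dims) - 1L)) {
    # He initialization for the rectifier layers
    net$W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                      sd = sqrt(2 / dims[l])),
                         dims[l], dims[l + 1L])
    net$b[[l]] <- rep(0, dims[l + 1L])
  }
  net
}

# forward pass; returns probabilities and, when keepCache, the
# activations needed for backprop. dropMask (0/1 matrix over inputs) is
# supplied during training only; inference runs with dropout disabled.
#' @keywords internal
.forward <- function(net, X, dropMask = NULL, keepCache = FALSE) {
  L <- length(net$W)
  A <- if (is.null(dropMask)) X else X * dropMask / (1 - net$spec$inputDropout)
  cache <- list(A)
  for (l in seq_len(L - 1L)) {
    Z <- A %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    A <- Z * (Z > 0)
    if (keepCache) cache[[l + 1L]] <- A
  }
  z <- as.numeric(A %*% net$W[[L]]) + net$b[[L]]
  p <- 1 / (1 + exp(-z))
  if (keepCache) list(p = p, cache = cache, hiddenLast = A) else p
}

#' Focal loss
#'
#' `FL(p_t) = -alpha * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = p` for positive labels and `1 - p` otherwise, mean-reduced.
#' Down-weights easy examples so training concentrates on hard ones;
#' `gamma = 0`, `alpha = 1` recovers binary cross-entropy. Probabilities
#' are clipped to \[1e-7, 1 - 1e-7\].
#'
#' @param p predicted probabilities in (0, 1).
#' @param y 0/1 labels.
#' @param gamma focusing exponent (>= 0, default 2).
#' @param alpha constant loss weight in (0, 1\] (default 0.5).
#' @param reduce mean-reduce over the batch (default) or return
#'   per-example losses.
#' @return scalar mean loss (or per-example vector).
#' @export
focalLoss <- function(p, y, gamma = 2, alpha = 0.5, reduce = TRUE) {
  stopifnot(gamma >= 0, alpha > 0, alpha <= 1)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, p, 1 - p)
  l <- -alpha * (1 - pt)^gamma * log(pt)
  if (reduce) mean(l) else l
}

# d(mean focal loss)/dp, vectorized
#' @keywords internal
.focalLossGradP <- function(p, y, gamma, alpha) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, p, 1 - p)
  dLdpt <- alpha * gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
    alpha * (1 - pt)^gamma / pt
  if (gamma == 0) dLdpt <- -alpha / pt
  dLdpt * ifelse(y == 1, 1, -1) / length(p)
}

# one forward+backward pass; returns loss, weight gradients
#' @keywords internal
.backward <- function(net, X, y, gamma, alpha, dropMask = NULL) {
  fw <- .forward(net, X, dropMask, keepCache = TRUE)
  p <- fw$p
  loss <- focalLoss(p, y, gamma, alpha)
  L <- length(net$W)
  dLdp <- .focalLossGradP(p, y, gamma, alpha)
  delta <- matrix(dLdp * p * (1 - p), ncol = 1L)  # d loss / d logit
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    A <- fw$cache[[l]]
    gW[[l]] <- crossprod(A, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (fw$cache[[l]] > 0)
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

# gradient of the output (probability, or raw logit) with respect to the
# input, one row per input row (dropout disabled); used by integrated
# gradients
#' @keywords internal
.inputGradient <- function(net, X, output = "prob") {
  fw <- .forward(net, X, keepCache = TRUE)
  L <- length(net$W)
  delta <- if (output == "logit") matrix(1, length(fw$p), 1L) else
    matrix(fw$p * (1 - fw$p), ncol = 1L)  # d p / d logit
  for (l in rev(seq_len(L))) {
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (fw$cache[[l]] > 0)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  delta
}

#' @keywords internal
.adamInit <- function(net) {
  list(m = lapply(c(net$W, net$b), function(w) w * 0),
       v = lapply(c(net$W, net$b), function(w) w * 0), t = 0L)
}

#' @keywords internal
.adamStep <- function(net, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  L <- length(net$W)
  state$t <- state$t + 1L
  params <- c(net$W, net$b)
  gs <- c(grads$gW, grads$gb)
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gs[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gs[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  net$W <- params[seq_len(L)]
  net$b <- params[L + seq_len(L)]
  list(net = net, state = state)
}
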