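# Internal helpers shared across modules.

#' @keywords internal
.deriveSeed <- function(seed, k) {
  # distinct, reproducible sub-streams; keep within 32-bit integer range
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483629L)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form of the AUC; ties handled by midranks.
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @return AUC in \[0, 1\].
#' @keywords internal
.aucRank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
.colVars <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 rows for a variance")
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

# quantile-style median (IQR) summary used in cohort metrics tables
#' @keywords internal
.medIqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

#' @keywords internal
.hashConfig <- function(x) {
  # stable provenance hash without external digest packages
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 4294967291)
}
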