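# Synthetic bilaterally symmetric template: two mirrored icospheres with
# identity vertex correspondence and a polar cap standing in for the
# medial wall. Stand-in for a symmetric average cortical surface.

#' @keywords internal
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = tr)
}

# midpoint 4-fold subdivision with shared-edge vertex reuse; result is
# re-projected to the unit sphere
#' @keywords internal
.subdivide <- function(vertices, triangles) {
  n <- nrow(vertices)
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mids <- new.env(parent = emptyenv())
  newV <- list()
  midpoint <- function(a, b) {
    k <- edgeKey(a, b)
    if (!is.null(mids[[k]])) return(mids[[k]])
    m <- (vertices[a, ] + vertices[b, ]) / 2
    newV[[length(newV) + 1L]] <<- m
    idx <- n + length(newV)
    mids[[k]] <- idx
    idx
  }
  newT <- matrix(0L, nrow(triangles) * 4L, 3L)
  for (t in seq_len(nrow(triangles))) {
    a <- triangles[t, 1]; b <- triangles[t, 2]; c <- triangles[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newT[4L * t - 3L, ] <- c(a, ab, ca)
    newT[4L * t - 2L, ] <- c(b, bc, ab)
    newT[4L * t - 1L, ] <- c(c, ca, bc)
    newT[4L * t, ] <- c(ab, bc, ca)
  }
  v <- rbind(vertices, do.call(rbind, newV))
  v <- v / sqrt(rowSums(v^2))
  list(vertices = v, triangles = newT)
}

#' Build the synthetic symmetric template
#'
#' Two mirrored icospheres (`10 * 4^level + 2` vertices each) with
#' identical connectivity and exact mirror coordinates across the `x = 0`
#' plane. A polar cap (`z > capFraction * radius` above the sphere centre)
#' is marked non-cortex as a medial-wall stand-in.
#'
#' @param level number of 4-fold subdivisions (>= 1); level 3 gives 642
#'   vertices per hemisphere, level 4 gives 2562.
#' @param radius sphere radius in mm (default 65, the scale of an adult
#'   hemisphere).
#' @param centerOffset distance of each sphere centre from the midline
#'   along x (mm).
#' @param capFraction fraction of the radius above which vertices are
#'   marked non-cortex.
#' @return a [SymmetricTemplate-class].
#' @examples
#' tpl <- makeTemplate(1)
#' nVertices(tpl) # 42
#' @export
makeTemplate <- function(level, radius = 65, centerOffset = 70,
                         capFraction = 0.9) {
  stopifnot(level >= 1)
  ico <- .icosahedron()
  for (k in seq_len(level)) ico <- .subdivide(ico$vertices, ico$triangles)
  v <- ico$vertices * radius
  cortex <- v[, 3] < capFraction * radius
  leftV <- cbind(v[, 1] - centerOffset, v[, 2], v[, 3])
  rightV <- cbind(-leftV[, 1], leftV[, 2], leftV[, 3])
  tr <- ico$triangles
  # mirroring flips orientation; swap two indices to keep windings consistent
  trR <- tr[, c(1, 3, 2)]
  new("SymmetricTemplate",
      left = SurfaceMesh(leftV, tr, cortex),
      right = SurfaceMesh(rightV, trR, cortex))
}
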