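# Independent oracles: textbook implementations used only to check the
# package's geometry primitives. They share no code with the package
# internals (no igraph, no sparse matrices).

# brute-force edge enumeration from the triangle list
bruteEdgesOracle <- function(mesh) {
  tr <- mesh@triangles
  n <- nVertices(mesh)
  adj <- vector("list", n)
  for (t in seq_len(nrow(tr))) {
    for (pair in list(c(1, 2), c(2, 3), c(1, 3))) {
      a <- tr[t, pair[1]]; b <- tr[t, pair[2]]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  lapply(adj, function(v) sort(as.integer(v)))
}

# O(V^2) single-source-set Dijkstra on the cortex subgraph
dijkstraOracle <- function(mesh, seeds) {
  n <- nVertices(mesh)
  e <- meshEdges(mesh)
  keep <- mesh@cortexMask[e$i] & mesh@cortexMask[e$j]
  e <- e[keep, , drop = FALSE]
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- rbind(adj[[e$i[r]]], c(e$j[r], e$length[r]))
    adj[[e$j[r]]] <- rbind(adj[[e$j[r]]], c(e$i[r], e$length[r]))
  }
  dist <- rep(Inf, n)
  dist[seeds] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (dist[u] + nb[r, 2] < dist[v]) dist[v] <- dist[u] + nb[r, 2]
      }
    }
  }
  dist[!mesh@cortexMask] <- NA_real_
  dist
}

# iterative flood fill; labels numbered by smallest contained vertex
floodFillOracle <- function(mesh, flag) {
  adj <- bruteEdgesOracle(mesh)
  labels <- rep(NA_integer_, length(flag))
  nextLab <- 0L
  for (v0 in seq_along(flag)) {
    if (!flag[v0] || !is.na(labels[v0])) next
    nextLab <- nextLab + 1L
    stack <- v0
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(labels[v])) next
      labels[v] <- nextLab
      nb <- adj[[v]]
      stack <- c(stack, nb[flag[nb] & is.na(labels[nb])])
    }
  }
  sizes <- if (nextLab) as.integer(table(labels)) else integer()
  list(labels = labels, sizes = sizes)
}

# jittered icosphere: random-looking mesh with icosphere connectivity
jitteredMesh <- function(level, seed, jitter = 0.15, radius = 20) {
  tpl <- makeTemplate(level, radius = radius, centerOffset = 0)
  m <- tpl@left
  set.seed(seed)
  v <- m@vertices * (1 + matrix(stats::runif(length(m@vertices),
                                             -jitter, jitter),
                                ncol = 3))
  SurfaceMesh(v, m@triangles, m@cortexMask)
}

# a 2 x k triangulated strip with unit horizontal spacing; distances
# along the bottom row are hand-checkable
stripMesh <- function(k = 5) {
  v <- rbind(cbind(0:(k - 1), 0, 0), cbind(0:(k - 1), 1, 0))
  tr <- NULL
  for (i in seq_len(k - 1)) {
    tr <- rbind(tr, c(i, i + 1, k + i), c(i + 1, k + i + 1, k + i))
  }
  SurfaceMesh(v, tr)
}
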