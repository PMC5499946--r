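# Independent brute-force oracles used to validate the package's
# topology and extraction code paths. These deliberately avoid igraph:
# distances come from Floyd-Warshall, path counts from a dynamic program
# over nodes ordered by distance.

# quick cell_graph from an edge matrix/data.frame (ids 1..n)
cg <- function(edges, n = NULL, areas = NULL, types = NULL) {
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("from", "to")
  if (is.null(areas)) areas <- rep(1, nrow(edges))
  edges$area_um2 <- areas
  if (is.null(n)) n <- max(edges$from, edges$to)
  nodes <- data.frame(cell_id = seq_len(n))
  if (!is.null(types)) nodes$cell_type <- types
  cell_graph(nodes, edges)
}

# all-pairs shortest-path distances and path counts
bf_paths <- function(n, edges, w, tol = 1e-9) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    D[a, b] <- min(D[a, b], w[k])
    D[b, a] <- D[a, b]
  }
  W <- D  # direct edge lengths
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    S[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(is.finite(W[, v]) &
                      abs(D[s, ] + W[, v] - D[s, v]) < tol)
      S[s, v] <- sum(S[s, pred])
    }
  }
  list(D = D, S = S, W = W)
}

# raw (unnormalized) node and edge betweenness over unordered pairs,
# accumulated per node/edge with whole (s, t)-matrix operations
bf_betweenness <- function(graph, weighted = FALSE, tol = 1e-9) {
  n <- nrow(graph$nodes)
  id <- setNames(seq_len(n), graph$nodes$cell_id)
  edges <- data.frame(from = unname(id[as.character(graph$edges$from)]),
                      to = unname(id[as.character(graph$edges$to)]))
  w <- if (weighted) 1 / graph$edges$area_um2 else rep(1, nrow(edges))
  bp <- bf_paths(n, edges, w, tol)
  D <- bp$D; S <- bp$S
  upper <- upper.tri(D)
  ok <- upper & is.finite(D) & S > 0

  node <- numeric(n)
  for (v in seq_len(n)) {
    on <- abs(outer(D[, v], D[v, ], "+") - D) < tol
    contrib <- outer(S[, v], S[v, ]) / ifelse(S > 0, S, 1)
    contrib[!on | !ok] <- 0
    contrib[v, ] <- 0; contrib[, v] <- 0
    node[v] <- sum(contrib)
  }
  edge <- numeric(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    sh <- (abs(outer(D[, a], D[b, ], "+") + w[k] - D) < tol) *
      outer(S[, a], S[b, ]) +
      (abs(outer(D[, b], D[a, ], "+") + w[k] - D) < tol) *
      outer(S[, b], S[a, ])
    sh <- sh / ifelse(S > 0, S, 1)
    sh[!ok] <- 0
    edge[k] <- sum(sh)
  }
  list(node = node, edge = edge)
}

# random connected graph with n nodes (random spanning tree + extras)
random_connected_graph <- function(n, extra = n %/% 2, areas = FALSE) {
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    from <- c(from, u); to <- c(to, v)
  }
  tries <- 0
  while (extra > 0 && tries < 20 * extra) {
    tries <- tries + 1
    a <- sample(n, 1); b <- sample(n, 1)
    if (a == b) next
    key <- paste(pmin(from, to), pmax(from, to))
    if (paste(min(a, b), max(a, b)) %in% key) next
    from <- c(from, min(a, b)); to <- c(to, max(a, b))
    extra <- extra - 1
  }
  ar <- if (areas) exp(runif(length(from), -1, 3)) else rep(1, length(from))
  cg(data.frame(from = from, to = to), n = n, areas = ar)
}

# naive O(voxels x 6) face-scan region adjacency oracle
bf_face_scan <- function(labels, voxel_um, excluded = 0L) {
  dims <- dim(labels)
  fa <- c(voxel_um[2] * voxel_um[3], voxel_um[1] * voxel_um[3],
          voxel_um[1] * voxel_um[2])
  acc <- new.env(parent = emptyenv())
  step <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[3])) {
      a <- labels[z, y, x]
      if (a %in% excluded) next
      for (ax in 1:3) {
        p <- c(z, y, x) + step[[ax]]
        if (p[1] > dims[1] || p[2] > dims[2] || p[3] > dims[3]) next
        b <- labels[p[1], p[2], p[3]]
        if (b %in% excluded || a == b) next
        key <- paste(min(a, b), max(a, b))
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + fa[ax]
      }
    }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(from = integer(0), to = integer(0),
                      area_um2 = numeric(0)))
  parts <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(from = as.integer(parts[, 1]),
                    to = as.integer(parts[, 2]),
                    area_um2 = vapply(keys, function(k) acc[[k]], 0))
  out[order(out$from, out$to), ]
}

# random small labeled array (blocky regions, possibly with background)
random_labeled_array <- function(max_voxels = 1000) {
  repeat {
    d <- c(sample(2:10, 1), sample(2:10, 1), sample(2:10, 1))
    if (prod(d) <= max_voxels) break
  }
  nlab <- sample(2:6, 1)
  labs <- array(sample(0:nlab, prod(d), replace = TRUE,
                       prob = c(0.2, rep(0.8 / nlab, nlab))), dim = d)
  # ensure at least two labels present
  labs[1] <- 1L; labs[length(labs)] <- 2L
  labs
}

toy_graph_path <- function(n) cg(data.frame(from = 1:(n - 1), to = 2:n))
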