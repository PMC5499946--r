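#' Per-cell and per-interface topological measures
#'
#' Computes the network measures of a cellular connectivity graph with
#' pair-count normalizations so values are comparable across organs of
#' different size:
#' \itemize{
#'   \item `degree`: incident interface count per cell.
#'   \item `bc`: node betweenness centrality over unweighted shortest
#'     paths (fractional counting over tied paths), normalized by
#'     `2/((N-1)(N-2))` where `N` is the node count, so the center of a
#'     star is 1.
#'   \item `wbc`: betweenness over paths minimizing total edge length
#'     where an edge's length is the reciprocal of its interface area —
#'     large walls make short steps — with the same node normalization.
#'   \item `ebc`: edge betweenness normalized by `2/(N(N-1))`.
#' }
#' All centralities are computed on the full graph including buffer
#' cells; use [report_central()] to restrict reported rows.
#'
#' @param graph a [cell_graph()]
#' @param measures character vector among
#'   `c("degree", "bc", "wbc", "ebc")`
#' @return list with `nodes` (cell_id, cell_type, buffer, requested node
#'   measures, `log10_bc` where `bc` was requested) and `edges` (from,
#'   to, area_um2, `ebc` if requested) data.frames
#' @export
measure_topology <- function(graph,
                             measures = c("degree", "bc", "wbc", "ebc")) {
  stopifnot(inherits(graph, "cell_graph"))
  measures <- match.arg(measures, c("degree", "bc", "wbc", "ebc"),
                        several.ok = TRUE)
  ig <- as_igraph(graph)
  N <- igraph::vcount(ig)
  nodes <- graph$nodes[c("cell_id", "cell_type", "buffer")]
  edges <- graph$edges
  if (!igraph::is_connected(ig) && any(c("bc", "wbc", "ebc") %in% measures))
    warning("graph is disconnected; betweenness computed per component, ",
            "normalized with whole-graph N = ", N)
  if ("degree" %in% measures)
    nodes$degree <- as.integer(igraph::degree(ig))
  if ("bc" %in% measures) {
    nodes$bc <- node_betweenness(graph)
    nodes$log10_bc <- ifelse(nodes$bc > 0, log10(nodes$bc), NA_real_)
  }
  if ("wbc" %in% measures)
    nodes$wbc <- weighted_node_betweenness(graph)
  if ("ebc" %in% measures)
    edges$ebc <- edge_betweenness(graph)
  list(nodes = nodes, edges = edges)
}

#' Normalized node betweenness centrality
#'
#' Counts, for every unordered pair of other cells, the fraction of tied
#' shortest paths (by hop count) running through a cell, and normalizes
#' the sum by `2/((N-1)(N-2))`.
#'
#' @param graph a [cell_graph()] with at least 3 cells
#' @return numeric vector of normalized betweenness in `[0, 1]`, in node
#'   table order
#' @export
node_betweenness <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  N <- n_cells(graph)
  if (N < 3) stop("node betweenness normalization needs N >= 3")
  ig <- as_igraph(graph)
  unname(igraph::betweenness(ig, directed = FALSE, weights = NA)) *
    2 / ((N - 1) * (N - 2))
}

#' Normalized weighted node betweenness centrality
#'
#' As [node_betweenness()], but shortest paths minimize the summed
#' reciprocal interface area (`1/area_um2`), so routes through large
#' cell-cell interfaces are preferred.
#'
#' @param graph a [cell_graph()] with positive interface areas
#' @return numeric vector in node table order
#' @export
weighted_node_betweenness <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  N <- n_cells(graph)
  if (N < 3) stop("node betweenness normalization needs N >= 3")
  if (any(graph$edges$area_um2 <= 0)) stop("edge areas must be > 0")
  ig <- as_igraph(graph)
  unname(igraph::betweenness(ig, directed = FALSE,
                             weights = 1 / graph$edges$area_um2)) *
    2 / ((N - 1) * (N - 2))
}

#' Normalized edge betweenness centrality
#'
#' Shortest-path betweenness of each interface over unordered cell pairs,
#' normalized by `2/(N(N-1))`; a bridge carrying all traffic of a
#' two-cell network scores 1.
#'
#' @param graph a [cell_graph()] with at least 2 cells
#' @return numeric vector in edge table order
#' @export
edge_betweenness <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  N <- n_cells(graph)
  if (N < 2) stop("edge betweenness needs N >= 2")
  ig <- as_igraph(graph)
  unname(igraph::edge_betweenness(ig, directed = FALSE, weights = NA)) *
    2 / (N * (N - 1))
}

#' Current-flow (random-walk) edge betweenness
#'
#' The expected net current through each interface when a unit current is
#' injected and withdrawn at every unordered cell pair, computed from the
#' Moore-Penrose pseudoinverse of the graph Laplacian with unit
#' conductances, and normalized by `2/(N(N-1))`. On trees it equals the
#' shortest-path edge betweenness (all flow follows the unique path).
#' Disconnected graphs are handled per component (with a warning),
#' keeping the whole-graph `N` in the normalization.
#'
#' @param graph a [cell_graph()]
#' @return numeric vector in edge table order
#' @export
current_flow_edge_betweenness <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  N <- n_cells(graph)
  if (N < 2) stop("current-flow betweenness needs N >= 2")
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)
  if (comp$no > 1)
    warning("graph is disconnected; current flow computed per component")
  ids <- graph$nodes$cell_id
  idx <- setNames(seq_along(ids), ids)
  out <- numeric(nrow(graph$edges))
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    n <- length(vs)
    if (n < 2) next
    esel <- which(idx[as.character(graph$edges$from)] %in% vs)
    if (!length(esel)) next
    # Laplacian pseudoinverse of the component
    sub <- match(seq_along(ids), vs)         # global -> local
    A <- matrix(0, n, n)
    ef <- sub[idx[as.character(graph$edges$from[esel])]]
    et <- sub[idx[as.character(graph$edges$to[esel])]]
    for (k in seq_along(esel)) {
      A[ef[k], et[k]] <- A[ef[k], et[k]] + 1
      A[et[k], ef[k]] <- A[et[k], ef[k]] + 1
    }
    L <- diag(rowSums(A)) - A
    Linv <- MASS::ginv(L)
    for (k in seq_along(esel)) {
      # potential difference profile of edge (u,v) across all sources:
      # F_x = Linv[u,x] - Linv[v,x]; summed |F_s - F_t| over pairs s<t
      Fv <- Linv[ef[k], ] - Linv[et[k], ]
      Fs <- sort(Fv)
      i <- seq_len(n)
      out[esel[k]] <- sum((2 * i - n - 1) * Fs)
    }
  }
  out * 2 / (N * (N - 1))
}

#' Log10-transform betweenness values
#'
#' Betweenness distributions are heavily right-skewed; mean and standard
#' deviation summaries use `log10(bc)`. Cells with `bc = 0` have no
#' defined logarithm and are excluded from the transformed set.
#'
#' @param bc nonnegative numeric vector
#' @return list with `values` (log10 of the positive entries) and
#'   `n_excluded` (count of zeros dropped)
#' @export
log10_transform <- function(bc) {
  if (any(bc < 0)) stop("betweenness values must be >= 0")
  list(values = log10(bc[bc > 0]), n_excluded = sum(bc == 0))
}

#' Restrict a measure table to reportable central cells
#'
#' Drops buffered (boundary-adjacent) rows and vascular rows from
#' reported statistics. Vascular cells participate in every centrality
#' computation but their per-cell values are not reported, as their
#' segmentation is unreliable in practice. Values of retained rows are
#' untouched.
#'
#' @param table the `nodes` data.frame of [measure_topology()] (or any
#'   data.frame with `buffer` and `cell_type` columns)
#' @param drop_vasculature exclude vasculature rows (default TRUE)
#' @return the filtered data.frame
#' @export
report_central <- function(table, drop_vasculature = TRUE) {
  stopifnot(is.data.frame(table))
  keep <- !table$buffer
  if (drop_vasculature) keep <- keep & table$cell_type != "vasculature"
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all cells are buffered or excluded")
  rownames(out) <- NULL
  out
}
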