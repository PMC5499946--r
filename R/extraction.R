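#' Extract the cell-adjacency graph of a labeled volume
#'
#' Scans the segmentation for voxel faces shared by two different labels
#' (6-connectivity; diagonal contacts are not physical walls) and sums the
#' physical face areas into per-pair interface areas. Faces against
#' background or excluded labels contribute to a cell's exterior surface,
#' not to edges.
#'
#' @param volume a [labeled_volume()]
#' @param annotation optional data.frame with `cell_id`, `cell_type` and
#'   optionally `boundary` columns used to annotate the nodes
#' @return a [cell_graph()]; node `area_um2` is the cell's total surface
#'   (interfaces plus exterior), `volume_um3` its voxel volume
#' @export
extract_adjacency <- function(volume, annotation = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  labs <- volume$labels
  vx <- volume$voxel_um
  if (any(vx <= 0)) stop("voxel dimensions must be positive")
  ids <- setdiff(sort(unique(as.vector(labs))), volume$excluded_labels)
  if (length(ids) < 2)
    stop("need at least 2 non-excluded labels, got ", length(ids))

  excl <- volume$excluded_labels
  face_area <- c(vx[2] * vx[3], vx[1] * vx[3], vx[1] * vx[2]) # z,y,x steps
  acc_a <- list(); acc_b <- list(); acc_w <- list(); k <- 0L
  for (ax in 1:3) {
    n <- dim(labs)[ax]
    if (n < 2) next
    idx1 <- switch(ax,
      list(1:(n - 1), TRUE, TRUE), list(TRUE, 1:(n - 1), TRUE),
      list(TRUE, TRUE, 1:(n - 1)))
    idx2 <- switch(ax,
      list(2:n, TRUE, TRUE), list(TRUE, 2:n, TRUE), list(TRUE, TRUE, 2:n))
    a <- do.call(`[`, c(list(labs), idx1))
    b <- do.call(`[`, c(list(labs), idx2))
    sel <- a != b & !(a %in% excl) & !(b %in% excl)
    if (!any(sel)) next
    k <- k + 1L
    acc_a[[k]] <- pmin(a[sel], b[sel])
    acc_b[[k]] <- pmax(a[sel], b[sel])
    acc_w[[k]] <- rep(face_area[ax], sum(sel))
  }
  if (k == 0L)
    edges <- data.frame(from = integer(), to = integer(),
                        area_um2 = numeric())
  else {
    a <- unlist(acc_a); b <- unlist(acc_b); w <- unlist(acc_w)
    key <- paste(a, b)
    agg <- rowsum(w, key)
    parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    edges <- data.frame(from = as.integer(parts[, 1]),
                        to = as.integer(parts[, 2]),
                        area_um2 = as.numeric(agg))
  }

  counts <- table(factor(as.vector(labs), levels = ids))
  nodes <- data.frame(cell_id = ids,
                      volume_um3 = as.numeric(counts) * prod(vx))
  # total surface per cell: 2 faces per voxel along each axis, minus the
  # internal (same-label) faces, each counted once per adjacent pair
  surf <- 2 * as.numeric(counts) * sum(face_area)
  for (ax in 1:3) {
    n <- dim(labs)[ax]
    if (n < 2) next
    idx1 <- switch(ax,
      list(1:(n - 1), TRUE, TRUE), list(TRUE, 1:(n - 1), TRUE),
      list(TRUE, TRUE, 1:(n - 1)))
    idx2 <- switch(ax,
      list(2:n, TRUE, TRUE), list(TRUE, 2:n, TRUE), list(TRUE, TRUE, 2:n))
    a <- do.call(`[`, c(list(labs), idx1))
    b <- do.call(`[`, c(list(labs), idx2))
    sel <- a == b & !(a %in% excl)
    if (any(sel)) {
      internal <- table(factor(a[sel], levels = ids))
      surf <- surf - 2 * as.numeric(internal) * face_area[ax]
    }
  }
  nodes$area_um2 <- surf
  if (!is.null(annotation)) {
    ann <- as.data.frame(annotation)
    m <- match(nodes$cell_id, ann$cell_id)
    if ("cell_type" %in% names(ann))
      nodes$cell_type <- ifelse(is.na(m), "unassigned", ann$cell_type[m])
    if ("boundary" %in% names(ann))
      nodes$boundary <- !is.na(m) & as.logical(ann$boundary[m])
  }
  cell_graph(nodes, edges)
}

#' Remove small cell-cell interfaces
#'
#' Interfaces below the area threshold are imaging-artifact candidates and
#' are removed — unless either endpoint is vascular, whose thin genuine
#' interfaces are exempt. Nodes are never removed.
#'
#' @param graph an annotated [cell_graph()]
#' @param threshold_um2 removal threshold; edges with
#'   `area < threshold_um2` (strictly less) are dropped. Default 2.
#' @return the filtered `cell_graph`, with attribute `"removed"` giving
#'   the number of removed edges
#' @export
filter_small_interfaces <- function(graph, threshold_um2 = 2.0) {
  stopifnot(inherits(graph, "cell_graph"))
  if (threshold_um2 <= 0) stop("threshold_um2 must be > 0")
  type_of <- setNames(graph$nodes$cell_type, graph$nodes$cell_id)
  vasc <- type_of[as.character(graph$edges$from)] == "vasculature" |
    type_of[as.character(graph$edges$to)] == "vasculature"
  keep <- graph$edges$area_um2 >= threshold_um2 | vasc
  out <- cell_graph(graph$nodes, graph$edges[keep, , drop = FALSE])
  attr(out, "removed") <- sum(!keep)
  out
}

#' Flag cells near the sample boundary as buffer cells
#'
#' Cut organs have distorted topology near the imaging boundary. Buffered
#' cells stay in the graph (and in all centrality computations) but are
#' excluded from reported statistics by [report_central()].
#'
#' @param graph a [cell_graph()] with `boundary` flags on its nodes
#' @param depth graph-hop radius: every cell within `depth` hops of a
#'   boundary cell is flagged (depth 0 flags the boundary cells only)
#' @return the `cell_graph` with its `buffer` column set
#' @export
mark_buffer <- function(graph, depth = 2L) {
  stopifnot(inherits(graph, "cell_graph"))
  if (depth < 0) stop("depth must be >= 0")
  if (!any(graph$nodes$boundary)) {
    if (depth > 0)
      warning("no boundary cells flagged; buffer marking is a no-op")
    graph$nodes$buffer <- FALSE
    return(graph)
  }
  ig <- as_igraph(graph)
  d <- igraph::distances(ig, v = igraph::V(ig),
                         to = igraph::V(ig)[graph$nodes$boundary])
  graph$nodes$buffer <- apply(d, 1, min) <= depth
  graph
}
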