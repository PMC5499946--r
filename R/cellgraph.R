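#' Cellular connectivity graph
#'
#' A `cell_graph` is the package's central container: an undirected graph
#' whose nodes are cells and whose edges are shared wall interfaces carrying
#' a positive area in square micrometres.
#'
#' @param nodes data.frame with at least `cell_id` (positive integers,
#'   unique) and optionally `cell_type`, `boundary`, `buffer`, `area_um2`,
#'   `volume_um3` plus generator bookkeeping columns. Missing optional
#'   columns are filled with defaults (`unassigned`, `FALSE`, `NA`).
#' @param edges data.frame with columns `from`, `to`, `area_um2`. Edges are
#'   stored with `from < to`; self loops and duplicate pairs are rejected,
#'   as are non-positive areas.
#'
#' @return an object of class `cell_graph`, a list with elements `nodes`
#'   and `edges`.
#' @export
cell_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (!"cell_id" %in% names(nodes))
    stop("`nodes` must have a cell_id column")
  if (anyDuplicated(nodes$cell_id))
    stop("duplicate cell ids in `nodes`")
  if (any(nodes$cell_id <= 0) || any(nodes$cell_id != round(nodes$cell_id)))
    stop("cell ids must be positive integers")
  if (!"cell_type" %in% names(nodes)) nodes$cell_type <- "unassigned"
  bad <- setdiff(unique(nodes$cell_type), CELL_TYPES)
  if (length(bad))
    stop("unknown cell type(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CELL_TYPES, collapse = ", "))
  if (!"boundary" %in% names(nodes)) nodes$boundary <- FALSE
  if (!"buffer" %in% names(nodes)) nodes$buffer <- FALSE
  if (!"area_um2" %in% names(nodes)) nodes$area_um2 <- NA_real_
  if (!"volume_um3" %in% names(nodes)) nodes$volume_um3 <- NA_real_

  if (nrow(edges)) {
    need <- c("from", "to", "area_um2")
    if (!all(need %in% names(edges)))
      stop("`edges` must have columns from, to, area_um2")
    if (any(edges$from == edges$to)) stop("self loops are not allowed")
    if (any(!is.finite(edges$area_um2)) || any(edges$area_um2 <= 0))
      stop("all edge areas must be finite and > 0")
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- a
    edges$to <- b
    if (anyDuplicated(paste(a, b)))
      stop("duplicate edges between the same cell pair")
    if (!all(c(a, b) %in% nodes$cell_id))
      stop("edge endpoints not present in `nodes`")
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        area_um2 = numeric())
  }
  structure(list(nodes = nodes, edges = edges), class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  tt <- table(x$nodes$cell_type)
  cat(sprintf("<cell_graph> %d cells, %d interfaces\n",
              nrow(x$nodes), nrow(x$edges)))
  cat("  cell types:",
      paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  if (any(x$nodes$boundary))
    cat(sprintf("  boundary cells: %d; buffered: %d\n",
                sum(x$nodes$boundary), sum(x$nodes$buffer)))
  invisible(x)
}

#' Number of cells in a cell graph
#' @param graph a `cell_graph`
#' @return integer node count
#' @export
n_cells <- function(graph) nrow(graph$nodes)

#' Convert a cell graph to an igraph object
#'
#' Vertex name is the cell id (as character); vertex attributes carry the
#' node table columns and edges carry `area_um2`.
#'
#' @param graph a `cell_graph`
#' @return an [igraph::igraph] object
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  vert <- graph$nodes
  vert <- cbind(name = as.character(vert$cell_id), vert)
  ed <- graph$edges
  ed$from <- as.character(ed$from)
  ed$to <- as.character(ed$to)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vert)
}

edge_key <- function(edges) paste(pmin(edges$from, edges$to),
                                  pmax(edges$from, edges$to), sep = "-")

#' Test two cell graphs for identical topology
#'
#' Compares node id sets and unordered edge sets; areas are compared when
#' `areas = TRUE` (within `tol`).
#'
#' @param a,b `cell_graph` objects
#' @param areas also compare interface areas
#' @param tol relative tolerance on areas
#' @return logical
#' @export
same_topology <- function(a, b, areas = FALSE, tol = 1e-9) {
  if (!setequal(a$nodes$cell_id, b$nodes$cell_id)) return(FALSE)
  ka <- edge_key(a$edges)
  kb <- edge_key(b$edges)
  if (!setequal(ka, kb) || length(ka) != length(kb)) return(FALSE)
  if (areas) {
    aa <- a$edges$area_um2[order(ka)]
    bb <- b$edges$area_um2[order(kb)]
    if (any(abs(aa - bb) > tol * pmax(aa, 1))) return(FALSE)
  }
  TRUE
}
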