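#' Read a cellular network from an edge-list text export
#'
#' The exchange format used by MorphoGraphX-style exports: whitespace- or
#' tab-delimited text, one interface per line as
#' `cell_id_1 cell_id_2 area_um2`, with `#` comment lines ignored.
#'
#' @param path file to read
#' @param annotation optional [read_annotation()] result (or any data.frame
#'   with `cell_id`, `cell_type`, `boundary`) to annotate nodes
#' @return a [cell_graph()]
#' @export
read_edge_list <- function(path, annotation = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 3)
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": expected 'id1 id2 area'")
  m <- matrix(unlist(fields), ncol = 3, byrow = TRUE)
  from <- suppressWarnings(as.integer(m[, 1]))
  to <- suppressWarnings(as.integer(m[, 2]))
  area <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(from) | is.na(to) | is.na(area))
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path)
  bad <- which(area <= 0)
  if (length(bad))
    stop("non-positive interface area on line ", lineno[bad[1]],
         " of ", path)
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate cell pair on line ", lineno[d], " of ", path)
  }
  ids <- sort(unique(c(from, to)))
  nodes <- data.frame(cell_id = ids)
  if (!is.null(annotation)) {
    ann <- as.data.frame(annotation)
    i <- match(ids, ann$cell_id)
    if ("cell_type" %in% names(ann))
      nodes$cell_type <- ifelse(is.na(i), "unassigned", ann$cell_type[i])
    if ("boundary" %in% names(ann))
      nodes$boundary <- !is.na(i) & as.logical(ann$boundary[i])
  }
  cell_graph(nodes, data.frame(from = from, to = to, area_um2 = area))
}

#' @rdname read_edge_list
#' @param graph a [cell_graph()] to write
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "cell_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cell_id_1 cell_id_2 area_um2", con)
  writeLines(sprintf("%d\t%d\t%.17g", graph$edges$from, graph$edges$to,
                     graph$edges$area_um2), con)
  invisible(path)
}

#' Read a cell-type annotation table
#'
#' CSV with header columns `cell_id`, `cell_type` and optionally
#' `boundary` (logical or 0/1).
#'
#' @param path file to read
#' @return data.frame with `cell_id`, `cell_type`, `boundary`
#' @export
read_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ",
         paste(need, collapse = ", "))
  bad <- setdiff(unique(ann$cell_type), CELL_TYPES)
  if (length(bad))
    stop("unknown cell type(s) in ", path, ": ",
         paste(bad, collapse = ", "),
         "; allowed: ", paste(CELL_TYPES, collapse = ", "))
  if (!"boundary" %in% names(ann)) ann$boundary <- FALSE
  ann$boundary <- as.logical(ann$boundary)
  ann[c("cell_id", "cell_type", "boundary")]
}

#' @rdname read_annotation
#' @param graph a [cell_graph()] whose node annotations to write
#' @export
write_annotation <- function(graph, path) {
  stopifnot(inherits(graph, "cell_graph"))
  utils::write.csv(graph$nodes[c("cell_id", "cell_type", "boundary")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write or read a per-cell attribute map ("heat map")
#'
#' Two-column text (`cell_id value`) consumable as a MorphoGraphX-style
#' attribute map for in-situ false coloring of segmented cells; values are
#' written at full precision so a round trip is lossless.
#'
#' @param values named numeric vector (names are cell ids) or data.frame
#'   with columns `cell_id`, `value`
#' @param path file to write/read
#' @return `write_heatmap` the path; `read_heatmap` a named numeric vector
#' @export
write_heatmap <- function(values, path) {
  if (is.data.frame(values)) {
    ids <- values$cell_id
    v <- values$value
  } else {
    ids <- names(values)
    v <- as.numeric(values)
  }
  writeLines(sprintf("%s\t%.17g", ids, v), path)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  m <- utils::read.table(path, header = FALSE,
                         colClasses = c("character", "numeric"))
  setNames(m[[2]], m[[1]])
}

#' Read or write a labeled volume as multi-page TIFF
#'
#' Thin wrappers over the `tiff` package (one z-slice per page); available
#' when `tiff` is installed.
#'
#' @param path TIFF file
#' @param voxel_um voxel dimensions `(dz, dy, dx)` in um
#' @return a [labeled_volume()]
#' @export
read_labeled_tiff <- function(path, voxel_um) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF volumes requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- as.integer(pages[[i]])
  labeled_volume(arr, voxel_um)
}

#' @rdname read_labeled_tiff
#' @param volume a [labeled_volume()] to write
#' @export
write_labeled_tiff <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF volumes requires the 'tiff' package")
  labs <- volume$labels
  if (max(labs) > 65535L)
    stop("TIFF writer supports labels up to 65535 (16-bit)")
  pages <- lapply(seq_len(dim(labs)[1]),
                  function(i) matrix(labs[i, , ] / 65535,
                                     nrow = dim(labs)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}
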