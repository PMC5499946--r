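#' Per-cell tracer concentration from a labeled volume and signal channel
#'
#' For every cell, the concentration is the summed signal over the cell's
#' voxels divided by the cell's physical volume (voxel count times voxel
#' volume), in signal units per cubic micrometre. Background and excluded
#' labels are ignored.
#'
#' @param volume a [labeled_volume()]
#' @param signal a signal volume (from [generate_signal_volume()] or a
#'   list with `intensities` co-registered with `volume`)
#' @param annotation optional data.frame (`cell_id`, `cell_type`) to
#'   annotate rows
#' @return data.frame with `cell_id`, `cell_type`, `raw_concentration`,
#'   `total_signal`, `volume_um3`
#' @export
quantify_concentration <- function(volume, signal, annotation = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  ints <- if (is.list(signal)) signal$intensities else signal
  if (!identical(dim(ints), dim(volume$labels)))
    stop("signal and labeled volume shapes differ")
  if (any(ints < 0)) stop("signal intensities must be nonnegative")
  labs <- as.vector(volume$labels)
  keep <- !(labs %in% volume$excluded_labels)
  if (!any(keep)) stop("no labeled cells in volume")
  f <- factor(labs[keep])
  tot <- tapply(as.vector(ints)[keep], f, sum)
  nvox <- tabulate(f)
  vol <- nvox * prod(volume$voxel_um)
  out <- data.frame(cell_id = as.integer(levels(f)),
                    total_signal = as.numeric(tot),
                    volume_um3 = vol,
                    raw_concentration = as.numeric(tot) / vol)
  if (!is.null(annotation)) {
    ann <- as.data.frame(annotation)
    m <- match(out$cell_id, ann$cell_id)
    out$cell_type <- ifelse(is.na(m), "unassigned", ann$cell_type[m])
  }
  rownames(out) <- NULL
  out
}

#' Mean-normalize concentrations over a pooled comparison set
#'
#' Divides every concentration by the mean over the pooled set (by
#' default all rows), so the pooled mean of the result is exactly 1;
#' normalizing twice is the same as normalizing once.
#'
#' @param table result of [quantify_concentration()] (rows from several
#'   replicates may be concatenated first)
#' @param pool logical vector selecting the cells defining the pool
#'   (default: all)
#' @return the table with a `normalized_concentration` column
#' @export
mean_normalize <- function(table, pool = rep(TRUE, nrow(table))) {
  stopifnot(is.data.frame(table), "raw_concentration" %in% names(table))
  m <- mean(table$raw_concentration[pool])
  if (!is.finite(m) || m <= 0) stop("pool mean must be > 0")
  table$normalized_concentration <- table$raw_concentration / m
  table
}

#' Compare tracer concentration between two cell types
#'
#' Two-sample t-test (Welch by default) on normalized concentrations of
#' the two epidermal cell types; fewer than 40 cells per type triggers a
#' warning, as smaller samples are below the usual protocol target.
#'
#' @param table a [mean_normalize()]d concentration table with
#'   `cell_type`
#' @param type_a,type_b the two cell types to compare
#' @param alpha significance threshold (default 0.001)
#' @param var_equal use the pooled-variance t-test instead of Welch
#' @return data.frame row: `test`, `statistic`, `p_value`, `significant`,
#'   `mean_a`, `mean_b`
#' @export
compare_cell_types <- function(table, type_a = "atrichoblast",
                               type_b = "trichoblast", alpha = 0.001,
                               var_equal = FALSE) {
  stopifnot(is.data.frame(table),
            "normalized_concentration" %in% names(table))
  va <- table$normalized_concentration[table$cell_type == type_a]
  vb <- table$normalized_concentration[table$cell_type == type_b]
  if (length(va) < 2 || length(vb) < 2)
    stop("need at least 2 cells of each type (",
         type_a, ": ", length(va), ", ", type_b, ": ", length(vb), ")")
  if (length(va) < 40 || length(vb) < 40)
    warning("fewer than 40 cells per type; below protocol target")
  res <- t.test(va, vb, var.equal = var_equal)
  data.frame(test = if (var_equal) "t_test" else "t_test_welch",
             statistic = unname(res$statistic), p_value = res$p.value,
             significant = res$p.value <= alpha,
             mean_a = mean(va), mean_b = mean(vb))
}
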