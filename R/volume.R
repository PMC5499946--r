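#' Labeled 3D volume
#'
#' A segmentation image: a 3D integer array in `(z, y, x)` axis order with
#' one label per cell, label 0 reserved for background, and physical voxel
#' dimensions in um.
#'
#' @param labels 3D integer array, axis order `(z, y, x)`
#' @param voxel_um numeric triple `(dz, dy, dx)`, all > 0
#' @param excluded_labels labels to treat as non-cellular (air spaces etc.)
#'   in addition to background 0
#' @return a `labeled_volume` object
#' @export
labeled_volume <- function(labels, voxel_um, excluded_labels = integer(0)) {
  if (length(dim(labels)) != 3) stop("`labels` must be a 3D array")
  if (length(voxel_um) != 3 || any(voxel_um <= 0))
    stop("voxel_um must be three positive dimensions (dz, dy, dx)")
  structure(list(labels = labels, voxel_um = as.numeric(voxel_um),
                 excluded_labels = unique(c(0L, as.integer(excluded_labels)))),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels at (%.3g, %.3g, %.3g) um, %d labels\n",
              paste(dim(x$labels), collapse = " x "),
              x$voxel_um[1], x$voxel_um[2], x$voxel_um[3],
              length(setdiff(unique(as.vector(x$labels)),
                             x$excluded_labels))))
  invisible(x)
}

#' Rasterize a synthetic organ into a labeled volume
#'
#' Paints each generated cell as a contiguous voxel region of a cylinder,
#' using the same angular layout as [generate_organ()], so that the
#' face-adjacency graph of the result reproduces the generated topology
#' (up to interface-area discretization) once voxels are fine enough.
#'
#' @param spec an [organ_spec()]
#' @param voxel_um voxel dimensions `(dz, dy, dx)` in um
#' @return a [labeled_volume()]; labels are the cell ids of
#'   [generate_organ()], 0 is exterior background
#' @export
rasterize_organ <- function(spec, voxel_um) {
  stopifnot(inherits(spec, "organ_spec"))
  if (length(voxel_um) != 3 || any(voxel_um <= 0))
    stop("voxel_um must be three positive dimensions (dz, dy, dx)")
  files <- organ_files(spec)
  files$id0 <- cumsum(c(0L, files$n_axial[-nrow(files)]))
  r_in <- spec$core_radius_um +
    cumsum(c(0, vapply(spec$rings, `[[`, 0, "thickness_um")))
  r_in[1] <- 0
  R <- r_in[length(r_in)]
  L <- spec$organ_length_um
  dz <- voxel_um[1]; dy <- voxel_um[2]; dx <- voxel_um[3]

  nz <- ceiling(L / dz)
  ny <- ceiling(2 * R / dy) + 2L
  nx <- ceiling(2 * R / dx) + 2L
  zc <- (seq_len(nz) - 0.5) * dz
  yc <- (seq_len(ny) - 0.5) * dy - ny * dy / 2
  xc <- (seq_len(nx) - 0.5) * dx - nx * dx / 2

  # in-plane lookup: ring and file for every (y, x) voxel column
  xy_r <- sqrt(outer(yc^2, xc^2, `+`))
  theta <- (atan2(outer(yc, rep(1, nx)), outer(rep(1, ny), xc)) /
              (2 * pi)) %% 1
  ring <- array(findInterval(xy_r, r_in, left.open = TRUE), dim(xy_r))
  ring[xy_r >= R] <- 0L            # outside the organ
  ang0 <- ring_ang0(spec)
  nfile <- vapply(spec$rings, `[[`, 1L, "n_files")
  filei <- array(0L, dim(xy_r))
  inside <- ring > 0L
  fi <- ring[inside]
  filei[inside] <- as.integer(floor((theta[inside] - ang0[fi]) * nfile[fi])) %%
    nfile[fi]

  # per-file base id and axial-layer lookup, addressed by (ring, file)
  key <- paste(files$ring, files$file)
  col_row <- array(NA_integer_, dim(xy_r))
  col_row[inside] <- match(paste(ring, filei)[inside], key)
  col_id0 <- array(NA_integer_, dim(xy_r))
  col_id0[inside] <- files$id0[col_row[inside]]
  zfrac <- zc / L
  axmat <- t(vapply(files$bnd, function(b)
    pmin(length(b) - 1L, pmax(1L, findInterval(zfrac, b))),
    integer(nz)))                     # file x z-layer -> axial cell (1-based)

  labels <- array(0L, dim = c(nz, ny, nx))
  for (iz in seq_len(nz)) {
    lab <- col_id0 + axmat[cbind(as.vector(col_row), iz)]
    lab[!inside] <- 0L
    labels[iz, , ] <- lab
  }
  n_cells <- sum(files$n_axial)
  got <- tabulate(labels[labels > 0L], nbins = n_cells)
  if (any(got == 0L))
    stop("voxel grid too coarse: cell(s) ",
         paste(head(which(got == 0L), 5), collapse = ", "),
         " received no voxels")
  labeled_volume(labels, voxel_um)
}

#' Synthetic fluorescence signal for a labeled volume
#'
#' Stand-in for a co-registered tracer channel: every voxel of a cell
#' draws its intensity from Normal(mean of the cell's type, `noise_sd`),
#' truncated at 0; background voxels are 0.
#'
#' @param volume a [labeled_volume()]
#' @param annotation data.frame with `cell_id` and `cell_type` columns (a
#'   [generate_organ()] node table works directly)
#' @param per_type_mean named numeric vector of mean intensities, one per
#'   cell type present (all >= 0)
#' @param noise_sd Gaussian noise standard deviation (>= 0)
#' @param seed integer seed
#' @return a `signal_volume`: list with 3D `intensities` and `voxel_um`
#' @export
generate_signal_volume <- function(volume, annotation, per_type_mean,
                                   noise_sd = 0, seed = 1L) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(per_type_mean < 0)) stop("per_type_mean must be nonnegative")
  ann <- as.data.frame(annotation)
  type_of <- setNames(ann$cell_type, ann$cell_id)
  labs <- volume$labels
  ids <- setdiff(unique(as.vector(labs)), volume$excluded_labels)
  types <- type_of[as.character(ids)]
  if (anyNA(types))
    stop("annotation missing for label(s): ",
         paste(head(ids[is.na(types)], 5), collapse = ", "))
  miss <- setdiff(unique(types), names(per_type_mean))
  if (length(miss))
    stop("per_type_mean missing cell type(s): ", paste(miss, collapse = ", "))
  mu_of <- setNames(per_type_mean[types], ids)
  sig <- array(0, dim(labs))
  cellv <- labs > 0 & !(labs %in% volume$excluded_labels)
  mu <- mu_of[as.character(labs[cellv])]
  sig[cellv] <- with_seed(seed,
    pmax(0, rnorm(sum(cellv), mean = mu, sd = noise_sd)))
  structure(list(intensities = sig, voxel_um = volume$voxel_um),
            class = "signal_volume")
}
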