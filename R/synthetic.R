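#' Ring description for a synthetic organ
#'
#' A synthetic organ is a stack of concentric cell layers ("rings"). Each
#' ring is a set of circumferential cell files; each file is a column of
#' cells along the organ axis. The outermost ring must have
#' `cell_type = "epidermis"`: its files alternate between trichoblasts
#' (even file index, sitting over the junction of two underlying cortical
#' files) and atrichoblasts (odd index, sitting over a single cortical
#' file).
#'
#' @param cell_type one of `"vasculature"`, `"endodermis"`,
#'   `"inner_cortex"`, `"outer_cortex"`, `"epidermis"`
#' @param n_files number of circumferential cell files (>= 1; for the
#'   epidermis it must equal twice the file count of the ring beneath)
#' @param n_axial number of cells per file along the axis (>= 1)
#' @param interface_area_mean_um2 mean shared-wall area for interfaces of
#'   this layer, in um^2 (> 0)
#' @param interface_area_cv coefficient of variation of interface areas
#'   (>= 0); areas are drawn lognormal
#' @param thickness_um radial thickness of the ring, in um
#' @return a `ring_spec` list
#' @export
ring_spec <- function(cell_type, n_files, n_axial,
                      interface_area_mean_um2, interface_area_cv = 0.3,
                      thickness_um = 15) {
  allowed <- c("vasculature", "endodermis", "inner_cortex",
               "outer_cortex", "epidermis")
  if (!cell_type %in% allowed)
    stop("ring cell_type must be one of: ", paste(allowed, collapse = ", "))
  if (n_files < 1 || n_files != round(n_files))
    stop("n_files must be a positive integer")
  if (n_axial < 1 || n_axial != round(n_axial))
    stop("n_axial must be a positive integer")
  if (interface_area_mean_um2 <= 0)
    stop("interface_area_mean_um2 must be > 0")
  if (interface_area_cv < 0)
    stop("interface_area_cv must be >= 0")
  if (thickness_um <= 0) stop("thickness_um must be > 0")
  structure(list(cell_type = cell_type,
                 n_files = as.integer(n_files),
                 n_axial = as.integer(n_axial),
                 interface_area_mean_um2 = interface_area_mean_um2,
                 interface_area_cv = interface_area_cv,
                 thickness_um = thickness_um),
            class = "ring_spec")
}

#' Parametric description of a synthetic cylindrical organ
#'
#' @param rings list of [ring_spec()] ordered innermost (vasculature core)
#'   to outermost (epidermis)
#' @param organ_length_um organ length in um (> 0)
#' @param conduit_mode when `TRUE`, atrichoblast files carry half as many
#'   (hence twice as long) cells as trichoblast files, so paths along
#'   atrichoblast files need fewer hops — the generator's "conduit"
#'   property. When `FALSE` both epidermal types use the ring's `n_axial`.
#' @param artifact_rate fraction of spurious small-interface edges to
#'   inject (see [inject_artifacts()]); 0 disables
#' @param core_radius_um radius of the innermost ring, in um
#' @param size_jitter_cv lognormal coefficient of variation of per-cell
#'   size variation applied to wall area and volume
#' @param axial_phase when `TRUE`, each cell file gets a random axial
#'   stagger (a quantized phase shift of its cell boundaries), as in real
#'   tissue where files are not ring-aligned; `FALSE` gives a perfectly
#'   regular lattice
#' @param n_axial_cv lognormal coefficient of variation of the per-file
#'   axial cell count around the ring's `n_axial` (0 disables); this is
#'   what makes replicate organs from different seeds topologically
#'   distinct
#' @param contact_wobble_q probability that a cell develops a genuine
#'   contact with a file of the adjacent ring whose angular sector it does
#'   not overlap but nearly reaches (within half its own width). Emulates
#'   cell-wall wobble near file junctions in real 3D packings, where such
#'   grazing contacts are common; 0 gives the bare lattice. Wobble
#'   contacts exist only in the generated graph, not in rasterized
#'   volumes.
#' @param seed integer seed driving all randomness of the generator
#' @return an `organ_spec` list
#' @export
organ_spec <- function(rings, organ_length_um, conduit_mode = FALSE,
                       artifact_rate = 0, core_radius_um = 20,
                       size_jitter_cv = 0.15, axial_phase = TRUE,
                       n_axial_cv = 0, contact_wobble_q = 0.35,
                       seed = 1L) {
  if (length(rings) < 2) stop("an organ needs at least 2 rings")
  if (!all(vapply(rings, inherits, TRUE, "ring_spec")))
    stop("`rings` must be a list of ring_spec objects")
  types <- vapply(rings, `[[`, "", "cell_type")
  if (sum(types == "epidermis") != 1 || types[length(types)] != "epidermis")
    stop("exactly one ring must be epidermal and it must be outermost")
  if (organ_length_um <= 0) stop("organ_length_um must be > 0")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must be in [0, 1]")
  nr <- length(rings)
  fe <- rings[[nr]]$n_files
  fb <- rings[[nr - 1]]$n_files
  if (fe != 2L * fb)
    stop("cannot tile the cylinder: the epidermal ring needs exactly ",
         "twice the file count of the ring beneath it (", 2L * fb,
         "), got ", fe)
  if (conduit_mode && rings[[nr]]$n_axial %% 2L != 0L)
    stop("conduit_mode requires an even epidermal n_axial ",
         "(atrichoblast files carry half as many cells)")
  if (n_axial_cv < 0) stop("n_axial_cv must be >= 0")
  if (contact_wobble_q < 0 || contact_wobble_q > 1)
    stop("contact_wobble_q must be in [0, 1]")
  structure(list(rings = rings, organ_length_um = organ_length_um,
                 conduit_mode = conduit_mode,
                 artifact_rate = artifact_rate,
                 core_radius_um = core_radius_um,
                 size_jitter_cv = size_jitter_cv,
                 axial_phase = isTRUE(axial_phase),
                 n_axial_cv = n_axial_cv,
                 contact_wobble_q = contact_wobble_q,
                 seed = as.integer(seed)),
            class = "organ_spec")
}

#' Default hypocotyl-scale organ (about 1700 cells)
#'
#' Interface-area means are ordered cortex > epidermis > vasculature, in
#' line with measured shared wall areas of the hypocotyl layers; the exact
#' values are free parameters of the generator.
#'
#' @param conduit_mode,seed passed to [organ_spec()]
#' @return an `organ_spec`
#' @export
default_organ_spec <- function(conduit_mode = FALSE, seed = 1L) {
  organ_spec(
    rings = list(
      ring_spec("vasculature",  4, 40,  60, 0.35, thickness_um = 20),
      ring_spec("endodermis",   8, 40, 250, 0.30),
      ring_spec("inner_cortex", 8, 40, 420, 0.30),
      ring_spec("outer_cortex", 8, 40, 400, 0.30),
      ring_spec("epidermis",   16, 40, 200, 0.30)
    ),
    organ_length_um = 2000, conduit_mode = conduit_mode, seed = seed)
}

#' Toy organ (about 220 cells) for fast examples and tests
#' @param conduit_mode,seed passed to [organ_spec()]
#' @return an `organ_spec`
#' @export
toy_organ_spec <- function(conduit_mode = FALSE, seed = 1L) {
  organ_spec(
    rings = list(
      ring_spec("vasculature",  2, 10,  60, 0.35, thickness_um = 12),
      ring_spec("endodermis",   4, 10, 250, 0.30, thickness_um = 10),
      ring_spec("inner_cortex", 4, 10, 420, 0.30, thickness_um = 10),
      ring_spec("outer_cortex", 4, 10, 400, 0.30, thickness_um = 10),
      ring_spec("epidermis",    8, 10, 200, 0.30, thickness_um = 10)
    ),
    organ_length_um = 500, conduit_mode = conduit_mode,
    core_radius_um = 12, seed = seed)
}

# --- internal layout ---------------------------------------------------

# Angular layout of every file: start angle (turns) of file 0 per ring.
# Rings alternate a half-sector stagger so that boundaries of adjacent
# rings never coincide; the epidermal ring is placed so that even
# (trichoblast) files are centered exactly on the boundaries of the ring
# beneath, making each trichoblast file overlap two underlying cortical
# files while each atrichoblast file sits strictly inside one.
ring_ang0 <- function(spec) {
  nr <- length(spec$rings)
  s <- rep(0, nr)
  for (i in seq_len(nr - 1)) s[i] <- if (i %% 2 == 0) 0.5 else 0
  ang0 <- numeric(nr)
  for (i in seq_len(nr - 1)) ang0[i] <- s[i] / spec$rings[[i]]$n_files
  delta <- 2 * s[nr - 1]           # trichoblast centers on below-boundaries
  ang0[nr] <- (delta - 0.5) / spec$rings[[nr]]$n_files
  ang0
}

# File-level layout table: one row per cell file, with an `bnd` list
# column holding the axial cell boundaries (fractions of organ length).
# The layout consumes the spec seed, so the graph generator and the
# rasterizer see the same organ.
organ_files <- function(spec) {
  nr <- length(spec$rings)
  ang0 <- ring_ang0(spec)
  out <- with_seed(spec$seed, {
    sdlog <- sqrt(log(1 + spec$n_axial_cv^2))
    rows <- list()
    for (i in seq_len(nr)) {
      rg <- spec$rings[[i]]
      F <- rg$n_files
      f <- seq_len(F) - 1L
      if (rg$cell_type == "epidermis") {
        type <- ifelse(f %% 2L == 0L, "trichoblast", "atrichoblast")
        base <- ifelse(type == "atrichoblast" & spec$conduit_mode,
                       rg$n_axial %/% 2L, rg$n_axial)
      } else {
        type <- rep(rg$cell_type, F)
        base <- rep(rg$n_axial, F)
      }
      nax <- if (spec$n_axial_cv > 0)
        pmax(2L, as.integer(round(base * rlnorm(F, 0, sdlog))))
      else as.integer(base)
      phase <- if (spec$axial_phase) sample(c(0, 0.25, 0.5), F, TRUE)
      else rep(0, F)
      bnd <- lapply(seq_len(F), function(k) {
        n <- nax[k]
        # per-boundary jitter (quarter-cell quanta) staggers individual
        # cell walls, as in real files where cells do not line up
        jit <- if (spec$axial_phase)
          sample(c(-0.25, 0, 0.25), n - 1L, TRUE) else rep(0, n - 1L)
        c(0, (seq_len(n - 1L) + phase[k] + jit) / n, 1)
      })
      df <- data.frame(ring = i, file = f, cell_type = type,
                       n_axial = nax,
                       ang_lo = ang0[i] + f / F,
                       ang_hi = ang0[i] + (f + 1) / F)
      df$bnd <- bnd
      rows[[i]] <- df
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

# circular overlap (in turns) of [a1,b1) and [a2,b2)
circ_overlap <- function(a1, b1, a2, b2) {
  ov <- 0
  for (s in c(-1, 0, 1))
    ov <- ov + pmax(0, pmin(b1, b2 + s) - pmax(a1, a2 + s))
  ov
}

# circular distance (in turns) between two disjoint arcs; 0 if they overlap
circ_gap <- function(a1, b1, a2, b2) {
  if (circ_overlap(a1, b1, a2, b2) > 0) return(0)
  g <- Inf
  for (s in c(-1, 0, 1)) {
    d1 <- (a2 + s) - b1
    d2 <- a1 - (b2 + s)
    if (d1 >= 0) g <- min(g, d1)
    if (d2 >= 0) g <- min(g, d2)
  }
  g
}

# index pairs (0-based) of axially overlapping cells between two files
# given their boundary vectors (fractions, first 0, last 1)
axial_pairs <- function(bA, bB, tol = 1e-9) {
  nA <- length(bA) - 1L
  nB <- length(bB) - 1L
  i0 <- pmax(1L, findInterval(bB[-length(bB)] + tol, bA))
  i1 <- pmin(nA, findInterval(bB[-1] - tol, bA) + 1L)
  i1 <- pmax(i1, i0)
  # trim to strict overlap
  res_i <- integer(0); res_j <- integer(0)
  for (j in seq_len(nB)) {
    ii <- seq(i0[j], i1[j])
    keep <- pmin(bA[ii + 1L], bB[j + 1L]) - pmax(bA[ii], bB[j]) > tol
    ii <- ii[keep]
    res_i <- c(res_i, ii - 1L)
    res_j <- c(res_j, rep(j - 1L, length(ii)))
  }
  cbind(i = res_i, j = res_j)
}

#' Generate a synthetic organ network
#'
#' Builds the cell lattice of a cylindrical organ: axial neighbors within
#' each file, circumferential neighbors between adjacent files of a ring,
#' and radial neighbors between files of adjacent rings whose angular
#' sectors overlap (cells connect when their axial extents also overlap).
#' Interface areas are drawn from a lognormal model per layer pair; cells
#' carry synthetic wall area and volume with lognormal size jitter. Cells
#' of the first and last axial layer of each file are flagged as sample
#' boundary cells.
#'
#' @param spec an [organ_spec()]
#' @return a [cell_graph()] whose node table carries `cell_type`, `ring`,
#'   `file`, `axial`, `boundary`, `area_um2` and `volume_um3`
#' @export
generate_organ <- function(spec) {
  stopifnot(inherits(spec, "organ_spec"))
  files <- organ_files(spec)
  files$file_row <- seq_len(nrow(files))
  files$id0 <- cumsum(c(0L, files$n_axial[-nrow(files)]))  # first id - 1

  n_cells <- sum(files$n_axial)
  nodes <- data.frame(
    cell_id = seq_len(n_cells),
    cell_type = rep(files$cell_type, files$n_axial),
    ring = rep(files$ring, files$n_axial),
    file = rep(files$file, files$n_axial),
    axial = unlist(lapply(files$n_axial, function(n) seq_len(n) - 1L))
  )
  nodes$boundary <- nodes$axial == 0L |
    nodes$axial == rep(files$n_axial, files$n_axial) - 1L

  pair_files <- function(ra, rb) {
    # all cell pairs between file-table rows ra and rb (axial overlap)
    ij <- axial_pairs(files$bnd[[ra]], files$bnd[[rb]])
    cbind(files$id0[ra] + ij[, "i"] + 1L, files$id0[rb] + ij[, "j"] + 1L)
  }

  ef <- list(); et <- list(); k <- 0L
  # axial edges within each file
  for (r in files$file_row) {
    n <- files$n_axial[r]
    if (n > 1) {
      k <- k + 1L
      ef[[k]] <- files$id0[r] + seq_len(n - 1L)
      et[[k]] <- files$id0[r] + seq_len(n - 1L) + 1L
    }
  }
  edges <- data.frame(from = unlist(ef), to = unlist(et))

  # circumferential edges between neighboring files of the same ring
  circ <- list(); k <- 0L
  for (i in seq_along(spec$rings)) {
    rows <- files$file_row[files$ring == i]
    F <- length(rows)
    if (F < 2) next
    for (f in seq_len(F)) {
      g <- if (f == F) 1L else f + 1L
      if (!(g > f || (f == F && F > 2))) next
      k <- k + 1L
      circ[[k]] <- pair_files(rows[f], rows[g])
    }
  }
  # radial edges between files of adjacent rings with angular overlap;
  # near-miss file pairs (within half the narrower file's width) are
  # "wobble" candidates: their cell pairs gain a contact with
  # probability contact_wobble_q
  rad <- list(); k <- 0L
  wob <- list(); kw <- 0L
  for (i in seq_len(length(spec$rings) - 1L)) {
    ra <- files[files$ring == i, ]
    rb <- files[files$ring == i + 1L, ]
    for (a in seq_len(nrow(ra))) for (b in seq_len(nrow(rb))) {
      ov <- circ_overlap(ra$ang_lo[a], ra$ang_hi[a],
                         rb$ang_lo[b], rb$ang_hi[b])
      if (ov > 1e-9) {
        k <- k + 1L
        rad[[k]] <- pair_files(ra$file_row[a], rb$file_row[b])
      } else if (spec$contact_wobble_q > 0) {
        w <- 0.5 * min(ra$ang_hi[a] - ra$ang_lo[a],
                       rb$ang_hi[b] - rb$ang_lo[b])
        if (circ_gap(ra$ang_lo[a], ra$ang_hi[a],
                     rb$ang_lo[b], rb$ang_hi[b]) <= w + 1e-9) {
          kw <- kw + 1L
          wob[[kw]] <- pair_files(ra$file_row[a], rb$file_row[b])
        }
      }
    }
  }
  if (length(wob)) {
    wob <- do.call(rbind, wob)
    keep <- with_seed(spec$seed + 2000003L,
                      runif(nrow(wob)) < spec$contact_wobble_q)
    wob <- wob[keep, , drop = FALSE]
  } else wob <- NULL
  more <- do.call(rbind, c(circ, rad, list(wob)))
  edges <- rbind(edges, data.frame(from = more[, 1], to = more[, 2]))

  # lognormal interface areas per layer-pair class and node geometry
  ring_mean <- vapply(spec$rings, `[[`, 0, "interface_area_mean_um2")
  ring_cv <- vapply(spec$rings, `[[`, 0, "interface_area_cv")
  r_in <- spec$core_radius_um +
    cumsum(c(0, vapply(spec$rings, `[[`, 0, "thickness_um")))
  r_in[1] <- 0                       # the core fills to the axis
  graph <- with_seed(spec$seed + 1000003L, {
    ri <- nodes$ring[edges$from]
    rj <- nodes$ring[edges$to]
    m <- sqrt(ring_mean[ri] * ring_mean[rj])
    cv <- (ring_cv[ri] + ring_cv[rj]) / 2
    p <- lnorm_pars(m, pmax(cv, 1e-8))
    edges$area_um2 <- rlnorm(nrow(edges), p$meanlog, p$sdlog)

    nr <- nodes$ring
    len <- spec$organ_length_um *
      unlist(lapply(files$bnd, diff), use.names = FALSE)
    w <- 1 / vapply(spec$rings, `[[`, 1L, "n_files")[nr]   # turns
    r0 <- r_in[nr]; r1 <- r_in[nr + 1L]
    cross <- pi * (r1^2 - r0^2) * w
    s <- rlnorm(nrow(nodes), 0, sqrt(log(1 + spec$size_jitter_cv^2)))
    nodes$volume_um3 <- cross * len * s^1.5
    nodes$area_um2 <- (2 * cross + 2 * pi * (r0 + r1) * w * len +
                         2 * (r1 - r0) * len) * s
    cell_graph(nodes, edges)
  })
  if (spec$artifact_rate > 0)
    graph <- inject_artifacts(graph, spec$artifact_rate,
                              max_area_um2 = 1.9, seed = spec$seed + 7L)
  graph
}

#' Inject spurious small interfaces into a cell graph
#'
#' Emulates segmentation artifacts: thin, erroneous contacts between cells
#' that are not true neighbors. Adds `round(rate * ecount)` edges between
#' randomly chosen non-adjacent, non-vascular cell pairs with areas drawn
#' uniformly in `(0, max_area_um2)`. Such edges are removed again by
#' [filter_small_interfaces()] at the standard 2 um^2 threshold.
#'
#' @param graph a [cell_graph()]
#' @param rate fraction of the original edge count to add, in \[0, 1\]
#' @param max_area_um2 upper bound of injected areas (0 < max < 2)
#' @param seed integer seed
#' @return a new `cell_graph` with the artifact edges added
#' @export
inject_artifacts <- function(graph, rate, max_area_um2 = 1.9, seed = 1L) {
  stopifnot(inherits(graph, "cell_graph"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (max_area_um2 <= 0) stop("max_area_um2 must be > 0")
  if (max_area_um2 >= 2)
    warning("injected areas >= 2 um^2 will survive the standard filter")
  n_add <- round(rate * nrow(graph$edges))
  if (n_add == 0) return(graph)
  cand <- graph$nodes$cell_id[graph$nodes$cell_type != "vasculature"]
  have <- edge_key(graph$edges)
  with_seed(seed, {
    new_from <- integer(0); new_to <- integer(0)
    guard <- 0L
    while (length(new_from) < n_add) {
      guard <- guard + 1L
      if (guard > 1000L) stop("could not find enough non-adjacent pairs")
      m <- (n_add - length(new_from)) * 2L
      a <- sample(cand, m, replace = TRUE)
      b <- sample(cand, m, replace = TRUE)
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- paste(lo, hi, sep = "-")
      ok <- lo != hi & !key %in% have & !duplicated(key)
      lo <- lo[ok]; hi <- hi[ok]; key <- key[ok]
      take <- seq_len(min(length(lo), n_add - length(new_from)))
      new_from <- c(new_from, lo[take])
      new_to <- c(new_to, hi[take])
      have <- c(have, key[take])
    }
    areas <- runif(n_add, 0, max_area_um2)
    areas[areas == 0] <- max_area_um2 / 2
    cell_graph(graph$nodes,
               rbind(graph$edges,
                     data.frame(from = new_from, to = new_to,
                                area_um2 = areas)))
  })
}
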