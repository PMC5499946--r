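#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults follow the
#' standard protocol: 2 um^2 interface filter, 2-hop boundary buffer,
#' alpha 0.05 Bonferroni-corrected for 3200 study-wide comparisons, kNN
#' MI with k = 3, and 3-cluster average-linkage grouping.
#'
#' @param input `"synthetic"`, `"edge_list"` or `"volume"`
#' @param spec an [organ_spec()] (synthetic input; default
#'   [default_organ_spec()])
#' @param edge_list_paths,annotation_paths character vectors, one per
#'   replicate (edge_list input)
#' @param volume_paths labeled-volume TIFF paths (volume input)
#' @param voxel_um voxel dimensions for volume input
#' @param n_replicates number of biological replicates (synthetic input);
#'   replicate r uses seed `seed + r - 1`
#' @param conduit_mode passed to the synthetic generator
#' @param filter_threshold_um2 interface filter threshold (0 disables)
#' @param buffer_depth boundary buffer depth in graph hops
#' @param alpha family-wise error rate
#' @param m_comparisons Bonferroni comparison count
#' @param mi_k kNN parameter for mutual information
#' @param cluster_k number of clusters
#' @param linkage agglomeration method
#' @param seed master seed; all stage seeds derive from it
#' @return a `run_config` list
#' @export
run_config <- function(input = c("synthetic", "edge_list", "volume"),
                       spec = NULL, edge_list_paths = NULL,
                       annotation_paths = NULL, volume_paths = NULL,
                       voxel_um = NULL, n_replicates = 3L,
                       conduit_mode = FALSE,
                       filter_threshold_um2 = 2.0, buffer_depth = 2L,
                       alpha = 0.05, m_comparisons = 3200L, mi_k = 3L,
                       cluster_k = 3L, linkage = "average", seed = 1L) {
  input <- match.arg(input)
  if (filter_threshold_um2 < 0) stop("filter_threshold_um2 must be >= 0")
  if (buffer_depth < 0) stop("buffer_depth must be >= 0")
  if (input == "edge_list") {
    if (is.null(edge_list_paths))
      stop("edge_list input needs edge_list_paths")
    if (is.null(annotation_paths))
      stop("edge_list input needs annotation_paths (annotation file ",
           "missing)")
  }
  if (input == "volume" && is.null(volume_paths))
    stop("volume input needs volume_paths")
  structure(list(input = input, spec = spec,
                 edge_list_paths = edge_list_paths,
                 annotation_paths = annotation_paths,
                 volume_paths = volume_paths, voxel_um = voxel_um,
                 n_replicates = as.integer(n_replicates),
                 conduit_mode = conduit_mode,
                 filter_threshold_um2 = filter_threshold_um2,
                 buffer_depth = as.integer(buffer_depth), alpha = alpha,
                 m_comparisons = as.integer(m_comparisons),
                 mi_k = as.integer(mi_k),
                 cluster_k = as.integer(cluster_k), linkage = linkage,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the end-to-end organ-topology analysis
#'
#' Ingests or generates replicate organ networks, applies interface
#' filtering and boundary buffering, computes the topological measure
#' table, compares cell-type degree and betweenness distributions at the
#' Bonferroni-corrected level, estimates the mutual-information panel per
#' cell type, and clusters cell types by their distribution distances.
#' Deterministic given the configuration (including its seed).
#'
#' @param config a [run_config()]
#' @param out_dir optional directory; when given, writes `measures.csv`,
#'   `comparisons.csv`, `mi.csv`, `clusters.csv`, `dendrogram.nwk` and
#'   `log.txt` there
#' @return (invisibly) list with `measures`, `reported`, `comparisons`,
#'   `mi`, `clusters`, `log`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  say("organtopo pipeline; input=", config$input, " seed=", config$seed)

  graphs <- switch(config$input,
    synthetic = {
      spec <- if (is.null(config$spec))
        default_organ_spec(conduit_mode = config$conduit_mode)
      else config$spec
      lapply(seq_len(config$n_replicates), function(r) {
        s <- spec
        s$seed <- config$seed + r - 1L
        s$conduit_mode <- config$conduit_mode
        generate_organ(s)
      })
    },
    edge_list = {
      if (length(config$annotation_paths) != length(config$edge_list_paths))
        stop("need one annotation per edge list")
      missing <- config$edge_list_paths[!file.exists(config$edge_list_paths)]
      missing <- c(missing,
                   config$annotation_paths[!file.exists(config$annotation_paths)])
      if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
      Map(function(e, a) read_edge_list(e, read_annotation(a)),
          config$edge_list_paths, config$annotation_paths)
    },
    volume = {
      missing <- config$volume_paths[!file.exists(config$volume_paths)]
      if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
      ann <- if (!is.null(config$annotation_paths))
        lapply(config$annotation_paths, read_annotation)
      else vector("list", length(config$volume_paths))
      Map(function(v, a)
        extract_adjacency(read_labeled_tiff(v, config$voxel_um), a),
        config$volume_paths, ann)
    })
  say("replicates: ", length(graphs), "; cells: ",
      paste(vapply(graphs, n_cells, 1L), collapse = ", "))

  measures <- list()
  for (r in seq_along(graphs)) {
    g <- graphs[[r]]
    if (config$filter_threshold_um2 > 0) {
      g <- filter_small_interfaces(g, config$filter_threshold_um2)
      say("replicate ", r, ": removed ", attr(g, "removed"),
          " small interfaces (< ", config$filter_threshold_um2, " um^2)")
    }
    g <- mark_buffer(g, config$buffer_depth)
    mt <- measure_topology(g)
    nt <- mt$nodes
    nt$replicate <- r
    nt$area_um2 <- g$nodes$area_um2
    nt$volume_um3 <- g$nodes$volume_um3
    measures[[r]] <- nt
  }
  measures <- do.call(rbind, measures)
  reported <- report_central(measures)
  say("reported cells (central, non-vascular): ", nrow(reported))

  athr <- bonferroni_threshold(config$alpha, config$m_comparisons)
  say(sprintf("significance threshold: %g / %d = %g", config$alpha,
              config$m_comparisons, athr))
  types <- sort(unique(reported$cell_type))
  comparisons <- list(); k <- 0L
  for (i in seq_along(types)) for (j in seq_along(types)) {
    if (j <= i) next
    va <- reported[reported$cell_type == types[i], ]
    vb <- reported[reported$cell_type == types[j], ]
    cd <- tryCatch(compare_degree(va$degree, vb$degree, alpha = athr),
                   error = function(e) {
                     say("degree comparison ", types[i], " vs ", types[j],
                         " undefined: ", conditionMessage(e))
                     data.frame(test = "chi_squared", statistic = NA_real_,
                                p_value = NA_real_, significant = FALSE)
                   })
    cb <- compare_bc(va$bc, vb$bc, alpha = athr)
    row <- cbind(data.frame(type_a = types[i], type_b = types[j]),
                 rbind(cd, cb))
    comparisons[[k <- k + 1L]] <- row
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL

  if (anyNA(reported$area_um2) || anyNA(reported$volume_um3)) {
    say("cell geometry unavailable; mutual-information panel skipped")
    mi <- data.frame(cell_type = character(), feature_1 = character(),
                     feature_2 = character(), mi_bits = numeric())
  } else {
    mi <- lapply(types, function(ty) {
      f <- reported[reported$cell_type == ty,
                    c("area_um2", "volume_um3", "degree", "bc")]
      tryCatch(cbind(cell_type = ty, mi_panel(f, k = config$mi_k)),
               error = function(e) {
                 say("MI panel skipped for ", ty, ": ",
                     conditionMessage(e))
                 NULL
               })
    })
    mi <- do.call(rbind, mi)
  }

  groups <- lapply(types, function(ty) reported$bc[reported$cell_type == ty])
  names(groups) <- types
  dmat <- distribution_distance_matrix(groups, measure = "bc")
  cl <- cluster_groups(dmat, k = min(config$cluster_k, length(groups)),
                       linkage = config$linkage)
  clusters <- data.frame(group = names(cl$labels),
                         cluster = unname(cl$labels))
  say("clusters: ",
      paste(sprintf("%s=%d", clusters$group, clusters$cluster),
            collapse = ", "))

  res <- list(measures = measures, reported = reported,
              comparisons = comparisons, mi = mi, distance = dmat,
              clusters = clusters, newick = cl$newick, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(measures, file.path(out_dir, "measures.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(mi, file.path(out_dir, "mi.csv"), row.names = FALSE)
    utils::write.csv(clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    writeLines(cl$newick, file.path(out_dir, "dendrogram.nwk"))
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  invisible(res)
}

#' Write or read a run configuration as YAML
#'
#' The configuration round-trips losslessly (the synthetic `spec` is
#' expanded into its ring table). Requires the `yaml` package.
#'
#' @param config a [run_config()]
#' @param path file path
#' @return `write_run_config` the path; `read_run_config` a `run_config`
#' @export
write_run_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config files require the 'yaml' package")
  x <- unclass(config)
  if (!is.null(x$spec)) {
    sp <- unclass(x$spec)
    sp$rings <- lapply(sp$rings, unclass)
    x$spec <- sp
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("config files require the 'yaml' package")
  x <- yaml::read_yaml(path)
  spec <- NULL
  if (!is.null(x$spec)) {
    rings <- lapply(x$spec$rings, function(r)
      ring_spec(r$cell_type, r$n_files, r$n_axial,
                r$interface_area_mean_um2, r$interface_area_cv,
                r$thickness_um))
    spec <- organ_spec(rings, x$spec$organ_length_um,
                       conduit_mode = x$spec$conduit_mode,
                       artifact_rate = x$spec$artifact_rate,
                       core_radius_um = x$spec$core_radius_um,
                       size_jitter_cv = x$spec$size_jitter_cv,
                       axial_phase = x$spec$axial_phase,
                       n_axial_cv = x$spec$n_axial_cv,
                       contact_wobble_q = x$spec$contact_wobble_q,
                       seed = x$spec$seed)
  }
  run_config(input = x$input, spec = spec,
             edge_list_paths = x$edge_list_paths,
             annotation_paths = x$annotation_paths,
             volume_paths = x$volume_paths, voxel_um = x$voxel_um,
             n_replicates = x$n_replicates,
             conduit_mode = x$conduit_mode,
             filter_threshold_um2 = x$filter_threshold_um2,
             buffer_depth = x$buffer_depth, alpha = x$alpha,
             m_comparisons = x$m_comparisons, mi_k = x$mi_k,
             cluster_k = x$cluster_k, linkage = x$linkage,
             seed = x$seed)
}
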