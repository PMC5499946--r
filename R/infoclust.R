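#' Nonparametric mutual information between two per-cell features
#'
#' Estimates the Shannon mutual information, in bits, between paired
#' samples, choosing the estimator by variable kind:
#' \itemize{
#'   \item continuous-continuous: Kraskov-Stoegbauer-Grassberger kNN
#'     estimator (algorithm 1, Chebyshev metric);
#'   \item discrete-continuous: Ross kNN estimator;
#'   \item discrete-discrete: plug-in estimate from the joint frequency
#'     table.
#' }
#' kNN estimates are noisy around zero and may come out slightly
#' negative; they are reported as-is unless `floor_at_zero = TRUE`.
#'
#' @param x,y equal-length paired samples
#' @param kind_x,kind_y `"continuous"` or `"discrete"`
#' @param k number of nearest neighbors for the kNN estimators
#' @param floor_at_zero clip negative kNN estimates to 0
#' @return estimated mutual information in bits
#' @export
mutual_information <- function(x, y, kind_x = "continuous",
                               kind_y = "continuous", k = 3L,
                               floor_at_zero = FALSE) {
  kind_x <- match.arg(kind_x, c("continuous", "discrete"))
  kind_y <- match.arg(kind_y, c("continuous", "discrete"))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  knn <- !(kind_x == "discrete" && kind_y == "discrete")
  if (knn && k >= n) stop("k must be smaller than the sample size")
  if (n < 20)
    warning("fewer than 20 observations; MI estimate will be unstable")
  if (kind_x == "discrete" && kind_y == "discrete") {
    tab <- table(x, y) / n
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    mi <- sum(tab[nz] * log2(tab[nz] / outer(px, py)[nz]))
  } else {
    if (k >= n) stop("k must be smaller than the sample size")
    if (kind_x == "continuous" && kind_y == "continuous")
      mi <- ksg_mi_nats(as.numeric(x), as.numeric(y), as.integer(k)) / log(2)
    else {
      d <- if (kind_x == "discrete") as.integer(x) else as.integer(y)
      cont <- if (kind_x == "discrete") as.numeric(y) else as.numeric(x)
      # classes observed once carry no neighborhood information for the
      # kNN estimate and are dropped (standard practice)
      keep <- d %in% as.integer(names(which(table(d) >= 2)))
      if (sum(keep) <= k)
        stop("too few points in multiply-observed discrete classes")
      mi <- ross_mi_nats(d[keep], cont[keep], as.integer(k)) / log(2)
    }
  }
  if (floor_at_zero) mi <- max(0, mi)
  mi
}

#' Mutual-information panel over geometric and topological features
#'
#' Estimates MI for the standard feature pairs — (area, volume),
#' (area, degree), (degree, bc), (area, bc), (volume, bc) — using the
#' kind-appropriate estimator (degree is discrete, the rest continuous).
#'
#' @param features data.frame with columns `area_um2`, `volume_um3`,
#'   `degree`, `bc`
#' @param k kNN parameter
#' @return data.frame with `feature_1`, `feature_2`, `mi_bits`
#' @export
mi_panel <- function(features, k = 3L) {
  need <- c("area_um2", "volume_um3", "degree", "bc")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  pairs <- list(c("area_um2", "volume_um3"), c("area_um2", "degree"),
                c("degree", "bc"), c("area_um2", "bc"),
                c("volume_um3", "bc"))
  kind <- c(area_um2 = "continuous", volume_um3 = "continuous",
            degree = "discrete", bc = "continuous")
  out <- lapply(pairs, function(p) {
    data.frame(feature_1 = p[1], feature_2 = p[2],
               mi_bits = mutual_information(features[[p[1]]],
                                            features[[p[2]]],
                                            kind[[p[1]]], kind[[p[2]]],
                                            k = k))
  })
  do.call(rbind, out)
}

#' Distribution-distance matrix between groups
#'
#' The test statistic comparing two distributions (chi-squared for the
#' discrete degree, Kolmogorov-Smirnov D for the continuous betweenness)
#' is used as the distance between groups. `transform = "inverse"`
#' reproduces the alternative reading where the reciprocal of the
#' statistic is taken as the distance.
#'
#' @param groups named list: group label -> numeric vector (pooled cells)
#'   or [grouped_sample()]
#' @param measure `"degree"` or `"bc"`
#' @param transform `"statistic"` (default) or `"inverse"`
#' @return symmetric matrix with zero diagonal
#' @export
distribution_distance_matrix <- function(groups,
                                         measure = c("degree", "bc"),
                                         transform = c("statistic",
                                                       "inverse")) {
  measure <- match.arg(measure)
  transform <- match.arg(transform)
  if (length(groups) < 2) stop("need at least 2 groups")
  labs <- names(groups)
  ng <- length(groups)
  D <- matrix(0, ng, ng, dimnames = list(labs, labs))
  for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
    s <- if (measure == "degree")
      compare_degree(groups[[i]], groups[[j]])$statistic
    else compare_bc(groups[[i]], groups[[j]])$statistic
    D[i, j] <- D[j, i] <- s
  }
  if (transform == "inverse") {
    off <- row(D) != col(D)
    pos <- D[off][D[off] > 0]
    cap <- if (length(pos)) 10 * max(1 / pos) else 1
    D[off] <- ifelse(D[off] > 0, 1 / D[off], cap)
  }
  D
}

#' Hierarchical clustering of groups from a distance matrix
#'
#' Agglomerative clustering on a precomputed distribution-distance matrix,
#' cut into `k` clusters; the dendrogram can be exported as Newick text.
#'
#' @param dmat symmetric distance matrix (zero diagonal), e.g. from
#'   [distribution_distance_matrix()]
#' @param k number of clusters to cut (<= number of groups)
#' @param linkage agglomeration method, default `"average"` (UPGMA)
#' @param newick_file optional path; when given, the dendrogram is
#'   written there in Newick format
#' @return list with `labels` (named cluster memberships), `hclust` (the
#'   tree), and `newick` (character)
#' @export
cluster_groups <- function(dmat, k = 3L, linkage = "average",
                           newick_file = NULL) {
  if (!isSymmetric(unname(dmat), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (any(diag(dmat) != 0)) stop("distance matrix must have zero diagonal")
  if (k > nrow(dmat)) stop("k cannot exceed the number of groups")
  hc <- hclust(as.dist(dmat), method = linkage)
  labels <- cutree(hc, k = k)
  phy <- ape::as.phylo(hc)
  newick <- ape::write.tree(phy)
  if (!is.null(newick_file)) writeLines(newick, newick_file)
  list(labels = labels, hclust = hc, newick = newick)
}
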