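#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (0 < alpha < 1)
#' @param m number of pairwise comparisons (>= 1); the study-wide default
#'   used throughout this package is 3200
#' @return `alpha / m`
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3200L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Grouped per-cell samples
#'
#' Container for one group's (genotype/species x cell type) per-cell
#' values across biological replicates.
#'
#' @param label group label
#' @param replicates list of numeric vectors, one per biological
#'   replicate (sizes may differ)
#' @return a `grouped_sample`
#' @export
grouped_sample <- function(label, replicates) {
  if (!length(replicates)) stop("need at least one replicate")
  if (any(!vapply(replicates, is.numeric, TRUE)))
    stop("replicates must be numeric vectors")
  if (any(lengths(replicates) == 0)) stop("empty replicate")
  structure(list(label = label, replicates = replicates),
            class = "grouped_sample")
}

pool_values <- function(x) {
  if (inherits(x, "grouped_sample")) unlist(x$replicates, use.names = FALSE)
  else as.numeric(x)
}

#' Mean binned frequency distribution across replicates
#'
#' Bins each replicate separately, normalizes counts to frequencies
#' summing to 1, and returns per-bin mean and standard deviation across
#' replicates — the distribution representation used for plotting degree
#' and betweenness histograms with replicate error bars.
#'
#' @param sample a [grouped_sample()]
#' @param breaks monotone numeric vector of bin edges; values are binned
#'   into `[b_i, b_{i+1})`, with the last bin closed
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_freq`, `sd_freq`
#' @export
binned_distribution <- function(sample, breaks) {
  stopifnot(inherits(sample, "grouped_sample"))
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  nb <- length(breaks) - 1L
  freq <- vapply(sample$replicates, function(v) {
    if (!length(v)) stop("empty replicate")
    f <- findInterval(v, breaks, rightmost.closed = TRUE)
    if (any(f < 1 | f > nb))
      stop("values outside the bin range")
    tabulate(f, nbins = nb) / length(v)
  }, numeric(nb))
  freq <- matrix(freq, nrow = nb)
  sd_freq <- if (ncol(freq) > 1) apply(freq, 1, sd) else rep(0, nb)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             mean_freq = rowMeans(freq), sd_freq = sd_freq)
}

#' Compare two degree distributions (chi-squared homogeneity test)
#'
#' Cells are pooled across replicates within each group; the contingency
#' table over the union of observed degree values is tested for
#' homogeneity. Categories with expected count below `min_expected` are
#' merged with their nearest neighbor category to keep the test valid.
#'
#' @param a,b [grouped_sample()]s (or plain numeric vectors) of degrees
#' @param alpha significance threshold applied to the p-value (use
#'   [bonferroni_threshold()] for corrected tests)
#' @param min_expected smallest tolerated expected count per category
#' @return data.frame row: `test`, `statistic`, `p_value`, `significant`
#' @export
compare_degree <- function(a, b, alpha = bonferroni_threshold(),
                           min_expected = 5) {
  va <- pool_values(a); vb <- pool_values(b)
  if (length(unique(c(va, vb))) < 2)
    stop("need at least 2 distinct degree values across groups")
  lv <- sort(unique(c(va, vb)))
  tab <- rbind(table(factor(va, levels = lv)),
               table(factor(vb, levels = lv)))
  tab <- merge_sparse_categories(tab, min_expected)
  if (ncol(tab) < 2)
    stop("degree categories collapse to one after merging; ",
         "chi-squared test undefined")
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  p <- res$p.value
  if (is.nan(p)) p <- 1   # zero-variance table (identical constant groups)
  data.frame(test = "chi_squared", statistic = unname(res$statistic),
             p_value = p, significant = p <= alpha)
}

# merge contingency-table columns until all expected counts reach the
# minimum; merging is always into the adjacent (nearest degree) column
merge_sparse_categories <- function(tab, min_expected) {
  repeat {
    if (ncol(tab) < 2) return(tab)
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- which(apply(exp, 2, min) < min_expected)
    if (!length(low)) return(tab)
    j <- low[1]
    k <- if (j == 1) 2 else j - 1
    tab[, k] <- tab[, k] + tab[, j]
    colnames(tab)[k] <- paste(colnames(tab)[k], colnames(tab)[j],
                              sep = "+")
    tab <- tab[, -j, drop = FALSE]
  }
}

#' Compare two betweenness distributions (two-sample Kolmogorov-Smirnov)
#'
#' Raw (untransformed) betweenness values are pooled across replicates
#' per group and compared by the asymptotic two-sample KS test.
#'
#' @inheritParams compare_degree
#' @return data.frame row: `test`, `statistic` (D), `p_value`,
#'   `significant`
#' @export
compare_bc <- function(a, b, alpha = bonferroni_threshold()) {
  va <- pool_values(a); vb <- pool_values(b)
  if (length(va) < 2 || length(vb) < 2)
    stop("need at least 2 values per group")
  res <- suppressWarnings(ks.test(va, vb, exact = FALSE))
  data.frame(test = "ks_2samp", statistic = unname(res$statistic),
             p_value = res$p.value,
             significant = res$p.value <= alpha)
}

#' Robustness analysis: coefficient of variation of log10 betweenness
#'
#' For each group and replicate, computes `CV = sd / |mean|` of the
#' log10-transformed betweenness values (zeros excluded by
#' [log10_transform()]), then tests for group differences with a one-way
#' ANOVA and Tukey's HSD. A group is flagged `distinct` when it differs
#' from every other group at `level`.
#'
#' @param groups named list: group label -> list of replicate numeric
#'   vectors of raw betweenness values
#' @param level significance level for the ANOVA and Tukey tests
#' @return list with `cv` (group, replicate, cv), `summary` (per-group
#'   mean/sd of CV and `distinct` flag), `anova_p`, and `tukey` (pairwise
#'   table)
#' @export
cv_analysis <- function(groups, level = 0.01) {
  if (length(groups) < 2) stop("need at least 2 groups")
  rows <- list(); k <- 0L
  for (g in names(groups)) {
    reps <- groups[[g]]
    if (length(reps) < 2) stop("group ", g, " needs >= 2 replicates")
    for (r in seq_along(reps)) {
      lt <- log10_transform(reps[[r]])
      m <- mean(lt$values)
      if (length(lt$values) < 2 || m == 0) {
        warning("CV undefined for group ", g, " replicate ", r,
                "; excluded")
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(group = g, replicate = r,
                              cv = sd(lt$values) / abs(m))
    }
  }
  cv <- do.call(rbind, rows)
  cv$group <- factor(cv$group, levels = names(groups))
  fit <- aov(cv ~ group, data = cv)
  anova_p <- summary(fit)[[1]]["group", "Pr(>F)"]
  tk <- as.data.frame(TukeyHSD(fit)$group)
  tk$pair <- rownames(tk)
  rownames(tk) <- NULL
  distinct <- vapply(names(groups), function(g) {
    sel <- grepl(paste0("(^", g, "-)|(-", g, "$)"), tk$pair)
    sum(sel) == length(groups) - 1 && all(tk$`p adj`[sel] <= level)
  }, TRUE)
  summary <- data.frame(group = names(groups),
                        mean_cv = tapply(cv$cv, cv$group, mean),
                        sd_cv = tapply(cv$cv, cv$group, sd),
                        distinct = distinct)
  rownames(summary) <- NULL
  list(cv = cv, summary = summary, anova_p = anova_p, tukey = tk)
}
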