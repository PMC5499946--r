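test_that("mutual information recovers closed-form values", {
  # independent variables: MI near 0
  set.seed(1)
  x <- rnorm(5000); y <- rnorm(5000)
  expect_lt(abs(mutual_information(x, y)), 0.05)

  # discrete identity: MI = H = log2(4) exactly under the plug-in
  d <- rep(1:4, each = 250)
  expect_equal(mutual_information(d, d, "discrete", "discrete"), 2.0)

  # correlated Gaussian: MI = -0.5 log2(1 - rho^2)
  set.seed(2)
  rho <- 0.9; n <- 10000
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(mutual_information(x, y), -0.5 * log2(1 - rho^2),
               tolerance = 0.05 / 1.198)
})

test_that("kNN MI estimator is accurate across correlation strengths", {
  set.seed(3)
  n <- 10000
  for (rho in c(0, 0.5, 0.9)) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    truth <- -0.5 * log2(1 - rho^2)
    expect_lt(abs(mutual_information(x, y) - truth), 0.05)
  }
})

test_that("MI is symmetric and respects deterministic coarsening", {
  set.seed(4)
  x <- rnorm(2000); y <- 0.7 * x + rnorm(2000)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  d <- sample(1:3, 2000, TRUE)
  expect_identical(
    mutual_information(d, y, "discrete", "continuous"),
    mutual_information(y, d, "continuous", "discrete"))
  # data-processing: coarsening y cannot add information (up to noise)
  f <- as.integer(cut(y, breaks = quantile(y, 0:4 / 4),
                      include.lowest = TRUE))
  mi_fine <- mutual_information(x, y)
  mi_coarse <- mutual_information(f, x, "discrete", "continuous")
  expect_lt(mi_coarse, mi_fine + 0.05)
})

test_that("MI input validation", {
  expect_error(mutual_information(1:5, 1:4), "length")
  expect_error(mutual_information(rnorm(10), rnorm(10), k = 10), "k")
  expect_warning(mutual_information(rnorm(10), rnorm(10)), "20")
  set.seed(5)
  x <- rnorm(200)
  expect_gte(mutual_information(x, x + rnorm(200), floor_at_zero = TRUE), 0)
})

test_that("the MI panel ranks deterministic dependence highest", {
  set.seed(6)
  n <- 600
  area <- rlnorm(n, 5, 0.4)
  feats <- data.frame(area_um2 = area, volume_um3 = 3 * area,
                      degree = sample(4:9, n, TRUE),
                      bc = rlnorm(n, -6, 1))
  panel <- mi_panel(feats)
  expect_equal(nrow(panel), 5)
  top <- panel$mi_bits[panel$feature_1 == "area_um2" &
                         panel$feature_2 == "volume_um3"]
  expect_equal(top, max(panel$mi_bits))

  # fully independent features: everything near zero
  feats2 <- data.frame(area_um2 = rlnorm(n, 5, 0.4),
                       volume_um3 = rlnorm(n, 7, 0.4),
                       degree = sample(4:9, n, TRUE),
                       bc = rlnorm(n, -6, 1))
  expect_true(all(abs(mi_panel(feats2)$mi_bits) < 0.05))
})

test_that("generated organs couple size to size, not size to topology", {
  g <- generate_organ(default_organ_spec(seed = 2))
  g <- mark_buffer(g, 2)
  mt <- measure_topology(g, c("degree", "bc"))
  nodes <- mt$nodes
  nodes$area_um2 <- g$nodes$area_um2
  nodes$volume_um3 <- g$nodes$volume_um3
  rep_tab <- report_central(nodes)
  f <- rep_tab[rep_tab$cell_type == "atrichoblast",
               c("area_um2", "volume_um3", "degree", "bc")]
  panel <- mi_panel(f)
  mi_av <- panel$mi_bits[panel$feature_1 == "area_um2" &
                           panel$feature_2 == "volume_um3"]
  mi_ab <- panel$mi_bits[panel$feature_1 == "area_um2" &
                           panel$feature_2 == "bc"]
  expect_gt(mi_av, mi_ab)
})

test_that("distance matrices are symmetric statistics with zero diagonal", {
  set.seed(7)
  groups <- list(a = rlnorm(200, -6, 1), b = rlnorm(200, -6, 1),
                 c = rlnorm(200, -3, 1))
  D <- distribution_distance_matrix(groups, "bc")
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), names(groups)))
  # the shifted group is farther from both others
  expect_gt(min(D["c", c("a", "b")]), D["a", "b"])

  same <- list(a = c(1:50) / 10, b = c(1:50) / 10)
  D0 <- distribution_distance_matrix(same, "bc")
  expect_equal(unname(D0), matrix(0, 2, 2))

  dg <- list(a = sample(4:8, 300, TRUE), b = sample(4:8, 300, TRUE))
  Dd <- distribution_distance_matrix(dg, "degree")
  expect_equal(Dd, t(Dd))

  Di <- distribution_distance_matrix(groups, "bc", transform = "inverse")
  expect_gt(Di["a", "b"], Di["a", "c"])
})

test_that("clustering recovers separated families and ignores group order", {
  set.seed(9)
  fam <- function(mu) lapply(1:3, function(i) rnorm(150, mu, 0.2))
  groups <- c(fam(0), fam(5), fam(10))
  names(groups) <- paste0("g", 1:9)
  D <- distribution_distance_matrix(groups, "bc")
  cl <- cluster_groups(D, k = 3)
  expect_equal(length(unique(cl$labels)), 3)
  expect_equal(unname(cl$labels[1:3]), rep(cl$labels[[1]], 3))
  expect_equal(unname(cl$labels[4:6]), rep(cl$labels[[4]], 3))
  expect_equal(unname(cl$labels[7:9]), rep(cl$labels[[7]], 3))

  # permuting groups permutes labels consistently
  perm <- sample(9)
  cl2 <- cluster_groups(D[perm, perm], k = 3)
  agree <- outer(cl$labels[perm], cl$labels[perm], "==") ==
    outer(cl2$labels, cl2$labels, "==")
  expect_true(all(agree))

  # k = number of groups: singletons
  cl_all <- cluster_groups(D, k = 9)
  expect_equal(sort(unname(cl_all$labels)), 1:9)
  expect_error(cluster_groups(D, k = 10), "exceed")

  # dendrogram is valid Newick
  phy <- ape::read.tree(text = cl$newick)
  expect_equal(sort(phy$tip.label), sort(names(groups)))
})

test_that("clustering is deterministic given the matrix", {
  set.seed(10)
  M <- matrix(runif(36), 6, 6)
  M <- M + t(M); diag(M) <- 0
  dimnames(M) <- list(letters[1:6], letters[1:6])
  expect_identical(cluster_groups(M, 2)$labels,
                   cluster_groups(M, 2)$labels)
})
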