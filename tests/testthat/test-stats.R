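test_that("Bonferroni threshold reproduces the study-wide level", {
  expect_equal(bonferroni_threshold(0.05, 3200), 1.5625e-5)
  expect_equal(signif(bonferroni_threshold(0.05, 3200), 3), 1.56e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("binned distributions average replicate frequencies", {
  one <- grouped_sample("g", list(c(1, 2, 2, 3)))
  b <- binned_distribution(one, breaks = c(1, 2, 3, 4))
  expect_equal(b$sd_freq, rep(0, 3))
  expect_equal(sum(b$mean_freq), 1)

  same <- grouped_sample("g", list(c(1, 2), c(1, 2)))
  expect_equal(binned_distribution(same, c(1, 2, 3))$sd_freq, c(0, 0))

  two <- grouped_sample("g", list(c(1, 1, 2), c(1, 2, 2)))
  b2 <- binned_distribution(two, breaks = c(1, 2, 3))
  expect_equal(b2$mean_freq, c(0.5, 0.5))
  expect_equal(b2$sd_freq, rep(sd(c(2 / 3, 1 / 3)), 2), tolerance = 1e-12)
  expect_equal(b2$sd_freq, rep(0.2357, 2), tolerance = 1e-3)

  # frequencies sum to 1 per replicate for arbitrary data
  set.seed(3)
  r <- lapply(1:3, function(i) sample(0:10, 50, TRUE))
  g <- grouped_sample("g", r)
  bb <- binned_distribution(g, breaks = seq(-0.5, 10.5, by = 1))
  expect_equal(sum(bb$mean_freq), 1, tolerance = 1e-12)
  expect_error(binned_distribution(grouped_sample("g", list(1)),
                                   c(2, 1)), "increasing")
})

test_that("degree comparison is the textbook chi-squared homogeneity test", {
  a <- grouped_sample("a", list(rep(c(4, 6), c(50, 50))))
  b <- grouped_sample("b", list(rep(c(4, 6), c(90, 10))))
  res <- compare_degree(a, b)
  # independent oracle: sum (O-E)^2/E on the 2x2 table
  O <- rbind(c(50, 50), c(90, 10))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_lt(res$p_value, 1e-5)
  expect_true(res$significant)

  same <- compare_degree(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # random tables match the oracle after category merging is disabled
  set.seed(5)
  for (rep in 1:10) {
    x <- sample(3:6, 300, TRUE)
    y <- sample(3:6, 260, TRUE, prob = c(1, 2, 2, 1))
    res <- compare_degree(x, y, min_expected = 0)
    lv <- sort(unique(c(x, y)))
    O <- rbind(table(factor(x, lv)), table(factor(y, lv)))
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  }
})

test_that("sparse degree categories are merged into neighbors", {
  x <- c(rep(4, 100), rep(5, 100), 12)     # degree 12 seen once
  y <- c(rep(4, 80), rep(5, 120))
  res <- compare_degree(x, y)
  expect_true(is.finite(res$statistic))
  expect_error(compare_degree(rep(4, 10), rep(4, 12)), "distinct")
})

test_that("betweenness comparison is a two-sample KS test", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  y <- c(0.3, 0.4, 0.5, 0.6)
  res <- compare_bc(x, y)
  expect_equal(res$statistic, 0.5)

  self <- suppressWarnings(compare_bc(x, x))
  expect_equal(self$statistic, 0)

  disjoint <- compare_bc(1:10 / 100, 5 + 1:10 / 100)
  expect_equal(disjoint$statistic, 1)
  expect_error(compare_bc(1, c(1, 2)), "at least 2")
})

test_that("CV analysis flags a divergent group", {
  # CV of {1,2,3} as log10 values: sd 1, mean 2 after rescaling
  lt <- c(1, 2, 3)
  expect_equal(sd(lt) / mean(lt), 0.5)

  set.seed(21)
  mk <- function(mu) lapply(1:3, function(i) 10^rnorm(60, mu, 0.3))
  groups <- list(a = mk(-2), b = mk(-2), c = mk(-6))
  res <- cv_analysis(groups)
  expect_lt(res$anova_p, 0.01)
  expect_true(res$summary$distinct[res$summary$group == "c"])
  expect_false(res$summary$distinct[res$summary$group == "a"])
  expect_true(all(res$cv$cv >= 0))

  # scale invariance: multiplying log10 values by c > 0 keeps CV
  v <- groups$a[[1]]
  cv1 <- sd(log10(v)) / abs(mean(log10(v)))
  cv2 <- sd(3 * log10(v)) / abs(mean(3 * log10(v)))
  expect_equal(cv1, cv2)
})

test_that("KS comparisons keep their size under the null", {
  set.seed(8)
  alpha <- bonferroni_threshold(0.05, 3200)
  rej <- 0L
  for (i in 1:200) {
    a <- rlnorm(150, -6, 1)
    b <- rlnorm(150, -6, 1)
    rej <- rej + (compare_bc(a, b, alpha = alpha)$significant)
  }
  expect_lte(rej, 1)
})
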