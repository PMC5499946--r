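mk_vol <- function(labs, vx = c(1, 1, 1)) labeled_volume(labs, vx)

test_that("concentration is total signal over physical volume", {
  labs <- array(1L, dim = c(2, 2, 2))
  sig <- array(5, dim = c(2, 2, 2))
  vol <- mk_vol(labs)
  # single cell needs a second label to build a volume? no: quantify only
  ct <- quantify_concentration(vol, sig)
  expect_equal(ct$raw_concentration, 5.0)

  labs2 <- array(0L, dim = c(1, 1, 2))
  labs2[1, 1, ] <- 1L
  sig2 <- array(c(2, 4), dim = c(1, 1, 2))
  ct2 <- quantify_concentration(mk_vol(labs2, c(0.5, 1, 1)), sig2)
  expect_equal(ct2$raw_concentration, 6 / 1.0)

  ct3 <- quantify_concentration(vol, array(0, dim = c(2, 2, 2)))
  expect_equal(ct3$raw_concentration, 0)

  expect_error(quantify_concentration(vol, array(0, dim = c(2, 2, 3))),
               "shape")
})

test_that("signal is conserved: sum(concentration x volume) = total signal", {
  set.seed(2)
  for (rep in 1:5) {
    labs <- random_labeled_array(800)
    vx <- runif(3, 0.3, 1.5)
    sig <- array(runif(length(labs), 0, 10), dim = dim(labs))
    ct <- quantify_concentration(mk_vol(labs, vx), sig)
    total <- sum(sig[!(labs %in% 0L)])
    expect_equal(sum(ct$raw_concentration * ct$volume_um3), total,
                 tolerance = 1e-9)
  }
})

test_that("mean normalization forces a unit pooled mean and is idempotent", {
  tab <- data.frame(cell_id = 1:3, cell_type = "trichoblast",
                    raw_concentration = c(1, 2, 3))
  out <- mean_normalize(tab)
  expect_equal(out$normalized_concentration, c(0.5, 1, 1.5))
  expect_equal(mean(out$normalized_concentration), 1)

  allsame <- data.frame(cell_id = 1:4, raw_concentration = rep(2, 4))
  expect_equal(mean_normalize(allsame)$normalized_concentration,
               rep(1, 4))

  twice <- out
  twice$raw_concentration <- out$normalized_concentration
  expect_equal(mean_normalize(twice)$normalized_concentration,
               out$normalized_concentration)

  zero <- data.frame(raw_concentration = c(0, 0))
  expect_error(mean_normalize(zero), "mean")
})

test_that("synthetic signal volumes follow the per-type means", {
  sp <- toy_organ_spec(seed = 3)
  sp$contact_wobble_q <- 0
  g <- generate_organ(sp)
  vol <- rasterize_organ(sp, c(2, 1, 1))
  means <- c(trichoblast = 1, atrichoblast = 2, outer_cortex = 0.5,
             inner_cortex = 0.5, endodermis = 0.5, vasculature = 0.1)
  sv <- generate_signal_volume(vol, g$nodes, means, noise_sd = 0)
  ct <- quantify_concentration(vol, sv, annotation = g$nodes)
  # per-voxel signal integrates to signal/voxel-volume per um^3
  expect_equal(ct$raw_concentration,
               unname(means[ct$cell_type]) / prod(vol$voxel_um),
               tolerance = 1e-12)
  expect_error(generate_signal_volume(vol, g$nodes, means[-1]),
               "missing cell type")
})

test_that("the epidermal concentration differential is detected", {
  sp <- toy_organ_spec(seed = 4)
  sp$contact_wobble_q <- 0
  g <- generate_organ(sp)
  vol <- rasterize_organ(sp, c(2, 1, 1))
  means <- c(trichoblast = 1, atrichoblast = 2, outer_cortex = 0.5,
             inner_cortex = 0.5, endodermis = 0.5, vasculature = 0.1)
  sv <- generate_signal_volume(vol, g$nodes, means, noise_sd = 0.1,
                               seed = 5)
  ct <- quantify_concentration(vol, sv, annotation = g$nodes)
  epi <- ct[ct$cell_type %in% c("trichoblast", "atrichoblast"), ]
  expect_gte(min(table(epi$cell_type)), 40)
  epi <- mean_normalize(epi)
  res <- compare_cell_types(epi)
  expect_true(res$significant)
  expect_lte(res$p_value, 0.001)
  expect_gt(res$mean_a, res$mean_b)   # atrichoblast higher

  swapped <- compare_cell_types(epi, type_a = "trichoblast",
                                type_b = "atrichoblast")
  expect_equal(swapped$statistic, -res$statistic)

  same <- epi
  same$normalized_concentration <- rep(c(1, 1.01), length.out = nrow(epi))
  expect_false(compare_cell_types(same)$significant)
  expect_error(compare_cell_types(epi, type_a = "endodermis"),
               "at least 2")
})

test_that("t-test size holds under equal means", {
  set.seed(6)
  rej <- 0L
  for (i in 1:300) {
    tab <- data.frame(cell_type = rep(c("atrichoblast", "trichoblast"),
                                      each = 40),
                      raw_concentration = rnorm(80, 5, 1))
    tab <- mean_normalize(tab)
    rej <- rej + compare_cell_types(tab)$significant
  }
  expect_lte(rej, 3)
})
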