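test_that("scene generation is a pure function of (config, seed)", {
  cfg <- scene_config(n_cells = 20, seed = 5,
                      bacteria = list(n_single = 10, n_clusters = 1,
                                      cluster_size_range = c(4, 8),
                                      single_intensity_mean = 60,
                                      single_intensity_sd = 12, sigma = 1))
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth, b$truth)
  # different seed, different scene
  cfg2 <- scene_config(n_cells = 20, seed = 6)
  expect_false(identical(generate_scene(cfg2)$channels$gfp, a$channels$gfp))
})

test_that("zero rates give pure background under the illumination field", {
  f <- illum_field(I0 = 10, xc = 100, xR = 80, sigma_y = 40, yc = 30)
  cfg <- scene_config(image_shape = c(60, 200), n_cells = 15,
                      rate_levels = c(anterior = 0, middle = 0, posterior = 0),
                      noise = list(gaussian_sd = 0, poisson = FALSE),
                      illumination = f, seed = 2)
  sc <- generate_scene(cfg)
  fld <- eval_illum_field(f, c(60, 200))
  expect_equal(sc$channels$gfp, 10 * fld / max(fld), tolerance = 1e-12)
})

test_that("ground-truth region labels and rate ratios hold by construction", {
  cfg <- scene_config(image_shape = c(100, 600), n_cells = 150,
                      cell_radius = 3, min_separation = 9, seed = 9)
  sc <- generate_scene(cfg)
  cells <- sc$truth$cells
  ap <- cells$x / (600 - 1)
  expect_identical(cells$region,
                   ifelse(ap < 0.25, "anterior",
                          ifelse(ap < 0.75, "middle", "posterior")))
  # the configured lognormal medians have ratio 2 (anterior) and 1.6
  # (posterior) to the middle; check the generating parameters, not a sample
  expect_equal(unname(cfg$rate_levels["anterior"] / cfg$rate_levels["middle"]), 2)
  expect_equal(unname(cfg$rate_levels["posterior"] / cfg$rate_levels["middle"]), 1.6)
})

test_that("region rate medians are recovered from ground truth at n >= 50 per region", {
  # direct resimulation: sample medians of 50+ lognormal draws concentrate
  # around the configured regional medians
  ratios <- sapply(1:8, function(s) {
    cfg <- scene_config(image_shape = c(120, 800), n_cells = 200,
                        cell_radius = 3, min_separation = 9, seed = s)
    tl <- generate_timelapse(cfg, c(0, 1, 2))
    cells <- tl$truth$cells
    med <- tapply(cells$rate, cells$region, stats::median)
    c(med[["anterior"]] / med[["middle"]], med[["posterior"]] / med[["middle"]])
  })
  expect_lt(abs(mean(ratios[1, ]) - 2.0), 0.3)
  expect_lt(abs(mean(ratios[2, ]) - 1.6), 0.24)
})

test_that("total GFP signal decomposes into background plus per-cell integrals", {
  cfg <- scene_config(image_shape = c(80, 240), n_cells = 10, cell_radius = 3,
                      noise = list(gaussian_sd = 0, poisson = FALSE),
                      min_separation = 15, seed = 4)
  sc <- generate_scene(cfg, time = 6)
  cells <- sc$truth$cells
  # independent per-cell rendering and direct summation
  per_cell <- sapply(seq_len(nrow(cells)), function(i) {
    amp <- cells$rate[i] * 6
    g <- expand.grid(r = 1:80, c = 1:240)
    sum(amp * exp(-(((g$r - 1) - cells$y[i])^2 +
                      ((g$c - 1) - cells$x[i])^2) / (2 * 9)))
  })
  expect_equal(sum(sc$channels$gfp),
               10 * 80 * 240 + sum(per_cell), tolerance = 1e-6)
})

test_that("noiseless time-lapse traces are exactly affine in time", {
  cfg <- scene_config(image_shape = c(60, 200), n_cells = 4, cell_radius = 3,
                      noise = list(gaussian_sd = 0, poisson = FALSE),
                      rate_sdlog = 0, min_separation = 50, seed = 11)
  tl <- generate_timelapse(cfg, 0:5)
  tr <- extract_traces(tl, tracks_from_truth(tl))
  for (id in unique(tr$cell_id)) {
    v <- tr$value[tr$cell_id == id]
    d <- diff(v)
    expect_equal(max(abs(d - d[1])), 0, tolerance = 1e-9 * max(v))
  }
})

test_that("frames before every onset equal frame zero up to noise", {
  cfg <- scene_config(image_shape = c(50, 150), n_cells = 5, cell_radius = 3,
                      noise = list(gaussian_sd = 0, poisson = FALSE),
                      onset = list(t0 = 3, jitter = 0), seed = 13)
  tl <- generate_timelapse(cfg, c(0, 1, 2, 2.9))
  for (k in 2:4) expect_identical(tl$frames[[k]]$gfp, tl$frames[[1]]$gfp)
})

test_that("time grids must be valid and packing limits are enforced", {
  cfg <- scene_config(n_cells = 5, seed = 1)
  expect_error(generate_timelapse(cfg, c(-1, 0, 1)), "nonnegative")
  expect_error(generate_timelapse(cfg, c(0, 1, 1)), "increasing")
  expect_error(scene_config(image_shape = c(20, 20), n_cells = 500),
               "packing")
  expect_error(scene_config(region_fractions = c(anterior = 0.3, middle = 0.3,
                                                 posterior = 0.3)),
               "sum to 1")
})

test_that("spatial count generation is deterministic and matches its spec", {
  spec <- list(flat = rep(0.01, 5), graded = c(0.02, 0.015, 0.01, 0.01, 0.01))
  a <- generate_spatial_counts(500, spec, n_bins = 5, seed = 3)
  b <- generate_spatial_counts(500, spec, n_bins = 5, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_identical(a$coords, b$coords)
  expect_error(generate_spatial_counts(10, list(g = c(-0.1, 0.1)), 2),
               "nonnegative")
})

test_that("specified AP frequency profiles are recovered at large n", {
  # law of large numbers at n = 10,000: anterior bin frequency 2x the rest
  spec <- list(ushape = c(0.02, 0.01, 0.01, 0.01, 0.01))
  sim <- generate_spatial_counts(10000, spec, n_bins = 5, seed = 7)
  freq <- sim$counts[, "ushape"] / rowSums(sim$counts)
  bin <- sim$truth$bin
  m <- tapply(freq, bin, mean)
  expect_equal(unname(m[1] / mean(m[2:5])), 2, tolerance = 0.1)
  # flat gene: bin means statistically indistinguishable
  sim2 <- generate_spatial_counts(10000, list(flat = rep(0.01, 5)), 5, seed = 8)
  freq2 <- sim2$counts[, "flat"] / rowSums(sim2$counts)
  m2 <- tapply(freq2, sim2$truth$bin, mean)
  expect_lt(max(m2) / min(m2), 1.1)
})
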