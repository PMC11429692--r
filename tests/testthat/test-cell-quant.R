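test_that("disk sums match lattice enumeration, including the 113-pixel disk", {
  ones <- matrix(1, 40, 40)
  m <- disk_sum(ones, tibble::tibble(x = 20, y = 20), radius = 6)
  expect_identical(m$summed_intensity, 113)
  expect_identical(m$n_pixels_in_disk, 113L)

  delta <- matrix(0, 21, 21)
  delta[11, 11] <- 4.5
  expect_identical(disk_sum(delta, tibble::tibble(x = 10, y = 10), 6)$summed_intensity,
                   4.5)

  # corner center: only in-bounds pixels counted, against the loop oracle
  set.seed(14)
  img <- matrix(stats::runif(35 * 45), 35, 45)
  corner <- disk_sum(img, tibble::tibble(x = 0, y = 0), 6)
  oracle <- bf_disk_sum(img, 0, 0, 6)
  expect_equal(corner$summed_intensity, oracle$sum)
  expect_identical(corner$n_pixels_in_disk, oracle$n)
})

test_that("disk sums agree with the brute-force oracle at random fractional centers", {
  set.seed(15)
  img <- matrix(stats::rexp(50 * 70), 50, 70)
  centers <- tibble::tibble(x = stats::runif(40, 0, 69),
                            y = stats::runif(40, 0, 49))
  got <- disk_sum(img, centers, radius = 6)
  for (k in seq_len(nrow(centers))) {
    oracle <- bf_disk_sum(img, centers$x[k], centers$y[k], 6)
    expect_equal(got$summed_intensity[k], oracle$sum)
    expect_identical(got$n_pixels_in_disk[k], oracle$n)
  }
})

test_that("disk sums reject out-of-bounds centers and are monotone in intensity", {
  img <- matrix(1, 10, 10)
  expect_error(disk_sum(img, tibble::tibble(x = c(2, 12), y = c(2, 2))),
               "rows: 2")
  set.seed(16)
  base <- matrix(stats::runif(400), 20, 20)
  centers <- tibble::tibble(x = c(5, 14.5), y = c(6, 9))
  before <- disk_sum(base, centers, 5)$summed_intensity
  bump <- base
  bump[8, 8] <- bump[8, 8] + 3
  after <- disk_sum(bump, centers, 5)$summed_intensity
  expect_true(all(after >= before))
})

test_that("reporter dose linearity: doubling amplitude doubles median disk sum", {
  mk <- function(mult, seed) {
    cfg <- scene_config(image_shape = c(80, 300), n_cells = 40, cell_radius = 3,
                        rate_levels = c(anterior = 2, middle = 1,
                                        posterior = 1.6) * mult,
                        min_separation = 12, seed = seed)
    sc <- generate_scene(cfg)
    m <- disk_sum(sc$channels$gfp, sc$truth$cells, 6)
    stats::median(m$summed_intensity - 10 * m$n_pixels_in_disk)
  }
  r <- mk(2, 31) / mk(1, 31)  # same seed: same cells, doubled expression
  expect_equal(r, 2, tolerance = 0.02)
})

test_that("nuclear segmentation counts well-separated blobs and drops speckles", {
  blank <- array(0, c(20, 20, 8))
  res <- segment_nuclei(blank, blur_sigma = 1, min_voxels = 5)
  expect_identical(nrow(res$nuclei), 0L)

  st <- array(0, c(30, 60, 10))
  put_blob <- function(st, cy, cx, cz, a = 100, s = 1.5) {
    for (i in -4:4) for (j in -4:4) for (k in -3:3) {
      st[cy + i, cx + j, cz + k] <- st[cy + i, cx + j, cz + k] +
        a * exp(-(i^2 + j^2 + k^2) / (2 * s^2))
    }
    st
  }
  st <- put_blob(st, 10, 15, 5)
  st <- put_blob(st, 20, 45, 5)
  res <- segment_nuclei(st, blur_sigma = 1, min_voxels = 10)
  expect_identical(nrow(res$nuclei), 2L)
  # labels cover both blob peaks
  expect_true(res$labels[10, 15, 5] > 0 && res$labels[20, 45, 5] > 0)
  expect_true(res$labels[10, 15, 5] != res$labels[20, 45, 5])

  # sub-minimum speckles (bacteria-sized) are excluded
  spk <- st
  spk[3, 3, 2] <- 500
  res2 <- segment_nuclei(spk, blur_sigma = 0, threshold = 10, min_voxels = 10)
  expect_identical(nrow(res2$nuclei), 2L)

  expect_error(segment_nuclei(st, blur_sigma = 0, threshold = -5),
               "degenerate")
})

test_that("shell correction is exact on constant backgrounds", {
  st <- array(7, c(12, 12, 8))  # background b = 7
  lab <- array(0L, dim(st))
  lab[5:7, 5:7, 4:5] <- 1L     # 18-voxel nucleus
  sig <- st
  sig[lab == 1L] <- 7 + 11     # signal s = 11 on top of b
  rec <- shell_corrected_sum(sig, lab, dilation_px = 2)
  expect_equal(rec$corrected_sum, 18 * 11)
  expect_false(rec$negative_flag)

  # zero background: corrected equals raw
  sig0 <- array(0, dim(st))
  sig0[lab == 1L] <- 3
  rec0 <- shell_corrected_sum(sig0, lab)
  expect_equal(rec0$corrected_sum, rec0$raw_sum)
})

test_that("shell correction is invariant to additive constants and matches the scan oracle", {
  set.seed(18)
  st <- array(stats::runif(10 * 10 * 6), c(10, 10, 6))
  lab <- array(0L, dim(st))
  lab[4:6, 4:6, 3:4] <- 1L
  a <- shell_corrected_sum(st, lab)$corrected_sum
  b <- shell_corrected_sum(st + 123.4, lab)$corrected_sum
  expect_equal(a, b, tolerance = 1e-9)
  expect_equal(a, bf_shell_sum(st, lab, 1L), tolerance = 1e-9)

  # linear gradient: error bounded by |grad| * n * dilation
  grad <- array(rep(seq_len(10), each = 1), c(10, 10, 6)) * 0.5
  sig <- grad
  sig[lab == 1L] <- sig[lab == 1L] + 9
  got <- shell_corrected_sum(sig, lab)$corrected_sum
  expect_lt(abs(got - 18 * 9), 0.5 * 18 * 2)
  expect_equal(got, bf_shell_sum(sig, lab, 1L), tolerance = 1e-9)
})

test_that("shells exclude voxels of neighboring nuclei", {
  st <- array(0, c(8, 14, 4))
  lab <- array(0L, dim(st))
  lab[3:5, 3:5, 2:3] <- 1L
  lab[3:5, 7:9, 2:3] <- 2L   # 2 px gap: dilated shells would reach each other
  sig <- st
  sig[lab == 2L] <- 1000     # bright neighbor must not leak into shell 1
  rec <- shell_corrected_sum(sig, lab, dilation_px = 2)
  expect_equal(rec$corrected_sum[1], 0)
})

test_that("response classification splits partial from complete like the exhaustive oracle", {
  medians <- tibble::tibble(larva_id = 1:5,
                            median_intensity = c(10, 11, 12, 1000, 1100))
  got <- classify_response(medians, mock_medians = c(4, 5, 6))
  expect_identical(got$class, c("partial", "partial", "partial",
                                "complete", "complete"))
  thr_oracle <- bf_split2(log10(medians$median_intensity))
  expect_equal(log10(got$split_threshold[1]), thr_oracle, tolerance = 1e-9)

  # all below the mock floor
  low <- tibble::tibble(larva_id = 1:3, median_intensity = c(4, 5, 4.5))
  expect_identical(classify_response(low, mock_medians = c(4, 5, 6))$class,
                   rep("none", 3))

  # identical medians above the floor: degenerate, warned
  same <- tibble::tibble(larva_id = 1:3, median_intensity = c(50, 50, 50))
  expect_warning(res <- classify_response(same, mock_medians = c(1, 2)),
                 "degenerate")
  expect_true(all(res$degenerate))
  expect_identical(length(unique(res$class)), 1L)

  expect_error(classify_response(medians), "mock")
  one <- tibble::tibble(larva_id = 1, median_intensity = 100)
  expect_error(classify_response(one, mock_medians = c(1, 2)), "split_threshold")
})

test_that("classification is invariant to positive rescaling of all medians", {
  set.seed(19)
  medians <- tibble::tibble(larva_id = 1:8,
                            median_intensity = c(stats::runif(4, 8, 30),
                                                 stats::runif(4, 500, 3000)))
  a <- classify_response(medians, mock_medians = c(1, 2, 1.5))
  scaled <- dplyr::mutate(medians, median_intensity = median_intensity * 37)
  b <- classify_response(scaled, mock_medians = c(1, 2, 1.5) * 37)
  expect_identical(a$class, b$class)
})
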