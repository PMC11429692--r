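test_that("traces from a static scene are constant and match disk_sum", {
  set.seed(61)
  frame <- matrix(stats::runif(40 * 60, 0, 5), 40, 60)
  frames <- list(frame, frame, frame)
  tracks <- tidyr::crossing(tibble::tibble(larva_id = 1, cell_id = 1:3,
                                           x = c(10, 30, 50), y = c(10, 20, 30)),
                            frame = 0:2)
  tr <- extract_traces(frames, tracks, radius = 5, times = c(0, 1, 2))
  per_cell <- split(tr$value, tr$cell_id)
  for (v in per_cell) expect_true(all(v == v[1]))
  # oracle equivalence against independent disk_sum calls
  ds <- disk_sum(frame, tibble::tibble(x = c(10, 30, 50), y = c(10, 20, 30)), 5)
  expect_equal(sort(unique(tr$value)), sort(ds$summed_intensity))
})

test_that("tracking a moving blob reproduces the static trace", {
  mk_frame <- function(cx) {
    img <- matrix(0, 30, 80)
    for (i in -6:6) for (j in -6:6) {
      img[15 + i, cx + 1 + j] <- 50 * exp(-(i^2 + j^2) / (2 * 4))
    }
    img
  }
  xs <- c(20, 30, 40, 55)
  frames <- lapply(xs, mk_frame)
  moving <- tibble::tibble(larva_id = 1, cell_id = 1, frame = 0:3,
                           x = xs, y = 15)
  tr <- extract_traces(frames, moving, radius = 6, times = 0:3)
  expect_equal(max(abs(tr$value - tr$value[1])), 0, tolerance = 1e-9)

  static <- extract_traces(list(mk_frame(20)),
                           tibble::tibble(larva_id = 1, cell_id = 1, frame = 0,
                                          x = 20, y = 15),
                           radius = 6, times = 0)
  expect_equal(tr$value[1], static$value[1], tolerance = 1e-9)
})

test_that("missing frames are flagged but traces are still returned", {
  frames <- list(matrix(1, 10, 10), matrix(2, 10, 10), matrix(3, 10, 10))
  tracks <- tibble::tibble(larva_id = 1, cell_id = 1, frame = c(0, 2),
                           x = 5, y = 5)
  expect_warning(tr <- extract_traces(frames, tracks, radius = 2,
                                      times = 0:2),
                 "gaps")
  expect_identical(nrow(tr), 2L)
  expect_error(extract_traces(frames, dplyr::mutate(tracks, frame = c(0, 5)),
                              times = 0:2),
               "out of range")
})

test_that("exact linear traces are fit exactly", {
  t <- 0:8
  fit <- fit_activation_rate(t, 2 + 3 * t, window_policy = "full")
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$rms, 0, tolerance = 1e-12)

  flat <- fit_activation_rate(t, rep(5, 9), window_policy = "full")
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("the initial-phase window starts at onset and spans four hours", {
  t <- seq(0, 10, by = 0.5)
  v <- ifelse(t < 3, 10, 10 + 6 * (t - 3))  # onset at 3 h
  fit <- fit_activation_rate(t, v)
  expect_true(fit$onset_found)
  expect_lte(fit$t_b - fit$t_a, 4.5)
  expect_gte(fit$t_a, 3)
  expect_equal(fit$slope, 6, tolerance = 1e-9)

  # onset never detected: full-trace fallback with the flag cleared
  noisefree <- fit_activation_rate(t, rep(2, length(t)))
  expect_false(noisefree$onset_found)
  expect_identical(noisefree$n_points, length(t))
})

test_that("fitted slopes follow the closed-form OLS sampling distribution", {
  t <- seq(0, 6, by = 0.5)
  sxx <- sum((t - mean(t))^2)
  r <- 4
  sigma <- 2
  se <- sigma / sqrt(sxx)
  set.seed(62)
  slopes <- replicate(200, {
    v <- 1 + r * t + stats::rnorm(length(t), 0, sigma)
    fit_activation_rate(t, v, window_policy = "full")$slope
  })
  covered <- mean(abs(slopes - r) <= stats::qnorm(0.995) * se)
  expect_gte(covered, 0.96)  # 99% nominal coverage, 200 draws
})

test_that("rate fits are equivariant under scaling and shifts of intensity", {
  set.seed(63)
  t <- seq(0, 6, by = 0.5)
  v <- 3 + 2 * t + stats::rnorm(length(t), 0, 0.3)
  base <- fit_activation_rate(t, v, window_policy = "full")
  scaled <- fit_activation_rate(t, 5 * v, window_policy = "full")
  expect_equal(scaled$slope, 5 * base$slope, tolerance = 1e-9)
  shifted <- fit_activation_rate(t, v + 11, window_policy = "full")
  expect_equal(shifted$slope, base$slope, tolerance = 1e-9)
  expect_equal(shifted$intercept, base$intercept + 11, tolerance = 1e-9)
})

test_that("noiseless pipeline slopes equal rate times the disk-integration factor", {
  cfg <- scene_config(image_shape = c(80, 400), n_cells = 4, cell_radius = 3,
                      noise = list(gaussian_sd = 0, poisson = FALSE),
                      rate_sdlog = 0, min_separation = 60, seed = 11)
  tl <- generate_timelapse(cfg, 0:6)
  fits <- fit_activation_rates(extract_traces(tl, tracks_from_truth(tl)),
                               window_policy = "full")
  cells <- tl$truth$cells
  K <- sapply(seq_len(nrow(cells)), function(i) {
    g <- expand.grid(r = ceiling(cells$y[i] - 6):floor(cells$y[i] + 6),
                     c = ceiling(cells$x[i] - 6):floor(cells$x[i] + 6))
    d2 <- (g$r - cells$y[i])^2 + (g$c - cells$x[i])^2
    sum(exp(-d2 / (2 * 9))[d2 <= 36])
  })
  fits <- dplyr::arrange(fits, cell_id)
  expect_lt(max(abs(fits$slope / (cells$rate * K) - 1)), 1e-9)
})

test_that("rate summaries report regional medians, ratios and endpoint R^2", {
  fits <- tibble::tibble(
    slope = rep(2, 9),
    region = rep(c("anterior", "middle", "posterior"), each = 3),
    endpoint_value = stats::runif(9))
  s <- summarize_rates(fits)
  expect_equal(s$anterior_middle_ratio, 1)
  expect_equal(s$posterior_middle_ratio, 1)
  expect_true(all(s$regions$median_rate == 2))

  # endpoint exactly 6 * slope: perfect correlation
  set.seed(64)
  f2 <- tibble::tibble(slope = stats::runif(30, 1, 5),
                       region = sample(c("anterior", "middle", "posterior"),
                                       30, replace = TRUE),
                       endpoint_value = NA)
  f2$endpoint_value <- 6 * f2$slope
  expect_equal(summarize_rates(f2)$r_squared, 1, tolerance = 1e-12)

  # empty region reported with n = 0 and NA statistics
  f3 <- dplyr::filter(f2, region != "posterior")
  s3 <- summarize_rates(f3)
  post <- s3$regions[s3$regions$region == "posterior", ]
  expect_identical(post$n, 0L)
  expect_true(is.na(post$median_rate))

  # medians are invariant to reordering
  s4 <- summarize_rates(f2[sample(nrow(f2)), ])
  expect_equal(s4$regions$median_rate,
               summarize_rates(f2)$regions$median_rate)
  expect_identical(names(glance(s4)),
                   c("anterior_middle_ratio", "posterior_middle_ratio",
                     "r_squared"))
})

test_that("configured regional rate ratios are recovered through the full pipeline", {
  ratios <- sapply(1:3, function(s) {
    cfg <- scene_config(image_shape = c(120, 800), n_cells = 200,
                        cell_radius = 3, min_separation = 9, seed = s)
    tl <- generate_timelapse(cfg, seq(0, 6, by = 0.5))
    fits <- fit_activation_rates(extract_traces(tl, tracks_from_truth(tl)))
    s <- summarize_rates(fits)
    c(s$anterior_middle_ratio, s$posterior_middle_ratio)
  })
  expect_lt(abs(mean(ratios[1, ]) / 2.0 - 1), 0.15)
  expect_lt(abs(mean(ratios[2, ]) / 1.6 - 1), 0.15)
})
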