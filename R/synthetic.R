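# Synthetic larva scenes with exported ground truth.
#
# The generator emulates the study conditions of the imaging pipeline: a
# field of fat-body cells whose reporter expression rate varies along the
# anterior-posterior (AP) axis in a U-shape (anterior ~2x the middle median,
# posterior ~1.6x), the Lorentzian-times-Gaussian sheet illumination field,
# point-like and clustered bacterial fluorescence, and linear-in-time
# per-cell GFP accumulation with onset. Every generator is a pure function
# of (config, seed).

#' Configuration for synthetic larva scenes
#'
#' @param image_shape `c(ny, nx)` in pixels; x is the AP axis (anterior at
#'   low x), y the short/vertical axis.
#' @param pixel_size Micrometers per pixel.
#' @param n_cells Number of fat-body cells.
#' @param cell_radius Gaussian radius (sigma) of a rendered cell, px.
#' @param rate_levels Named median expression rates (a.u./h) for
#'   `anterior`, `middle`, `posterior`. Defaults 2.0 : 1.0 : 1.6, the
#'   regional rate comparisons the pipeline is designed to detect.
#' @param region_fractions Named AP-axis fractions for the three regions;
#'   must be positive and sum to 1. Default 0.25 / 0.50 / 0.25.
#' @param rate_sdlog Log-normal spread (sdlog) of per-cell rates around the
#'   regional median. Default 0.35: a continuous but clearly regionalized
#'   spread.
#' @param express_prob Named per-region probabilities that a cell expresses
#'   at all (rate 0 otherwise). Default 1 everywhere; partial-response
#'   scenes lower the middle value so that only scattered middle cells
#'   express while the outer lobes respond uniformly.
#' @param baseline_intensity Per-cell amplitude at t = 0 (a.u.). Default 0.
#' @param background_level Additive background of the GFP channel (a.u.).
#' @param noise List: `gaussian_sd` (additive read noise, a.u.) and
#'   `poisson` (logical; apply shot noise). `gaussian_sd = 0, poisson =
#'   FALSE` disables noise.
#' @param illumination Optional [illum_field()] applied multiplicatively
#'   (scaled to unit maximum) before noise; `NULL` for none.
#' @param bacteria List describing the bacteria channel: `n_single`,
#'   `n_clusters`, `cluster_size_range` (cells per cluster, inclusive),
#'   `single_intensity_mean`, `single_intensity_sd` (peak amplitude of one
#'   bacterium), `sigma` (px).
#' @param nucleus_radius,nucleus_intensity Nuclear-channel blob shape.
#' @param onset List: `t0` (h, activation onset) and `jitter` (sd of
#'   per-cell onset jitter, h).
#' @param min_separation Minimum center-to-center distance between cells,
#'   px; default `3 * cell_radius`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated `scene_config`.
#' @export
scene_config <- function(image_shape = c(120L, 400L),
                         pixel_size = 1,
                         n_cells = 60L,
                         cell_radius = 4,
                         rate_levels = c(anterior = 2.0, middle = 1.0,
                                         posterior = 1.6),
                         region_fractions = c(anterior = 0.25, middle = 0.50,
                                              posterior = 0.25),
                         rate_sdlog = 0.35,
                         express_prob = c(anterior = 1, middle = 1,
                                          posterior = 1),
                         baseline_intensity = 0,
                         background_level = 10,
                         noise = list(gaussian_sd = 1, poisson = FALSE),
                         illumination = NULL,
                         bacteria = list(n_single = 0L, n_clusters = 0L,
                                         cluster_size_range = c(5L, 15L),
                                         single_intensity_mean = 60,
                                         single_intensity_sd = 12,
                                         sigma = 1),
                         nucleus_radius = 2.5,
                         nucleus_intensity = 100,
                         onset = list(t0 = 0, jitter = 0),
                         min_separation = NULL,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            n_cells >= 0, cell_radius > 0, pixel_size > 0,
            rate_sdlog >= 0, baseline_intensity >= 0, background_level >= 0)
  reg <- c("anterior", "middle", "posterior")
  if (!all(reg %in% names(rate_levels)) || any(rate_levels < 0)) {
    stop("rate_levels must name nonnegative anterior/middle/posterior rates",
         call. = FALSE)
  }
  if (!all(reg %in% names(region_fractions)) || any(region_fractions <= 0) ||
      abs(sum(region_fractions) - 1) > 1e-8) {
    stop("region_fractions must be positive and sum to 1", call. = FALSE)
  }
  if (!all(reg %in% names(express_prob)) ||
      any(express_prob < 0 | express_prob > 1)) {
    stop("express_prob must name per-region probabilities in [0, 1]",
         call. = FALSE)
  }
  if (is.null(min_separation)) min_separation <- 3 * cell_radius
  if (n_cells > 0) {
    packing <- n_cells * pi * (min_separation / 2)^2 / prod(image_shape)
    if (packing > 0.7) {
      stop(sprintf(
        paste0("image of %d x %d px cannot host %d cells at minimum ",
               "separation %.1f px (packing fraction %.2f exceeds limit 0.7)"),
        image_shape[1], image_shape[2], n_cells, min_separation, packing),
        call. = FALSE)
    }
  }
  stopifnot(is.null(illumination) || inherits(illumination, "illum_field"))
  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_cells = as.integer(n_cells), cell_radius = cell_radius,
    rate_levels = rate_levels[reg], region_fractions = region_fractions[reg],
    rate_sdlog = rate_sdlog, express_prob = express_prob[reg],
    baseline_intensity = baseline_intensity,
    background_level = background_level, noise = noise,
    illumination = illumination, bacteria = bacteria,
    nucleus_radius = nucleus_radius, nucleus_intensity = nucleus_intensity,
    onset = onset, min_separation = min_separation, seed = as.integer(seed)),
    class = "scene_config")
}

# Add Gaussian blobs (rows of centers: x, y, amplitude) to an image.
render_blobs <- function(img, centers, sigma) {
  if (nrow(centers) == 0L) return(img)
  ny <- nrow(img)
  nx <- ncol(img)
  w <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centers))) {
    cx <- centers$x[k]
    cy <- centers$y[k]
    a <- centers$amplitude[k]
    rows <- max(1L, floor(cy + 1 - w)):min(ny, ceiling(cy + 1 + w))
    cols <- max(1L, floor(cx + 1 - w)):min(nx, ceiling(cx + 1 + w))
    dy2 <- ((rows - 1) - cy)^2
    dx2 <- ((cols - 1) - cx)^2
    img[rows, cols] <- img[rows, cols] +
      a * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  }
  img
}

region_of <- function(ap, fractions) {
  cuts <- cumsum(fractions)
  ifelse(ap < cuts[1L], "anterior", ifelse(ap < cuts[2L], "middle", "posterior"))
}

# Rejection-sample cell centers with a minimum separation.
place_cells <- function(config) {
  ny <- config$image_shape[1L]
  nx <- config$image_shape[2L]
  n <- config$n_cells
  if (n == 0L) {
    return(tibble::tibble(cell_id = integer(), x = double(), y = double()))
  }
  m <- 2 * config$cell_radius
  xs <- ys <- numeric(0)
  attempts <- 0L
  max_attempts <- 400L * n
  while (length(xs) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- stats::runif(1, m, nx - 1 - m)
    y <- stats::runif(1, m, ny - 1 - m)
    if (length(xs) == 0L ||
        min((xs - x)^2 + (ys - y)^2) >= config$min_separation^2) {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
  }
  if (length(xs) < n) {
    stop(sprintf(
      "could not place %d cells at minimum separation %.1f px in a %d x %d image",
      n, config$min_separation, ny, nx), call. = FALSE)
  }
  tibble::tibble(cell_id = seq_len(n), x = xs, y = ys)
}

draw_cell_truth <- function(config) {
  cells <- place_cells(config)
  if (nrow(cells) == 0L) {
    return(dplyr::mutate(cells, region = character(), rate = double(),
                         t0 = double()))
  }
  ap <- cells$x / (config$image_shape[2L] - 1)
  region <- region_of(ap, config$region_fractions)
  rate <- stats::rlnorm(nrow(cells),
                        meanlog = log(pmax(config$rate_levels[region],
                                           .Machine$double.xmin)),
                        sdlog = config$rate_sdlog)
  rate[config$rate_levels[region] == 0] <- 0
  expressed <- stats::runif(nrow(cells)) < config$express_prob[region]
  rate[!expressed] <- 0
  t0 <- config$onset$t0 +
    if (config$onset$jitter > 0)
      abs(stats::rnorm(nrow(cells), 0, config$onset$jitter)) else 0
  dplyr::mutate(cells, region = region, rate = unname(rate), t0 = t0,
                expressed = unname(expressed))
}

draw_bacteria_truth <- function(config) {
  b <- config$bacteria
  ny <- config$image_shape[1L]
  nx <- config$image_shape[2L]
  singles <- if (b$n_single > 0) {
    tibble::tibble(
      x = stats::runif(b$n_single, 2, nx - 3),
      y = stats::runif(b$n_single, 2, ny - 3),
      n_cells_true = 1L, type = "single")
  } else NULL
  clusters <- if (b$n_clusters > 0) {
    k <- sample(seq(b$cluster_size_range[1L], b$cluster_size_range[2L]),
                b$n_clusters, replace = TRUE)
    tibble::tibble(
      x = stats::runif(b$n_clusters, 8, nx - 9),
      y = stats::runif(b$n_clusters, 8, ny - 9),
      n_cells_true = as.integer(k), type = "cluster")
  } else NULL
  out <- dplyr::bind_rows(singles, clusters)
  if (is.null(out)) out <- tibble::tibble(x = double(), y = double(),
                                          n_cells_true = integer(),
                                          type = character())
  dplyr::mutate(out, object_id = dplyr::row_number(), .before = 1L)
}

render_bacteria_channel <- function(config, truth) {
  b <- config$bacteria
  img <- matrix(0, config$image_shape[1L], config$image_shape[2L])
  if (nrow(truth) == 0L) return(img)
  pieces <- list()
  for (k in seq_len(nrow(truth))) {
    n <- truth$n_cells_true[k]
    amp <- pmax(stats::rnorm(n, b$single_intensity_mean, b$single_intensity_sd),
                0.2 * b$single_intensity_mean)
    if (n == 1L) {
      pieces[[k]] <- tibble::tibble(x = truth$x[k], y = truth$y[k],
                                    amplitude = amp)
    } else {
      # cells packed in a tight clump around the cluster center
      pieces[[k]] <- tibble::tibble(
        x = truth$x[k] + stats::rnorm(n, 0, 1.6),
        y = truth$y[k] + stats::rnorm(n, 0, 1.6),
        amplitude = amp)
    }
  }
  render_blobs(img, dplyr::bind_rows(pieces), b$sigma)
}

apply_illumination <- function(img, config) {
  if (is.null(config$illumination)) return(img)
  f <- eval_illum_field(config$illumination, dim(img))
  img * (f / max(f))
}

apply_noise <- function(img, config) {
  if (isTRUE(config$noise$poisson)) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                  nrow(img), ncol(img))
  }
  sd <- config$noise$gaussian_sd
  if (!is.null(sd) && sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, sd), nrow(img), ncol(img))
  }
  img
}

render_frame <- function(config, cells, time, bacteria_truth = NULL) {
  shape <- config$image_shape
  amp <- config$baseline_intensity +
    cells$rate * pmax(0, time - cells$t0)
  gfp <- render_blobs(matrix(config$background_level, shape[1L], shape[2L]),
                      dplyr::mutate(cells, amplitude = amp),
                      config$cell_radius)
  nuc <- render_blobs(matrix(0, shape[1L], shape[2L]),
                      dplyr::mutate(cells, amplitude = config$nucleus_intensity),
                      config$nucleus_radius)
  ch <- list(gfp = gfp, nuclei = nuc)
  if (!is.null(bacteria_truth)) {
    ch$bacteria <- render_bacteria_channel(config, bacteria_truth)
  }
  ch <- lapply(ch, apply_illumination, config = config)
  lapply(ch, apply_noise, config = config)
}

#' Generate a synthetic larva scene
#'
#' Renders a multi-channel (GFP, nuclei, bacteria) single-time-point scene:
#' fat-body cells are Gaussian blobs whose GFP amplitude follows
#' `baseline + rate * max(0, time - t0)`, bacteria are point-like or
#' clustered blobs, the illumination field is applied multiplicatively
#' before noise, and the full per-cell/per-object ground truth is returned.
#'
#' @param config A [scene_config()].
#' @param time Scene time in hours post infection (default 6).
#' @return A `larva_scene`: list with `channels` (named list of matrices),
#'   `truth` (list of tibbles `cells`, `bacteria`, plus the illumination
#'   field), `time` and `config`.
#' @export
generate_scene <- function(config, time = 6) {
  stopifnot(inherits(config, "scene_config"), time >= 0)
  withr::with_seed(config$seed, {
    cells <- draw_cell_truth(config)
    bact <- draw_bacteria_truth(config)
    channels <- render_frame(config, cells, time, bacteria_truth = bact)
    structure(list(channels = channels,
                   truth = list(cells = cells, bacteria = bact,
                                illumination = config$illumination),
                   time = time, config = config),
              class = "larva_scene")
  })
}

#' Generate a synthetic time-lapse
#'
#' One cell population is drawn once; each frame is rendered (GFP + nuclei
#' channels) at the given times with independent noise. Per-cell mean
#' intensity follows `baseline + rate * max(0, t - t0)`.
#'
#' @param config A [scene_config()].
#' @param t_grid Strictly increasing, nonnegative times in hours.
#' @return A `larva_timelapse`: list with `frames` (list of per-frame
#'   channel lists), `times`, `truth` (cells tibble) and `config`.
#' @export
generate_timelapse <- function(config, t_grid) {
  stopifnot(inherits(config, "scene_config"))
  if (any(t_grid < 0)) stop("t_grid times must be nonnegative", call. = FALSE)
  if (any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    cells <- draw_cell_truth(config)
    frames <- lapply(t_grid, function(t) render_frame(config, cells, t))
    structure(list(frames = frames, times = t_grid,
                   truth = list(cells = cells), config = config),
              class = "larva_timelapse")
  })
}

#' Generate a noisy illumination reference image
#'
#' Emulates the averaged uniform-fluorophore picture used to fit the
#' illumination field: the analytic field at each pixel center plus
#' zero-mean Gaussian noise.
#'
#' @param field An [illum_field()].
#' @param shape `c(ny, nx)`.
#' @param noise_sigma Additive Gaussian noise sd (0 = exact field).
#' @param seed Integer seed.
#' @return Numeric matrix.
#' @export
generate_illumination_reference <- function(field, shape, noise_sigma = 0,
                                            seed = 1L) {
  img <- eval_illum_field(field, shape)
  if (noise_sigma > 0) {
    img <- img + withr::with_seed(seed, matrix(
      stats::rnorm(length(img), 0, noise_sigma), nrow(img), ncol(img)))
  }
  img
}

#' Generate a synthetic spatial count matrix with AP-patterned genes
#'
#' Cells get a uniform AP coordinate in [0, 1); each specified gene's count
#' in a cell is Poisson with mean `frequency_profile[bin] * depth`, and a
#' background gene absorbs the remaining transcriptome so that per-cell
#' transcript frequencies are meaningful.
#'
#' @param n_cells Number of cells.
#' @param genes_spec Named list; each element a length-`n_bins` vector of
#'   expected transcript frequencies (nonnegative, binwise sum over genes
#'   < 1).
#' @param n_bins Number of AP bins the profiles are specified over.
#' @param depth Expected total transcripts per cell (default 1000).
#' @param seed Integer seed.
#' @return List with `counts` (cells x genes integer matrix, including a
#'   final `background` gene), `coords` (tibble `cell_id`, `ap`) and
#'   `truth` (the generating profiles, depth, and bin edges).
#' @export
generate_spatial_counts <- function(n_cells, genes_spec, n_bins,
                                    depth = 1000, seed = 1L) {
  stopifnot(n_cells >= 1, n_bins >= 1, depth > 0, length(genes_spec) >= 1,
            !is.null(names(genes_spec)))
  prof <- do.call(rbind, genes_spec)  # genes x bins
  if (ncol(prof) != n_bins) {
    stop("each gene profile must have n_bins values", call. = FALSE)
  }
  if (any(prof < 0)) {
    stop("specified transcript frequencies must be nonnegative", call. = FALSE)
  }
  if (any(colSums(prof) >= 1)) {
    stop("per-bin frequencies must sum to < 1 across genes", call. = FALSE)
  }
  withr::with_seed(seed, {
    ap <- stats::runif(n_cells)
    edges <- seq(0, 1, length.out = n_bins + 1L)
    bin <- pmin(findInterval(ap, edges), n_bins)
    counts <- vapply(seq_along(genes_spec), function(g) {
      stats::rpois(n_cells, prof[g, bin] * depth)
    }, integer(n_cells))
    if (n_cells == 1L) counts <- matrix(counts, nrow = 1L)
    bg <- stats::rpois(n_cells, (1 - colSums(prof)[bin]) * depth)
    counts <- cbind(counts, bg)
    colnames(counts) <- c(names(genes_spec), "background")
    list(counts = counts,
         coords = tibble::tibble(cell_id = seq_len(n_cells), ap = ap),
         truth = list(genes_spec = genes_spec, depth = depth,
                      bin_edges = edges, bin = bin))
  })
}
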