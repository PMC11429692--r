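# Plain-format I/O: TIFF images and stacks, track/center CSVs, dense or
# MTX count matrices, and ground-truth JSON/CSV export.

#' Read a TIFF image or stack
#'
#' Undoes the intensity scaling recorded by [write_image()] in the
#' `<path>.scale.json` sidecar, if present.
#'
#' @param path TIFF file; multi-page files become 3D arrays `[y, x, z]`.
#' @return Numeric matrix or array.
#' @export
read_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".scale.json")
  if (file.exists(sidecar)) {
    s <- jsonlite::fromJSON(sidecar)
    pages <- lapply(pages, function(p) p * (s$hi - s$lo) + s$lo)
  }
  if (length(pages) == 1L) return(pages[[1L]])
  arr <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

#' Write a TIFF image or stack (32-bit float)
#'
#' Intensities are stored min-max scaled to [0, 1] (the range TIFF float
#' writers accept portably); the affine transform is recorded in a
#' `<path>.scale.json` sidecar and undone by [read_image()].
#'
#' @param image Numeric matrix or 3D array `[y, x, z]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  d <- dim(image)
  lo <- min(image)
  hi <- max(image)
  span <- if (hi > lo) hi - lo else 1
  scaled <- (image - lo) / span
  pages <- if (length(d) == 3L) {
    lapply(seq_len(d[3L]), function(k) scaled[, , k])
  } else {
    list(scaled)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(lo = lo, hi = hi), paste0(path, ".scale.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cell-center / track table
#'
#' Expects columns `larva_id, cell_id, frame, x, y[, z]` (or a subset for
#' single-time-point centers); `x`, `y`, `z` are 0-based pixel coordinates
#' and `frame` is a 0-based frame index.
#'
#' @param path CSV file.
#' @return Tibble.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) {
    stop("track CSV needs at least x and y columns", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write scene ground truth as CSV + JSON
#'
#' Per-cell and per-object tables go to `cells.csv` / `bacteria.csv`;
#' scalar parameters (config echo, illumination field) to
#' `ground_truth.json`.
#'
#' @param scene A `larva_scene` from [generate_scene()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(scene, dir) {
  stopifnot(inherits(scene, "larva_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(scene$truth$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$truth$bacteria, file.path(dir, "bacteria.csv"),
                   row.names = FALSE)
  cfg <- scene$config
  scal <- list(
    image_shape = cfg$image_shape, pixel_size = cfg$pixel_size,
    n_cells = cfg$n_cells, cell_radius = cfg$cell_radius,
    rate_levels = as.list(cfg$rate_levels),
    region_fractions = as.list(cfg$region_fractions),
    rate_sdlog = cfg$rate_sdlog, background_level = cfg$background_level,
    noise = cfg$noise, seed = cfg$seed, time = scene$time,
    illumination = if (is.null(cfg$illumination)) NULL else
      unclass(cfg$illumination))
  jsonlite::write_json(scal, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a spatial count matrix with coordinates
#'
#' Either a dense CSV (cells x genes, header = gene names) or a MatrixMarket
#' `.mtx` file plus a gene-name text file, together with a coordinate CSV
#' carrying an `ap` column.
#'
#' @param counts_file Dense CSV or `.mtx`.
#' @param coords_file CSV with per-cell `ap` coordinate.
#' @param genes_file Gene names (one per line), required for `.mtx`.
#' @return A [spatial_expression()].
#' @export
read_spatial_expression <- function(counts_file, coords_file,
                                    genes_file = NULL) {
  if (grepl("\\.mtx$", counts_file)) {
    if (is.null(genes_file)) {
      stop("genes_file is required for MTX input", call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(counts_file))
    colnames(m) <- readLines(genes_file)
  } else {
    m <- as.matrix(utils::read.csv(counts_file, check.names = FALSE))
  }
  coords <- utils::read.csv(coords_file)
  if (!"ap" %in% names(coords)) {
    stop("coordinate CSV needs an 'ap' column", call. = FALSE)
  }
  spatial_expression(m, coords$ap)
}
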