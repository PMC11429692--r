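# Per-cell reporter quantification: fixed-radius disk sums at given centers,
# 3D nuclear segmentation, shell-background-corrected nuclear sums, and
# per-larva partial/complete response classification.

#' Sum reporter intensity in a fixed-radius disk around each cell center
#'
#' For each center, sums the pixels whose integer coordinates satisfy
#' `(i - cy)^2 + (j - cx)^2 <= radius^2`, clipped to the image. Centers are
#' 0-based pixel coordinates (x = column, y = row) and may be fractional;
#' no anti-aliasing is applied. The default radius of 6 px corresponds to
#' about 2 um at the 20x single-time-point optics and about 5.5 um at the
#' 5x time-lapse optics.
#'
#' @param image Numeric matrix.
#' @param centers Data frame with numeric columns `x`, `y` (0-based px);
#'   any other columns (`larva_id`, `cell_id`, ...) are carried through.
#' @param radius Disk radius in pixels, >= 1.
#' @return The `centers` tibble with `summed_intensity` and
#'   `n_pixels_in_disk` appended. Errors if any center lies outside the
#'   image, listing the offending rows.
#' @export
disk_sum <- function(image, centers, radius = 6) {
  stopifnot(is.matrix(image), is.data.frame(centers),
            all(c("x", "y") %in% names(centers)), radius >= 1)
  ny <- nrow(image)
  nx <- ncol(image)
  bad <- which(centers$x < 0 | centers$x > nx - 1 |
                 centers$y < 0 | centers$y > ny - 1 |
                 !is.finite(centers$x) | !is.finite(centers$y))
  if (length(bad) > 0L) {
    stop("centers outside the image at rows: ",
         paste(utils::head(bad, 20L), collapse = ", "), call. = FALSE)
  }
  n <- nrow(centers)
  sums <- numeric(n)
  npx <- integer(n)
  for (k in seq_len(n)) {
    cx <- centers$x[k]
    cy <- centers$y[k]
    rows <- max(1L, ceiling(cy + 1 - radius)):min(ny, floor(cy + 1 + radius))
    cols <- max(1L, ceiling(cx + 1 - radius)):min(nx, floor(cx + 1 + radius))
    inside <- outer(((rows - 1) - cy)^2, ((cols - 1) - cx)^2, "+") <= radius^2
    sums[k] <- sum(image[rows, cols][inside])
    npx[k] <- sum(inside)
  }
  dplyr::mutate(tibble::as_tibble(centers),
                summed_intensity = sums, n_pixels_in_disk = npx)
}

#' Segment nuclei by Gaussian blur and global thresholding
#'
#' Blur, global threshold (Otsu on the blurred intensities by default, or a
#' fixed value), connected components at full connectivity, and a minimum
#' size filter that drops small dim objects (e.g. bacteria visible in the
#' nuclear channel).
#'
#' @param stack Numeric matrix (2D) or 3D array.
#' @param blur_sigma Gaussian blur sd in pixels.
#' @param threshold `"otsu"` or a fixed numeric threshold applied to the
#'   blurred image.
#' @param min_voxels Minimum component size kept.
#' @return List with `labels` (integer array) and `nuclei` (tibble: `label`,
#'   `voxel_count`, centroid `x`, `y`, `z`). An empty foreground yields an
#'   empty tibble; an all-foreground threshold is an error.
#' @export
segment_nuclei <- function(stack, blur_sigma = 2, threshold = "otsu",
                           min_voxels = 30L) {
  stopifnot(is.numeric(stack), length(dim(stack)) %in% c(2L, 3L))
  blurred <- gaussian_blur(stack, blur_sigma)
  th <- if (identical(threshold, "otsu")) otsu_threshold(blurred) else threshold
  if (!is.finite(th)) {
    # constant image: no separable foreground
    return(list(labels = array(0L, dim(stack)),
                nuclei = label_stats(array(0L, dim(stack)))[0, ]))
  }
  mask <- blurred > th
  if (all(mask)) {
    stop("threshold is degenerate: the whole stack is foreground",
         call. = FALSE)
  }
  labels <- label_components(mask)
  st <- label_stats(labels)
  keep <- st$label[st$voxel_count >= min_voxels]
  labels[!(labels %in% keep)] <- 0L
  # relabel 1..k in original order
  if (length(keep) > 0L) {
    labels <- array(match(labels, keep, nomatch = 0L), dim(labels))
  }
  st <- st[st$voxel_count >= min_voxels, c("label", "voxel_count", "x", "y", "z")]
  st$label <- seq_len(nrow(st))
  list(labels = labels, nuclei = st)
}

#' Shell-background-corrected nuclear sums
#'
#' For each nucleus, local background is the mean signal in a shell obtained
#' by dilating the nuclear mask by `dilation_px` and subtracting the
#' original mask; voxels belonging to any other nucleus are excluded from
#' the shell. The corrected sum is
#' `raw_sum - shell_mean * voxel_count`.
#'
#' @param signal_stack Numeric array, same shape as `labels`.
#' @param labels Integer label array from [segment_nuclei()].
#' @param dilation_px Shell thickness in pixels (default 2).
#' @return Tibble: `label`, `voxel_count`, `raw_sum`, `shell_mean`,
#'   `corrected_sum`, `negative_flag`. A nucleus with an empty shell is an
#'   error.
#' @export
shell_corrected_sum <- function(signal_stack, labels, dilation_px = 2) {
  stopifnot(identical(dim(signal_stack), dim(labels)))
  ids <- sort(unique(labels[labels > 0L]))
  d <- dim(labels)
  nd <- length(d)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    vox <- which(labels == id)
    coords <- arrayInd(vox, d)
    # work in a bounding box padded by the dilation for speed
    lo <- pmax(apply(coords, 2L, min) - dilation_px - 1L, 1L)
    hi <- pmin(apply(coords, 2L, max) + dilation_px + 1L, d)
    idx <- lapply(seq_len(nd), function(dd) lo[dd]:hi[dd])
    sub_labels <- do.call(`[`, c(list(labels), idx, list(drop = FALSE)))
    sub_signal <- do.call(`[`, c(list(signal_stack), idx, list(drop = FALSE)))
    sub_mask <- sub_labels == id
    shell <- dilate_mask(sub_mask, dilation_px) & !sub_mask & sub_labels == 0L
    if (!any(shell)) {
      stop(sprintf("nucleus %d has an empty background shell", id),
           call. = FALSE)
    }
    raw <- sum(sub_signal[sub_mask])
    nvox <- sum(sub_mask)
    sm <- mean(sub_signal[shell])
    out[[k]] <- tibble::tibble(
      label = id, voxel_count = nvox, raw_sum = raw, shell_mean = sm,
      corrected_sum = raw - sm * nvox)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(label = integer(), voxel_count = integer(),
                          raw_sum = double(), shell_mean = double(),
                          corrected_sum = double())
  }
  dplyr::mutate(res, negative_flag = .data$corrected_sum < 0)
}

#' Classify per-larva responses as none / partial / complete
#'
#' Larvae whose median cell intensity is at or below a background floor
#' derived from mock-injected controls (`mean(mock) + k * sd(mock)`) are
#' called `none`. The remaining larvae are split into `partial` and
#' `complete` by 2-cluster k-means on `log10(median)`, with the split
#' threshold at the midpoint of the cluster centers. With fewer than two
#' larvae above the floor, an explicit `split_threshold` (on the raw median
#' scale) is required. If all remaining medians are identical the split is
#' degenerate: all are assigned one class and flagged with a warning.
#'
#' @param medians Data frame with `larva_id` and `median_intensity`.
#' @param mock_medians Numeric vector of per-larva medians from mock
#'   controls (required unless `split_threshold` is given).
#' @param k Mock-floor multiplier (default 3).
#' @param split_threshold Optional explicit partial/complete threshold.
#' @return Tibble: `larva_id`, `median_intensity`, `class`,
#'   `split_threshold`, `floor`, `degenerate`.
#' @export
classify_response <- function(medians, mock_medians = NULL, k = 3,
                              split_threshold = NULL) {
  stopifnot(is.data.frame(medians),
            all(c("larva_id", "median_intensity") %in% names(medians)),
            nrow(medians) >= 1L)
  if (is.null(mock_medians) && is.null(split_threshold)) {
    stop("classify_response() needs mock controls or an explicit split_threshold",
         call. = FALSE)
  }
  floor_val <- if (!is.null(mock_medians)) {
    s <- if (length(mock_medians) > 1L) stats::sd(mock_medians) else 0
    mean(mock_medians) + k * s
  } else {
    -Inf
  }
  m <- medians$median_intensity
  cls <- rep(NA_character_, length(m))
  cls[m <= floor_val] <- "none"
  active <- which(is.na(cls))
  degenerate <- FALSE
  thr <- NA_real_
  if (length(active) > 0L) {
    if (!is.null(split_threshold)) {
      thr <- split_threshold
      cls[active] <- ifelse(m[active] >= thr, "complete", "partial")
    } else if (length(active) < 2L) {
      stop("fewer than 2 larvae above the mock floor: supply split_threshold",
           call. = FALSE)
    } else {
      lx <- log10(m[active])
      if (diff(range(lx)) == 0) {
        degenerate <- TRUE
        warning("identical medians above the floor: degenerate split, ",
                "all assigned 'complete'", call. = FALSE)
        cls[active] <- "complete"
      } else {
        km <- stats::kmeans(lx, centers = matrix(range(lx), ncol = 1L))
        thr_log <- mean(km$centers)
        thr <- 10^thr_log
        cls[active] <- ifelse(lx >= thr_log, "complete", "partial")
      }
    }
  }
  tibble::tibble(larva_id = medians$larva_id, median_intensity = m,
                 class = cls, split_threshold = thr, floor = floor_val,
                 degenerate = degenerate)
}
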