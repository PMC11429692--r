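# Two-phase bacteria segmentation and per-object cell-count estimation.
#
# Phase 1 targets single cells and small clumps with a Difference of
# Gaussians (band-pass) filter; phase 2 targets large diffuse clusters
# (often internalized by nephrocytes/hemocytes) with a plain Gaussian blur.
# The union of both masks is labeled, each object's summed raw intensity
# S_i is normalized by the median object intensity and rounded up to give
# an estimated cell count, and objects with fewer than 3 estimated cells
# are flagged planktonic (freely suspended in the hemolymph).

#' Segment bacteria in two phases
#'
#' `mask = (DoG(image; sigma_small, sigma_large) > dog_threshold) |
#' (Gauss(image; cluster_sigma) > cluster_threshold)`, followed by
#' connected-component labeling (full connectivity) and a minimum-size
#' filter. Thresholds default to robust multiples of the filtered images'
#' spread (`k_mad` median absolute deviations above zero for the band-pass
#' response, above the median for the blurred image).
#'
#' @param image Numeric matrix or 3D array, bacteria channel.
#' @param dog_sigmas `c(sigma_small, sigma_large)` in px, increasing.
#' @param dog_threshold Threshold on the DoG response; `NULL` for
#'   `k_mad * mad(DoG)`.
#' @param cluster_sigma Blur sd for the cluster phase (default 6 px).
#' @param cluster_threshold Threshold on the blurred image; `NULL` for
#'   `median + k_mad * mad`.
#' @param min_voxels Minimum object size kept (default 4).
#' @param k_mad Robust threshold multiplier for the automatic thresholds.
#' @return List with `labels` and `objects` (tibble: `label`, centroid
#'   `x`,`y`,`z`, `voxel_count`, `sum_intensity`, `phase` in
#'   spot/cluster/merged). All-foreground masks are an error.
#' @export
segment_bacteria <- function(image, dog_sigmas = c(1, 3), dog_threshold = NULL,
                             cluster_sigma = 6, cluster_threshold = NULL,
                             min_voxels = 4L, k_mad = 8) {
  stopifnot(length(dog_sigmas) == 2L, dog_sigmas[1L] < dog_sigmas[2L])
  dog <- gaussian_blur(image, dog_sigmas[1L]) -
    gaussian_blur(image, dog_sigmas[2L])
  if (is.null(dog_threshold)) {
    dog_threshold <- k_mad * stats::mad(as.vector(dog))
    if (dog_threshold == 0) dog_threshold <- k_mad * stats::sd(as.vector(dog))
  }
  blurred <- gaussian_blur(image, cluster_sigma)
  if (is.null(cluster_threshold)) {
    v <- as.vector(blurred)
    s <- stats::mad(v)
    if (s == 0) s <- stats::sd(v)
    cluster_threshold <- stats::median(v) + k_mad * s
  }
  mask_spot <- dog > dog_threshold
  mask_cluster <- blurred > cluster_threshold
  mask <- mask_spot | mask_cluster
  if (all(mask)) {
    stop("bacteria thresholds are degenerate: the whole image is foreground",
         call. = FALSE)
  }
  labels <- label_components(mask)
  st <- label_stats(labels, signal = image)
  if (nrow(st) > 0L) {
    keep <- st$voxel_count >= min_voxels
    drop_ids <- st$label[!keep]
    if (length(drop_ids) > 0L) labels[labels %in% drop_ids] <- 0L
    st <- st[keep, ]
    if (nrow(st) > 0L) {
      labels <- array(match(labels, st$label, nomatch = 0L), dim(labels))
      phase <- vapply(seq_len(nrow(st)), function(k) {
        vox <- labels == k
        has_spot <- any(mask_spot[vox])
        has_cluster <- any(mask_cluster[vox])
        if (has_spot && has_cluster) "merged"
        else if (has_spot) "spot" else "cluster"
      }, character(1L))
      st$label <- seq_len(nrow(st))
      st$phase <- phase
    }
  }
  if (nrow(st) == 0L) {
    st <- tibble::tibble(label = integer(), voxel_count = integer(),
                         sum_intensity = double(), x = double(), y = double(),
                         z = double(), phase = character())
  }
  list(labels = labels, objects = st)
}

#' Estimate bacteria cell counts per object
#'
#' `n_i = ceiling(S_i / median(S))`, where the median runs over all detected
#' objects by default (singletons dominate the detections) or only over
#' spot-phase objects. Objects with `n_i < 3` are flagged planktonic.
#'
#' @param objects Tibble from [segment_bacteria()] (needs `sum_intensity`;
#'   `phase` needed for `median_over = "spot"`).
#' @param median_over `"all"` (default) or `"spot"`.
#' @return The tibble with `estimated_count` and `planktonic` appended; an
#'   empty input yields an empty output.
#' @export
estimate_counts <- function(objects, median_over = c("all", "spot")) {
  median_over <- match.arg(median_over)
  stopifnot(is.data.frame(objects), "sum_intensity" %in% names(objects))
  if (nrow(objects) == 0L) {
    return(dplyr::mutate(tibble::as_tibble(objects),
                         estimated_count = integer(), planktonic = logical()))
  }
  s <- objects$sum_intensity
  ref <- if (median_over == "spot") {
    if (!"phase" %in% names(objects) || !any(objects$phase == "spot")) {
      stop("no spot-phase objects to take the median over", call. = FALSE)
    }
    s[objects$phase == "spot"]
  } else s
  m <- stats::median(ref)
  if (!is.finite(m) || m <= 0) {
    stop("median object intensity is not positive; cannot normalize",
         call. = FALSE)
  }
  n <- as.integer(ceiling(s / m))
  dplyr::mutate(tibble::as_tibble(objects),
                estimated_count = pmax(n, 1L),
                planktonic = .data$estimated_count < 3L)
}

#' AP histogram of (planktonic) bacteria counts
#'
#' Sums estimated cell counts over half-open AP bins of object centroid x,
#' restricted to planktonic objects by default.
#'
#' @param objects Tibble from [estimate_counts()] (needs `x`,
#'   `estimated_count`, `planktonic`).
#' @param bin_edges Strictly increasing AP bin edges (px).
#' @param planktonic_only Count only planktonic objects (default TRUE).
#' @return Tibble: `bin_lo`, `bin_hi`, `count`.
#' @export
planktonic_ap_profile <- function(objects, bin_edges, planktonic_only = TRUE) {
  stopifnot(is.data.frame(objects), length(bin_edges) >= 2L)
  if (any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  nb <- length(bin_edges) - 1L
  base <- tibble::tibble(bin_lo = bin_edges[-length(bin_edges)],
                         bin_hi = bin_edges[-1L])
  if (nrow(objects) == 0L) return(dplyr::mutate(base, count = 0L))
  stopifnot(all(c("x", "estimated_count", "planktonic") %in% names(objects)))
  sel <- if (planktonic_only) objects$planktonic else rep(TRUE, nrow(objects))
  obj <- objects[sel, ]
  bin <- findInterval(obj$x, bin_edges)
  ok <- bin >= 1L & bin <= nb & obj$x < bin_edges[length(bin_edges)]
  counts <- vapply(seq_len(nb), function(b)
    sum(obj$estimated_count[ok & bin == b]), numeric(1L))
  dplyr::mutate(base, count = as.integer(counts))
}
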