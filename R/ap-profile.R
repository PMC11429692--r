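# Tissue-scale anterior-posterior (AP) expression profiles: two-threshold
# multi-Otsu on log intensity selects the strong-GFP pixel class, masked raw
# intensity is summed along the short (y) axis, and per-larva profiles are
# normalized, averaged across larvae, and summarized as region ratios.

new_ap_profile <- function(df, thresholds, degenerate, axis_length,
                           normalized = FALSE) {
  structure(df,
            class = c("ap_profile", class(tibble::tibble()))) -> out
  attr(out, "thresholds") <- thresholds
  attr(out, "degenerate") <- degenerate
  attr(out, "axis_length") <- axis_length
  attr(out, "normalized") <- normalized
  out
}

#' AP expression profile from a maximum intensity projection
#'
#' Computes 2 Otsu thresholds (3 classes) on `log(image + log_offset)`,
#' masks the top class (strong GFP signal), sums masked raw intensity over
#' the short axis per x-column, and aggregates columns into half-open AP
#' bins. An image with fewer than 3 distinct log-intensity levels yields an
#' all-zero profile flagged degenerate.
#'
#' @param image 2D maximum intensity projection (AP axis = x = columns).
#' @param n_bins Number of AP bins (default 50).
#' @param log_offset Added before the log transform (default 1).
#' @param fixed_thresholds Optional length-2 numeric thresholds on the raw
#'   intensity scale (the manual-threshold path for widefield images);
#'   bypasses multi-Otsu.
#' @return An `ap_profile` tibble (`bin_lo`, `bin_hi`, `value`; bin edges
#'   in 0-based x pixel units) with attributes `thresholds` (on the log
#'   scale), `degenerate`, `axis_length` and `normalized`.
#' @export
ap_profile_from_image <- function(image, n_bins = 50, log_offset = 1,
                                  fixed_thresholds = NULL) {
  stopifnot(is.matrix(image), n_bins >= 1)
  nx <- ncol(image)
  edges <- seq(0, nx, length.out = n_bins + 1L)
  base <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1L])
  logim <- log(image + log_offset)
  if (!is.null(fixed_thresholds)) {
    stopifnot(length(fixed_thresholds) == 2L)
    tau <- sort(log(fixed_thresholds + log_offset))
  } else {
    mo <- multiotsu_thresholds(logim)
    if (mo$degenerate) {
      return(new_ap_profile(dplyr::mutate(base, value = 0),
                            thresholds = c(NA_real_, NA_real_),
                            degenerate = TRUE, axis_length = nx))
    }
    tau <- mo$tau
  }
  mask <- logim > tau[2L]
  col_signal <- colSums(image * mask)
  bin <- pmin(findInterval(seq_len(nx) - 1, edges), n_bins)
  value <- vapply(seq_len(n_bins),
                  function(b) sum(col_signal[bin == b]), numeric(1L))
  new_ap_profile(dplyr::mutate(base, value = value), thresholds = tau,
                 degenerate = FALSE, axis_length = nx)
}

#' Normalize an AP profile to its maximum
#'
#' @param profile An `ap_profile`.
#' @return The profile divided by its maximum value (unchanged if all 0),
#'   with the `normalized` attribute set.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "ap_profile"))
  mx <- max(profile$value)
  out <- profile
  if (mx > 0) out$value <- out$value / mx
  attr(out, "normalized") <- TRUE
  out
}

#' Normalize and average AP profiles across larvae
#'
#' Each profile is mapped to a normalized AP coordinate in [0, 1],
#' resampled to `common_n_bins` bin centers by linear interpolation,
#' divided by its own maximum, and then averaged per bin across larvae
#' (mean and standard deviation). Degenerate (all-zero) profiles are
#' excluded with a warning.
#'
#' @param profiles List of `ap_profile` objects.
#' @param common_n_bins Number of bins of the common grid (default 20).
#' @return Tibble: `ap` (bin center, 0-1), `mean`, `sd`, `n_larvae`.
#' @export
normalize_and_average <- function(profiles, common_n_bins = 20) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  degen <- vapply(profiles, function(p) isTRUE(attr(p, "degenerate")) ||
                    max(p$value) <= 0, logical(1L))
  if (any(degen)) {
    warning(sum(degen), " degenerate profile(s) excluded from the average",
            call. = FALSE)
    profiles <- profiles[!degen]
  }
  if (length(profiles) == 0L) {
    stop("no non-degenerate profiles to average", call. = FALSE)
  }
  target <- (seq_len(common_n_bins) - 0.5) / common_n_bins
  resampled <- vapply(profiles, function(p) {
    centers <- (p$bin_lo + p$bin_hi) / 2 / attr(p, "axis_length")
    v <- stats::approx(centers, p$value, xout = target, rule = 2)$y
    v / max(v)
  }, numeric(common_n_bins))
  resampled <- matrix(resampled, nrow = common_n_bins)
  tibble::tibble(
    ap = target,
    mean = rowMeans(resampled),
    sd = if (ncol(resampled) < 2L) rep(0, common_n_bins) else
      apply(resampled, 1L, stats::sd),
    n_larvae = length(profiles))
}

#' Anterior / middle / posterior region boundaries
#'
#' @param anterior,middle,posterior Positive AP-axis fractions summing to 1.
#'   Default 0.25 / 0.50 / 0.25.
#' @return A `region_spec`.
#' @export
region_spec <- function(anterior = 0.25, middle = 0.50, posterior = 0.25) {
  f <- c(anterior = anterior, middle = middle, posterior = posterior)
  if (any(f <= 0) || abs(sum(f) - 1) > 1e-8) {
    stop("region fractions must be positive and sum to 1", call. = FALSE)
  }
  structure(as.list(f), class = "region_spec")
}

#' Region mean expression and anterior/posterior-to-middle ratios
#'
#' Region means average the bin values whose centers fall in each region of
#' the normalized AP axis; the ratios compare anterior and posterior means
#' to the middle mean. A zero middle mean gives `Inf` ratios with a flag.
#'
#' @param profile An `ap_profile` (or tibble with `bin_lo`, `bin_hi`,
#'   `value`).
#' @param regions A [region_spec()].
#' @param axis_length AP axis length in px; taken from the profile attribute
#'   when present.
#' @return One-row tibble: region means, `anterior_middle_ratio`,
#'   `posterior_middle_ratio`, `middle_zero_flag`.
#' @export
region_ratios <- function(profile, regions = region_spec(),
                          axis_length = attr(profile, "axis_length")) {
  stopifnot(is.data.frame(profile),
            all(c("bin_lo", "bin_hi", "value") %in% names(profile)),
            inherits(regions, "region_spec"))
  if (isTRUE(attr(profile, "degenerate"))) {
    stop("cannot compute region ratios of a degenerate profile", call. = FALSE)
  }
  if (is.null(axis_length)) axis_length <- max(profile$bin_hi)
  ap <- (profile$bin_lo + profile$bin_hi) / 2 / axis_length
  cut1 <- regions$anterior
  cut2 <- regions$anterior + regions$middle
  region <- ifelse(ap < cut1, "anterior", ifelse(ap < cut2, "middle",
                                                 "posterior"))
  counts <- table(factor(region, levels = c("anterior", "middle", "posterior")))
  if (any(counts == 0)) {
    stop("region(s) ", paste(names(counts)[counts == 0], collapse = ", "),
         " contain no bin centers; increase n_bins", call. = FALSE)
  }
  means <- tapply(profile$value, region, mean)
  mid0 <- means[["middle"]] == 0
  tibble::tibble(
    anterior_mean = means[["anterior"]],
    middle_mean = means[["middle"]],
    posterior_mean = means[["posterior"]],
    anterior_middle_ratio = if (mid0) Inf else
      means[["anterior"]] / means[["middle"]],
    posterior_middle_ratio = if (mid0) Inf else
      means[["posterior"]] / means[["middle"]],
    middle_zero_flag = mid0)
}
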