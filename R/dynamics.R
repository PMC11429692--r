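# Time-lapse reporter dynamics: disk-summed traces at tracked centers,
# initial-phase linear rate fitting, regional rate summaries, and the
# rate-vs-endpoint correlation.

#' Extract disk-summed traces from a time-lapse at tracked centers
#'
#' For every (cell, frame) row of the tracks table, sums the reporter
#' channel in a fixed-radius disk at that frame's center (tracking the cell
#' through motion), then assembles per-cell traces.
#'
#' @param timelapse A `larva_timelapse` from [generate_timelapse()], or a
#'   plain list of numeric matrices (one per frame).
#' @param tracks Data frame with `larva_id`, `cell_id`, `frame` (0-based
#'   frame index), `x`, `y` (0-based px); an optional `region` column is
#'   carried through.
#' @param radius Disk radius in px (default 6).
#' @param times Frame times in hours; taken from the time-lapse object when
#'   available, else required.
#' @param channel Channel name used when `timelapse` is a `larva_timelapse`.
#' @return Tibble of trace points: `larva_id`, `cell_id`, `frame`, `time`,
#'   `value` (plus `region` if supplied), ordered by cell and time. Cells
#'   missing some frames keep their remaining points; a warning flags the
#'   gaps.
#' @export
extract_traces <- function(timelapse, tracks, radius = 6, times = NULL,
                           channel = "gfp") {
  if (inherits(timelapse, "larva_timelapse")) {
    frames <- lapply(timelapse$frames, `[[`, channel)
    if (is.null(times)) times <- timelapse$times
  } else {
    frames <- timelapse
  }
  stopifnot(is.list(frames), length(frames) >= 1L,
            is.data.frame(tracks),
            all(c("larva_id", "cell_id", "frame", "x", "y") %in% names(tracks)))
  if (is.null(times)) stop("supply frame times in hours", call. = FALSE)
  if (length(times) != length(frames)) {
    stop("times must have one entry per frame", call. = FALSE)
  }
  if (any(tracks$frame < 0 | tracks$frame >= length(frames))) {
    stop("track frames out of range of the time-lapse", call. = FALSE)
  }
  pieces <- lapply(split(seq_len(nrow(tracks)), tracks$frame), function(rows) {
    fr <- tracks$frame[rows[1L]]
    meas <- disk_sum(frames[[fr + 1L]], tracks[rows, , drop = FALSE], radius)
    dplyr::mutate(meas, time = times[fr + 1L], value = .data$summed_intensity)
  })
  out <- dplyr::arrange(dplyr::bind_rows(pieces),
                        .data$larva_id, .data$cell_id, .data$time)
  n_frames <- length(frames)
  gaps <- dplyr::summarise(dplyr::group_by(out, .data$larva_id, .data$cell_id),
                           n = dplyr::n(), .groups = "drop")
  if (any(gaps$n < n_frames)) {
    warning(sum(gaps$n < n_frames),
            " cell(s) are missing frames; their traces have gaps",
            call. = FALSE)
  }
  keep <- c("larva_id", "cell_id", "frame", "time", "value",
            intersect("region", names(out)))
  out[keep]
}

#' Fit a linear activation rate to the initial phase of one trace
#'
#' Ordinary least squares of intensity on time within a fit window. The
#' default `"initial"` policy detects onset as the first time the trace
#' exceeds `baseline mean + onset_k * baseline sd` (baseline = the first
#' `baseline_n` points) and fits from onset to onset + `window_hours`,
#' clipped to the trace; if onset is never detected the full trace is fit
#' and flagged. `"full"` fits the whole trace; `"fixed"` fits inside
#' `window = c(t_a, t_b)`.
#'
#' @param times,values Numeric vectors (hours, a.u.), strictly increasing
#'   times, at least 3 points.
#' @param window_policy `"initial"`, `"full"` or `"fixed"`.
#' @param window Length-2 window for the fixed policy.
#' @param baseline_n,onset_k,window_hours Initial-phase parameters.
#' @return One-row tibble: `slope` (a.u./h), `intercept`, `t_a`, `t_b`,
#'   `rms`, `r_squared`, `n_points`, `onset_found`.
#' @export
fit_activation_rate <- function(times, values,
                                window_policy = c("initial", "full", "fixed"),
                                window = NULL, baseline_n = 3, onset_k = 3,
                                window_hours = 4) {
  window_policy <- match.arg(window_policy)
  stopifnot(length(times) == length(values), length(times) >= 3L,
            all(diff(times) > 0), all(is.finite(values)))
  onset_found <- NA
  if (window_policy == "initial") {
    nb <- min(baseline_n, length(values) - 1L)
    base <- values[seq_len(nb)]
    thr <- mean(base) + onset_k * stats::sd(base)
    if (!is.finite(thr)) thr <- mean(base)
    hit <- which(values > thr)
    if (length(hit) == 0L) {
      onset_found <- FALSE
      sel <- seq_along(times)
    } else {
      onset_found <- TRUE
      t_on <- times[hit[1L]]
      sel <- which(times >= t_on & times <= t_on + window_hours)
      # a slope needs at least 3 points; extend past the window if short
      while (length(sel) < 3L && max(sel) < length(times)) {
        sel <- c(sel, max(sel) + 1L)
      }
    }
  } else if (window_policy == "fixed") {
    stopifnot(length(window) == 2L, window[1L] < window[2L])
    sel <- which(times >= window[1L] & times <= window[2L])
    if (length(sel) < 3L) {
      stop("fewer than 3 trace points inside the fit window", call. = FALSE)
    }
  } else {
    sel <- seq_along(times)
  }
  t <- times[sel]
  v <- values[sel]
  fit <- stats::lm(v ~ t)
  res <- stats::residuals(fit)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  tibble::tibble(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    t_a = min(t), t_b = max(t),
    rms = sqrt(mean(res^2)), r_squared = r2,
    n_points = length(sel), onset_found = onset_found)
}

#' Fit activation rates for every cell in a trace table
#'
#' Applies [fit_activation_rate()] per (larva, cell) and records the
#' endpoint intensity: the trace value at the frame nearest
#' `endpoint_time`.
#'
#' @param traces Trace tibble from [extract_traces()].
#' @param endpoint_time Hours post infection of the endpoint (default 6).
#' @param ... Passed to [fit_activation_rate()].
#' @return Tibble of per-cell fits with `region` (if present) and
#'   `endpoint_value`.
#' @export
fit_activation_rates <- function(traces, endpoint_time = 6, ...) {
  stopifnot(is.data.frame(traces),
            all(c("larva_id", "cell_id", "time", "value") %in% names(traces)))
  grp <- dplyr::group_by(traces, .data$larva_id, .data$cell_id)
  dplyr::ungroup(dplyr::reframe(grp, {
    fit <- fit_activation_rate(.data$time, .data$value, ...)
    fit$endpoint_value <- .data$value[which.min(abs(.data$time - endpoint_time))]
    if ("region" %in% names(traces)) fit$region <- .data$region[1L]
    fit
  }))
}

#' Regional rate summaries and the rate-vs-endpoint correlation
#'
#' Per-region median and quartiles of fitted slopes, the
#' anterior/middle and posterior/middle median-rate ratios, and the R
#' squared of the least-squares regression of endpoint intensity on slope
#' across all cells.
#'
#' @param fits Tibble from [fit_activation_rates()], with `slope`,
#'   `region` and `endpoint_value`.
#' @return A `rate_summary` list: `regions` (tibble `region`, `n`,
#'   `median_rate`, `q25`, `q75`), `anterior_middle_ratio`,
#'   `posterior_middle_ratio`, `r_squared`. Empty regions are reported with
#'   `n = 0` and `NA` statistics.
#' @export
summarize_rates <- function(fits) {
  stopifnot(is.data.frame(fits),
            all(c("slope", "region", "endpoint_value") %in% names(fits)))
  lev <- c("anterior", "middle", "posterior")
  regions <- lapply(lev, function(r) {
    s <- fits$slope[fits$region == r]
    if (length(s) == 0L) {
      tibble::tibble(region = r, n = 0L, median_rate = NA_real_,
                     q25 = NA_real_, q75 = NA_real_)
    } else {
      q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
      tibble::tibble(region = r, n = length(s), median_rate = q[2L],
                     q25 = q[1L], q75 = q[3L])
    }
  })
  regions <- dplyr::bind_rows(regions)
  med <- stats::setNames(regions$median_rate, regions$region)
  r2 <- {
    fit <- stats::lm(endpoint_value ~ slope, data = fits)
    # summary() warns on exact fits; an R^2 of 1 is a legitimate outcome here
    suppressWarnings(summary(fit)$r.squared)
  }
  structure(list(
    regions = regions,
    anterior_middle_ratio = unname(med["anterior"] / med["middle"]),
    posterior_middle_ratio = unname(med["posterior"] / med["middle"]),
    r_squared = r2), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("<rate_summary>\n")
  print(x$regions)
  cat(sprintf("anterior/middle median-rate ratio:  %.3f\n",
              x$anterior_middle_ratio))
  cat(sprintf("posterior/middle median-rate ratio: %.3f\n",
              x$posterior_middle_ratio))
  cat(sprintf("endpoint-vs-rate R^2: %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
#' @rdname summarize_rates
#' @param x A `rate_summary`.
#' @param ... Unused.
tidy.rate_summary <- function(x, ...) x$regions

#' @export
#' @rdname summarize_rates
glance.rate_summary <- function(x, ...) {
  tibble::tibble(anterior_middle_ratio = x$anterior_middle_ratio,
                 posterior_middle_ratio = x$posterior_middle_ratio,
                 r_squared = x$r_squared)
}
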