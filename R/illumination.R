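# Light-sheet illumination field: a Lorentzian profile along the sheet
# propagation axis (x) times a Gaussian along the vertical axis (y),
#   I(x, y) = I0 / (1 + ((x - xc)/xR)^2) * exp(-(y - yc)^2 / (2 sigma_y^2)).
# The Lorentzian half-width xR reflects the beam's Rayleigh range; sigma_y
# the incomplete vertical filling of the detection plane at low zoom.

#' Construct an illumination field
#'
#' @param I0 Peak intensity (a.u.), > 0.
#' @param xc Center along the sheet propagation axis (px, 0-based).
#' @param xR Lorentzian half-width along x (px), > 0.
#' @param sigma_y Gaussian width along the vertical axis (px), > 0.
#' @param yc Vertical center (px, 0-based).
#' @return Object of class `illum_field`.
#' @export
illum_field <- function(I0, xc, xR, sigma_y, yc = 0) {
  stopifnot(is.finite(c(I0, xc, xR, sigma_y, yc)))
  if (I0 <= 0) stop("illumination peak intensity I0 must be > 0", call. = FALSE)
  if (xR <= 0 || sigma_y <= 0) {
    stop("illumination widths xR and sigma_y must be > 0", call. = FALSE)
  }
  structure(list(I0 = I0, xc = xc, xR = xR, sigma_y = sigma_y, yc = yc),
            class = "illum_field")
}

#' @export
print.illum_field <- function(x, ...) {
  cat(sprintf(
    "<illum_field> I0 = %.4g, xc = %.4g px, xR = %.4g px, sigma_y = %.4g px, yc = %.4g px\n",
    x$I0, x$xc, x$xR, x$sigma_y, x$yc))
  if (!is.null(x$rms)) cat(sprintf("  fit residual RMS = %.4g over %d px\n",
                                   x$rms, x$n_pixels))
  invisible(x)
}

#' Evaluate an illumination field on a pixel grid
#'
#' Pixel centers are at 0-based integer coordinates; the value at
#' `(xc, yc)` is `I0`.
#'
#' @param field An [illum_field()].
#' @param shape Image shape `c(ny, nx)` (rows = y, cols = x).
#' @return Numeric matrix `shape[1] x shape[2]`.
#' @export
eval_illum_field <- function(field, shape) {
  stopifnot(inherits(field, "illum_field"), length(shape) == 2L, all(shape >= 1))
  x <- seq_len(shape[2]) - 1
  y <- seq_len(shape[1]) - 1
  lor <- field$I0 / (1 + ((x - field$xc) / field$xR)^2)
  gau <- exp(-(y - field$yc)^2 / (2 * field$sigma_y^2))
  outer(gau, lor)
}

# Half-width at half-maximum of a marginal profile, as a crude scale guess.
marginal_hwhm <- function(p) {
  p <- p - min(p)
  above <- sum(p > max(p) / 2)
  max(above / 2, 1)
}

#' Fit an illumination field to a uniform-fluorophore reference image
#'
#' Least-squares fit of the Lorentzian-times-Gaussian sheet profile to every
#' pixel of a reference image (an averaged picture of a uniform fluorescent
#' solution). Initialization comes from intensity moments (centroid for the
#' centers, marginal half-widths for the scales, the maximum for `I0`);
#' the Levenberg-Marquardt fit is retried from up to `max_restarts` jittered
#' starts if it fails to converge.
#'
#' @param reference Numeric matrix with strictly positive median.
#' @param max_restarts Number of jittered restarts after a failed fit.
#' @return An `illum_fit` (also an `illum_field`) carrying the fitted
#'   parameters plus `rms` (residual root-mean-square) and `n_pixels`.
#'   Errors if no restart converges, reporting the best residual seen.
#' @export
fit_illumination_field <- function(reference, max_restarts = 5L) {
  stopifnot(is.matrix(reference), all(is.finite(reference)))
  if (stats::median(reference) <= 0) {
    stop("reference image must have a strictly positive median", call. = FALSE)
  }
  ny <- nrow(reference)
  nx <- ncol(reference)
  df <- data.frame(
    x = rep(seq_len(nx) - 1, each = ny),
    y = rep(seq_len(ny) - 1, times = nx),
    z = as.vector(reference)
  )
  w <- pmax(reference, 0)
  tot <- sum(w)
  start0 <- list(
    I0 = max(reference),
    xc = sum(colSums(w) * (seq_len(nx) - 1)) / tot,
    xR = marginal_hwhm(colSums(reference)),
    sy = marginal_hwhm(rowSums(reference)) / sqrt(2 * log(2)),
    yc = sum(rowSums(w) * (seq_len(ny) - 1)) / tot
  )
  lower <- c(I0 = .Machine$double.eps, xc = -nx, xR = 1e-3,
             sy = 1e-3, yc = -ny)
  upper <- c(I0 = Inf, xc = 2 * nx, xR = 10 * nx, sy = 10 * ny, yc = 2 * ny)

  best_fit <- NULL
  best_dev <- Inf
  for (attempt in seq_len(max_restarts + 1L)) {
    start <- start0
    if (attempt > 1L) {
      jit <- 1 + 0.3 * stats::qnorm((attempt - 0.5) / (max_restarts + 1))
      start <- lapply(start0, function(v) v * abs(jit))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ I0 / (1 + ((x - xc) / xR)^2) * exp(-(y - yc)^2 / (2 * sy^2)),
        data = df, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- stats::deviance(fit)
    if (dev < best_dev) {
      best_dev <- dev
      best_fit <- fit
    }
    if (isTRUE(fit$convInfo$isConv)) break
  }
  if (is.null(best_fit)) {
    stop("illumination-field fit failed to converge after ",
         max_restarts + 1L, " starts", call. = FALSE)
  }
  if (!isTRUE(best_fit$convInfo$isConv)) {
    stop(sprintf(
      "illumination-field fit did not converge after %d starts (best residual RMS %.4g)",
      max_restarts + 1L, sqrt(best_dev / nrow(df))), call. = FALSE)
  }
  p <- as.list(stats::coef(best_fit))
  out <- illum_field(I0 = p$I0, xc = p$xc, xR = p$xR,
                     sigma_y = p$sy, yc = p$yc)
  out$rms <- sqrt(best_dev / nrow(df))
  out$n_pixels <- nrow(df)
  class(out) <- c("illum_fit", class(out))
  out
}

#' @export
#' @rdname fit_illumination_field
#' @param x,object An `illum_fit`.
#' @param ... Unused.
tidy.illum_fit <- function(x, ...) {
  tibble::tibble(
    term = c("I0", "xc", "xR", "sigma_y", "yc"),
    estimate = c(x$I0, x$xc, x$xR, x$sigma_y, x$yc)
  )
}

#' @export
#' @rdname fit_illumination_field
glance.illum_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, n_pixels = x$n_pixels)
}

#' Correct an image for the illumination field
#'
#' Crops a fraction of rows from the top and the bottom (the vertical ends
#' of the sheet, where the fit is unreliable), then divides by the field
#' scaled to unit maximum over the cropped domain, so the brightest point of
#' the field is left unchanged and dim edges are boosted.
#'
#' @param image Numeric matrix.
#' @param field An [illum_field()].
#' @param crop_fraction Fraction of rows removed from each vertical end;
#'   in `[0, 0.5)`. Default 0.1.
#' @return Corrected matrix of `(1 - 2 crop_fraction) * nrow(image)` rows.
#' @export
correct_illumination <- function(image, field, crop_fraction = 0.1) {
  stopifnot(is.matrix(image), inherits(field, "illum_field"))
  if (crop_fraction < 0 || crop_fraction >= 0.5) {
    stop("crop_fraction must be in [0, 0.5)", call. = FALSE)
  }
  ny <- nrow(image)
  drop_n <- floor(crop_fraction * ny)
  rows <- seq.int(drop_n + 1L, ny - drop_n)
  f <- eval_illum_field(field, dim(image))[rows, , drop = FALSE]
  if (any(f <= 0)) {
    stop("illumination field evaluates <= 0 on the image domain; cannot normalize",
         call. = FALSE)
  }
  image[rows, , drop = FALSE] / (f / max(f))
}
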