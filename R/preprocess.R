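# Reconstruction of analysis-ready images from raw light-sheet acquisitions:
# dual-illumination averaging, stage-coordinate tile fusion, and maximum
# intensity projection. Illumination-field correction lives in
# correct_illumination().

#' Average the two light-sheet illumination directions
#'
#' Light-sheet acquisitions image each z-plane with both excitation sheets;
#' the two exposures are combined with a simple element-wise average.
#'
#' @param img_a,img_b Numeric arrays of identical shape.
#' @return Float-valued array, the element-wise mean.
#' @export
average_dual_illumination <- function(img_a, img_b) {
  if (!identical(dim(img_a), dim(img_b))) {
    stop("dual-illumination images must have identical shapes", call. = FALSE)
  }
  (img_a + img_b) / 2
}

#' Fuse image tiles using stage coordinates
#'
#' Places each tile at its stage offset converted to whole pixels
#' (`round(offset_um / pixel_size)`; no interpolation), on a canvas covering
#' the union of all tiles. Where tiles overlap the mean of the contributing
#' tiles is used; pixels covered by no tile are 0.
#'
#' @param tiles A tibble/data frame with a list-column `image` (matrices of
#'   identical shape) and numeric columns `stage_x`, `stage_y` in
#'   micrometers (x = anterior-posterior axis = columns, y = rows).
#' @param pixel_size Pixel size in micrometers per pixel, > 0.
#' @return Fused numeric matrix.
#' @export
fuse_tiles <- function(tiles, pixel_size) {
  stopifnot(is.data.frame(tiles),
            all(c("image", "stage_x", "stage_y") %in% names(tiles)),
            nrow(tiles) >= 1L)
  if (length(pixel_size) != 1L || !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a single positive number", call. = FALSE)
  }
  imgs <- tiles$image
  d <- dim(imgs[[1L]])
  if (!all(vapply(imgs, function(im) identical(dim(im), d), logical(1L)))) {
    stop("all tiles must share the same shape", call. = FALSE)
  }
  off_x <- round((tiles$stage_x - min(tiles$stage_x)) / pixel_size)
  off_y <- round((tiles$stage_y - min(tiles$stage_y)) / pixel_size)
  canvas <- c(max(off_y) + d[1L], max(off_x) + d[2L])
  acc <- matrix(0, canvas[1L], canvas[2L])
  cnt <- matrix(0L, canvas[1L], canvas[2L])
  for (k in seq_along(imgs)) {
    rows <- seq_len(d[1L]) + off_y[k]
    cols <- seq_len(d[2L]) + off_x[k]
    acc[rows, cols] <- acc[rows, cols] + imgs[[k]]
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  out <- acc
  covered <- cnt > 0L
  out[covered] <- acc[covered] / cnt[covered]
  out
}

#' Maximum intensity projection
#'
#' Per-(y, x) maximum of a 3D stack over z.
#'
#' @param stack Numeric 3D array `[y, x, z]`.
#' @return Numeric matrix `[y, x]`.
#' @export
max_project <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3L) stop("max_project() expects a 3D stack", call. = FALSE)
  out <- stack[, , 1L]
  for (k in seq_len(d[3L])[-1L]) out <- pmax(out, stack[, , k])
  out
}
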