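# Low-level image primitives shared across the pipeline.
#
# Images are plain numeric matrices [y, x] or 3D arrays [y, x, z]; y is the
# short (vertical) axis, x the anterior-posterior axis. External coordinates
# are 0-based pixel units (x = column - 1, y = row - 1).

# Convolve along the first dimension with a 1D kernel, replicate padding.
conv_first_dim <- function(x, kernel) {
  d <- dim(x)
  n <- d[1]
  m <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = d)
  idx_all <- seq_len(n)
  for (o in seq(-m, m)) {
    idx <- pmin(pmax(idx_all + o, 1L), n)
    k <- kernel[o + m + 1L]
    if (length(d) == 2L) {
      out <- out + k * x[idx, , drop = FALSE]
    } else {
      out <- out + k * x[idx, , , drop = FALSE]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  m <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-m, m))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur for 2D or 3D images
#'
#' Applies a 1D Gaussian kernel (truncated at 4 sigma, replicate padding)
#' along each array dimension in turn.
#'
#' @param x Numeric matrix or 3D array.
#' @param sigma Standard deviation in pixels; a scalar (applied to every
#'   dimension) or one value per dimension.
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.numeric(x), all(sigma >= 0))
  d <- dim(x)
  nd <- length(d)
  if (is.null(d) || nd < 2L || nd > 3L) {
    stop("gaussian_blur() expects a 2D matrix or 3D array", call. = FALSE)
  }
  sigma <- rep_len(sigma, nd)
  out <- x
  for (dd in seq_len(nd)) {
    if (sigma[dd] > 0) {
      perm <- c(dd, setdiff(seq_len(nd), dd))
      out <- aperm(conv_first_dim(aperm(out, perm), gaussian_kernel_1d(sigma[dd])),
                   order(perm))
    }
  }
  out
}

# Forward half of the full (8/26) neighbourhood, as integer offset rows.
forward_offsets <- function(nd) {
  g <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  keep <- apply(g, 1L, function(r) {
    nz <- which(r != 0)
    length(nz) > 0 && r[nz[1]] > 0
  })
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Full connectivity (8 in 2D, 26 in 3D). Foreground voxels become vertices
#' of an adjacency graph whose connected components define the labels,
#' assigned deterministically in voxel (column-major) order.
#'
#' @param mask Logical matrix or 3D array.
#' @return Integer array of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)), nd %in% c(2L, 3L))
  mask <- mask != 0
  fg <- which(mask)
  labels <- array(0L, dim = d)
  if (length(fg) == 0L) return(labels)
  rank <- integer(prod(d))
  rank[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  strides <- cumprod(c(1, d[-nd]))
  offs <- forward_offsets(nd)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[r, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (dd in seq_len(nd)) ok <- ok & nb[, dd] >= 1L & nb[, dd] <= d[dd]
    if (!any(ok)) next
    lin <- as.integer((nb[ok, , drop = FALSE] - 1) %*% strides) + 1L
    nbrank <- rank[lin]
    hit <- nbrank > 0L
    if (any(hit)) edges[[r]] <- cbind(rank[fg[ok]][hit], nbrank[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  labels
}

#' Binary dilation with a Euclidean ball
#'
#' @param mask Logical matrix or 3D array.
#' @param radius Ball radius in pixels (voxels treated isotropically).
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, radius) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L), radius >= 0)
  mask <- mask != 0
  if (radius == 0 || !any(mask)) return(mask)
  r <- floor(radius)
  g <- as.matrix(expand.grid(rep(list(seq(-r, r)), nd)))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  coords <- arrayInd(which(mask), d)
  strides <- cumprod(c(1, d[-nd]))
  out <- array(FALSE, dim = d)
  for (k in seq_len(nrow(g))) {
    nb <- sweep(coords, 2L, g[k, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (dd in seq_len(nd)) ok <- ok & nb[, dd] >= 1L & nb[, dd] <= d[dd]
    if (!any(ok)) next
    out[as.integer((nb[ok, , drop = FALSE] - 1) %*% strides) + 1L] <- TRUE
  }
  out
}

# Intensity levels and counts used by the Otsu-family thresholds. Exact on
# data with <= max_levels distinct values, otherwise a fixed-width histogram.
otsu_levels <- function(v, max_levels = 256L) {
  u <- sort(unique(v))
  if (length(u) <= max_levels) {
    list(levels = u, counts = tabulate(match(v, u), nbins = length(u)),
         exact = TRUE)
  } else {
    edges <- seq(min(v), max(v), length.out = max_levels + 1L)
    bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), max_levels)
    # threshold at a bin's upper edge keeps the induced classes clean
    list(levels = edges[-1L], counts = tabulate(bin, nbins = max_levels),
         exact = FALSE)
  }
}

#' Multi-Otsu thresholds (two thresholds, three classes)
#'
#' Chooses the threshold pair maximizing between-class variance of the
#' intensity distribution, by exact search over cumulative class moments.
#' Thresholds are inclusive upper bounds: class 1 is `x <= tau1`, class 2 is
#' `tau1 < x <= tau2`, class 3 is `x > tau2`. Ties are broken toward the
#' smallest threshold pair.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @return List with `tau` (length-2 numeric), `between_var`, and
#'   `degenerate` (TRUE when fewer than 3 distinct values exist, in which
#'   case `tau` is `NA`).
#' @export
multiotsu_thresholds <- function(x) {
  v <- as.vector(x)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 3L) {
    return(list(tau = c(NA_real_, NA_real_), between_var = NA_real_,
                degenerate = TRUE))
  }
  h <- otsu_levels(v)
  L <- length(h$levels)
  w <- h$counts / sum(h$counts)
  cw <- cumsum(w)
  cm <- cumsum(w * h$levels)
  mu <- cm[L]
  best <- -Inf
  best_ij <- c(NA_integer_, NA_integer_)
  # nonempty classes only
  for (i in seq_len(L - 2L)) {
    W1 <- cw[i]
    if (W1 == 0) next
    M1 <- cm[i] / W1
    j <- seq(i + 1L, L - 1L)
    W2 <- cw[j] - cw[i]
    W3 <- 1 - cw[j]
    ok <- W2 > 0 & W3 > 0
    if (!any(ok)) next
    M2 <- (cm[j] - cm[i]) / W2
    M3 <- (cm[L] - cm[j]) / W3
    bcv <- W1 * (M1 - mu)^2 + W2 * (M2 - mu)^2 + W3 * (M3 - mu)^2
    bcv[!ok] <- -Inf
    jbest <- which.max(bcv)
    if (bcv[jbest] > best) {
      best <- bcv[jbest]
      best_ij <- c(i, j[jbest])
    }
  }
  list(tau = h$levels[best_ij], between_var = best, degenerate = FALSE)
}

#' Single Otsu threshold
#'
#' Two-class special case of the same exact search; class 1 is `x <= tau`.
#'
#' @param x Numeric vector, matrix or array.
#' @return Threshold value, or `NA` for fewer than 2 distinct values.
#' @export
otsu_threshold <- function(x) {
  v <- as.vector(x)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L) return(NA_real_)
  h <- otsu_levels(v)
  L <- length(h$levels)
  w <- h$counts / sum(h$counts)
  cw <- cumsum(w)
  cm <- cumsum(w * h$levels)
  mu <- cm[L]
  i <- seq_len(L - 1L)
  W1 <- cw[i]
  W2 <- 1 - W1
  ok <- W1 > 0 & W2 > 0
  bcv <- ifelse(ok, (cm[i] - mu * W1)^2 / (W1 * W2), -Inf)
  h$levels[which.max(bcv)]
}

# Per-label summaries of a label array over a signal of the same shape.
label_stats <- function(labels, signal = NULL) {
  fg <- which(labels > 0L)
  if (length(fg) == 0L) {
    return(tibble::tibble(label = integer(), voxel_count = integer(),
                          sum_intensity = double(),
                          x = double(), y = double(), z = double()))
  }
  lab <- labels[fg]
  d <- dim(labels)
  coords <- arrayInd(fg, d)
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  n <- as.integer(table(f))
  s <- if (is.null(signal)) rep(NA_real_, length(ids)) else
    as.numeric(tapply(signal[fg], f, sum))
  cy <- as.numeric(tapply(coords[, 1L], f, mean)) - 1
  cx <- as.numeric(tapply(coords[, 2L], f, mean)) - 1
  cz <- if (length(d) == 3L) as.numeric(tapply(coords[, 3L], f, mean)) - 1 else
    rep(NA_real_, length(ids))
  tibble::tibble(label = ids, voxel_count = n, sum_intensity = s,
                 x = cx, y = cy, z = cz)
}
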