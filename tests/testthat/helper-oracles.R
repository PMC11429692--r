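# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Disk sum by explicit per-pixel loop (0-based fractional center).
bf_disk_sum <- function(image, cx, cy, radius) {
  total <- 0
  npx <- 0L
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (((i - 1) - cy)^2 + ((j - 1) - cx)^2 <= radius^2) {
        total <- total + image[i, j]
        npx <- npx + 1L
      }
    }
  }
  list(sum = total, n = npx)
}

# Exhaustive two-threshold Otsu over all pairs of observed values; between
# class variance computed directly from class means.
bf_multiotsu <- function(v) {
  u <- sort(unique(v))
  mu <- mean(v)
  best <- -Inf
  best_tau <- c(NA, NA)
  for (i in seq_len(length(u) - 2)) {
    for (j in seq((i + 1), length(u) - 1)) {
      c1 <- v[v <= u[i]]
      c2 <- v[v > u[i] & v <= u[j]]
      c3 <- v[v > u[j]]
      bcv <- length(c1) / length(v) * (mean(c1) - mu)^2 +
        length(c2) / length(v) * (mean(c2) - mu)^2 +
        length(c3) / length(v) * (mean(c3) - mu)^2
      if (bcv > best) {
        best <- bcv
        best_tau <- c(u[i], u[j])
      }
    }
  }
  best_tau
}

# Exhaustive 1-D two-partition minimizing within-cluster sum of squares;
# returns the midpoint of the two cluster means.
bf_split2 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  thr <- NA
  for (s in seq_len(n - 1)) {
    a <- xs[1:s]
    b <- xs[(s + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) {
      best <- ss
      thr <- (mean(a) + mean(b)) / 2
    }
  }
  thr
}

# Upper-tail hypergeometric P(overlap >= k) by enumerating every possible
# draw of n_up genes from a universe of size N containing K immune genes.
bf_hyper_p <- function(N, K, n_up, k) {
  draws <- utils::combn(N, n_up)
  hits <- apply(draws, 2, function(d) sum(d <= K) >= k)
  mean(hits)
}

# Shell-corrected nuclear sum by explicit voxel scanning: shell = voxels
# within Chebyshev window of the mask at Euclidean distance <= dil of any
# mask voxel, excluding every labeled voxel.
bf_shell_sum <- function(signal, labels, id, dil = 2) {
  d <- dim(labels)
  vox <- which(labels == id)
  coords <- arrayInd(vox, d)
  in_shell <- array(FALSE, d)
  all_idx <- which(array(TRUE, d))
  all_coords <- arrayInd(all_idx, d)
  for (q in seq_len(nrow(all_coords))) {
    if (labels[all_idx[q]] != 0) next
    d2 <- Inf
    for (p in seq_len(nrow(coords))) {
      dd <- sum((all_coords[q, ] - coords[p, ])^2)
      if (dd < d2) d2 <- dd
    }
    if (d2 <= dil^2) in_shell[all_idx[q]] <- TRUE
  }
  raw <- sum(signal[vox])
  raw - mean(signal[in_shell]) * length(vox)
}

# A small 3-level test image: three well-separated intensity plateaus in
# random proportions.
make_three_level_image <- function(ny, nx, levels = c(2, 30, 400)) {
  p <- stats::runif(3, 0.2, 1)
  p <- p / sum(p)
  vals <- sample(levels, ny * nx, replace = TRUE, prob = p)
  matrix(vals, ny, nx)
}

# Full-grid track table for every cell of a generated time-lapse.
tracks_from_truth <- function(tl, larva_id = 1) {
  cells <- tl$truth$cells[c("cell_id", "x", "y", "region")]
  tr <- tidyr::crossing(cells, frame = seq_along(tl$times) - 1L)
  tr$larva_id <- larva_id
  tr
}
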