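# AP-binned spatial-transcriptomics profiles on a cells x genes count matrix
# with per-cell AP coordinates: detection-fraction filtering, bootstrap
# error bars on per-bin mean transcript frequency, and immunity-gene-list
# overlap. "Transcript frequency" of a gene in a cell is its count divided
# by the cell's total counts.

#' Construct a spatial expression container
#'
#' @param counts Cells x genes matrix of nonnegative integer counts with
#'   unique column (gene) names.
#' @param ap Per-cell AP coordinate (finite numeric, length `nrow(counts)`).
#' @return A `spatial_expression`: list with `counts`, `ap`, `totals`.
#' @export
spatial_expression <- function(counts, ap) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), nrow(counts) == length(ap), all(is.finite(ap)))
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts needs unique gene (column) names", call. = FALSE)
  }
  structure(list(counts = counts, ap = as.numeric(ap),
                 totals = rowSums(counts)),
            class = "spatial_expression")
}

#' @export
print.spatial_expression <- function(x, ...) {
  cat(sprintf("<spatial_expression> %d cells x %d genes, median depth %.0f\n",
              nrow(x$counts), ncol(x$counts), stats::median(x$totals)))
  invisible(x)
}

#' Filter genes by detection fraction
#'
#' Keeps genes detected (count > 0) in at least `min_fraction` of cells
#' (inclusive at the boundary), preserving gene order. Idempotent.
#'
#' @param expr A [spatial_expression()].
#' @param min_fraction Detection threshold in (0, 1]; default 0.05.
#' @return Filtered `spatial_expression`.
#' @export
detection_filter <- function(expr, min_fraction = 0.05) {
  stopifnot(inherits(expr, "spatial_expression"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  det <- colMeans(expr$counts > 0)
  keep <- det >= min_fraction
  out <- expr
  out$counts <- expr$counts[, keep, drop = FALSE]
  out
}

#' AP-binned mean transcript frequency with bootstrap error bars
#'
#' Per-cell transcript frequency of the gene (count / total counts) is
#' averaged within each AP bin; the error bar is the standard deviation of
#' that average over `B` groups of cells resampled with replacement within
#' the bin. Cells with zero total counts are excluded with a warning.
#' Deterministic given `seed`.
#'
#' @param expr A [spatial_expression()].
#' @param gene Gene name.
#' @param n_bins Number of AP bins (default 10).
#' @param B Bootstrap resamples (default 100).
#' @param seed Integer seed (required for reproducibility).
#' @return An `ap_expression_profile` tibble: `gene`, `bin`, `bin_lo`,
#'   `bin_hi`, `n_cells`, `mean_freq`, `boot_sd` (empty bins give `NA`),
#'   with attributes `B` and `seed`.
#' @export
ap_bootstrap_profile <- function(expr, gene, n_bins = 10, B = 100, seed) {
  stopifnot(inherits(expr, "spatial_expression"), B >= 1, n_bins >= 1)
  if (missing(seed)) stop("supply a seed for the bootstrap", call. = FALSE)
  if (!gene %in% colnames(expr$counts)) {
    stop(sprintf("gene '%s' not present", gene), call. = FALSE)
  }
  ok <- expr$totals > 0
  if (!all(ok)) {
    warning(sum(!ok), " cell(s) with zero total counts excluded",
            call. = FALSE)
  }
  freq <- expr$counts[ok, gene] / expr$totals[ok]
  ap <- expr$ap[ok]
  edges <- seq(min(ap), max(ap), length.out = n_bins + 1L)
  bin <- pmin(findInterval(ap, edges, rightmost.closed = TRUE), n_bins)
  res <- withr::with_seed(seed, {
    lapply(seq_len(n_bins), function(b) {
      f <- freq[bin == b]
      n <- length(f)
      if (n == 0L) {
        return(tibble::tibble(bin = b, n_cells = 0L, mean_freq = NA_real_,
                              boot_sd = NA_real_))
      }
      boots <- vapply(seq_len(B), function(i) {
        mean(f[sample.int(n, n, replace = TRUE)])
      }, numeric(1L))
      tibble::tibble(bin = b, n_cells = n, mean_freq = mean(f),
                     boot_sd = stats::sd(boots))
    })
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(out, gene = gene, bin_lo = edges[.data$bin],
                       bin_hi = edges[.data$bin + 1L],
                       .before = 1L)
  out <- structure(out, class = c("ap_expression_profile", class(out)))
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}

#' Overlap of an upregulated gene list with a known-immunity gene list
#'
#' Identifiers are compared after whitespace trimming and case folding;
#' duplicates are removed with a warning. The p-value is the upper-tail
#' hypergeometric probability of an overlap at least as large, given
#' `universe_size` genes of which `length(immunity_list)` are immune.
#'
#' @param upregulated Character vector of upregulated gene identifiers.
#' @param immunity_list Character vector of known immunity genes.
#' @param universe_size Total genes in the universe; must be at least the
#'   size of the union of the two lists.
#' @return One-row tibble: `n_upregulated`, `n_immunity`, `overlap`,
#'   `universe_size`, `p_value`.
#' @export
immune_overlap <- function(upregulated, immunity_list, universe_size) {
  norm <- function(x) tolower(trimws(x))
  up <- norm(upregulated)
  imm <- norm(immunity_list)
  if (anyDuplicated(up) || anyDuplicated(imm)) {
    warning("duplicate gene identifiers removed", call. = FALSE)
    up <- unique(up)
    imm <- unique(imm)
  }
  if (universe_size < length(union(up, imm))) {
    stop("universe_size smaller than the union of the gene lists",
         call. = FALSE)
  }
  k <- length(intersect(up, imm))
  p <- stats::phyper(k - 1, length(imm), universe_size - length(imm),
                     length(up), lower.tail = FALSE)
  tibble::tibble(n_upregulated = length(up), n_immunity = length(imm),
                 overlap = k, universe_size = universe_size, p_value = p)
}
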