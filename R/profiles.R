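# Binned tag-density matrices around window summits (heatmap input, rows in
# the caller's order, typically a fold-change ranking) and their per-bin
# average profiles.

#' Tag-density matrix around window summits
#'
#' For each window, bins of `bin_width` bp tile the half-open span
#' `[summit - span/2, summit + span/2)`; bin `j` counts the sample's cut
#' positions in `[summit - span/2 + j*bin_width, ... + bin_width)`, scaled
#' by the sample's normalization factor.  Rows follow the order of
#' `windows` as supplied.  Windows whose span is clipped by a chromosome
#' edge keep out-of-range bins at zero and are flagged in the `clipped`
#' attribute.
#'
#' @param windows a window set (rows in the desired output order, e.g.
#'   reordered by [rank_windows()]).
#' @param track cut-site data frame (`chrom`, `pos`).
#' @param factor normalization factor for this sample (default 1).
#' @param bin_width bin size in bp (default 10).
#' @param span total profile width in bp (default 2000; must be even and a
#'   multiple of `bin_width`).
#' @return A `profile_matrix`: numeric matrix (windows x `span/bin_width`
#'   bins) with window ids as row names and bin start offsets as column
#'   names; attributes `bin_width`, `span`, `factor`, `clipped`.
#' @export
density_matrix <- function(windows, track, factor = 1, bin_width = 10, span = 2000) {
  stopifnot(span %% 2 == 0, span %% bin_width == 0, bin_width > 0)
  B <- span / bin_width
  half <- span / 2
  n <- nrow(windows)
  m <- matrix(0, n, B, dimnames = list(windows$window_id,
                                       seq(-half, half - bin_width, by = bin_width)))
  span_start <- windows$summit - half
  if (n > 0 && nrow(track) > 0) {
    sgr <- GenomicRanges::GRanges(windows$chrom,
                                  IRanges::IRanges(start = pmax(span_start, 0) + 1,
                                                   end = windows$summit + half))
    shared <- intersect(unique(windows$chrom), unique(track$chrom))
    tr <- track[track$chrom %in% shared, , drop = FALSE]
    if (nrow(tr)) {
      hits <- GenomicRanges::findOverlaps(sgr, .cp_points_gr(tr$chrom, tr$pos))
      wi <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
      off <- tr$pos[ci] - span_start[wi]
      keep <- off >= 0 & off < span            # guard clipped spans
      bin <- off[keep] %/% bin_width
      enc <- tabulate((wi[keep] - 1L) * B + bin + 1L, nbins = n * B)
      m <- matrix(enc, nrow = n, ncol = B, byrow = TRUE,
                  dimnames = dimnames(m))
    }
  }
  m <- m * factor
  attr(m, "bin_width") <- bin_width
  attr(m, "span") <- span
  attr(m, "factor") <- factor
  attr(m, "clipped") <- span_start < 0
  class(m) <- c("profile_matrix", class(m))
  m
}

#' Average tag-density profile
#'
#' Per-bin arithmetic mean over the windows of a [density_matrix()].
#'
#' @param matrix a `profile_matrix` with at least one row.
#' @return Numeric vector of per-bin means, named by bin offset.
#' @export
average_profile <- function(matrix) {
  if (nrow(matrix) == 0) cp_stop("cp_empty_matrix", "profile matrix has no rows")
  colMeans(matrix)
}
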