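# Cross-sample scaling.  DNase/ATAC count matrices are equalized with a
# correction factor based on the median of each sample's top-N window counts
# (N = 25,000 on genome-scale data, clamped to the number of windows);
# ChIP-style tracks are scaled by mapped-read depth.  In both cases the
# common reference is the geometric mean of the per-sample statistics, which
# makes the factors symmetric in the samples and idempotent on re-application.

.cp_norm_factors <- function(sample, m, method, n_top = NA_integer_) {
  G <- exp(mean(log(m)))
  nf <- data.frame(sample = sample, m = m, factor = G / m,
                   stringsAsFactors = FALSE)
  rownames(nf) <- NULL
  attr(nf, "method") <- method
  attr(nf, "reference") <- G
  attr(nf, "n_top") <- n_top
  class(nf) <- c("norm_factors", "data.frame")
  nf
}

#' Median-of-top-N-peaks normalization factors
#'
#' For each sample, `m_s` is the median of its `n_top` largest window counts
#' (restricted to `basis_windows` when given — e.g. a replicate-intersected
#' high-confidence window subset — and to all windows when the matrix has
#' fewer than `n_top`).  Factors are `G / m_s` with `G` the geometric mean of
#' the `m_s`, so multiplying by them equalizes the per-sample top-N medians.
#'
#' @param matrix raw count matrix from [count_cuts()].
#' @param n_top number of top windows entering the median (default 25000).
#' @param basis_windows optional character vector of window ids restricting
#'   the basis.
#' @return A `norm_factors` data frame (`sample`, `m`, `factor`) with the
#'   method, the reference statistic `G` and the `n_top` used as attributes.
#' @export
topn_median_factors <- function(matrix, n_top = 25000, basis_windows = NULL) {
  # accepts normalized input too: factors computed on an already-equalized
  # matrix are all 1, making re-normalization the identity
  if (!is.null(basis_windows)) {
    missing <- setdiff(basis_windows, rownames(matrix))
    if (length(missing))
      cp_stop("cp_config_error", "basis window not in matrix: %s", missing[1])
    matrix <- matrix[basis_windows, , drop = FALSE]
  }
  n_use <- min(n_top, nrow(matrix))
  if (n_use < 1) cp_stop("cp_config_error", "no windows available for normalization")
  m <- apply(matrix, 2, function(x) median(sort(x, decreasing = TRUE)[seq_len(n_use)]))
  if (any(m == 0)) {
    cp_stop("cp_degenerate_sample", "top-%d median is zero for sample %s",
            n_use, colnames(matrix)[which(m == 0)[1]])
  }
  .cp_norm_factors(colnames(matrix), m, "topn_median", as.integer(n_use))
}

#' Mapped-read-depth normalization factors
#'
#' `factor_s = G / depth_s` with `G` the geometric mean depth.
#'
#' @param mapped_read_counts named vector of positive per-sample depths.
#' @return A `norm_factors` data frame.
#' @export
depth_factors <- function(mapped_read_counts) {
  if (is.null(names(mapped_read_counts)))
    cp_stop("cp_config_error", "depths must be named by sample")
  if (any(mapped_read_counts <= 0)) {
    cp_stop("cp_degenerate_sample", "non-positive depth for sample %s",
            names(mapped_read_counts)[which(mapped_read_counts <= 0)[1]])
  }
  .cp_norm_factors(names(mapped_read_counts), as.numeric(mapped_read_counts), "depth")
}

#' Apply normalization factors to a raw count matrix
#'
#' @param matrix raw count matrix.
#' @param factors a `norm_factors` object covering every sample column.
#' @return The scaled matrix, flagged normalized, with the factors attached
#'   as the `norm_factors` attribute.
#' @export
apply_factors <- function(matrix, factors) {
  idx <- match(colnames(matrix), factors$sample)
  if (anyNA(idx)) {
    cp_stop("cp_missing_factor", "no factor for sample %s",
            colnames(matrix)[which(is.na(idx))[1]])
  }
  out <- sweep(matrix, 2, factors$factor[idx], `*`)
  attr(out, "normalized") <- TRUE
  attr(out, "norm_factors") <- factors
  out
}
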