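# Linking accessibility to expression: TPM filtering and upper-quartile
# normalization, gene-level log2 fold changes, nearest-TSS assignment, and
# the fold-change-rank vs expression trend with its Spearman statistic.

#' Filter and upper-quartile-normalize a TPM table
#'
#' Genes detected with TPM > 1 in at least one sample are retained; each
#' sample is then scaled so its upper quartile (75th percentile, linear
#' interpolation / type 7) of retained TPMs equals the geometric mean of the
#' per-sample upper quartiles; finally values are transformed as
#' `log2(TPM + 1)`.
#'
#' @param table genes x samples TPM matrix (see [read_expression()]).
#' @return Log2-scale matrix of retained genes with attributes
#'   `uq_factors` (per-sample scale factors) and `n_filtered`.
#' @export
normalize_tpm <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  keep <- apply(table, 1, function(x) any(x > 1))
  m <- table[keep, , drop = FALSE]
  if (nrow(m) == 0) cp_stop("cp_config_error", "no genes pass the TPM > 1 filter")
  uq <- apply(m, 2, quantile, probs = 0.75, type = 7, names = FALSE)
  if (any(uq == 0)) {
    cp_stop("cp_degenerate_sample", "upper quartile is zero for sample %s",
            colnames(m)[which(uq == 0)[1]])
  }
  G <- exp(mean(log(uq)))
  factors <- G / uq
  out <- log2(sweep(m, 2, factors, `*`) + 1)
  attr(out, "uq_factors") <- setNames(factors, colnames(m))
  attr(out, "n_filtered") <- sum(!keep)
  attr(out, "samples") <- attr(table, "samples")
  out
}

#' Per-gene log2 fold change between two sample groups
#'
#' `log2FC = mean_A(log2(TPM+1)) - mean_B(log2(TPM+1))` on the normalized
#' log-scale matrix; `over_3fold` flags `|log2FC| > log2(3)`, the fold
#' component of the "more than 3-fold changed" filter (significance testing
#' of expression, if wanted, is supplied externally and joined on
#' `gene_id`).
#'
#' @param logmatrix output of [normalize_tpm()].
#' @param samples_a,samples_b character vectors of column names.
#' @param adjusted_p optional named vector of externally computed adjusted
#'   p-values, joined by gene id.
#' @return Data frame: `gene_id`, `log2fc`, `over_3fold` (and `adj_p` when
#'   supplied).
#' @export
gene_fold_changes <- function(logmatrix, samples_a, samples_b, adjusted_p = NULL) {
  .cp_check_samples(logmatrix, c(samples_a, samples_b))
  fc <- rowMeans(logmatrix[, samples_a, drop = FALSE]) -
    rowMeans(logmatrix[, samples_b, drop = FALSE])
  out <- data.frame(gene_id = rownames(logmatrix), log2fc = fc,
                    over_3fold = abs(fc) > log2(3),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(adjusted_p)) out$adj_p <- adjusted_p[out$gene_id]
  out
}

#' Assign each window its nearest gene TSS
#'
#' Nearest by `|summit - tss|` on the same chromosome, irrespective of
#' strand; ties are broken by the lower TSS coordinate, then lexicographic
#' `gene_id`.  The signed distance is negative when the summit lies upstream
#' of the TSS in the gene's orientation.  Windows with no same-chromosome
#' TSS are returned unlinked (`NA` gene, infinite distance).
#'
#' @param windows a [make_windows()] window set.
#' @param tss TSS table (`gene_id`, `chrom`, `tss`, `strand`).
#' @return Data frame: `window_id`, `gene_id`, `distance`,
#'   `signed_distance`.
#' @export
nearest_gene <- function(windows, tss) {
  n <- nrow(windows)
  gene <- rep(NA_character_, n); dist <- rep(Inf, n); sdist <- rep(NA_real_, n)
  for (ch in unique(windows$chrom)) {
    qi <- which(windows$chrom == ch)
    t <- tss[tss$chrom == ch, , drop = FALSE]
    if (!nrow(t)) next
    t <- t[order(t$tss, t$gene_id), , drop = FALSE]
    q <- windows$summit[qi]
    idx <- findInterval(q, t$tss)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, nrow(t))
    dlo <- abs(q - t$tss[lo]); dhi <- abs(q - t$tss[hi])
    # ties between flanking TSSs go to the lower coordinate (lo side)
    use_lo <- idx >= 1L & (idx >= nrow(t) | dlo <= dhi)
    best_val <- ifelse(use_lo, t$tss[lo], t$tss[hi])
    # first row of the winning tss value = lex smallest gene_id at that tss
    win <- match(best_val, t$tss)
    gene[qi] <- t$gene_id[win]
    dist[qi] <- abs(q - best_val)
    rel <- q - best_val
    sdist[qi] <- ifelse(t$strand[win] == "-", -rel, rel)
  }
  data.frame(window_id = windows$window_id, gene_id = gene,
             distance = dist, signed_distance = sdist,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression trend along the accessibility fold-change ranking
#'
#' Joins ranked windows to their nearest-gene fold changes and computes the
#' Spearman correlation between window rank and gene log2 fold change — the
#' summary statistic behind ranked-DHS vs nearest-gene-expression trend
#' plots.  An optional centered rolling median smooths the series for
#' plotting.
#'
#' @param ranked_ids window ids in rank order (from [rank_windows()]).
#' @param links nearest-gene links from [nearest_gene()].
#' @param gene_fc gene fold changes from [gene_fold_changes()].
#' @param roll odd rolling-median width (0 disables smoothing).
#' @return List: `series` (data frame `rank`, `window_id`, `gene_id`,
#'   `log2fc`, and `smoothed` when `roll > 0`), `rho`, `n`.
#' @export
rank_expression_trend <- function(ranked_ids, links, gene_fc, roll = 0) {
  li <- match(ranked_ids, links$window_id)
  gid <- links$gene_id[li]
  fc <- gene_fc$log2fc[match(gid, gene_fc$gene_id)]
  series <- data.frame(rank = seq_along(ranked_ids), window_id = ranked_ids,
                       gene_id = gid, log2fc = fc, stringsAsFactors = FALSE)
  ok <- !is.na(series$log2fc)
  rho <- if (sum(ok) >= 3 && stats::sd(series$log2fc[ok]) > 0)
    suppressWarnings(cor(series$rank[ok], series$log2fc[ok], method = "spearman"))
  else 0
  if (roll > 0) {
    stopifnot(roll %% 2 == 1)
    h <- (roll - 1) / 2
    v <- series$log2fc
    series$smoothed <- vapply(seq_along(v), function(i) {
      w <- v[max(1, i - h):min(length(v), i + h)]
      median(w, na.rm = TRUE)
    }, numeric(1))
  }
  list(series = series, rho = rho, n = sum(ok))
}
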