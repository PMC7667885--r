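# TPM filtering and upper-quartile normalization, gene fold changes,
# nearest-TSS linkage, and the accessibility-rank vs expression trend.

tpm_mat <- function(..., genes = NULL) {
  m <- rbind(...)
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  m
}

test_that("normalize_tpm filters, upper-quartile scales, and log-transforms", {
  # single sample worked example: UQ of {1.5, 3, 7, 15} is 9 (type-7), factor 1
  m <- tpm_mat(c(1.5), c(3), c(7), c(15))
  colnames(m) <- "s1"
  out <- normalize_tpm(m)
  expect_equal(unname(attr(out, "uq_factors")), 1)
  expect_equal(quantile(m[, 1], 0.75, type = 7, names = FALSE), 9)
  expect_equal(unname(out["g4", 1]), log2(15 + 1))

  # genes with TPM <= 1 everywhere are removed; a retained zero logs to 0
  m2 <- tpm_mat(c(0.5, 0.9), c(0, 8), c(4, 4))
  out2 <- normalize_tpm(m2)
  expect_equal(rownames(out2), c("g2", "g3"))
  f <- attr(out2, "uq_factors")
  expect_equal(unname(out2["g2", 1]), log2(0 * f[[1]] + 1))
  expect_equal(unname(out2["g2", 1]), 0)
})

test_that("normalize_tpm equalizes upper quartiles and is idempotent", {
  set.seed(900)
  m <- tpm_mat(matrix(rexp(400, 1 / 20), 100, 4))
  m[, 3] <- m[, 3] * 5
  out <- normalize_tpm(m)
  lin <- 2^out - 1                               # back to the scaled TPM scale
  uq <- apply(lin, 2, quantile, probs = 0.75, type = 7)
  expect_equal(unname(uq / exp(mean(log(uq)))), rep(1, 4), tolerance = 1e-9)
  refac <- exp(mean(log(uq))) / uq
  expect_equal(unname(refac), rep(1, 4), tolerance = 1e-9)
})

test_that("degenerate samples in the TPM table are rejected", {
  m <- tpm_mat(c(2, 0), c(3, 0), c(4, 0), c(5, 0))
  expect_error(normalize_tpm(m), class = "cp_degenerate_sample")
})

test_that("gene fold changes are mean log differences with a 3-fold flag", {
  lm <- tpm_mat(c(5, 5, 3, 3), c(2, 2, 2, 2), genes = c("up", "flat"))
  colnames(lm) <- c("a1", "a2", "b1", "b2")
  fc <- gene_fold_changes(lm, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fc$log2fc, c(2, 0))
  expect_equal(fc$over_3fold, c(TRUE, FALSE))     # 2 > log2(3) ~ 1.585

  sub <- lm["up", , drop = FALSE]                  # filtered gene absent, no imputation
  expect_equal(gene_fold_changes(sub, c("a1", "a2"), c("b1", "b2"))$gene_id, "up")

  padj <- c(up = 0.01, flat = 0.9)
  expect_equal(gene_fold_changes(lm, c("a1", "a2"), c("b1", "b2"), padj)$adj_p,
               c(0.01, 0.9), ignore_attr = TRUE)
})

test_that("nearest_gene links by TSS distance with pinned tie-breaks", {
  w <- windows_at("chr1", 10000)
  tss <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                    tss = c(9000, 15000), strand = c("+", "+"))
  link <- nearest_gene(w, tss)
  expect_equal(link$gene_id, "geneA")
  expect_equal(link$distance, 1000)
  expect_equal(link$signed_distance, 1000)         # summit downstream of + TSS

  # equidistant: lower coordinate wins; equal coordinate: lexicographic gene_id
  tie <- data.frame(gene_id = c("geneC", "geneB"), chrom = "chr1",
                    tss = c(8000, 12000), strand = "+")
  expect_equal(nearest_gene(w, tie)$gene_id, "geneC")
  same_pos <- data.frame(gene_id = c("zz", "aa"), chrom = "chr1",
                         tss = c(9000, 9000), strand = "+")
  expect_equal(nearest_gene(w, same_pos)$gene_id, "aa")

  # minus-strand signed distance flips sign; unlinked window reported
  minus <- data.frame(gene_id = "gm", chrom = "chr1", tss = 9000, strand = "-")
  expect_equal(nearest_gene(w, minus)$signed_distance, -1000)
  off <- nearest_gene(w, data.frame(gene_id = "gx", chrom = "chr9",
                                    tss = 1, strand = "+"))
  expect_true(is.na(off$gene_id))
  expect_equal(off$distance, Inf)
})

test_that("nearest_gene equals the quadratic oracle on random instances", {
  set.seed(901)
  for (i in 1:30) {
    w <- make_windows(rand_summits(sample(1:50, 1)))
    nt <- sample(1:60, 1)
    tss <- data.frame(gene_id = paste0("g", sample(1000, nt)),
                      chrom = sample(c("chr1", "chr2"), nt, replace = TRUE),
                      tss = sample.int(5000, nt, replace = TRUE) - 1L,
                      strand = sample(c("+", "-"), nt, replace = TRUE),
                      stringsAsFactors = FALSE)
    got <- nearest_gene(w, tss)
    want <- oracle_nearest_gene(w, tss)
    expect_identical(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
  }
})

test_that("the rank/expression trend statistic behaves on pinned series", {
  links <- data.frame(window_id = paste0("w", 1:5), gene_id = paste0("g", 1:5),
                      distance = 0, signed_distance = 0)
  flat <- data.frame(gene_id = paste0("g", 1:5), log2fc = rep(1.5, 5),
                     over_3fold = FALSE)
  expect_equal(rank_expression_trend(paste0("w", 1:5), links, flat)$rho, 0)

  mono <- data.frame(gene_id = paste0("g", 1:5), log2fc = c(-2, -1, 0, 1, 2),
                     over_3fold = FALSE)
  tr <- rank_expression_trend(paste0("w", 1:5), links, mono)
  expect_equal(tr$rho, 1)
  expect_equal(tr$n, 5)

  sm <- rank_expression_trend(paste0("w", 1:5), links, mono, roll = 3)
  expect_equal(sm$series$smoothed, c(-1.5, -1, 0, 1, 1.5))
})

test_that("genes linked to cytokine-dependent windows show higher expression fold change", {
  p <- shared_pipeline_objects()
  links <- nearest_gene(p$windows, p$ds$tss)
  logm <- normalize_tpm(p$ds$tpm)
  gfc <- gene_fold_changes(logm, c("A_rep1", "A_rep2"), c("A_nil_rep1", "A_nil_rep2"))
  cls <- match_truth(p$windows, p$ds$truth)
  fc_of <- function(cl) {
    g <- links$gene_id[!is.na(cls) & cls == cl]
    mean(gfc$log2fc[match(g, gfc$gene_id)], na.rm = TRUE)
  }
  expect_gt(fc_of("dependent_primed"), fc_of("invariant") + 1)
})
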