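# Independent brute-force oracles.  Each is a direct, quadratic or
# exhaustive transcription of the operation's definition, deliberately
# avoiding the code paths (interval trees, findInterval, Biostrings) used by
# the implementation.

oracle_count_cuts <- function(windows, tracks) {
  m <- matrix(0L, nrow(windows), length(tracks),
              dimnames = list(windows$window_id, names(tracks)))
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    for (i in seq_len(nrow(windows))) {
      m[i, s] <- sum(tr$chrom == windows$chrom[i] &
                       tr$pos >= windows$start[i] & tr$pos < windows$end[i])
    }
  }
  m
}

oracle_overlap_flags <- function(query, target) {
  qs <- if ("pos" %in% names(query)) query$pos else query$start
  qe <- if ("pos" %in% names(query)) query$pos + 1 else query$end
  ts <- if ("pos" %in% names(target)) target$pos else target$start
  te <- if ("pos" %in% names(target)) target$pos + 1 else target$end
  vapply(seq_along(qs), function(i) {
    any(target$chrom == query$chrom[i] & ts < qe[i] & te > qs[i])
  }, logical(1))
}

oracle_nearest_distance <- function(query, target, max_dist) {
  qpos <- if ("summit" %in% names(query)) query$summit else query$pos
  tpos <- if ("summit" %in% names(target)) target$summit else target$pos
  d <- vapply(seq_along(qpos), function(i) {
    t <- tpos[target$chrom == query$chrom[i]]
    if (!length(t)) Inf else min(abs(qpos[i] - t))
  }, numeric(1))
  data.frame(distance = d, within = d <= max_dist)
}

oracle_nearest_gene <- function(windows, tss) {
  out <- lapply(seq_len(nrow(windows)), function(i) {
    t <- tss[tss$chrom == windows$chrom[i], , drop = FALSE]
    if (!nrow(t)) return(list(gene = NA_character_, dist = Inf))
    d <- abs(windows$summit[i] - t$tss)
    cand <- t[d == min(d), , drop = FALSE]
    cand <- cand[order(cand$tss, cand$gene_id), , drop = FALSE]
    list(gene = cand$gene_id[1], dist = min(d))
  })
  data.frame(gene_id = vapply(out, `[[`, "", "gene"),
             distance = vapply(out, `[[`, 0, "dist"))
}

oracle_call_dependent <- function(matrix, pairs, params) {
  member <- vapply(seq_len(nrow(matrix)), function(w) {
    all(vapply(pairs, function(p) {
      a <- matrix[w, p[1]]; b <- matrix[w, p[2]]
      (a + params$pseudocount) / (b + params$pseudocount) >= params$fold_threshold &&
        max(a, b) >= params$min_count
    }, logical(1)))
  }, logical(1))
  rownames(matrix)[member]
}

oracle_venn <- function(flag_vectors) {
  k <- length(flag_vectors); n <- length(flag_vectors[[1]])
  cells <- integer(0)
  for (code in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(code))[k:1]
    hit <- rep(TRUE, n)
    for (j in seq_len(k)) hit <- hit & (as.integer(flag_vectors[[j]]) == bits[j])
    cells[paste(bits, collapse = "")] <- sum(hit)
  }
  cells
}

oracle_pool_summits <- function(summits, cluster_dist) {
  # union-find transitive closure over all pairs within cluster_dist
  n <- nrow(summits)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && summits$chrom[i] == summits$chrom[j] &&
        abs(summits$pos[i] - summits$pos[j]) <= cluster_dist) {
      parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), root), function(idx) {
    sc <- ifelse(is.na(summits$score[idx]), -Inf, summits$score[idx])
    idx[order(-sc, summits$pos[idx], summits$sample_id[idx])[1]]
  }, integer(1))
  out <- summits[sort(reps), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# IUPAC consensus -> regex, and oracle scan on explicit region strings
iupac_regex <- function(consensus) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]", S = "[CG]",
           W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(consensus, "")[[1]]], collapse = "")
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_scan <- function(region, consensus) {
  grepl(iupac_regex(consensus), region) ||
    grepl(iupac_regex(revcomp_chr(consensus)), region)
}

# random-instance generators ---------------------------------------------------

rand_cutsites <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000) {
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(max_pos, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

rand_summits <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000) {
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(max_pos, n, replace = TRUE) - 1L,
             score = round(runif(n, 0, 100), 1),
             sample_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(300, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
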