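# Set-level annotation of DHS calls: overlap with external peak sets, Venn
# partitions across several targets, IUPAC consensus motif scanning around
# summits, and summit-to-summit proximity.

#' Declare an IUPAC consensus motif
#'
#' @param name motif name (e.g. `"STAT5_GAS"`).
#' @param consensus IUPAC consensus string (length >= 4).
#' @param max_mismatches mismatches tolerated (default 0).
#' @param flank scan half-width around the summit in bp (default 100).
#' @return A `motif_model` list.
#' @export
motif_model <- function(name, consensus, max_mismatches = 0, flank = 100) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4) cp_stop("cp_config_error", "consensus must be >= 4 bases")
  if (grepl("[^ACGTRYSWKMBDHVN]", consensus))
    cp_stop("cp_config_error", "consensus contains non-IUPAC letters: %s", consensus)
  structure(list(name = name, consensus = consensus,
                 max_mismatches = max_mismatches, flank = flank),
            class = "motif_model")
}

#' Default consensus motif library
#'
#' Deterministic stand-ins for the inducible and cytokine-response motif
#' families: the STAT5/GAS palindrome `TTCYNRGAA` and the AP-1 heptamer
#' `TGASTCA`.  Consensus matching approximates, and does not reproduce,
#' position-weight-matrix scanning.
#'
#' @return Named list of [motif_model()] objects.
#' @export
default_motifs <- function() {
  list(STAT5_GAS = motif_model("STAT5_GAS", "TTCYNRGAA"),
       AP1 = motif_model("AP1", "TGASTCA"))
}

.cp_intervals_gr <- function(x) {
  if (inherits(x, "window_set") || all(c("start", "end") %in% names(x)))
    return(.cp_windows_gr(x))
  if ("pos" %in% names(x)) return(.cp_points_gr(x$chrom, x$pos))
  cp_stop("cp_config_error", "cannot interpret interval input")
}

#' Flag query windows overlapping a target interval set
#'
#' True iff the query window shares at least 1 bp with any target interval
#' (half-open coordinates on both sides).
#'
#' @param query window set or interval data frame (`chrom`, `start`, `end`,
#'   or `chrom`, `pos` for 1-bp records).
#' @param target interval data frame.
#' @return Logical vector, one flag per query row.
#' @export
overlap_flags <- function(query, target) {
  qgr <- .cp_intervals_gr(query)
  if (nrow(target) == 0) return(rep(FALSE, length(qgr)))
  # disjoint chromosome sets are a legitimate all-FALSE case, not a warning
  suppressWarnings(as.logical(IRanges::overlapsAny(qgr, .cp_intervals_gr(target))))
}

#' Venn partition of overlap flags
#'
#' Given `k` boolean vectors over the same query set, counts every
#' presence/absence cell of the `2^k` partition, plus the number and
#' fraction of queries present in at least one target.
#'
#' @param flag_vectors named list of equal-length logical vectors.
#' @return List with `cells` (named counts, names like `"101"` in the order
#'   of `flag_vectors`), `labels`, `n`, `n_any`, `fraction_any`.
#' @export
venn_partition <- function(flag_vectors) {
  stopifnot(is.list(flag_vectors), length(flag_vectors) >= 1)
  n <- unique(lengths(flag_vectors))
  if (length(n) != 1) cp_stop("cp_length_mismatch", "flag vectors have unequal lengths")
  k <- length(flag_vectors)
  combos <- expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE]
  cell_names <- apply(combos, 1, paste, collapse = "")
  pattern <- do.call(paste0, lapply(flag_vectors, function(v) as.integer(v)))
  counts <- table(factor(pattern, levels = sort(cell_names)))
  n_any <- if (n == 0) 0L else sum(Reduce(`|`, flag_vectors))
  list(cells = setNames(as.integer(counts), names(counts)),
       labels = names(flag_vectors), n = n, n_any = n_any,
       fraction_any = if (n == 0) NA_real_ else n_any / n)
}

.cp_genome_seqs <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  cp_stop("cp_config_error", "genome must be a FASTA path, named character vector, or DNAStringSet")
}

#' Scan summit-flanking sequence for a consensus motif
#'
#' Extracts `summit +/- flank` (clipped at contig ends) for each window and
#' reports whether the IUPAC consensus matches anywhere on the forward or
#' reverse-complement strand with at most `max_mismatches` mismatches.
#' Windows on contigs absent from the genome get `FALSE` and a
#' `cp_missing_sequence` warning.
#'
#' @param windows a window set (uses `summit`) or summit data frame (`pos`).
#' @param genome FASTA path, named character vector, or
#'   [Biostrings::DNAStringSet].
#' @param motif a [motif_model()].
#' @return Named logical vector (window ids or row indices).
#' @export
scan_consensus <- function(windows, genome, motif) {
  seqs <- .cp_genome_seqs(genome)
  # FASTA headers may carry descriptions; key on the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  pos <- if ("summit" %in% names(windows)) windows$summit else windows$pos
  ids <- if ("window_id" %in% names(windows)) windows$window_id else as.character(seq_along(pos))
  out <- setNames(rep(FALSE, length(pos)), ids)
  present <- windows$chrom %in% names(seqs)
  if (any(!present)) {
    cp_warn("cp_missing_sequence", "%d windows on contigs absent from the genome (%s)",
            sum(!present), paste(unique(windows$chrom[!present]), collapse = ", "))
  }
  if (!any(present)) return(out)
  lens <- Biostrings::width(seqs)[match(windows$chrom[present], names(seqs))]
  # 0-based [pos - flank, pos + flank + 1) -> 1-based [pos - flank + 1, pos + flank + 1]
  from <- pmax(1, pos[present] - motif$flank + 1)
  to <- pmin(lens, pos[present] + motif$flank + 1)
  regions <- Biostrings::DNAStringSet(seqs[windows$chrom[present]],
                                      start = from, end = to)
  fwd <- Biostrings::vcountPattern(motif$consensus, regions,
                                   max.mismatch = motif$max_mismatches, fixed = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif$consensus)))
  rev <- Biostrings::vcountPattern(rc, regions,
                                   max.mismatch = motif$max_mismatches, fixed = FALSE)
  out[present] <- (fwd + rev) > 0
  out
}

#' Distance from each query summit to the nearest target summit
#'
#' Distances are summit-to-summit (`min |query_pos - target_pos|` over
#' same-chromosome targets); queries with no same-chromosome target get
#' `Inf`.  The `within` flag tests `distance <= max_dist` (default 25 kb,
#' the local-cooperation distance between primed and inducible sites).
#'
#' @param query,target summit data frames (`chrom`, `pos`) or window sets
#'   (`chrom`, `summit`).
#' @param max_dist proximity threshold in bp (default 25000).
#' @return Data frame aligned with `query`: `distance`, `within`,
#'   `nearest_pos`.
#' @export
nearest_distance <- function(query, target, max_dist = 25000) {
  qpos <- if ("summit" %in% names(query)) query$summit else query$pos
  tpos <- if ("summit" %in% names(target)) target$summit else target$pos
  n <- length(qpos)
  dist <- rep(Inf, n); npos <- rep(NA_real_, n)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    t <- sort(tpos[target$chrom == ch])
    if (!length(t)) next
    idx <- findInterval(qpos[qi], t)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(t))
    dlo <- abs(qpos[qi] - t[lo]); dhi <- abs(qpos[qi] - t[hi])
    use_lo <- idx >= 1L & (idx >= length(t) | dlo <= dhi)
    dist[qi] <- ifelse(use_lo, dlo, dhi)
    npos[qi] <- ifelse(use_lo, t[lo], t[hi])
  }
  data.frame(distance = dist, within = dist <= max_dist, nearest_pos = npos)
}
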