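# Union window construction from per-sample summits and per-window tag
# counting.  The union is built by single-linkage clustering of per-sample
# summits (distance <= cluster_dist); an externally computed union summit BED
# (e.g. from peak calling on pooled alignments) can be supplied instead and
# fed straight into make_windows().

#' Pool per-sample summit sets into a union summit set
#'
#' Single-linkage clustering per chromosome: consecutive summits at most
#' `cluster_dist` bp apart join one cluster, and each cluster is represented
#' by its highest-scoring summit (ties: lower coordinate, then lexicographic
#' `sample_id`).  Pooling is idempotent: applying it to its own output
#' returns the same set.
#'
#' @param summit_sets a summit data frame or a (possibly named) list of them
#'   (columns `chrom`, `pos`, `score`, `sample_id`).
#' @param cluster_dist linkage distance in bp (default 200).
#' @return A summit data frame sorted by (chrom, pos).
#' @export
pool_summits <- function(summit_sets, cluster_dist = 200) {
  stopifnot(cluster_dist >= 0)
  if (is.data.frame(summit_sets)) summit_sets <- list(summit_sets)
  all <- do.call(rbind, lapply(summit_sets, function(s)
    s[c("chrom", "pos", "score", "sample_id")]))
  if (is.null(all) || nrow(all) == 0) return(.cp_empty_records("summit"))
  all <- all[order(all$chrom, all$pos), , drop = FALSE]
  out <- lapply(split(all, all$chrom), function(g) {
    cl <- cumsum(c(1, diff(g$pos) > cluster_dist))
    sc <- ifelse(is.na(g$score), -Inf, g$score)
    reps <- vapply(split(seq_len(nrow(g)), cl), function(idx) {
      o <- order(-sc[idx], g$pos[idx], g$sample_id[idx])
      idx[o[1]]
    }, integer(1))
    g[sort(reps), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build summit-centered counting windows
#'
#' Each summit becomes the window `[pos - flank, pos + flank + 1)` (401 bp at
#' the default flank of 200), clipped at zero and, when `chrom_lengths` is
#' supplied, at the chromosome end.  Window ids are assigned in
#' (chrom, start) sort order.
#'
#' @param summits summit data frame (`chrom`, `pos`, ...).
#' @param flank half-width in bp (default 200).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return A `window_set` data frame: `window_id`, `chrom`, `summit`,
#'   `start`, `end`.
#' @export
make_windows <- function(summits, flank = 200, chrom_lengths = NULL) {
  stopifnot(flank >= 0)
  start <- pmax(0, summits$pos - flank)
  end <- summits$pos + flank + 1
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[summits$chrom]
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  w <- data.frame(chrom = summits$chrom, summit = summits$pos,
                  start = start, end = end, stringsAsFactors = FALSE)
  w <- w[order(w$chrom, w$start, w$end), , drop = FALSE]
  w <- data.frame(window_id = sprintf("w%05d", seq_len(nrow(w))), w,
                  stringsAsFactors = FALSE)
  rownames(w) <- NULL
  class(w) <- c("window_set", "data.frame")
  w
}

.cp_windows_gr <- function(windows) {
  GenomicRanges::GRanges(windows$chrom,
                         IRanges::IRanges(start = windows$start + 1, end = windows$end))
}

.cp_points_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1, width = 1))
}

#' Count cut-site tags per window per sample
#'
#' Entry (w, s) is the number of cut positions `p` of sample `s` with
#' `start <= p < end` (half-open).  A cut inside two overlapping windows is
#' counted in both.  Tags on chromosomes absent from the window set are
#' ignored with an `cp_unknown_chromosome` warning reporting how many.
#'
#' @param windows a [make_windows()] window set.
#' @param tracks named list of cut-site data frames (`chrom`, `pos`).
#' @return Raw integer count matrix (windows x samples) with window ids as
#'   row names and the `normalized` attribute set to `FALSE`.
#' @export
count_cuts <- function(windows, tracks) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  wgr <- .cp_windows_gr(windows)
  known <- unique(windows$chrom)
  m <- matrix(0L, nrow(windows), length(tracks),
              dimnames = list(windows$window_id, names(tracks)))
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    alien <- !(tr$chrom %in% known)
    if (any(alien)) {
      cp_warn("cp_unknown_chromosome",
              "sample %s: %d tags on chromosomes absent from the window set (%s) ignored",
              s, sum(alien), paste(unique(tr$chrom[alien]), collapse = ", "))
      tr <- tr[!alien, , drop = FALSE]
    }
    if (nrow(tr)) {
      m[, s] <- GenomicRanges::countOverlaps(wgr, .cp_points_gr(tr$chrom, tr$pos))
    }
  }
  attr(m, "normalized") <- FALSE
  m
}

#' Naive summit caller for synthetic cut tracks
#'
#' Convenience caller used only on simulated data (peak-calling proper is an
#' upstream input): bins coverage at `bin` bp, smooths with a 3-bin moving
#' average (zero-padded ends), emits local maxima whose smoothed count
#' reaches `min_count` (summit = center of the maximal bin), and merges
#' maxima closer than `2 * bin`, keeping the higher.
#'
#' @param track cut-site data frame (`chrom`, `pos`).
#' @param bin bin width in bp (default 50).
#' @param min_count smoothed-count threshold for emitting a summit.
#' @param sample_id label attached to the emitted records.
#' @return Summit data frame (`chrom`, `pos`, `score`, `sample_id`).
#' @export
naive_summit_call <- function(track, bin = 50, min_count = 20, sample_id = NA_character_) {
  stopifnot(bin > 0)
  out <- lapply(split(track$pos, track$chrom), function(pos) {
    counts <- tabulate(pos %/% bin + 1L)
    n <- length(counts)
    if (n == 0) return(NULL)
    s <- (c(0, counts[-n]) + counts + c(counts[-1], 0)) / 3
    left <- c(-Inf, s[-n]); right <- c(s[-1], -Inf)
    peak <- which(s >= left & s > right & s >= min_count)
    if (!length(peak)) return(NULL)
    # merge maxima closer than 2*bin, keeping the higher (earlier on ties)
    keep <- logical(length(peak))
    o <- order(-s[peak], peak)
    taken <- integer()
    for (i in o) {
      if (!any(abs(peak[i] - taken) < 2)) { keep[i] <- TRUE; taken <- c(taken, peak[i]) }
    }
    peak <- sort(peak[keep])
    data.frame(pos = as.integer((peak - 1L) * bin + bin %/% 2), score = s[peak])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(.cp_empty_records("summit"))
  res <- do.call(rbind, Map(function(chrom, df)
    data.frame(chrom = chrom, pos = df$pos, score = df$score,
               sample_id = sample_id, stringsAsFactors = FALSE),
    names(out), out))
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}
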