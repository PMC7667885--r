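# The core computation: per-window fold changes between condition pairs and
# the replicate-consistent classification rule.  A window enters a
# condition-dependent DHS set only if its fold change clears the threshold
# in EVERY replicate pair and the higher of the two normalized counts clears
# a background cutoff in every pair.  No p-values are computed: the rule is a
# pure fold-change filter with an explicit background count cutoff.

#' Declare a contrast between two conditions
#'
#' @param label contrast name (e.g. `"pDHS"`).
#' @param pairs list of `c(sample_A, sample_B)` character pairs; replicates
#'   are paired positionally (rep1 with rep1, rep2 with rep2, ...).  Fold
#'   changes are A over B.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(label, pairs) {
  if (!length(pairs)) cp_stop("cp_config_error", "contrast '%s' has no replicate pairs", label)
  pairs <- lapply(pairs, function(p) {
    if (length(p) != 2L) cp_stop("cp_config_error", "each pair must name two samples")
    as.character(p)
  })
  structure(list(label = label, pairs = pairs), class = "contrast_spec")
}

#' Classification parameters
#'
#' @param fold_threshold minimum per-replicate fold change (default 2, the
#'   "at least twofold in each replicate" rule; closed threshold, `>=`).
#' @param pseudocount added to both normalized counts before the ratio
#'   (default 1).
#' @param min_count background cutoff: the higher of the two normalized
#'   counts in a pair must reach this (default 20).
#' @return A `class_params` list.
#' @export
class_params <- function(fold_threshold = 2, pseudocount = 1, min_count = 20) {
  if (fold_threshold < 1) cp_stop("cp_config_error", "fold_threshold must be >= 1")
  if (pseudocount < 0) cp_stop("cp_config_error", "pseudocount must be >= 0")
  if (min_count < 0) cp_stop("cp_config_error", "min_count must be >= 0")
  structure(list(fold_threshold = fold_threshold, pseudocount = pseudocount,
                 min_count = min_count), class = "class_params")
}

.cp_check_normalized <- function(matrix) {
  if (!isTRUE(attr(matrix, "normalized")))
    cp_stop("cp_config_error", "classification requires a normalized count matrix")
}

.cp_check_samples <- function(matrix, samples) {
  missing <- setdiff(samples, colnames(matrix))
  if (length(missing))
    cp_stop("cp_config_error", "sample not in matrix: %s", missing[1])
}

#' Per-window fold change between two samples
#'
#' `FC_w = (a_w + p) / (b_w + p)` on normalized counts.  With `p = 0` a zero
#' denominator yields `Inf` (and `0/0` yields `NaN`); the default `p = 1`
#' keeps all fold changes finite.
#'
#' @param matrix normalized count matrix.
#' @param pair `c(sample_A, sample_B)`.
#' @param pseudocount pseudo-count `p` (default 1).
#' @return Named numeric vector of fold changes, one per window.
#' @export
per_window_fold <- function(matrix, pair, pseudocount = 1) {
  .cp_check_normalized(matrix)
  .cp_check_samples(matrix, pair)
  (matrix[, pair[1]] + pseudocount) / (matrix[, pair[2]] + pseudocount)
}

#' Call condition-dependent DHSs with the replicate-consistency rule
#'
#' Window `w` is a member iff, for every replicate pair `(a, b)` of the
#' contrast, `FC_w >= fold_threshold` and `max(a_w, b_w) >= min_count`.
#' Fold changes for all windows are retained for ranking and plotting.
#'
#' @param matrix normalized count matrix.
#' @param contrast a [contrast_spec()].
#' @param params a [class_params()].
#' @return A `dhs_call_set`: `label`, `members` (window ids), `fc` (windows x
#'   pairs fold-change matrix), `params`, `window_ids` (the full universe).
#' @export
call_dependent <- function(matrix, contrast, params = class_params()) {
  .cp_check_normalized(matrix)
  for (p in contrast$pairs) .cp_check_samples(matrix, p)
  fc <- vapply(contrast$pairs, function(p)
    per_window_fold(matrix, p, params$pseudocount), numeric(nrow(matrix)))
  fc <- matrix(fc, nrow = nrow(matrix),
               dimnames = list(rownames(matrix),
                               vapply(contrast$pairs, paste, "", collapse = "/")))
  hi <- vapply(contrast$pairs, function(p)
    pmax(matrix[, p[1]], matrix[, p[2]]), numeric(nrow(matrix)))
  hi <- matrix(hi, nrow = nrow(matrix))
  member <- rowSums(fc >= params$fold_threshold) == ncol(fc) &
    rowSums(hi >= params$min_count) == ncol(hi)
  structure(list(label = contrast$label, members = rownames(matrix)[member],
                 fc = fc, params = params, window_ids = rownames(matrix)),
            class = "dhs_call_set")
}

#' @export
print.dhs_call_set <- function(x, ...) {
  cat(sprintf("<dhs_call_set '%s': %d of %d windows (fold >= %g in each of %d pairs, min count %g)>\n",
              x$label, length(x$members), length(x$window_ids),
              x$params$fold_threshold, ncol(x$fc), x$params$min_count))
  invisible(x)
}

#' Intersect two DHS call sets
#'
#' Both sets must be defined on the same window universe.  Membership is the
#' set intersection, in the window order of the universe; the parents are
#' recorded in the `parents` field.
#'
#' @param set_a,set_b `dhs_call_set` objects.
#' @param label label for the result (default `"A & B"`).
#' @return A `dhs_call_set` with a `parents` provenance field.
#' @export
intersect_calls <- function(set_a, set_b, label = paste(set_a$label, "&", set_b$label)) {
  if (!identical(set_a$window_ids, set_b$window_ids))
    cp_stop("cp_windowset_mismatch", "call sets are defined on different window sets")
  members <- set_a$window_ids[set_a$window_ids %in% set_a$members &
                                set_a$window_ids %in% set_b$members]
  structure(list(label = label, members = members, fc = NULL,
                 params = set_a$params, window_ids = set_a$window_ids,
                 parents = c(set_a$label, set_b$label)),
            class = "dhs_call_set")
}

#' Select an invariant control window set
#'
#' Eligible windows have normalized count >= `min_count` in every sample
#' referenced by the supplied contrasts.  Each eligible window is scored by
#' the maximum `|log2 FC|` over all contrasts and replicate pairs, and the
#' `n` lowest-scoring windows are returned (ties broken by matrix row order,
#' i.e. genomic coordinate order).
#'
#' @param matrix normalized count matrix.
#' @param contrasts list of [contrast_spec()] objects.
#' @param n number of control windows.
#' @param params a [class_params()] (supplies `min_count` and `pseudocount`).
#' @return A `dhs_call_set` of invariant control windows.
#' @export
select_invariant <- function(matrix, contrasts, n, params = class_params()) {
  .cp_check_normalized(matrix)
  samples <- unique(unlist(lapply(contrasts, function(ct) unlist(ct$pairs))))
  .cp_check_samples(matrix, samples)
  eligible <- rowSums(matrix[, samples, drop = FALSE] >= params$min_count) == length(samples)
  if (n > sum(eligible)) {
    cp_stop("cp_insufficient_windows", "requested %d invariant windows but only %d are eligible",
            n, sum(eligible))
  }
  score <- rep(-Inf, nrow(matrix))
  for (ct in contrasts) {
    for (p in ct$pairs) {
      score <- pmax(score, abs(log2(per_window_fold(matrix, p, params$pseudocount))))
    }
  }
  idx <- which(eligible)
  sel <- idx[order(score[idx])][seq_len(n)]
  structure(list(label = "invariant", members = rownames(matrix)[sort(sel)],
                 fc = NULL, params = params, window_ids = rownames(matrix),
                 score = score),
            class = "dhs_call_set")
}

#' Rank windows by fold change
#'
#' Stable ascending sort of windows by `FC = (a + p)/(b + p)`, ties broken by
#' matrix row order (genomic coordinate order).  This is the ordering used
#' for fold-change-ranked tag-density heatmaps and for the accessibility
#' vs. expression trend.
#'
#' @inheritParams per_window_fold
#' @return Character vector of window ids, lowest fold change first.
#' @export
rank_windows <- function(matrix, pair, pseudocount = 1) {
  fc <- per_window_fold(matrix, pair, pseudocount)
  rownames(matrix)[order(fc)]  # order() is stable: ties stay in row order
}
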