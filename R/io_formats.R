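# Reading and writing the BED/TSV dialects the pipeline touches.  All
# coordinates are 0-based half-open (BED convention); a 1-bp summit interval
# has end == pos + 1.  Chromosome names are matched as exact strings.

.cp_read_lines <- function(path) {
  if (!file.exists(path)) cp_stop("cp_file_not_found", "file not found: %s", path)
  con <- file(path, "r")  # file() transparently decompresses gzip input
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.cp_is_data_line <- function(lines) {
  !(grepl("^\\s*$", lines) | grepl("^#", lines) |
      grepl("^track\\b", lines) | grepl("^browser\\b", lines))
}

.cp_int <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    cp_stop("cp_malformed_record", "line %d: non-integer %s '%s'",
            lineno[which(bad)[1]], what, x[which(bad)[1]])
  }
  v
}

#' Read genomic records from a BED-like file
#'
#' One reader covers the four record flavours the pipeline consumes.  Input is
#' tab-separated; `#`, `track` and `browser` lines and blank lines are
#' skipped.  Gzip-compressed files are accepted.
#'
#' * `kind = "peak"`: BED3/4/5/6 intervals (`chrom`, `start`, `end`, optional
#'   `name`, `score`, `strand`).
#' * `kind = "summit"`: 1-bp BED intervals (MACS summit style); `pos` is the
#'   BED start, the optional name column is kept as `sample_id` and column 5
#'   as `score`.
#' * `kind = "cutsite"`: 1-bp BED intervals giving single cut positions; any
#'   strand column is ignored.
#' * `kind = "tss"`: either a header TSV with columns
#'   `gene_id`, `chrom`, `tss`, `strand`, or BED6 with the name column as
#'   `gene_id` and `tss = start`.
#'
#' @param path file path (optionally `.gz`).
#' @param kind one of `"peak"`, `"summit"`, `"cutsite"`, `"tss"`.
#' @param sample_id default `sample_id` for summit records lacking a name
#'   column.
#' @return A data frame; columns depend on `kind` (see above).  Records are
#'   returned in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t500\tpk1\t7\t+", f)
#' read_intervals(f, "peak")
#' @export
read_intervals <- function(path, kind = c("peak", "summit", "cutsite", "tss")) {
  kind <- match.arg(kind)
  lines <- .cp_read_lines(path)
  keep <- .cp_is_data_line(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (kind == "tss" && length(lines) && grepl("\\bgene_id\\b", lines[1]))
    return(.cp_parse_tss_tsv(lines, lineno))
  if (!length(lines)) return(.cp_empty_records(kind))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  minf <- if (kind == "tss") 4L else 3L
  if (any(nf < minf)) {
    cp_stop("cp_malformed_record", "line %d: expected >= %d tab-separated columns, got %d",
            lineno[which(nf < minf)[1]], minf, nf[which(nf < minf)[1]])
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- col(1)
  if (any(!nzchar(chrom))) {
    cp_stop("cp_malformed_record", "line %d: empty chromosome name", lineno[which(!nzchar(chrom))[1]])
  }
  start <- .cp_int(col(2), lineno, "start")
  end <- .cp_int(col(3), lineno, "end")
  if (any(start < 0)) {
    cp_stop("cp_malformed_record", "line %d: negative start", lineno[which(start < 0)[1]])
  }
  if (any(end <= start)) {
    cp_stop("cp_malformed_record", "line %d: end (%s) must exceed start (%s)",
            lineno[which(end <= start)[1]],
            format(end[which(end <= start)[1]], scientific = FALSE),
            format(start[which(end <= start)[1]], scientific = FALSE))
  }
  name <- col(4); name[name %in% "."] <- NA_character_
  score <- suppressWarnings(as.numeric(col(5)))
  strand <- col(6)
  switch(kind,
    peak = {
      strand[!strand %in% c("+", "-", ".")] <- NA_character_
      data.frame(chrom = chrom, start = start, end = end, name = name,
                 score = score, strand = strand, stringsAsFactors = FALSE)
    },
    summit = {
      onebp <- end == start + 1
      if (any(!onebp)) {
        cp_stop("cp_malformed_record", "line %d: summit record is not a 1-bp interval",
                lineno[which(!onebp)[1]])
      }
      data.frame(chrom = chrom, pos = start, score = score,
                 sample_id = name, stringsAsFactors = FALSE)
    },
    cutsite = data.frame(chrom = chrom, pos = start, stringsAsFactors = FALSE),
    tss = {
      # BED6 dialect: name column is the gene id, tss = start
      gene_id <- name
      if (anyNA(gene_id)) {
        cp_stop("cp_malformed_record", "line %d: TSS record lacks a gene id",
                lineno[which(is.na(gene_id))[1]])
      }
      if (anyDuplicated(gene_id)) {
        cp_stop("cp_duplicate_key", "duplicate gene_id '%s'", gene_id[anyDuplicated(gene_id)])
      }
      strand[!strand %in% c("+", "-")] <- "."
      data.frame(gene_id = gene_id, chrom = chrom, tss = start,
                 strand = strand, stringsAsFactors = FALSE)
    })
}

.cp_parse_tss_tsv <- function(lines, lineno) {
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% hdr)) {
    cp_stop("cp_malformed_record", "TSS table header must contain %s", paste(need, collapse = ", "))
  }
  if (length(lines) == 1L) return(.cp_empty_records("tss"))
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  get <- function(nm) vapply(fields, function(f) f[match(nm, hdr)], "")
  tss <- .cp_int(get("tss"), lineno[-1], "tss")
  if (any(tss < 0)) cp_stop("cp_malformed_record", "negative tss coordinate")
  gene_id <- get("gene_id")
  if (anyDuplicated(gene_id)) {
    cp_stop("cp_duplicate_key", "duplicate gene_id '%s'", gene_id[anyDuplicated(gene_id)])
  }
  data.frame(gene_id = gene_id, chrom = get("chrom"), tss = tss,
             strand = get("strand"), stringsAsFactors = FALSE)
}

.cp_empty_records <- function(kind) {
  switch(kind,
    peak = data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE),
    summit = data.frame(chrom = character(), pos = numeric(), score = numeric(),
                        sample_id = character(), stringsAsFactors = FALSE),
    cutsite = data.frame(chrom = character(), pos = numeric(), stringsAsFactors = FALSE),
    tss = data.frame(gene_id = character(), chrom = character(), tss = numeric(),
                     strand = character(), stringsAsFactors = FALSE))
}

#' Write genomic records back to BED / TSV
#'
#' Inverse of [read_intervals()]: `read_intervals(write_intervals(x, f), kind)`
#' returns `x` for any valid record set.  Optional trailing fields that are
#' `NA` throughout are omitted; a missing name in a record that carries a
#' score is written as `"."`.
#'
#' @param records data frame as produced by [read_intervals()].
#' @param path output path.
#' @param kind record flavour; inferred from the columns when omitted.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(records, path,
                            kind = c("auto", "peak", "summit", "cutsite", "tss")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if ("gene_id" %in% names(records)) "tss"
      else if ("pos" %in% names(records) && "score" %in% names(records)) "summit"
      else if ("pos" %in% names(records)) "cutsite"
      else "peak"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) cp_stop("cp_unwritable_path", "directory does not exist: %s", dir)
  fmtn <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- switch(kind,
    peak = {
      n <- nrow(records)
      ncol_out <- if (n == 0) 3L
        else if (all(is.na(records$name)) && all(is.na(records$score)) &&
                 all(is.na(records$strand))) 3L
        else if (all(is.na(records$score)) && all(is.na(records$strand))) 4L
        else if (all(is.na(records$strand))) 5L else 6L
      cols <- list(records$chrom, fmtn(records$start), fmtn(records$end))
      if (ncol_out >= 4) cols <- c(cols, list(ifelse(is.na(records$name), ".", records$name)))
      if (ncol_out >= 5) cols <- c(cols, list(ifelse(is.na(records$score), ".", fmtn(records$score))))
      if (ncol_out >= 6) cols <- c(cols, list(ifelse(is.na(records$strand), ".", records$strand)))
      do.call(paste, c(cols, sep = "\t"))
    },
    summit = paste(records$chrom, fmtn(records$pos), fmtn(records$pos + 1),
                   ifelse(is.na(records$sample_id), ".", records$sample_id),
                   ifelse(is.na(records$score), ".", fmtn(records$score)), sep = "\t"),
    cutsite = paste(records$chrom, fmtn(records$pos), fmtn(records$pos + 1), sep = "\t"),
    tss = c(paste("gene_id", "chrom", "tss", "strand", sep = "\t"),
            if (nrow(records)) paste(records$gene_id, records$chrom, fmtn(records$tss),
                                     records$strand, sep = "\t")))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) cp_stop("cp_unwritable_path", "cannot write to %s", path)
  invisible(path)
}

#' Read a TPM expression table
#'
#' Expects a tab-separated table whose first column (named `gene_id`) holds
#' unique gene identifiers and whose remaining columns hold non-negative TPM
#' values, one column per sample.
#'
#' @param path TSV path (optionally gzip-compressed).
#' @param samples optional data frame with columns `sample`, `condition`,
#'   `replicate` declaring the design; attached as the `"samples"` attribute.
#' @return A numeric matrix (genes x samples) with gene ids as row names.
#' @export
read_expression <- function(path, samples = NULL) {
  lines <- .cp_read_lines(path)
  tab <- tryCatch(
    read.table(text = lines, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) cp_stop("cp_malformed_record", "cannot parse expression table: %s",
                                conditionMessage(e)))
  if (!"gene_id" %in% names(tab) || ncol(tab) < 2L) {
    cp_stop("cp_malformed_record", "expression table needs a gene_id column and >= 1 sample column")
  }
  gene_id <- as.character(tab$gene_id)
  if (anyDuplicated(gene_id)) {
    cp_stop("cp_duplicate_key", "duplicate gene_id '%s'", gene_id[anyDuplicated(gene_id)])
  }
  vals <- tab[setdiff(names(tab), "gene_id")]
  if (anyDuplicated(names(vals))) cp_stop("cp_duplicate_key", "duplicate sample labels")
  for (nm in names(vals)) {
    v <- suppressWarnings(as.numeric(vals[[nm]]))
    if (anyNA(v)) cp_stop("cp_malformed_record", "non-numeric TPM in sample '%s'", nm)
    if (any(v < 0)) cp_stop("cp_malformed_record", "negative TPM in sample '%s'", nm)
    vals[[nm]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_id
  if (!is.null(samples)) attr(m, "samples") <- samples
  m
}

#' Write a TPM expression table
#'
#' @param tpm genes x samples numeric matrix with gene ids as row names.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
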