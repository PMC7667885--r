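# End-to-end orchestration: simulate (or load) -> count -> normalize ->
# classify -> annotate -> link -> profile, driven by one declarative YAML
# config, with a machine-readable run summary.  Each stage writes the
# documented TSV/BED artifacts so stages are independently re-runnable.

.cp_default_config <- function() {
  list(
    seed = 1L,
    flank = 200, cluster_dist = 200, n_top = 25000,
    class_params = list(fold_threshold = 2, pseudocount = 1, min_count = 20),
    proximity_max_dist = 25000,
    motif_flank = 100,
    trend_roll = 0,
    stages = list(classify = TRUE, annotate = TRUE, link = TRUE, profile = FALSE)
  )
}

.cp_load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) cp_stop("cp_config_error", "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.cp_default_config(), config)
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns findings (character vector) instead of raising, so callers can
#' report all problems at once; an empty vector means [run_pipeline()]'s
#' preconditions hold.
#'
#' @param config config list or YAML path.
#' @return Character vector of findings (empty when valid).
#' @export
validate_config <- function(config) {
  cfg <- tryCatch(.cp_load_config(config), error = function(e) conditionMessage(e))
  if (is.character(cfg)) return(cfg)
  findings <- character()
  say <- function(msg, ...) findings <<- c(findings, sprintf(msg, ...))
  has_sim <- !is.null(cfg$simulation)
  has_real <- !is.null(cfg$samples)
  if (has_sim == has_real) say("exactly one input mode required: a 'simulation' block or a 'samples' table")
  sample_labels <- character()
  if (has_real) {
    st <- cfg$samples
    need <- c("sample", "condition", "replicate", "cuts", "summits")
    miss <- setdiff(need, names(st[[1]]))
    if (length(miss)) say("sample table entries need fields: %s", paste(miss, collapse = ", "))
    else {
      sample_labels <- vapply(st, `[[`, "", "sample")
      if (anyDuplicated(sample_labels)) say("duplicate sample labels")
      for (s in st) {
        for (f in c("cuts", "summits")) {
          if (!file.exists(s[[f]])) say("sample %s: missing %s file %s", s$sample, f, s[[f]])
        }
      }
    }
  }
  if (has_sim && !has_real) {
    ok <- tryCatch({ do.call(simulation_config, cfg$simulation); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) say("simulation block: %s", ok)
    else sample_labels <- simulation_samples(do.call(simulation_config, cfg$simulation))$sample
  }
  known_conds <- if (has_real && length(cfg$samples)) {
    unique(vapply(cfg$samples, `[[`, "", "condition"))
  } else if (has_sim) CP_CONDITIONS else character()
  for (ct in cfg$contrasts) {
    if (is.null(ct$label)) say("contrast without a label")
    conds <- c(ct$condition_a, ct$condition_b)
    if (length(conds) != 2) say("contrast %s: needs condition_a and condition_b", ct$label)
    else if (length(known_conds)) {
      for (cd in setdiff(conds, known_conds)) {
        say("contrast %s: unknown condition '%s'", ct$label %||% "?", cd)
      }
    }
  }
  for (f in c("tss", "tpm", "genome")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) say("missing %s file: %s", f, cfg[[f]])
  }
  if (!is.null(cfg$annotation_targets)) {
    for (tg in cfg$annotation_targets) {
      if (is.null(tg$label) || is.null(tg$path)) say("annotation target needs label and path")
      else if (!file.exists(tg$path)) say("annotation target %s: missing file %s", tg$label, tg$path)
    }
  }
  findings
}

.cp_pairs_for <- function(samples, cond_a, cond_b) {
  a <- samples$sample[samples$condition == cond_a][order(samples$replicate[samples$condition == cond_a])]
  b <- samples$sample[samples$condition == cond_b][order(samples$replicate[samples$condition == cond_b])]
  if (!length(a) || !length(b))
    cp_stop("cp_config_error", "no samples for conditions %s / %s", cond_a, cond_b)
  n <- min(length(a), length(b))
  lapply(seq_len(n), function(i) c(a[i], b[i]))
}

.cp_write_call_set <- function(set, windows, dir) {
  w <- windows[match(set$members, windows$window_id), , drop = FALSE]
  bed <- file.path(dir, paste0("calls_", gsub("[^A-Za-z0-9_.-]", "_", set$label), ".bed"))
  write_intervals(data.frame(chrom = w$chrom, start = w$start, end = w$end,
                             name = w$window_id, score = rep(NA_real_, nrow(w)),
                             strand = rep(NA_character_, nrow(w)),
                             stringsAsFactors = FALSE),
                  bed, "peak")
  if (!is.null(set$fc)) {
    tsv <- sub("\\.bed$", "_fc.tsv", bed)
    df <- data.frame(window_id = rownames(set$fc), set$fc, check.names = FALSE)
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bed
}

#' Run the full accessibility pipeline
#'
#' Executes the enabled stages in dependency order on either simulated or
#' supplied inputs, writes every stage's artifacts under `out_dir`, and
#' returns (and writes as `summary.json`) a machine-readable run summary.
#' Deterministic given the config and seed.
#'
#' @param config config list or YAML path.  Main fields: `simulation`
#'   (a [simulation_config()] argument list) or `samples` (list of
#'   `sample`/`condition`/`replicate`/`cuts`/`summits` entries),
#'   `contrasts` (list of `label`/`condition_a`/`condition_b`),
#'   `intersections` (list of `label`/`of` pairs of contrast labels),
#'   `invariant_n`, `proximity` (`query`/`target` contrast labels),
#'   `annotation_targets` (label/path BED list), `genome` + `motifs`,
#'   `tss`/`tpm` paths (simulation supplies its own), `trend`
#'   (`contrast`/`rank_pair` settings), thresholds `flank`, `cluster_dist`,
#'   `n_top`, `class_params`, `proximity_max_dist`, and `stages` toggles.
#' @param out_dir output directory.
#' @param seed optional root seed overriding the config's.
#' @return The run summary list, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- .cp_load_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  findings <- validate_config(cfg)
  if (length(findings)) {
    cp_stop("cp_config_error", "invalid config:\n- %s", paste(findings, collapse = "\n- "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  success <- FALSE
  manifest <- character()
  # partial outputs are removed when a stage fails
  on.exit(if (!success) suppressWarnings(file.remove(manifest[file.exists(manifest)])))
  summary <- list(version = as.character(utils::packageVersion("chromaprime")),
                  seed = cfg$seed, params = cfg[c("flank", "cluster_dist", "n_top",
                                                 "class_params", "proximity_max_dist")])
  note <- function(path) { manifest <<- c(manifest, path); path }

  # --- inputs: simulate or load ------------------------------------------------
  truth <- NULL; chrom_lengths <- NULL
  if (!is.null(cfg$simulation)) {
    sim_cfg <- do.call(simulation_config, utils::modifyList(cfg$simulation,
                                                            list(seed = cfg$seed)))
    ds <- simulate_experiment(sim_cfg)
    sim_paths <- write_synthetic_dataset(ds, file.path(out_dir, "simulated"))
    for (p in sim_paths) note(p)
    samples <- ds$samples
    tracks <- ds$cuts
    summit_sets <- ds$summits
    truth <- ds$truth
    chrom_lengths <- ds$chrom_lengths
    tss_tab <- ds$tss
    tpm_tab <- ds$tpm
  } else {
    samples <- do.call(rbind, lapply(cfg$samples, function(s)
      data.frame(sample = s$sample, condition = s$condition,
                 replicate = s$replicate, stringsAsFactors = FALSE)))
    tracks <- lapply(cfg$samples, function(s) read_intervals(s$cuts, "cutsite"))
    names(tracks) <- samples$sample
    summit_sets <- lapply(cfg$samples, function(s) {
      sm <- read_intervals(s$summits, "summit")
      sm$sample_id[is.na(sm$sample_id)] <- s$sample
      sm
    })
    names(summit_sets) <- samples$sample
    tss_tab <- if (!is.null(cfg$tss)) read_intervals(cfg$tss, "tss")
    tpm_tab <- if (!is.null(cfg$tpm)) read_expression(cfg$tpm, samples)
  }

  # --- count -------------------------------------------------------------------
  union <- if (!is.null(cfg$union_summits))
    read_intervals(cfg$union_summits, "summit")
  else pool_summits(summit_sets, cfg$cluster_dist)
  windows <- make_windows(union, cfg$flank, chrom_lengths)
  write_intervals(data.frame(chrom = windows$chrom, start = windows$start,
                             end = windows$end, name = windows$window_id,
                             score = NA_real_, strand = NA_character_,
                             stringsAsFactors = FALSE),
                  note(file.path(out_dir, "windows.bed")), "peak")
  raw <- count_cuts(windows, tracks)
  write.table(data.frame(window_id = rownames(raw), raw, check.names = FALSE),
              note(file.path(out_dir, "counts_raw.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$n_windows <- nrow(windows)
  summary$n_samples <- ncol(raw)

  # --- normalize ---------------------------------------------------------------
  factors <- topn_median_factors(raw, cfg$n_top)
  norm <- apply_factors(raw, factors)
  write.table(cbind(factors, method = attr(factors, "method")),
              note(file.path(out_dir, "norm_factors.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$norm_factors <- setNames(as.list(factors$factor), factors$sample)

  # --- classify ----------------------------------------------------------------
  params <- do.call(class_params, cfg$class_params)
  call_sets <- list()
  if (isTRUE(cfg$stages$classify)) {
    for (ct in cfg$contrasts) {
      spec <- contrast_spec(ct$label, .cp_pairs_for(samples, ct$condition_a, ct$condition_b))
      call_sets[[ct$label]] <- call_dependent(norm, spec, params)
      note(.cp_write_call_set(call_sets[[ct$label]], windows, out_dir))
    }
    for (ix in cfg$intersections) {
      call_sets[[ix$label]] <- intersect_calls(call_sets[[ix$of[[1]]]],
                                               call_sets[[ix$of[[2]]]], ix$label)
      note(.cp_write_call_set(call_sets[[ix$label]], windows, out_dir))
    }
    if (!is.null(cfg$invariant_n)) {
      specs <- lapply(cfg$contrasts, function(ct)
        contrast_spec(ct$label, .cp_pairs_for(samples, ct$condition_a, ct$condition_b)))
      call_sets[["invariant"]] <- select_invariant(norm, specs, cfg$invariant_n, params)
      note(.cp_write_call_set(call_sets[["invariant"]], windows, out_dir))
    }
    summary$call_sets <- lapply(call_sets, function(s) length(s$members))
    if (!is.null(truth)) {
      cls <- match_truth(windows, truth)
      recovery <- list()
      truth_of <- c(pDHS = "dependent_primed", iDHS = "inducible")
      for (lbl in intersect(names(call_sets), names(truth_of))) {
        tc <- truth_of[[lbl]]
        called <- windows$window_id %in% call_sets[[lbl]]$members
        planted <- !is.na(cls) & cls == tc
        recovery[[lbl]] <- list(
          sensitivity = if (any(planted)) sum(called & planted) / sum(planted) else NA,
          fdp = if (any(called)) sum(called & !planted) / sum(called) else 0)
      }
      summary$recovery <- recovery
    }
  }

  # --- annotate ----------------------------------------------------------------
  if (isTRUE(cfg$stages$annotate) && length(call_sets)) {
    if (!is.null(cfg$annotation_targets)) {
      qlabel <- cfg$overlap_query %||% names(call_sets)[1]
      qwin <- windows[windows$window_id %in% call_sets[[qlabel]]$members, , drop = FALSE]
      flags <- lapply(cfg$annotation_targets, function(tg)
        overlap_flags(qwin, read_intervals(tg$path, "peak")))
      names(flags) <- vapply(cfg$annotation_targets, `[[`, "", "label")
      venn <- venn_partition(flags)
      summary$overlap <- list(query = qlabel, n = venn$n,
                              per_target = lapply(flags, sum),
                              fraction_any = venn$fraction_any, cells = as.list(venn$cells))
      df <- data.frame(window_id = qwin$window_id, flags, check.names = FALSE)
      write.table(df, note(file.path(out_dir, "overlap_flags.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cfg[["proximity"]])) {
      q <- windows[windows$window_id %in% call_sets[[cfg[["proximity"]]$query]]$members, ]
      t <- windows[windows$window_id %in% call_sets[[cfg[["proximity"]]$target]]$members, ]
      nd <- nearest_distance(q, t, cfg$proximity_max_dist)
      out <- data.frame(window_id = q$window_id, nd)
      write.table(out, note(file.path(out_dir, "proximity.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$proximity <- list(query = cfg[["proximity"]]$query, target = cfg[["proximity"]]$target,
                                n = nrow(q), max_dist = cfg$proximity_max_dist,
                                fraction_within = if (nrow(q)) mean(nd$within) else NA)
    }
    if (!is.null(cfg$genome)) {
      motifs <- if (is.null(cfg[["motifs"]])) default_motifs()
        else lapply(cfg[["motifs"]], function(m)
          motif_model(m$name, m$consensus, m$max_mismatches %||% 0,
                      m$flank %||% cfg$motif_flank))
      qlabel <- cfg$motif_query %||% names(call_sets)[1]
      qwin <- windows[windows$window_id %in% call_sets[[qlabel]]$members, , drop = FALSE]
      mflags <- lapply(motifs, function(m) scan_consensus(qwin, cfg$genome, m))
      names(mflags) <- vapply(motifs, `[[`, "", "name")
      df <- data.frame(window_id = qwin$window_id, mflags, check.names = FALSE)
      write.table(df, note(file.path(out_dir, "motif_flags.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$motifs <- lapply(mflags, function(f)
        list(n_with_motif = sum(f), fraction = if (length(f)) mean(f) else NA))
    }
  }

  # --- link --------------------------------------------------------------------
  if (isTRUE(cfg$stages$link) && !is.null(tss_tab) && !is.null(tpm_tab) &&
      length(cfg$contrasts)) {
    links <- nearest_gene(windows, tss_tab)
    write.table(links, note(file.path(out_dir, "gene_links.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logm <- normalize_tpm(tpm_tab)
    tct <- cfg[["trend"]]$contrast %||% cfg$contrasts[[1]]$label
    ct <- Filter(function(x) x$label == tct, cfg$contrasts)[[1]]
    gfc <- gene_fold_changes(logm,
                             samples$sample[samples$condition == ct$condition_a],
                             samples$sample[samples$condition == ct$condition_b])
    write.table(gfc, note(file.path(out_dir, "gene_fold_changes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pair1 <- .cp_pairs_for(samples, ct$condition_a, ct$condition_b)[[1]]
    ranked <- rank_windows(norm, pair1, params$pseudocount)
    trend <- rank_expression_trend(ranked, links, gfc, cfg$trend_roll)
    write.table(trend$series, note(file.path(out_dir, "trend_series.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$trend <- list(contrast = tct, rho = trend$rho, n = trend$n)
  }

  # --- profile -----------------------------------------------------------------
  if (isTRUE(cfg$stages$profile) && length(call_sets)) {
    plabel <- cfg[["profile_set"]] %||% names(call_sets)[1]
    psample <- cfg[["profile_sample"]] %||% samples$sample[1]
    pw <- windows[windows$window_id %in% call_sets[[plabel]]$members, , drop = FALSE]
    if (nrow(pw)) {
      f <- factors$factor[match(psample, factors$sample)]
      pm <- density_matrix(pw, tracks[[psample]], f)
      write.table(data.frame(window_id = rownames(pm), unclass(pm), check.names = FALSE),
                  note(file.path(out_dir, "profile_matrix.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      avg <- average_profile(pm)
      write.table(data.frame(offset = as.numeric(names(avg)), mean_density = avg),
                  note(file.path(out_dir, "profile_average.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$profile <- list(set = plabel, sample = psample, n_windows = nrow(pm))
    }
  }

  # --- summary self-check and output -------------------------------------------
  for (lbl in names(call_sets)) {
    bed <- file.path(out_dir, paste0("calls_", gsub("[^A-Za-z0-9_.-]", "_", lbl), ".bed"))
    n_file <- nrow(read_intervals(bed, "peak"))
    if (n_file != length(call_sets[[lbl]]$members))
      cp_stop("cp_stage_error", "summary/file size mismatch for call set %s", lbl)
  }
  summary$manifest <- basename(manifest)
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  success <- TRUE
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
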