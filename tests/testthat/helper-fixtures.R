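# Shared fixture builders.  Everything is generated in code at test time.

as_norm <- function(m) { attr(m, "normalized") <- TRUE; m }

count_mat <- function(..., windows = NULL) {
  m <- rbind(...)
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  rownames(m) <- windows %||% sprintf("w%05d", seq_len(nrow(m)))
  attr(m, "normalized") <- FALSE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

windows_at <- function(chrom, summit, flank = 200) {
  make_windows(data.frame(chrom = chrom, pos = summit, score = NA_real_,
                          sample_id = NA_character_, stringsAsFactors = FALSE),
               flank)
}

# one small simulated experiment shared across tests (cached per session)
.shared <- new.env()

shared_sim <- function() {
  if (is.null(.shared$ds)) {
    cfg <- simulation_config(n_chroms = 2, chrom_length = 2e6,
                             n_dependent_primed = 60, n_inducible = 60,
                             n_invariant = 300, n_background_noise_windows = 20,
                             background_rate = 1e-3, seed = 42)
    .shared$cfg <- cfg
    .shared$ds <- simulate_experiment(cfg)
  }
  .shared$ds
}

shared_pipeline_objects <- function() {
  if (is.null(.shared$norm)) {
    ds <- shared_sim()
    w <- make_windows(pool_summits(ds$summits), 200, ds$chrom_lengths)
    raw <- suppressWarnings(count_cuts(w, ds$cuts))
    norm <- apply_factors(raw, topn_median_factors(raw))
    .shared$windows <- w; .shared$raw <- raw; .shared$norm <- norm
  }
  list(ds = shared_sim(), windows = .shared$windows,
       raw = .shared$raw, norm = .shared$norm)
}

pdhs_contrast <- function() {
  contrast_spec("pDHS", list(c("A_rep1", "A_nil_rep1"), c("A_rep2", "A_nil_rep2")))
}

idhs_contrast <- function() {
  contrast_spec("iDHS", list(c("A_stim_rep1", "A_rep1"), c("A_stim_rep2", "A_rep2")))
}

tiny_pipeline_config <- function(dir) {
  list(
    simulation = list(n_chroms = 2, chrom_length = 2e6, n_dependent_primed = 40,
                      n_inducible = 40, n_invariant = 150,
                      n_background_noise_windows = 10, background_rate = 1e-3),
    contrasts = list(
      list(label = "pDHS", condition_a = "A", condition_b = "A_nil"),
      list(label = "iDHS", condition_a = "A_stim", condition_b = "A"),
      list(label = "stim_dep", condition_a = "A_stim", condition_b = "A_stim_nil")),
    # cytokine-dependent inducible sites: inducible AND lost without cytokine
    intersections = list(list(label = "cyt_dep_iDHS", of = list("iDHS", "stim_dep"))),
    proximity = list(query = "pDHS", target = "iDHS"),
    invariant_n = 20,
    trend = list(contrast = "pDHS"),
    stages = list(classify = TRUE, annotate = TRUE, link = TRUE, profile = TRUE),
    seed = 5
  )
}
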