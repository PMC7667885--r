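# Seeded generator of DNase-style cut-site tracks with planted accessibility
# classes.  The design mirrors a cytokine-withdrawal experiment with TCR
# restimulation: four conditions
#   A          cytokine-maintained, unstimulated
#   A_nil      cytokine-withdrawn, unstimulated
#   A_stim     cytokine-maintained, stimulated
#   A_stim_nil cytokine-withdrawn, stimulated
# and n_replicates independent samples per condition.  Planted classes:
#   dependent_primed  mean base_mean with cytokine, base_mean/effect_fold without
#   inducible         mean base_mean unstimulated; base_mean*effect_fold when
#                     stimulated WITH cytokine (induction is cytokine-dependent)
#   invariant         mean base_mean everywhere
#   background        mean noise_mean everywhere (spurious summit calls)

CP_CONDITIONS <- c("A", "A_nil", "A_stim", "A_stim_nil")

#' Configuration for a synthetic accessibility experiment
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param spacing minimum distance between planted summits (bp); must comfortably
#'   exceed twice the window flank so default windows never merge.
#' @param n_dependent_primed,n_inducible,n_invariant,n_background_noise_windows
#'   number of windows planted per class.
#' @param base_mean expected tags per window per replicate at reference depth.
#' @param effect_fold multiplicative accessibility change for the planted
#'   dependent/inducible classes (> 1).
#' @param dispersion negative-binomial overdispersion `alpha`
#'   (variance = m + alpha * m^2); 0 gives Poisson counts.
#' @param noise_mean mean tag count of background-noise windows.
#' @param depth_factor optional named vector of per-sample depth multipliers.
#' @param cut_sd Gaussian scatter (bp) of cut positions around the summit.
#' @param background_rate uniform background tags per bp per sample.
#' @param n_replicates replicates per condition.
#' @param n_extra_genes genes not linked to any window (constant baseline TPM).
#' @param tss_max_dist maximum |TSS - summit| distance for linked genes (bp).
#' @param coupling_gain TPM per unit of true window mean for linked genes.
#' @param coupling_sdlog lognormal noise (sdlog) on TPM values.
#' @param baseline_tpm mean TPM of unlinked genes.
#' @param seed root seed; all per-sample streams derive from it via
#'   [substream_seed()].
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_chroms = 2L, chrom_length = 5e7, spacing = 2000,
                              n_dependent_primed = 200L, n_inducible = 200L,
                              n_invariant = 2000L, n_background_noise_windows = 100L,
                              base_mean = 50, effect_fold = 4, dispersion = 0.1,
                              noise_mean = base_mean / 10,
                              depth_factor = NULL, cut_sd = 60,
                              background_rate = 5e-3, n_replicates = 2L,
                              n_extra_genes = 100L, tss_max_dist = 10000,
                              coupling_gain = 1.0, coupling_sdlog = 0.25,
                              baseline_tpm = 10, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, msg, ...) if (!ok) cp_stop("cp_config_error", msg, ...)
  counts <- c(cfg$n_dependent_primed, cfg$n_inducible, cfg$n_invariant,
              cfg$n_background_noise_windows)
  chk(all(counts >= 0), "window class counts must be >= 0")
  chk(cfg$effect_fold > 1, "effect_fold must exceed 1")
  chk(cfg$dispersion >= 0, "dispersion must be >= 0")
  chk(cfg$spacing >= 1000, "spacing must be >= 1000 bp so default windows cannot merge")
  chk(cfg$cut_sd > 0, "cut_sd must be positive")
  chk(cfg$background_rate >= 0, "background_rate must be >= 0")
  chk(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  margin <- 2 * cfg$tss_max_dist
  capacity <- cfg$n_chroms * max(0, floor((cfg$chrom_length - 2 * margin) / cfg$spacing))
  chk(sum(counts) <= capacity,
      "genome too small: %d windows requested but capacity is %d", sum(counts), capacity)
  invisible(cfg)
}

#' Sample table for a simulation configuration
#'
#' @param config a `simulation_config`.
#' @return Data frame with columns `sample`, `condition`, `replicate`.
#' @export
simulation_samples <- function(config) {
  reps <- seq_len(config$n_replicates)
  df <- expand.grid(replicate = reps, condition = CP_CONDITIONS,
                    stringsAsFactors = FALSE)
  df$sample <- paste0(df$condition, "_rep", df$replicate)
  df[c("sample", "condition", "replicate")]
}

#' Draw negative-binomial counts with a mean/overdispersion parameterization
#'
#' Counts follow `E = mean`, `Var = mean + dispersion * mean^2`
#' (`size = 1/dispersion` in [stats::rnbinom()]); `dispersion = 0` degenerates
#' to Poisson and `mean = 0` returns exact zeros.
#'
#' @param n number of draws.
#' @param mean expected count (scalar or length-`n` vector), >= 0.
#' @param dispersion overdispersion alpha >= 0.
#' @return Integer vector of `n` draws, using the current RNG stream.
#' @export
negbin_draw <- function(n, mean, dispersion = 0) {
  stopifnot(all(mean >= 0), dispersion >= 0)
  mean <- rep_len(mean, n)
  out <- integer(n)
  pos <- mean > 0
  if (any(pos)) {
    out[pos] <- if (dispersion == 0) rpois(sum(pos), mean[pos])
      else rnbinom(sum(pos), size = 1 / dispersion, mu = mean[pos])
  }
  out
}

#' Scatter cut positions around a summit
#'
#' Positions are drawn from a normal centered on the summit, rounded to
#' integer bp and clipped into `[0, chrom_length)`.
#'
#' @param summit_pos 0-based summit coordinate.
#' @param count number of cuts to draw.
#' @param cut_sd standard deviation of the scatter (bp).
#' @param chrom_length chromosome length (bp).
#' @return Integer vector of `count` cut positions.
#' @export
scatter_cuts <- function(summit_pos, count, cut_sd, chrom_length) {
  stopifnot(count >= 0)
  if (count == 0) return(integer())
  p <- round(rnorm(count, mean = summit_pos, sd = cut_sd))
  as.integer(pmin(pmax(p, 0), chrom_length - 1))
}

.cp_class_means <- function(cfg) {
  rbind(
    dependent_primed = c(A = cfg$base_mean, A_nil = cfg$base_mean / cfg$effect_fold,
                         A_stim = cfg$base_mean, A_stim_nil = cfg$base_mean / cfg$effect_fold),
    inducible = c(A = cfg$base_mean, A_nil = cfg$base_mean,
                  A_stim = cfg$base_mean * cfg$effect_fold, A_stim_nil = cfg$base_mean),
    invariant = c(A = cfg$base_mean, A_nil = cfg$base_mean,
                  A_stim = cfg$base_mean, A_stim_nil = cfg$base_mean),
    background = rep(cfg$noise_mean, 4L))
}

#' Simulate a full multi-condition cut-site experiment
#'
#' Lays out planted windows across the genome, assigns each a class, draws
#' per-sample negative-binomial window counts scaled by sample depth, scatters
#' the corresponding cuts around the summit, adds uniform background tags,
#' and builds linked TSS and TPM tables (linked gene TPM = window true mean x
#' `coupling_gain` x lognormal noise).  Fully deterministic given
#' `config$seed`; each sample uses its own [substream_seed()] stream.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_dataset` list: `cuts` and `summits` (named per-sample
#'   lists of data frames), `truth` (window id, coordinates, class, true mean
#'   per condition), `tss`, `tpm`, `samples`, `chrom_lengths`, `config`.
#' @export
simulate_experiment <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  samples <- simulation_samples(cfg)
  depth <- rep(1, nrow(samples)); names(depth) <- samples$sample
  if (!is.null(cfg$depth_factor)) depth[names(cfg$depth_factor)] <- cfg$depth_factor
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  # window layout + class assignment (own substream)
  n_class <- c(dependent_primed = cfg$n_dependent_primed, inducible = cfg$n_inducible,
               invariant = cfg$n_invariant, background = cfg$n_background_noise_windows)
  n_tot <- sum(n_class)
  margin <- 2 * cfg$tss_max_dist
  per_chrom_cap <- floor((cfg$chrom_length - 2 * margin) / cfg$spacing)
  layout <- with_seed(substream_seed(cfg$seed, "layout"), {
    # round-robin across chromosomes so every chromosome carries windows
    slots_chrom <- chroms[(seq_len(n_tot) - 1L) %% cfg$n_chroms + 1L]
    slot_idx <- (seq_len(n_tot) - 1L) %/% cfg$n_chroms + 1L
    jitter <- floor(runif(n_tot, 0, cfg$spacing / 4))
    pos <- margin + (slot_idx - 1) * cfg$spacing + jitter
    cls <- sample(rep(names(n_class), times = n_class))
    ord <- order(slots_chrom, pos)
    data.frame(chrom = slots_chrom[ord], summit = as.integer(pos[ord]),
               class = cls[ord], stringsAsFactors = FALSE)
  })
  means4 <- .cp_class_means(cfg)
  truth <- cbind(
    data.frame(window_id = sprintf("w%05d", seq_len(max(n_tot, 1))[seq_len(n_tot)]),
               layout, stringsAsFactors = FALSE),
    as.data.frame(means4[layout$class, , drop = FALSE], row.names = FALSE))
  names(truth)[5:8] <- paste0("mean_", CP_CONDITIONS)
  rownames(truth) <- NULL

  # per-sample summits (true positions; score = true mean at that sample's depth)
  # and cut tracks
  cuts <- list(); summits <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]; cond <- samples$condition[i]; d <- depth[[s]]
    mu <- truth[[paste0("mean_", cond)]] * d
    summits[[s]] <- data.frame(chrom = truth$chrom, pos = truth$summit,
                               score = mu, sample_id = rep(s, n_tot),
                               stringsAsFactors = FALSE)
    cuts[[s]] <- with_seed(substream_seed(cfg$seed, paste0("cuts::", s)), {
      counts <- negbin_draw(n_tot, mu, cfg$dispersion)
      sig_chrom <- rep(truth$chrom, counts)
      sig_pos <- unlist(lapply(which(counts > 0), function(w)
        scatter_cuts(truth$summit[w], counts[w], cfg$cut_sd, cfg$chrom_length)),
        use.names = FALSE)
      bg_n <- rpois(cfg$n_chroms, cfg$background_rate * cfg$chrom_length * d)
      bg_chrom <- rep(chroms, bg_n)
      bg_pos <- as.integer(floor(runif(sum(bg_n), 0, cfg$chrom_length)))
      df <- data.frame(chrom = c(sig_chrom, bg_chrom),
                       pos = c(as.integer(sig_pos), bg_pos),
                       stringsAsFactors = FALSE)
      df[order(df$chrom, df$pos), , drop = FALSE]
    })
    rownames(cuts[[s]]) <- NULL
  }

  # linked TSS table: one dedicated gene per planted window.  The offset is
  # capped at both tss_max_dist and just under half the window spacing, so a
  # window's dedicated gene is identifiable as its nearest TSS (otherwise the
  # nearest-gene join would mostly hit neighboring windows' genes and the
  # coupling would be unobservable by construction).
  tss <- with_seed(substream_seed(cfg$seed, "tss"), {
    max_off <- min(cfg$tss_max_dist, floor(cfg$spacing / 2) - 1)
    offs <- as.integer(round(runif(n_tot, -max_off, max_off)))
    tss_pos <- truth$summit + offs
    tss_pos[tss_pos < 0] <- 0L
    gene_id <- if (n_tot) paste0("gene_", truth$window_id) else character()
    data.frame(gene_id = gene_id, chrom = truth$chrom,
               tss = tss_pos,
               strand = sample(c("+", "-"), n_tot, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  if (cfg$n_extra_genes > 0) {
    extra <- with_seed(substream_seed(cfg$seed, "tss_extra"), {
      data.frame(gene_id = sprintf("bg_gene_%04d", seq_len(cfg$n_extra_genes)),
                 chrom = sample(chroms, cfg$n_extra_genes, replace = TRUE),
                 tss = as.integer(floor(runif(cfg$n_extra_genes, 0, cfg$chrom_length))),
                 strand = sample(c("+", "-"), cfg$n_extra_genes, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    tss <- rbind(tss, extra)
  }

  # TPM table coupled to the true window means
  tpm <- matrix(0, nrow(tss), nrow(samples),
                dimnames = list(tss$gene_id, samples$sample))
  linked <- seq_len(n_tot)
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]; cond <- samples$condition[i]
    tpm[, s] <- with_seed(substream_seed(cfg$seed, paste0("tpm::", s)), {
      noise <- exp(rnorm(nrow(tss), 0, cfg$coupling_sdlog))
      base <- c(cfg$coupling_gain * truth[[paste0("mean_", cond)]],
                rep(cfg$baseline_tpm, nrow(tss) - n_tot))
      base * noise
    })
  }
  attr(tpm, "samples") <- samples

  structure(list(cuts = cuts, summits = summits, truth = truth, tss = tss,
                 tpm = tpm, samples = samples, chrom_lengths = chrom_lengths,
                 config = cfg),
            class = "synthetic_dataset")
}

#' Match pipeline windows to simulation truth labels
#'
#' Joins a window set back to the generator's truth table by exact
#' (chromosome, summit) position — valid because pooling identical true
#' summit sets preserves positions.
#'
#' @param windows a window set from [make_windows()].
#' @param truth the `truth` component of a `synthetic_dataset`.
#' @return Character vector of class labels aligned with `windows`
#'   (`NA` for windows absent from the truth table).
#' @export
match_truth <- function(windows, truth) {
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  truth$class[match(key(windows$chrom, windows$summit),
                    key(truth$chrom, truth$summit))]
}

#' Write a synthetic dataset to disk in the pipeline's file dialects
#'
#' Cut tracks and summit sets as BED, truth/TSS tables and the sample sheet
#' as TSV, TPM as a gene x sample TSV, and the configuration echo as YAML.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- list(truth = p("truth.tsv"), tss = p("tss.tsv"), tpm = p("tpm.tsv"),
                samples = p("samples.tsv"), config = p("config.yaml"))
  for (s in names(dataset$cuts)) {
    paths[[paste0("cuts_", s)]] <- p("cuts_", s, ".bed")
    write_intervals(dataset$cuts[[s]], paths[[paste0("cuts_", s)]], "cutsite")
    paths[[paste0("summits_", s)]] <- p("summits_", s, ".bed")
    write_intervals(dataset$summits[[s]], paths[[paste0("summits_", s)]], "summit")
  }
  write.table(dataset$truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  write_intervals(dataset$tss, paths$tss, "tss")
  write_expression(dataset$tpm, paths$tpm)
  write.table(dataset$samples, paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  writeLines(yaml::as.yaml(cfg[setdiff(names(cfg), "depth_factor")]), paths$config)
  invisible(paths)
}
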