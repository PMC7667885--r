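# The negative-binomial cut-site generator: noise-model moments, scatter,
# determinism, substream independence, and planted effect sizes.

test_that("negbin_draw matches its mean/variance parameterization", {
  expect_equal(negbin_draw(10, 0, 0.5), rep(0L, 10))

  set.seed(1)
  x <- negbin_draw(1e5, 50, 0)          # Poisson limit
  expect_gt(var(x) / mean(x), 0.95)
  expect_lt(var(x) / mean(x), 1.05)

  set.seed(2)
  y <- negbin_draw(1e5, 50, 0.1)        # Var = 50 + 0.1 * 50^2 = 300
  se_var <- sd((y - mean(y))^2) / sqrt(length(y))
  expect_lt(abs(var(y) - 300), 3 * se_var)
})

test_that("scatter_cuts clips to the chromosome and reproduces the scatter sd", {
  expect_identical(scatter_cuts(100, 0, 60, 1000), integer())

  set.seed(3)
  p <- scatter_cuts(50, 5000, 60, 200)  # summit near the edge
  expect_true(all(p >= 0 & p < 200))

  set.seed(4)
  q <- scatter_cuts(50000, 1e5, 60, 1e6)
  se_sd <- 60 / sqrt(2 * length(q))
  expect_lt(abs(sd(q) - 60), 3 * se_sd)
})

test_that("planted class sizes are exact and truth covers every window", {
  ds <- shared_sim()
  cfg <- ds$config
  expect_equal(sum(ds$truth$class == "dependent_primed"), cfg$n_dependent_primed)
  expect_equal(sum(ds$truth$class == "inducible"), cfg$n_inducible)
  expect_equal(sum(ds$truth$class == "invariant"), cfg$n_invariant)
  expect_equal(sum(ds$truth$class == "background"), cfg$n_background_noise_windows)
  expect_equal(nrow(ds$truth),
               cfg$n_dependent_primed + cfg$n_inducible + cfg$n_invariant +
                 cfg$n_background_noise_windows)
  # summits >= spacing apart within chromosomes
  for (ch in unique(ds$truth$chrom)) {
    pos <- sort(ds$truth$summit[ds$truth$chrom == ch])
    expect_true(all(diff(pos) >= 1000))
  }
})

test_that("zero class counts give a background-only dataset with empty truth", {
  cfg <- simulation_config(n_chroms = 1, chrom_length = 1e6,
                           n_dependent_primed = 0, n_inducible = 0,
                           n_invariant = 0, n_background_noise_windows = 0,
                           background_rate = 1e-4, seed = 9)
  ds <- simulate_experiment(cfg)
  expect_equal(nrow(ds$truth), 0)
  expect_equal(nrow(ds$summits[[1]]), 0)
  expect_gt(nrow(ds$cuts[[1]]), 0)     # uniform background tags remain
})

test_that("the same config and seed reproduce byte-identical outputs", {
  cfg <- simulation_config(n_chroms = 1, chrom_length = 1e6,
                           n_dependent_primed = 10, n_inducible = 5,
                           n_invariant = 20, n_background_noise_windows = 2,
                           background_rate = 1e-3, seed = 77)
  ds1 <- simulate_experiment(cfg)
  ds2 <- simulate_experiment(cfg)
  expect_identical(ds1[names(ds1) != "config"], ds2[names(ds2) != "config"])

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(ds1, d1)
  write_synthetic_dataset(ds2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, basename(f1)))))
})

test_that("adding replicates does not perturb existing samples' draws", {
  base <- list(n_chroms = 1, chrom_length = 1e6, n_dependent_primed = 10,
               n_inducible = 0, n_invariant = 30, n_background_noise_windows = 0,
               background_rate = 1e-3, seed = 13)
  ds2 <- simulate_experiment(do.call(simulation_config, c(base, n_replicates = 2)))
  ds3 <- simulate_experiment(do.call(simulation_config, c(base, n_replicates = 3)))
  expect_identical(ds2$cuts[["A_rep1"]], ds3$cuts[["A_rep1"]])
  expect_identical(ds2$cuts[["A_nil_rep2"]], ds3$cuts[["A_nil_rep2"]])
  expect_identical(ds2$tpm[, "A_rep1"], ds3$tpm[, "A_rep1"])
  expect_identical(ds2$truth, ds3$truth)
})

test_that("planted dependent windows carry the configured fold effect in pooled counts", {
  cfg <- simulation_config(n_chroms = 2, chrom_length = 2e6,
                           n_dependent_primed = 200, n_inducible = 0,
                           n_invariant = 50, n_background_noise_windows = 0,
                           base_mean = 50, effect_fold = 4, dispersion = 0.1,
                           background_rate = 1e-4, seed = 21)
  ds <- simulate_experiment(cfg)
  w <- make_windows(pool_summits(ds$summits), 200, ds$chrom_lengths)
  counts <- count_cuts(w, ds$cuts[c("A_rep1", "A_rep2", "A_nil_rep1", "A_nil_rep2")])
  dep <- match_truth(w, ds$truth) == "dependent_primed"
  ratio <- mean(counts[dep, c("A_rep1", "A_rep2")]) /
    mean(counts[dep, c("A_nil_rep1", "A_nil_rep2")])
  expect_gt(ratio, 3.6)
  expect_lt(ratio, 4.4)
})

test_that("per-class empirical count means match the configured means", {
  p <- shared_pipeline_objects()
  cls <- match_truth(p$windows, p$ds$truth)
  for (cl in c("dependent_primed", "invariant")) {
    rows <- which(cls == cl)
    truth_mean <- p$ds$truth[[
      "mean_A"]][match(p$windows$window_id[rows], p$ds$truth$window_id)]
    obs <- rowMeans(p$raw[rows, c("A_rep1", "A_rep2"), drop = FALSE])
    # background adds ~0.4 tags/window at this rate; allow 3 SE around mean + bg
    bg <- 401 * p$ds$config$background_rate
    se <- sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - mean(truth_mean) - bg), 3 * se + 0.5)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(effect_fold = 1), class = "cp_config_error")
  expect_error(simulation_config(dispersion = -1), class = "cp_config_error")
  expect_error(simulation_config(n_chroms = 1, chrom_length = 1e5,
                                 n_invariant = 1e4), class = "cp_config_error")
})
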