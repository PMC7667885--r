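# chromaprime

Differential chromatin-accessibility analysis of **cytokine-primed** and
**inducible** regulatory elements from DNase-Seq / ATAC-Seq cut-site data.

T cells that have been activated once keep thousands of regulatory elements
open ("primed" DHSs) as long as a gamma-chain cytokine such as IL-2 keeps
signalling; on TCR restimulation a further set of elements opens
("inducible" DHSs).  Identifying these classes from accessibility data
reduces to a small number of quantitative steps, which this package
implements as tested, seed-deterministic building blocks plus an
end-to-end pipeline:

* **Union windows** — per-sample peak summits are pooled (single-linkage,
  200 bp) and each union summit becomes a counting window of
  summit ± 200 bp (0-based, half-open BED coordinates throughout).
* **Counting** — cut-site tags are counted per window per sample.
* **Normalization** — samples are equalized with a correction factor based
  on the median of each sample's top *N* (default 25,000) window counts:
  `f_s = G / m_s` with `G` the geometric mean of the per-sample medians.
  Mapped-read-depth scaling is provided for ChIP-style tracks.
* **Classification** — window *w* is condition-dependent iff in **every**
  replicate pair `(a_w + p)/(b_w + p) >= 2` **and** `max(a_w, b_w) >= 20`
  (pseudocount `p = 1`; all thresholds configurable and logged).  The same
  rule with stimulated/unstimulated pairs calls inducible sites, and set
  intersection defines cytokine-dependent inducible sites.
* **Downstream** — overlap flags and Venn partitions against external peak
  sets, IUPAC consensus motif scanning around summits (STAT5/GAS
  `TTCYNRGAA` and AP-1 `TGASTCA` built in), summit-to-summit proximity
  (default 25 kb), nearest-TSS linkage of accessibility to
  upper-quartile-normalized `log2(TPM + 1)` expression with a Spearman
  rank-trend statistic, and binned tag-density profile matrices
  (10 bp bins over ± 1 kb).
* **Synthetic data** — a negative-binomial cut-site generator with planted
  primed/inducible/invariant classes, truth labels, and coupled TSS/TPM
  tables makes every stage verifiable without sequencing data.

See the vignette (`vignettes/differential-accessibility.Rmd`) for the model,
parameter meanings, and design decisions.

## Worked example

Simulate a small four-condition experiment (60 primed, 60 inducible, 300
invariant, 20 noise windows on a 2 × 2 Mb genome), then count, normalize,
and call IL-2-dependent primed sites:

```r
library(chromaprime)

cfg <- simulation_config(n_chroms = 2, chrom_length = 2e6,
                         n_dependent_primed = 60, n_inducible = 60,
                         n_invariant = 300, n_background_noise_windows = 20,
                         background_rate = 1e-3, seed = 42)
ds      <- simulate_experiment(cfg)
windows <- make_windows(pool_summits(ds$summits), flank = 200, ds$chrom_lengths)
raw     <- count_cuts(windows, ds$cuts)
f       <- topn_median_factors(raw)
norm    <- apply_factors(raw, f)
head(f, 4)
#>       sample    m    factor
#> 1     A_rep1 49.5 0.9508787
#> 2     A_rep2 50.0 0.9413699
#> 3 A_nil_rep1 44.0 1.0697385
#> 4 A_nil_rep2 45.0 1.0459666

pdhs <- call_dependent(norm,
  contrast_spec("pDHS", list(c("A_rep1", "A_nil_rep1"), c("A_rep2", "A_nil_rep2"))),
  class_params(fold_threshold = 2, pseudocount = 1, min_count = 20))
pdhs
#> <dhs_call_set 'pDHS': 47 of 440 windows (fold >= 2 in each of 2 pairs, min count 20)>
```

The per-sample medians `m` sit near the planted mean of 50 tags/window, and
the factors bring them to a common reference.  Comparing the 47 calls with
the generator's truth labels:

```r
cls <- match_truth(windows, ds$truth)
table(planted = cls == "dependent_primed", called = windows$window_id %in% pdhs$members)
#>        called
#> planted FALSE TRUE
#>   FALSE   379    1
#>   TRUE     14   46
```

46 of 60 planted fourfold-reduced windows are recovered with a single false
call — the strict per-replicate twofold rule trades sensitivity for a low
false-discovery proportion (see the vignette for why ~70–80% sensitivity is
the expected operating point at these counts).

The whole chain (including proximity, motif, expression-linkage, and
profile stages) can also be driven from one YAML config:

```r
run_pipeline("config.yaml", out_dir = "results", seed = 1)
```

or from the shell via the thin wrapper `inst/cli/chromaprime`
(`validate` / `simulate` / `run` subcommands, exit codes 0/1/2).

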