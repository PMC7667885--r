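---
title: "Calling cytokine-dependent primed and inducible DHSs from cut-site data"
author: "chromaprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling cytokine-dependent primed and inducible DHSs from cut-site data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaprime)
```

## The analysis this package implements

DNase-Seq and ATAC-Seq measure chromatin accessibility as a cloud of single
cut (or transposition) positions.  In cytokine-priming experiments on T
cells, two classes of regulatory elements are of interest:

* **primed DHSs (pDHSs)** — open-chromatin sites maintained by a
  gamma-chain cytokine signal (e.g. IL-2) that collapse when the cytokine is
  withdrawn, and
* **inducible DHSs (iDHSs)** — sites that open upon TCR-pathway
  restimulation (PMA/ionomycin), whose inducibility can itself depend on the
  cytokine.

`chromaprime` rebuilds the quantitative core of such an analysis as a
reusable, seed-deterministic pipeline:

1. per-sample peak summits are pooled into a **union summit set**;
2. windows of **summit ± 200 bp** (401 bp) are counted against each sample's
   cut sites;
3. samples are equalized with a **median-of-top-N-peaks correction factor**;
4. condition-dependent sites are called with a **replicate-consistent
   fold-change rule**: at least `fold_threshold`-fold in *every* replicate
   pair, above a background count cutoff;
5. downstream set biology: overlaps and Venn partitions against external
   peak sets, IUPAC consensus motif scanning around summits,
   summit-to-summit proximity (default 25 kb), nearest-gene linkage of
   accessibility to expression, and binned tag-density profile matrices.

No p-values are attached to the classification: the rule is a pure fold
filter with replicate consistency, which is how fold-change-ranked DHS
analyses of this design are usually reported.  Significance testing of
*expression* (moderated linear models, adjusted p-values) is deliberately
out of scope; externally computed adjusted p-values can be joined onto the
gene-level fold changes.

## Coordinate and counting conventions

Every coordinate in the package is **0-based, half-open** (BED convention);
a 1-bp summit interval has `end == pos + 1`.  Chromosome names are matched
as exact strings — no `chr` aliasing — and tags on chromosomes absent from
the window set are counted and reported, then ignored.

Cut sites are strandless single positions.  No shift or extension is
applied: the counting unit is the tag, not a reconstructed fragment.  A
window is `[summit - flank, summit + flank + 1)`; membership of a cut is
`start <= pos < end`, so a cut exactly at `end` is outside.  A cut inside
two overlapping windows is counted in both.  These boundary rules are pinned
because the classification thresholds are closed (`>=`): moving a boundary
by 1 bp can move a window across the twofold line.

The union summit set is built by single-linkage clustering of per-sample
summits at 200 bp, keeping the highest-scoring summit per cluster (ties:
lower coordinate, then sample label).  This replaces peak calling on pooled
alignments, which is an upstream step outside this package; a precomputed
union summit BED can be supplied instead (`union_summits` in the pipeline
config) when bit-faithful reruns of an external union are needed.

## Normalization

For each sample the statistic `m_s` is the median of its `n_top` largest
window counts (`n_top = 25000`, clamped to the number of windows; an
optional `basis_windows` subset supports high-confidence-peak variants of
the same correction).  Factors are

\[ f_s = G / m_s, \qquad G = \big(\prod_s m_s\big)^{1/S}, \]

so multiplying by `f_s` equalizes the per-sample top-N medians at `G`.  The
geometric-mean reference makes the factors symmetric in the samples and the
procedure idempotent: factors recomputed on a normalized matrix are all 1
(to numerical precision).  No reference sample is singled out; the basis and
reference are recorded on the returned object.  Scale equivariance holds in
the only sense a symmetric reference permits: scaling one sample's counts by
`c` divides its factor *relative to any other sample* by exactly `c`.
Read-depth scaling for ChIP-style tracks uses the same geometric-mean
construction on mapped-read counts.

## The classification rule

With normalized counts `a_w` (condition A) and `b_w` (condition B) in one
replicate pair, the fold change is `FC_w = (a_w + p) / (b_w + p)` with
pseudocount `p = 1`.  Window `w` enters the call set iff in **every**
replicate pair `FC_w >= fold_threshold` (default 2, closed) **and**
`max(a_w, b_w) >= min_count` (default 20).  The pseudocount bounds fold
changes at zero counts and is negligible at the `min_count` scale; the count
cutoff is the explicit stand-in for "exclude background and insignificant
peaks" and must be tuned to the sequencing depth at hand — it is logged with
every call set.  Replicates are paired positionally (rep1 with rep1), the
design under which per-replicate fold consistency is meaningful.

Invariant control sets are selected from windows that clear `min_count` in
every sample referenced by the supplied contrasts, taking the `n` windows
with the smallest worst-case `|log2 FC|` over all contrasts and pairs (ties
resolved in coordinate order, so the selection is deterministic).

## The synthetic-data generator

`simulate_experiment()` emulates a four-condition, two-replicate
cytokine-withdrawal + restimulation design
(`A`, `A_nil`, `A_stim`, `A_stim_nil`) with four planted window classes:

| class | A | A_nil | A_stim | A_stim_nil |
|---|---|---|---|---|
| dependent_primed | m | m/f | m | m/f |
| inducible | m | m | m·f | m |
| invariant | m | m | m | m |
| background | m/10 | m/10 | m/10 | m/10 |

with `m = base_mean = 50` expected tags per window per replicate and
`f = effect_fold = 4`.  Window counts are negative-binomial
(`Var = m + alpha m^2`, `alpha = 0.1`; `alpha = 0` degenerates to Poisson),
the standard overdispersed noise model for sequencing counts; cuts scatter
around the summit with a Gaussian of sd 60 bp; uniform background tags are
added at `5e-3` per bp (5×10⁵ tags per sample on the default 2 × 50 Mb
genome, about 2 tags per 401-bp window).  These sizes are the package's
desk-scale default design: large enough for stable top-N medians and class
recovery, small enough that a full run takes well under a minute.

Inducible windows are modelled as **cytokine-dependent in their induction**
(induced only in `A_stim`), so that intersecting the "inducible" and
"stimulation-dependent" call sets recovers them — the synthetic analogue of
defining cytokine-dependent iDHSs by intersection.  Real data are less tidy:
in the motivating biology only a minority of inducible sites are
cytokine-dependent, classes overlap, and effect sizes are continuous rather
than a single planted fold.

One root seed drives everything; each sample (and the layout, TSS, and
expression streams) derives its own substream by stable string hashing
(`substream_seed`), so adding a replicate never perturbs the draws of
existing samples.  Outputs are byte-identical across runs with the same
config and seed.

Windows are laid out round-robin across chromosomes at a minimum spacing of
2 kb (so default 401-bp windows can never merge during pooling).  Each
planted window gets a dedicated gene whose TSS offset is capped at both
10 kb and just under half the spacing: with the default layout the linked
gene is therefore its window's nearest TSS.  Without that cap the
nearest-gene join would mostly land on neighboring windows' genes purely
because the synthetic windows are much denser than real gene spacing, and
the planted expression coupling would be unobservable by construction.
Linked gene TPM is `coupling_gain × (true window mean) × lognormal noise`
(sdlog 0.25); unlinked background genes sit at a constant baseline TPM.

### What passing tests do and do not show

The generator reproduces the *statistical skeleton* the classifier assumes:
NB counts around planted means, replicate independence, uniform background,
Gaussian cut scatter.  It does not model GC or fragment-length bias,
chromatin-domain correlation between neighboring sites, mappability gaps,
or peak-shape heterogeneity.  Recovery rates measured on it are therefore
statements about the rule under its own noise model, not about any
particular sequencing data set.

Under the default design (NB mean 50 vs 12.5, dispersion 0.1), the
per-replicate probability that a truly fourfold-reduced window clears the
closed twofold rule is about 0.87, so the two-replicate AND-rule recovers
roughly 70–76% of planted sites while keeping the false discovery
proportion below 10%.  That asymmetry — strict control of false calls at
the price of sensitivity — is intrinsic to per-replicate fold thresholds at
these counts and is worth keeping in mind when interpreting call-set sizes.

## Expression linkage

TPM tables are filtered (TPM > 1 in at least one sample), upper-quartile
normalized (each sample's 75th percentile of retained TPMs scaled to the
geometric mean of those percentiles; type-7 linear interpolation, the
default percentile rule in R, pinned so exact tests are possible), and
transformed as `log2(TPM + 1)`.  Gene fold changes are differences of mean
log values, with a helper flag at the 3-fold threshold.  Each window links
to its nearest TSS by absolute distance, strand-ignored (gene-body overlap
does not override); ties break to the lower coordinate, then lexicographic
gene id.  The rank-vs-expression trend orders windows by accessibility fold
change and reports the Spearman correlation with the linked genes' log2
fold changes; an optional rolling median (logged width) smooths the series
for plotting, and the trend statistic is always computed on the raw series.

## Profiles

`density_matrix()` bins cuts in `[summit - span/2, summit + span/2)` at
10 bp (200 bins over 2 kb by default), scaled by the sample's normalization
factor, with rows in the caller's order — typically the fold-change ranking,
which is how ranked tag-density heatmaps are assembled.  Windows clipped by
a chromosome edge keep out-of-range bins at zero and are flagged.  Row sums
equal the windowed cut counts times the factor exactly; this conservation
identity is tested against the window counter.

## Numerical and degenerate-input choices

* "At least twofold" is the closed comparison `>=`, so boundary windows are
  members.
* `p = 0` is allowed in fold changes; `x/0` is `Inf` and `0/0` is `NaN`,
  both documented rather than masked.
* A zero top-N median, zero mapped depth, or zero upper quartile is a
  degenerate-sample error, never a silent `Inf` factor.
* Empty inputs (no summits, empty call sets, empty truth tables) flow
  through every stage and produce empty, well-formed outputs.
* All tie-breaks (summit pooling, invariant selection, ranking, nearest-TSS)
  are pinned and deterministic.

## Problem sizes used in the shipped verification

The package's own checks run the generator at 400–2,500 windows on 2–100 Mb
synthetic genomes: brute-force oracle comparisons at up to ~10³ × 10³
(100 seeded instances per primitive), recovery of the planted design at
200 dependent + 2,000 invariant windows, the expression trend at 500
windows, and end-to-end determinism on a ~240-window run.  These sizes were
chosen as the smallest at which the stochastic properties stabilize.

## Limitations

* Peak calling is an input, not a feature; the bundled naive caller exists
  only to exercise synthetic tracks.
* Consensus motif scanning (IUPAC strings, optional mismatches, both
  strands) approximates PWM scanning; counts derived from it are labelled
  approximate and will not reproduce matrix-based motif totals.
* The classifier is a fold-rule, not a test; it has no error-rate guarantee
  beyond what the simulation measures.
* Fragment-level (paired-end) counting, blacklist filtering, and bigWig
  export are out of scope.
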