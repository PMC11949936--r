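---
title: "Methods: tiled CRISPR screen analysis in tilescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiled CRISPR screen analysis in tilescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screen and its readout

A tiled CRISPR/Cas9 screen asks, for every targetable position of a genomic
window, whether a small Cas9-induced lesion at that position disrupts
expression of a reporter locus. A dense sgRNA library is delivered
lentivirally at low MOI (one guide per cell), cells are edited with Cas9,
and the expression-negative population is isolated by FACS. Guide cassettes
are PCR-amplified and sequenced from the sorted cells and from untreated
baseline cells carrying the same library. Guides that cut something the
locus needs — a coding exon, or a regulatory element such as an enhancer
module — are enriched in the sorted sample relative to baseline; exonic
guides thereby serve as built-in positive controls, and *enriched
non-exonic* guides are the regulatory-element candidates.

`tilescreen` implements the dry half of this experiment: library design,
guide counting from reads, enrichment statistics and hit calling, plus the
two auxiliary calculations used in validation work (dual-guide excision
sizes and 2^−ΔΔCt qPCR fold changes), and a simulator that generates every
input with known ground truth.

# Coordinates and library design

All coordinates are 0-based half-open internally; printed 1-based inclusive
browser coordinates are converted at the boundary (`start − 1`, `end`
unchanged) by `interval_from_1based()` / `parse_region()` and never mixed
internally. Whether a published boundary pair is read as 1-based inclusive
or 0-based exclusive changes the window length by a single bp — immaterial
at the 24-kb scale this analysis targets, so the package standardizes on
the browser convention.

`scan_protospacers()` enumerates every 20-nt spacer followed by an NGG PAM
on both strands, keeping only protospacers whose full 23 bp fit inside the
interval (unambiguous and conservative at the edges), and never emitting a
spacer containing `N`. The predicted cut site is the 0-based coordinate of
the bond cleaved by the canonical SpCas9 blunt cut between spacer positions
17 and 18 (3 bp 5′ of the PAM): `spacer_start + 17` on the plus strand,
`spacer_start + 3` on the minus strand. Guides are ordered by cut site
(plus strand first on ties, then by start — a fixed, documented tie-break)
and given zero-padded ids.

Default design filters: deduplication of identical spacers (a duplicated
spacer cannot be counted separately; the first copy by coordinate is kept)
and removal of spacers containing `TTTT`, which terminates Pol III
transcription from the U6 promoter used in sgRNA cassettes. GC bounds are
available but off by default — a tiling screen wants maximal coverage, and
low-activity guides merely cost a little power. On uniform random DNA the
expected density is `2·(L−22)/16` guides before filtering, roughly one cut
site per 8 bp.

A guide is labelled exonic when its cut window `[cut − 3, cut + 3)`
overlaps an annotated exon: indels extend a few bases around the cut, so a
cut just outside an exon boundary can still disrupt it.

# Counting guides from reads

The guide cassette is amplified with constant vector sequence flanking the
variable spacer, so counting reduces to anchor-delimited extraction: the 20
bases immediately after the first occurrence of the 5′ anchor, optionally
verified against a 3′ anchor, looked up in the library. Design choices:

- **Exact matching by default** (`max_mismatches = 0`): reproducible and
  conservative. With `max_mismatches = 1`, exact dictionary hits always
  win; a non-exact spacer is rescued only when it has a *unique* library
  neighbour at Hamming distance 1, otherwise it stays unassigned.
- **Paired-end**: the spacer is taken from R1; the reverse-complemented R2
  is consulted only when R1 yields nothing. R1-wins is deterministic and
  independent of read order.
- **Quality scores are ignored**; the anchors themselves are the specificity
  filter at amplicon read lengths.
- Conservation holds by construction: per sample, assigned + unassigned
  equals reads scanned.

Anchor sequences are configuration values (`default_anchors()` carries
standard U6/scaffold context used by the simulator); real analyses should
supply the vector's own context.

# The enrichment statistic

Counts are normalized to **counts per million** per sample — the minimal
depth correction compatible with comparing medians and ratios downstream;
no between-guide normalization is attempted because the screen statistic is
per-guide. For each guide:

- `median_sorted`, `median_baseline`: medians of normalized counts over the
  replicates of each condition (medians first, then the ratio — with 3
  replicates the median is a robust location estimate, and taking it before
  the ratio keeps a single outlying replicate from dominating). The
  alternative, the median of per-replicate ratios, is available as
  `fc_method = "ratio-median"`.
- `log2fc = log2((median_sorted + pc)/(median_baseline + pc))` with
  pseudocount `pc = 1` normalized unit, guarding zero baselines.
- `p_value`: one-sided two-sample Welch *t*-test of sorted > baseline
  across replicates. Welch, because sorted counts of a true hit have a
  several-fold larger mean and hence larger variance than baseline; the
  samples are not paired, so a paired test would be wrong.
- `score = −log10(p) · log2fc`, the composite volcano score written to the
  bedGraph track.

**Scale of the t-test.** The test is computed on `log2(CPM + pc)` by
default (`test_scale = "log2"`; raw CPM behind `test_scale = "cpm"`). For
overdispersed counts the standard deviation grows proportionally with the
mean, so on the raw scale an enriched guide's own signal inflates its
standard error: with n = 3 per group the Welch degrees of freedom collapse
toward 2 and even strong, consistent enrichment struggles to clear a 0.02
one-sided threshold. The log transform is variance-stabilizing (replicate
spread becomes approximately constant in the mean), which restores power at
triplicate scale while leaving the null calibration intact — the package's
acceptance checks measure both properties (planted-hit recovery across ten
seeds, and the p < 0.02 fraction on null screens against the test's
empirical size). Log-scale testing of normalized counts is the common
choice across screen and expression analysis for exactly this reason.

**Degenerate variance** (all replicates identical in both groups) is given
a total ordering instead of an exception: p = 1 when the sorted mean does
not exceed the baseline mean, the smallest positive double otherwise — so
scores stay finite and sortable.

**Hit calling** uses strict inequalities at `log2fc > 1.5` and
`p < 0.02` on the *raw* p-value; no multiple-testing correction enters the
calls (a BH-adjusted column is reported for reference). These thresholds
are deliberate: the screen is a candidate generator whose calls are
validated individually in follow-up experiments, so calibrated raw
thresholds matched to the published analysis are preferred over FDR
control that would change which guides are carried forward. Volcano
classes: `exonic` (positive controls, whatever their enrichment),
`enriched-non-exonic` (hits outside exons — the discovery class),
`non-exonic` (the rest).

The score track emits each guide's score at its 1-bp cut interval. Two
guides can share a cut coordinate (a plus/minus pair cleaving the same
bond); since bedGraph assigns one value per position, later duplicates are
shifted to the next free base in stable table order and each shift is
logged — positional error ≤ 2 bp on a track meant for visual inspection.

# Excision prediction and ΔΔCt

For a dual-guide treatment, `predict_excision()` reports the deleted span
as the interval between the two cleaved bonds and its size as the
coordinate difference of the cut sites — the quantity a perfect religation
of the outer ends removes. It is symmetric in the pair and independent of
either guide's strand; end resection and indel formation at the junction
are biological variability outside the prediction's scope.

`ddct_fold_change()` implements the plain 2^−ΔΔCt form with perfect
amplification efficiency assumed, as in the validation experiments it
mirrors. `summarize_ddct()` averages technical replicates on the Ct scale
(where replicate noise is approximately additive), forms per-sample ΔCt
against the control-group mean, and summarizes per group on the
fold-change scale with the n−1 sample SD; a single biological replicate
reports `NA`, never a misleading 0.

# What the simulator emulates — and what it does not

`screen_sim_params()` defaults encode the study design conditions: a 24,000
bp window at GC 0.41 (human-like), four exon blocks sized like the constant
region exons of a TCR locus (274/108/144/30 bp at fixed positions in the
window), 3 sorted + 3 baseline replicates, 200 reads per guide mean
coverage, six true non-exonic hits at 8-fold enrichment, and
negative-binomial count noise with size 10 over log-normal (sdlog 0.5)
baseline guide abundances — conventional pooled-screen noise magnitudes,
chosen once as realistic rather than estimated from any particular
dataset. Exon-window guides are enriched identically to planted hits,
because the screen observes enrichment, not mechanism. Sorted columns are
rescaled to the column target depth after enrichment, as sorting and
resequencing fix the depth, not the composition. Reads are the
anchor5+spacer+anchor3 construct embedded at a random offset in random
stuffer at 250 bp, shuffled, with optional per-base substitution errors.

The simulator deliberately does **not** model: FACS gating errors and
sorting impurity, infection statistics (MOI, multiple integrations),
population bottlenecks and drift during expansion, PCR jackpotting,
position-dependent guide activity, or Cas9 editing-outcome spectra. Passing
recovery tests therefore demonstrates that the statistics behave correctly
under the stated noise model at the study's sample sizes — not that any
particular biological screen will reach the same power.

All simulators are deterministic per seed; each derives its stream from the
user seed plus a fixed small offset, and restores the caller's RNG state.

# Problem sizes used in validation

The packaged checks run the protospacer-scan/brute-force equivalence on
1,000 random 500-bp sequences; cell-exact count recovery through simulated
reads at full screen depth (6 samples × ~380,000 reads); planted-hit
recovery and null calibration on ten seeded replicates of the standard
screen (~1,900–2,100 guides each). These sizes keep the whole suite at a
few minutes on one core while exercising every stage at realistic scale.

# Known limitations

- Enrichment is scored per guide; no sliding-window or region-level
  aggregation across neighbouring cut sites is attempted (peaks are left to
  visual inspection of the score track).
- Exact/1-mismatch dictionary matching cannot rescue reads with indels in
  the spacer or anchor.
- The t-test with n = 3 per condition has limited power for modest effect
  sizes; the thresholds are calibrated for strong enrichment such as
  knockout-like dropout of expression.
- FASTA handling loads whole records; the package targets locus-scale
  windows, not whole-genome scans.
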