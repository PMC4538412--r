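---
title: "Methods and design of the fluorosnc pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the fluorosnc pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorosnc)
```

# Scope and scientific setting

Chronic excess fluoride intake disturbs bone formation and remodeling, and
short noncoding RNAs — miRNAs and C/D-box snoRNAs — are candidate mediators
of that disturbance at the posttranscriptional level. `fluorosnc` implements
the computational stages of a sodium-fluoride exposure study in
osteoblast-lineage cell culture: a single-channel microarray screen of
mature noncoding RNA probes across a control and two sublethal dose groups,
sequence-feature analysis of the C/D-box snoRNA probe set, relative
quantification of validation qPCR assays, LC50 interpolation from an MTT
viability assay, and canonical seed-site scanning of candidate miRNAs
against gene UTRs. Every stage can be driven by the package's own
synthetic-data generators, which carry known ground truth so that the whole
chain is testable without any external download.

# Array screen

## Model

Probe intensities are treated as log-normal: processing happens on the log2
scale. The chain is

1. **Background adjustment** (optional): per sample, the 2nd-percentile
   intensity is subtracted and results are floored at 1.0 so the log2
   transform stays defined. This is a deliberate simplification of the
   normal-plus-exponential convolution background of full RMA; the stage is
   a plug-in and can be disabled (`background = FALSE`), and none of the
   downstream statistics depend on the convolution model.
2. **Quantile normalization**: every sample is mapped onto the across-sample
   mean of order statistics. Ties receive the mean of the target values at
   the ranks the tie group occupies. On tie-free data the per-sample sorted
   vectors are identical afterwards and the transform is idempotent; with
   ties the collapsed values necessarily perturb the sorted vectors at the
   tied positions — a property of any tie-averaging rule, not of this
   implementation.
3. **Summarization** (when several probes map to one feature):
   `stats::medpolish` row/column median sweeps, at most 10 iterations or a
   total change below 0.01; the probeset value per sample is overall effect
   plus column effect. Mature-miRNA arrays carry one probe per feature, so
   the demo pipeline skips this stage.
4. **Per-probe one-way ANOVA** across all groups (classical equal-variance
   F test; `stats::oneway.test` for single probes and an algebraically
   identical vectorized row-wise F computation for whole matrices — the two
   paths are cross-checked in the test suite). P-values are reported raw,
   without multiple-testing correction, matching the screening convention
   the pipeline reproduces; Benjamini–Hochberg can be applied afterwards
   with `p.adjust` if desired.
5. **Signed fold change** per dose against control:
   `r = 2^(mean_treated - mean_control)` reported as `r` when `r >= 1` and
   `-1/r` otherwise, so magnitudes are always at least 1 and down-regulation
   is negative. The default screen keeps probes with `p < 0.05` and
   `|FC| >= 1.5`.

Degenerate ANOVA inputs are resolved explicitly: zero within-group variance
yields p = 0 when group means differ and p = 1 when they are equal (with a
warning), and fewer observations than one error degree of freedom is an
error.

## What the generator emulates

`gen_probe_matrix()` draws per-probe baselines uniformly on log2 [4, 12],
adds Gaussian sample noise (default SD 0.25 log2 units), plants a chosen
fraction of probes with a fixed log2 shift (default 2) of random sign in
both treated groups, and exponentiates. It emulates the marginal log-normal
character and effect structure of array data — not probe-level chemistry,
probe-affinity biases, batch structure, or correlated noise. Passing
recovery and calibration tests on this generator therefore demonstrates the
correctness of the statistics, not robustness to real-array artifacts.
Group sizes default to 3/3/3; the replication of the original deposit is not
stated in text, so the demo uses a conventional triplicate design.

# C/D-box snoRNA features

C/D-box snoRNAs carry a C-box (`UGAUGA`) near the 5' end and a D-box
(`CUGA`) near the 3' end, with possible internal copies. The feature stage
computes, per sequence: all motif occurrences (overlap-aware substring
matching via `Biostrings::matchPattern`) with a terminal/internal class;
overlapping UG and CG dinucleotide counts; and a length-outlier flag.

* **Terminal window**: a box starting within the first 15 nt is 5'-terminal
  and one ending within the last 15 nt is 3'-terminal (5' precedence). The
  window is configurable; 15 nt is a pragmatic reading of "near the
  terminus" for molecules mostly 60–110 nt long.
* **Length outliers** use the Tukey fences `q25 - 1.5·IQR` and
  `q75 + 1.5·IQR`. The quantile estimator defaults to linear interpolation
  between order statistics (R type 7) but all standard types 1–9 are
  selectable, and `bounds_estimator_sweep()` reports the fences under every
  type so a published fence pair can be traced to its estimator. Flagging
  uses strict `length > upper` from computed bounds and `length >= t` when
  an explicit threshold is supplied, matching how a printed threshold is
  normally applied.
* **Homogeneity** of the outlier set is summarized by the mean pairwise
  Kimura two-parameter distance. The K2P model separates transitions
  (A↔G, C↔U; proportion P) from transversions (proportion Q):
  `d = -1/2·ln(1 - 2P - Q) - 1/4·ln(1 - 2Q)`. When `1 - 2P - Q` or
  `1 - 2Q` is non-positive the distance is undefined (saturation) and the
  pair is excluded from the mean and counted. Unequal-length sequences are
  first aligned with a global Needleman–Wunsch aligner (match +1, mismatch
  −1, linear gap −2, traceback ties resolved toward the diagonal so results
  are fully deterministic); gap columns are excluded. The scores are pinned
  for reproducibility, not optimized for snoRNA biology, and are
  overridable at the alignment layer.
* **D-box multiplicity vs regulation**: among length outliers, a 2×2 table
  of (≥ 2 D-boxes vs fewer) against (down vs not down) with per-stratum
  down-fractions, the summary used to ask whether long, D-box-rich snoRNAs
  respond differently to treatment.

`gen_snorna_set()` plants exact motif counts on a first-order Markov
background whose U→G transition weight is adjustable (making UG dinucleotide
enrichment controllable), drawing core lengths from [48, 112] and outlier
lengths from [114, 237]. Planting uses rejection: after motifs are written
into a background draw, the sequence is re-scanned and redrawn until the
found counts equal the planted counts, which provably removes accidental
motifs (including at junctions). The generator emulates motif counts,
length structure and dinucleotide composition — not snoRNA secondary
structure, conservation, or genomic context. In the demo, regulation truth
is planted to follow the architecture being summarized (outliers with ≥ 2
D-boxes down, others up), so the contingency summary exercises its code
path with a known answer rather than discovering biology.

# qPCR quantification

`ddct_fold_change()` implements `2^-ddCt` with an assumed amplification
efficiency of 2 (no efficiency correction, as none is estimable from a
validated-primer design). Per condition, `dCt` is the target's mean Ct minus
the reference aggregate, the arithmetic mean of the reference genes' mean
Cts — on the linear scale this equals normalizing by the geometric mean of
reference quantities, the conventional multi-reference rule. The signed
convention is as in the array stage. Dispersion is the SD of the signed
fold change over all pairings of one treated-replicate dCt with one
control-replicate dCt; whether published ± values are SD or SEM is usually
unstated, so the package documents its dispersion as exactly this pairing
SD. A single pairing yields dispersion 0 with a warning.

LC50 is interpolated log-linearly between the doses bracketing viability
0.5 (first crossing; an exact 0.5 observation wins). A four-parameter
logistic fit would be the fuller model; interpolation was chosen because
the quantity is supporting context for dose selection, not an inferential
endpoint, and the interpolation has an exact synthetic truth
(`gen_viability_table()` places viability exactly 0.5 at its `lc50`
argument).

# Seed-site scanning

`find_seed_sites()` reports exact Watson–Crick reverse complements of the
miRNA seed in a UTR, without G:U wobble, classed as 6mer (positions 2–7),
7mer-m8 (2–8), 7mer-A1 (2–7 plus an adenosine opposite position 1, which is
not required to pair) and 8mer (both). Each 6mer-core window is reported
once with its most specific type; coordinates are 0-based half-open on the
given strand, and orientation is the caller's responsibility. Thermodynamic
scoring, conservation filters and 3'-supplementary pairing are deliberately
out of scope: the stage answers "where could the seed pair?", not "which
sites are functional?".

# Numerical and design choices

* Quantile estimator for fences: type 7 default because it is R's default
  and matches linear interpolation between order statistics; the estimator
  sweep exists because published fences often come from a different,
  unstated estimator.
* Saturated K2P pairs are excluded-and-counted rather than propagated as
  `NA` or infinity, so a mean over a mostly-defined set remains usable
  while the exclusion count keeps it honest.
* The vectorized F screen recomputes sums of squares directly; it is tested
  against the scalar `oneway.test` path at 1e-10.
* Background adjustment floors at 1.0, which breaks exact scale
  equivariance of that stage; the pipeline-equivariance property therefore
  holds for the normalization+ANOVA chain (`background = FALSE`), as
  tested.
* All generators call `set.seed()` with an explicit argument and sub-seeds
  in the orchestrator are `seed + 1..4`, so one master seed reproduces a
  demo report byte-for-byte.

# Problem sizes

The shipped tests and the acceptance script use the sizes the analyses were
designed around: 500-probe matrices at 3/3/3 samples for recovery, a
2000-probe null for calibration, a 25-sequence snoRNA set (20 core + 5
outliers), 3-replicate Ct tables, and 100–1000-case randomized oracle
comparisons for the scanners. A full demo run completes in a few seconds on
one CPU.

# Known limitations

* The array stage consumes exported intensity matrices; CEL-file parsing
  and probe-level chemistry are out of scope.
* The percentile background is not RMA's convolution background; absolute
  normalized values differ from Expression Console output even where the
  downstream screen logic matches.
* `run_geo_recipe()` requires user-downloaded series-matrix exports; it
  never fetches data, and its group inference from sample titles is a
  heuristic that should be overridden with an explicit `groups` vector for
  real series.
* K2P on unequal-length sequences depends on the alignment; the pinned
  scores make it reproducible but different aligner settings will move the
  mean distance of a divergent set.
* The synthetic generators do not emulate correlated probes, batch effects,
  qPCR efficiency drift, or snoRNA structure, so green tests bound
  algorithmic correctness, not field performance on real data.
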