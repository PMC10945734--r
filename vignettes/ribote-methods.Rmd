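---
title: "Models and methods behind ribote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribote)
```

ribote analyses ribosome-profiling experiments laid out as a
2 genotype × 2 condition × 2 replicate design with paired
ribosome-protected-fragment (RPF) and RNA-seq libraries — sixteen count
columns per experiment. This vignette explains the statistical models, the
tunable parameters, what the synthetic-data generators do and do not
emulate, and the numerical choices a maintainer would want spelled out.

## Translational efficiency and the interaction model

TE of gene *g* in one (genotype, condition, replicate) unit is the
size-factor-normalized RPF count over its CDS divided by the normalized
RNA count. Size factors are median-of-ratios: for each library of one
assay, the median over genes (with all-positive counts) of the ratio of
the gene's count to its across-library geometric mean, rescaled to
geometric mean 1. `compute_te()` excludes genes with a zero RNA count
(reason `zero_rna`) rather than pseudocounting them; a configurable
pseudocount exists for sensitivity analysis but is off by default because
silent patching of zeros changes ratio estimates invisibly.

`delta_te()` tests TE changes between two cells with a per-gene log-link
negative-binomial GLM over the eight contrasted libraries,

> counts ~ assay + cell + assay:cell, offset = log(size factor),

with variance μ + αμ². The assay:cell interaction is exactly the log
fold-change of TE; it is reported in log2 units. The same engine drives
`delta_rro()`, with (uORF counts, CDS counts) standing in for (RPF, RNA),
so a single fitting path serves both analyses. We deliberately fit an
explicit interaction model rather than a ratio-of-ratios heuristic: the
design formula behind published TE analyses is rarely stated, and the
interaction coefficient is the one quantity whose meaning does not depend
on which normalization absorbed what.

**Dispersion.** With two replicates per cell, per-gene method-of-moments
dispersion estimates are unusable on their own. Each gene's pooled MoM
estimate is therefore shrunk toward a trend α(μ) = a₀ + a₁/μ fitted across
genes, with weight `dispersion_shrinkage` (default 0.5) on the trend. This
mirrors the empirical-Bayes idea of the established count-model tools
without reproducing their exact internals; we do no independent filtering
and no outlier replacement.

**Inference.** The Wald statistic for the interaction is referred to a
moderated t distribution. Residual df is n − 4 (= 4 here); because half
the dispersion weight comes from the genome-wide trend, the reference df
is inflated to residual × (1 + w/(1−w)) — 8 at the default w = 0.5 — the
usual prior-df accounting for borrowed variance information. The choice
matters: against a normal reference, full-null simulations (2000 genes,
dispersion 0.05) produced spurious q < 0.25 calls in most runs; with the
moderated t they produce none, while power at |log2 ΔTE| = 1 on deep
libraries remains essentially 1. A permutation alternative
(`method = "perm"`) enumerates the six reassignments of replicate units to
cells; its two-sided p floor is 2/6 (the complementary relabelling negates
the interaction), so it validates rankings rather than providing fine
p-values.

**Selection.** `select_by_fold()` cuts strictly at log2(fold). The
conventional ">1.41-fold" selection is √2, i.e. a strict cut at half a
log2 unit, so an effect of exactly 0.5 log2 does not qualify; callers
wanting this boundary behavior should pass `fold = sqrt(2)`.

## uORF relative ribosome occupancy

RRO divides the uORF's RPF count by the host CDS's RPF count within the
same library, on raw counts — numerator and denominator share the library,
so size factors cancel; cross-sample comparisons go through the
interaction model instead. Filters follow the 2/32 rule: mean uORF RPF
below 2 (flag `low_uorf`, which takes precedence) or mean CDS RPF below 32
(`low_cds`) over the combined samples of the comparison — read as the
arithmetic mean over all four libraries of a two-versus-two contrast, on
raw counts (whether published filters used normalized counts is unstated;
raw is assumed and flagged here). Group-versus-translatome comparisons use
the two-sided Mann–Whitney U test with the group included in the
background, matching how box-plot comparisons against "all mRNAs" are
drawn; a disjoint-background option exists.

## Tripeptide pause scores

Raw 3'-end footprint tracks are shifted upstream by `shift_nt` (default
18), positioning the first codon of a tripeptide in the E site; counts
shifted below position 0 are dropped and counted. The tripeptide at codon
k occupies the 9-nt span [cds_start + 3k, cds_start + 3k + 9); occurrences
whose ±`window_nt` (default 50) flanks leave the CDS are excluded, and the
occurrence score is the mean rpm over the span divided by the mean rpm
over the flanks. Two choices are config switches because the field's
descriptions are ambiguous: the numerator is the whole 9-nt span by
default (`pause_numerator = "a_site"` scores the third codon alone), and
the background excludes the motif span (`flank_excludes_motif = FALSE`
includes it; inclusion attenuates large pauses, which is why exclusion is
the default — it keeps the flat-track identity and planted-multiplier
recovery exact). Occurrences with a zero flank mean are skipped, not set
to infinity, and counted in an attribute. The occurrence floor
(`min_motif_occurrences`, default 100) counts occurrences passing the edge
filter within annotated CDSs, not raw genomic k-mers.

## Conditional-dependence classifier

Published analyses identified conditionally dependent genes by visual
heat-map inspection; reproducibility demands an operational rule, so the
classifier makes the pattern explicit. With the four standard contrasts
c1 = mutant+drug/WT+drug, c2 = mutant+drug/mutant, c3 = WT+drug/WT,
c4 = mutant/WT, a gene is `conditional_dependent` iff c1 ≤ −0.5 and
c2 ≤ −0.5 (appreciable reductions) and c3 ≥ −0.25 and c4 ≥ −0.25 (lesser
reduction, no change, or increase), with the discovery contrast's FDR
q1 < 0.25. Gating on q1 alone — not all four FDRs — matches how the
discovery set is defined in practice; all thresholds live in
`analysis_config()` and are inclusive at the boundary. Overlap of the
labelled set with uORF-bearing genes uses the one-sided hypergeometric
upper tail P(X ≥ k) over the universe of translated mRNAs; no published
test is named for such overlaps, and this choice reproduces the printed
two-decimal p-value on the study's set sizes (17 draws, 514 successes,
5482 genes, k = 3 → p ≈ 0.21).

## Polysome-gradient TE reconstruction

For each pooled fraction i with ribosome weight rᵢ (1 for 80S, 2 for
disomes, ...), the corrected amount is

> aᵢ = 2^−(CTᵢ − CT18Sᵢ) × (pooled volume / 300 µL) × (25 µL / RT-input
> volume) × (A260 shareᵢ / 18S shareᵢ) × gradient-recovery factor,

and TE = Σ rᵢaᵢ divided by the input target abundance normalized to ACT1
(both input abundances scaled by 5, since RNA is extracted from one fifth
of the input; the factor cancels in the ratio but is kept explicit). The
2^−CT quantification is interpreted as 2^−ΔCT against 18S measured in the
same fraction, since every mRNA measurement is paired with an 18S
measurement there. The two volume corrections are applied literally as
stated even though they could double-count if the extraction aliquot
equalled the pooled volume; both factors are visible per fraction so users
can audit them. Missing CTs drop the affected fraction with a warning
rather than failing the gradient; missing input CTs make the TE
unavailable. Replicate ΔTE (TE with drug over TE without, paired by
replicate culture) is summarized as mean ± SEM per strain and compared
between strains with a two-sided Welch t-test ("Student's t-test" without
a variance statement is read as Welch); when both ratio sets are constant
the p-value degenerates to 1 for equal means.

## What the generators emulate — and what they do not

`simulate_annotation()` draws CDS lengths of 300–3000 nt (multiples of 3),
5' UTRs of 60–300 nt, and places 1–2 uORFs (6–30 nt) in the 5' UTR of a
chosen fraction of transcripts, AUG and near-cognate starts in equal
shares. `simulate_counts()` draws NB counts with variance μ + αμ² over the
default 16-library design; dispersion 0 is the exact noiseless limit
(counts equal rounded expectations), which is what makes the "planted
effect recovered to 1e−6" fixtures meaningful. uORF footprints are
simulated as separate count columns with expectation true_RRO × host RPF
mean, keeping the RRO ground truth exact rather than carving reads out of
CDS counts. `simulate_track()` lays uniform density over each CDS,
multiplies planted motif spans, and optionally emits the corresponding
3'-end track so the shift step is exercised. `simulate_gradient()`
back-computes CT values through the exact inverse of the reconstruction
chain, so zero-noise recovery is an identity to machine precision, and
errors out when the requested TE exceeds the heaviest fraction's ribosome
weight (the mean load cannot exceed r_max).

None of the generators emulate raw reads, sequencing error, alignment
multi-mapping, nucleotide-level coverage biases, or library-preparation
artifacts. Passing tests therefore demonstrate the correctness of the
quantification and inference chain on data satisfying the count model's
assumptions — not robustness to upstream artifacts in real libraries.

## Simulation conditions and problem sizes

The validation suites use sizes chosen to make each property measurable
while keeping a full run in tens of seconds: full-null FDR control on
8 × 2000 genes at dispersion 0.05 (the regime of two correlated biological
replicates at moderate depth, where every declared gene is a false
discovery and the false-discovery proportion per run is 0 or 1); effect
recovery on 500 genes with planted log2 ΔTE ~ N(0, 0.5²) at ~10⁵ expected
counts per gene and dispersion 0.005, representative of deep, highly
correlated replicates (replicate CV ≈ 7%), where the measured RMSE is
≈ 0.15 log2 units and power at |log2 ΔTE| = 1 exceeds 80%; classifier
validation on 2000 genes with 20 planted profiles at twice the thresholds
and dispersion 0.003 (CV ≈ 5.5%), chosen a priori by a power calculation
so that per-contrast estimation noise (sd ≈ 0.11 log2) leaves ≥ 90%
sensitivity at the −0.25 "lesser" gates. Since median-of-ratios
normalization absorbs the median planted effect of the affected
libraries, recovery is assessed against median-centred truth.

## Known limitations

- Exact numerical replication of DESeq2 on real datasets is a non-goal;
  the cross-check test asserts agreement of interaction estimates, not of
  p-values.
- The NB fit assumes a common dispersion across a gene's eight libraries;
  assay-specific dispersions are not modelled.
- P-site offsets are a single configurable shift; read-length-stratified
  offset calibration is out of scope.
- Genomic-strand handling is out of scope: all inputs are
  transcript-oriented, and the annotation loaders expect 5'→3' transcript
  coordinates.
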