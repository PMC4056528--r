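---
title: "Methods: temporal ChIP-Seq occupancy analysis with chiptempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal ChIP-Seq occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

`chiptempo` analyzes a transcription factor's genome-wide occupancy measured
by ChIP-Seq at several differentiation stages (here three: an early
proliferative stage "d0", a committed stage "d9", a late mature stage
"d28"), and integrates occupancy with the factor's transcriptional output
measured by knockdown expression profiling and with the evolutionary
conservation of its binding sites. Peak calling and read alignment are out
of scope: peaks (with MACS-style −log10 p scores and read counts), signal
tracks, gene models, a PWM and a normalized expression matrix are inputs.

All coordinates are 0-based half-open (BED convention) internally;
refFlat-like input, which is already 0-based in UCSC dumps, is read without
shifting.

## Peak retention and intensity normalization

Peaks with −log10 p < 10 (P ≥ 1e-10) are *flagged* on load and removed by
an explicit `filter_peaks()` step rather than silently dropped, so the raw
record count is auditable. Read counts are normalized to a 10-million-read
library and intensities are `log2(1 + count * 1e7 / library_size)`. The
pseudocount of 1 is a deliberate choice: a time point with zero reads maps
to intensity exactly 0, which keeps presence/absence heatmaps and cluster
summaries finite without a special missing-value path.

## Six-category annotation

Windows per gene, strand-aware (TSS of a '−' gene is its `tx_end`):
promoter = TSS −1000 to +150 bp; upstream = TSS −20 kb to −1 kb;
TTS region = 150 bp inside the gene end through 1 kb downstream of the TTS;
exons and introns from the exon structure; everything else intergenic.
The TTS window's orientation is genuinely ambiguous in the field's usual
shorthand ("−150 bp to −1 kb of the TTS"); we resolve it to mirror the
promoter's asymmetry (mostly downstream of the gene end, reaching 150 bp
into the gene), and treat it as a configurable parameter
(`annotation_params()`).

A peak is classified at a single point — its summit if recorded, else the
interval midpoint — because one peak must land in exactly one category even
when it spans boundaries. A `largest_overlap` mode is available. When
windows of several genes cover the point, precedence is
promoter > TTS > exon > intron > upstream (genic fine structure outranks
flanking windows; promoter first because it is biologically the most
interpretable and empirically the most enriched class), then nearest TSS,
then lexicographic gene id — fully deterministic.

## Temporal clustering

Peaks from the T = 3 time-point sets are merged single-linkage on ≥ 1 bp
overlap (configurable minimum overlap). Each merged consensus region gets a
presence vector over time points; the 7 non-empty patterns are the
clusters, numbered 1 = (d0,d9,d28), 2 = (d0,d9), 3 = (d0,d28),
4 = (d9,d28), 5 = (d28), 6 = (d9), 7 = (d0). Numbers 1, 4, 5, 6, 7 follow
the study design this package models; 2 and 3 are an arbitrary but fixed
completion of the bijection. Book-ended (touching) peaks do **not** merge:
overlap must be at least one base.

## Background sampling and enrichment

Random background intervals (default 100 bp, count equal to the observed
peak count) are drawn with chromosome probability proportional to allowed
space and starts uniform within it; an exclusion set is honored by
sampling from the complement rather than by rejection, so the sampler
cannot stall. Enrichment is the ratio of observed to background category
fractions; zero background with non-zero observation reports `Inf` rather
than failing. Group comparisons of category counts use per-category 2×2
Fisher tests (in-category vs rest, group vs group) with BH correction
across the six categories.

## PWM scanning

Scores are log-odds in bits with pseudocount-regularized probabilities
(`p' = (p + 0.01)/(1 + 0.04)`; the pseudocount is applied once, at PWM
construction). The exact p-value function discretizes each matrix cell to
an ε = 1e-3-bit grid and convolves the four-letter score distribution
across positions under the background model; queries are floored onto the
grid so the returned p is conservative within one grid cell. Scanning
covers both strands (the '−' strand via the reverse-complement PWM);
windows containing ambiguous bases are skipped. The packaged default PWM is
a width-10 matrix whose consensus carries the TGTGGT core; the width
matters: a 6-mer cannot reach p < 1e-4 under a uniform background
(0.25⁶ ≈ 2.4e-4), so the planted-motif recovery criterion needs the wider
matrix.

Summit-distance profiles rank peaks into score tertiles by −log10 p and
histogram the signed distance from the best in-peak hit's center to the
summit (10-bp bins, ±500 bp), normalized per tier.

## Metagene windows

Per gene: ten 1-kb upstream windows, ten gene-body deciles, ten 1-kb
downstream windows, indexed 5′→3′. Deciles split the transcript length by
the integer rule "first `L mod 10` windows one base longer", applied in
transcript orientation. The window ratio is
`(mean IP + 0.5) / (mean Input + 0.5)`; the 0.5 floor guards zero-coverage
windows (uncovered bases contribute signal 0, matching read-density
semantics). Per-window group tests are two-sided Wilcoxon rank-sum with BH
across the 30 windows. Binding-level bins are quintiles of the mean window
ratio (bin I = top); the quintile rule is our choice — the field's "cluster
I–V" constructions are rarely specified precisely.

## Differential expression

The moderated t-test shrinks per-gene pooled variances (d = nA + nB − 2 df)
toward a prior: posterior variance s̃² = (d₀s₀² + ds²)/(d₀ + d), with
(d₀, s₀²) estimated by moment matching on log s² (E and Var of log s² under
the scaled inverse-chi-square model; trigamma inversion by uniroot). The t
statistic has d₀ + d df. This reproduces the standard empirical-Bayes
moderated t closely (the test suite checks correlation > 0.999 with limma's
t on heterogeneous-variance simulations) while keeping the implementation
self-contained; limma estimates the hyperparameters by a different
(F-distribution) method, so hyperparameters agree only approximately.

Classification: up if log2FC ≥ log2(1.5) and BH q < 0.05; down
symmetrically. The threshold has two readings in common usage —
"1.5-fold" (log2 ≈ 0.585) and "1.5 log2 units" — we default to the
fold-change reading and expose `mode = "log2"` for the strict one.

## Conservation

Per peak, the best motif hit's conservation score is the base-weighted mean
of the conservation track over the hit; per gene, scores average over its
associated peaks' sites (peaks without a hit are excluded and counted).
Down- and up-regulated gene groups are compared against greedy
length-matched non-responsive controls (targets processed in decreasing
length, nearest pool length, ties randomized under the seed; gene length =
transcript span) using the two-sample KS test.

# The synthetic study

`simulate_study()` emits the world the analyses are designed to detect:

- 2 chromosomes × 5 Mb of iid sequence (GC 0.5), 300 non-overlapping genes
  with 2–8 exons, log-uniform lengths 2–20 kb — an end-to-end run fits in a
  few minutes on one CPU.
- 70 peaks per (pattern × category) cell = 2,940 peaks; placements are
  validated against the real classifier at generation time and spaced so no
  two truth regions overlap, making truth labels exact by construction.
- Read counts are lognormal per cluster with means chosen so the
  constitutive cluster 1 is strongest and the d0-only cluster 7 weakest
  (log2 means 9 and 5), matching the biology the cluster summary is meant
  to display.
- The planted "down" genes (25 of 300; genes the factor activates) carry
  every coupled effect at once: 6× placement weight (more peaks per gene),
  4× day-9 read counts at promoter/upstream peaks (binding gain), a day-9
  TSS-proximal IP bump (amplitude 3, sd 1 kb) plus +0.5 gene-body signal,
  and +1.0 conservation at their motif sites. "Up" genes (60) differ only
  in expression. Expression effects are ±1 log2 unit (2-fold) with
  N(0, 0.2²) noise, 3 replicates per condition — chosen so recovery is
  high but not trivially perfect.
- Motifs: the PWM consensus is written at each summit with Gaussian jitter
  whose sd depends on the peak-score tertile (20/50/100 bp), truncated to
  stay inside every jittered peak instance.

What a green test does **not** establish: the generator has no read-level
noise, no duplicated/GC-biased coverage, no overlapping genes, no unmappable
regions, and its category placement is uniform over cells rather than
matching any real genome's composition. Recovery rates here bound what the
pipeline can do when its assumptions hold exactly, not performance on real
data.

# Numerical choices and edge cases

- Exact Mann-Whitney p-values (both groups ≤ 8) enumerate assignments of
  the pooled *observed values*, which is correct under ties; otherwise a
  tie-corrected, continuity-corrected normal approximation is used.
  Two-sided p = min(1, 2·min(P≤, P≥)). The approximation's relative error
  is small where it matters (< 4% for exact p ≥ 0.05 at n = 8) but
  unbounded deep in the tails — an intrinsic property of normal tail
  approximation; tests assert the bound on the p ≥ 0.05 region.
- Fisher's two-sided p sums hypergeometric probabilities ≤ the observed
  table's (with the customary 1 + 1e-7 tolerance); the odds ratio is the
  conditional MLE. Zero-margin tables return p = 1 with a note.
- The two-sample KS p uses the asymptotic Kolmogorov distribution at
  effective n = n_a·n_b/(n_a + n_b). It is conservative for small samples
  (measured empirical type-I ≈ 0.027 at n = 100 per group) and calibrated
  by n ≈ 250 (≈ 0.05); the null-calibration acceptance check therefore runs
  at n = 250.
- BH q-values: step-up `q_i = min_{j ≥ rank(i)} m·p_(j)/j`, clipped at 1;
  NA p-values propagate and are excluded from m.
- Degenerate inputs: empty peak files give empty (not failing)
  distributions; clusters with one region report SEM 0 with a flag; windows
  fully clipped by a chromosome edge get ratio 0 with a flag; genes shorter
  than 10 bases are excluded from the metagene schema with a message.

# Known limitations

- T is fixed at 3 for cluster numbering (the merge itself is generic).
- The scanner holds one chromosome's integer-coded sequence in memory;
  fine for the scales here, not for mammalian chromosome 1.
- `best_site_per_peak()` keys on peak names; duplicate names across merged
  peak sets would collapse, so the pipeline namespaces them per time point.
- The conditional-MLE odds ratio is a point estimate; no CI is reported.
- Deposited-data checks against public accessions (peak counts, promoter
  fractions on a real annotation) need downloads and are out of the offline
  test surface.
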