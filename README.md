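# chiptempo

Integrative analysis of transcription-factor ChIP-Seq occupancy across
differentiation time points, for regulatory genomicists studying how a
lineage-determining factor redistributes over the genome as cells
differentiate, and how that redistribution relates to the factor's
transcriptional output (knockdown expression changes) and to the
evolutionary conservation of its binding sites.

## What it computes

Given per-time-point peak calls (BED, MACS-style −log10 *p* scores and read
counts), gene models, IP/Input signal tracks, a binding-motif PWM, a
base-wise conservation track, and a knockdown-vs-control expression matrix,
the pipeline produces:

- **Six-category genomic annotation** of every peak: promoter (TSS −1 kb to
  +150 bp), upstream (−1 kb to −20 kb), exon, intron, TTS region (150 bp
  gene-side to 1 kb past the TTS), intergenic — strand-aware, one label per
  peak with precedence promoter > TTS > exon > intron > upstream.
- **Temporal presence/absence clustering**: peaks overlapping across the T=3
  time points are merged into consensus regions; the 2³−1 = 7 presence
  patterns define the clusters, with per-time intensity
  log2(1 + reads·10⁷/library), i.e. the base-2 log of read counts per 10
  million reads.
- **Category enrichment** against sampled random intervals (equal-count,
  100-bp background), and Fisher-exact comparison of category distributions
  between gene groups with Benjamini-Hochberg correction.
- **PWM scanning with exact p-values**: log-odds scores in bits,
  p(s) = Pr_bg[score ≥ s] by positionwise convolution on a discretized
  grid (FIMO-style threshold p < 10⁻⁴), best site per peak, and
  summit-distance probability profiles stratified by peak-score tertile.
- **Metagene signal profiles**: per gene, ten 1-kb upstream windows, ten
  gene-body deciles, ten 1-kb downstream windows; mean IP/Input ratio per
  window; per-window two-sided Wilcoxon rank-sum tests between gene groups.
- **Knockdown integration**: empirical-Bayes moderated *t* differential
  expression (posterior variance (d₀s₀² + ds²)/(d₀+d)), classification into
  up / down / nonresponsive at |log2 FC| ≥ log2 1.5 and FDR < 0.05, then
  peaks-per-gene, per-category binding fold change, and motif-site phyloP
  conservation with greedy length-matched non-responsive controls and
  Kolmogorov-Smirnov comparison.
- A **synthetic-study generator** (`simulate_study()`) that emits a full toy
  study — genome FASTA, gene models, three peak sets covering all 7×6
  pattern×category cells, signal tracks, planted motifs, conservation with a
  planted offset, expression with planted up/down genes — plus machine-
  readable ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(chiptempo)
library(data.table)

cfg <- sim_config(seed = 7, n_chromosomes = 2, chrom_length = 1e6,
                  n_genes = 60, peaks_per_cell = 10, n_up = 12, n_down = 6)
sim <- simulate_study(cfg, file.path(tempdir(), "demo"))

regions <- assign_temporal_clusters(build_consensus(sim$peak_sets))
cluster_summary(regions)[cluster_id %in% c(1, 6)]
#>    cluster_id   time     n mean_intensity       sem single_region
#> 1:          1     d0    60       9.269029 0.0938734         FALSE
#> 2:          1     d9    60       8.950583 0.0878127         FALSE
#> 3:          1    d28    60       8.859415 0.1092346         FALSE
#> 4:          6     d0    60       0.000000 0.0000000         FALSE
#> 5:          6     d9    60       6.660869 0.1142997         FALSE
#> 6:          6    d28    60       0.000000 0.0000000         FALSE
```

Cluster 1 (present at all three time points, pattern "111") carries the
strongest binding intensity at every stage; cluster 6 (day-9-only, pattern
"010") is present — intensity > 0 — only at day 9.

```r
bg <- sample_random_intervals(sim$sizes, nrow(sim$peak_sets[[2]]), seed = 7)
category_enrichment(sim$peak_sets[[2]], bg, sim$index)
#>      category count  fraction bg_fraction bg_count     ratio
#> 1:   promoter    40 0.1666667  0.02500000        6 6.6666667
#> 2:   upstream    40 0.1666667  0.51666667      124 0.3225806
#> 3:       exon    40 0.1666667  0.10833333       26 1.5384615
#> 4:     intron    40 0.1666667  0.06666667       16 2.5000000
#> 5: tts_region    40 0.1666667  0.02500000        6 6.6666667
#> 6: intergenic    40 0.1666667  0.25833333       62 0.6451613
```

Peaks are planted uniformly over the six categories (1/6 each), so small
genomic compartments (promoter, TTS) are strongly over-represented relative
to random background (ratio ≫ 1) and large ones (upstream, intergenic)
under-represented (ratio < 1) — the qualitative signature of genic
enrichment.

```r
de <- classify_genes(moderated_t_de(sim$expression, "shTF", "Scr"))
attr(de, "counts")
#>            up          down nonresponsive
#>            12             6            42
```

The moderated-*t* classifier recovers exactly the 12 planted up- and 6
planted down-regulated genes at the default thresholds.

The full pipeline over a study directory:

```r
res <- run_pipeline(pipeline_config(input_dir, output_dir, seed = 1))
```

writes one TSV per analysis (category distribution/enrichment, consensus
regions and cluster summaries, summit-distance profiles, metagene window
profiles and tests, DE table, peaks-per-gene, category comparisons, binding
fold change by location, conservation with KS results) plus a run manifest
with input checksums, thresholds, the seed and stage timings. A
command-line wrapper is installed at `inst/scripts/chiptempo-cli.R`
(subcommands `simulate`, `run`, `report`).

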