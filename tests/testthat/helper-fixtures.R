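# Shared fixtures built in code: tiny gene sets, tracks and a cached small
# simulated study reused across test files.

library(data.table)

# two genes on chr1 ('+' and '-'), one single-exon gene on chr2
toy_genes <- function() {
  gene_models(data.table(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(50000L, 110000L, 5000L),
    tx_end = c(60000L, 120000L, 6000L),
    exon_starts = list(c(50000L, 55000L), c(110000L, 116000L), 5000L),
    exon_ends = list(c(52000L, 60000L), c(114000L, 120000L), 6000L)))
}

toy_sizes <- function() c(chr1 = 200000L, chr2 = 50000L)

toy_index <- function() gene_region_index(toy_genes(), sizes = toy_sizes())

toy_track <- function(values = c(2, 4), bounds = c(0L, 10L, 20L),
                      chrom = "chr1") {
  signal_track(data.table(chrom = chrom, start = bounds[-length(bounds)],
                          end = bounds[-1], value = values))
}

# small study, simulated once per test run and cached
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7L, n_chromosomes = 2L, chrom_length = 1e6L,
                        n_genes = 60L, peaks_per_cell = 10L,
                        n_up = 12L, n_down = 6L)
      cache <<- simulate_study(cfg, file.path(tempdir(), "chiptempo_small_sim"))
    }
    cache
  }
})

# brute-force per-point six-category classifier, written independently of
# the package index machinery (plain loops over per-gene windows with the
# documented precedence and nearest-TSS tie-break)
oracle_classify <- function(chrom, pos, genes, sizes) {
  prec <- c(promoter = 1, tts_region = 2, exon = 3, intron = 4, upstream = 5)
  best <- list(cat = "intergenic", gene = NA_character_, key = c(Inf, Inf))
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    plus <- genes$strand[i] == "+"
    tss <- if (plus) genes$tx_start[i] else genes$tx_end[i]
    tts <- if (plus) genes$tx_end[i] else genes$tx_start[i]
    win <- list()
    if (plus) {
      win$promoter <- c(tss - 1000, tss + 150)
      win$upstream <- c(tss - 20000, tss - 1000)
      win$tts_region <- c(tts - 150, tts + 1000)
    } else {
      win$promoter <- c(tss - 150, tss + 1000)
      win$upstream <- c(tss + 1000, tss + 20000)
      win$tts_region <- c(tts - 1000, tts + 150)
    }
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    cats <- character()
    for (nm in names(win)) {
      w <- c(max(win[[nm]][1], 0), min(win[[nm]][2], sizes[[chrom]]))
      if (pos >= w[1] && pos < w[2]) cats <- c(cats, nm)
    }
    if (any(pos >= es & pos < ee)) cats <- c(cats, "exon")
    if (length(es) > 1 &&
        any(pos >= ee[-length(ee)] & pos < es[-1])) cats <- c(cats, "intron")
    for (cc in cats) {
      key <- c(prec[[cc]], abs(pos - tss))
      if (key[1] < best$key[1] ||
          (key[1] == best$key[1] && key[2] < best$key[2]) ||
          (key[1] == best$key[1] && key[2] == best$key[2] &&
           !is.na(best$gene) && genes$gene_id[i] < best$gene)) {
        best <- list(cat = cc, gene = genes$gene_id[i], key = key)
      }
    }
  }
  list(category = best$cat, gene_id = best$gene)
}

# exact null distribution of the Mann-Whitney U statistic (no ties), via
# the classic counting recurrence f(u; m, n) = f(u - n; m - 1, n) +
# f(u; m, n - 1); returns P(U = u) for u = 0..na*nb
mwu_null_distribution <- function(na, nb) {
  umax <- na * nb
  # f[m + 1, u + 1] = number of arrangements with U = u for m a-elements
  # against nb b-elements; build n = nb layer by layer
  f <- matrix(0, na + 1, umax + 1)
  f[, 1] <- 1                        # n = 0: U = 0 for every m
  for (n in seq_len(nb)) {
    g <- matrix(0, na + 1, umax + 1)
    g[1, 1] <- 1
    for (m in seq_len(na)) for (u in 0:(m * n)) {
      a_term <- if (u - n >= 0) g[m, u - n + 1] else 0   # f(u - n; m - 1, n)
      b_term <- f[m + 1, u + 1]                          # f(u; m, n - 1)
      g[m + 1, u + 1] <- a_term + b_term
    }
    f <- g
  }
  f[na + 1, ] / choose(na + nb, na)
}
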