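test_that("gene_region_windows matches the legend windows, strand-aware", {
  g <- gene_models(data.table(gene_id = "g", chrom = "chr1", strand = "+",
                              tx_start = 50000L, tx_end = 80000L,
                              exon_starts = list(c(50000L, 60000L)),
                              exon_ends = list(c(55000L, 80000L))))
  w <- gene_region_windows(g[1])
  expect_equal(unlist(w[category == "promoter", .(start, end)]),
               c(start = 49000L, end = 50150L))
  expect_equal(unlist(w[category == "upstream", .(start, end)]),
               c(start = 30000L, end = 49000L))
  expect_equal(unlist(w[category == "tts_region", .(start, end)]),
               c(start = 79850L, end = 81000L))
  expect_equal(w[category == "intron", .(start, end)],
               data.table(start = 55000L, end = 60000L))

  gm <- gene_models(data.table(gene_id = "g", chrom = "chr1", strand = "-",
                               tx_start = 10000L, tx_end = 20000L,
                               exon_starts = list(10000L),
                               exon_ends = list(20000L)))
  w <- gene_region_windows(gm[1])
  expect_equal(unlist(w[category == "promoter", .(start, end)]),
               c(start = 19850L, end = 21000L))
  expect_equal(unlist(w[category == "upstream", .(start, end)]),
               c(start = 21000L, end = 40000L))
  expect_equal(unlist(w[category == "tts_region", .(start, end)]),
               c(start = 9000L, end = 10150L))
  expect_equal(nrow(w[category == "intron"]), 0L)   # single exon

  # left clipping at chromosome start
  g0 <- gene_models(data.table(gene_id = "g", chrom = "chr1", strand = "+",
                               tx_start = 500L, tx_end = 2000L,
                               exon_starts = list(500L), exon_ends = list(2000L)))
  w <- gene_region_windows(g0[1])
  expect_equal(w[category == "promoter", start], 0L)
  expect_equal(nrow(w[category == "upstream"]), 0L)  # fully clipped, dropped
})

test_that("classification precedence and intergenic fallback work", {
  # gB promoter [119850, 121000) on chr1; gA exon2 [55000? no] -- build a
  # point inside gA's upstream that also lies in gB's ('-') promoter
  idx <- toy_index()
  # gA exon 1 [50000,52000); gB upstream is [121000,140000)
  pk <- peak_set(data.table(chrom = "chr1",
                            start = c(50010L, 1000L, 120000L),
                            end = c(50020L, 1010L, 120010L),
                            name = c("inExonAndPromoterA", "far", "gBprom")),
                 threshold = 0)
  ann <- classify_peaks(pk, idx)
  # 50010 is in gA's exon AND gA's promoter [49000,50150): promoter wins
  expect_equal(ann$category, c("promoter", "intergenic", "promoter"))
  expect_equal(ann$gene_id, c("gA", NA, "gB"))
  # chromosome absent from index -> intergenic with warning
  pk2 <- peak_set(data.table(chrom = "chrX", start = 1L, end = 10L), threshold = 0)
  expect_warning(ann2 <- classify_peaks(pk2, idx), "absent")
  expect_equal(ann2$category, "intergenic")
})

test_that("classifier agrees with the exhaustive containment oracle", {
  set.seed(31)
  genes <- toy_genes(); sizes <- toy_sizes(); idx <- toy_index()
  n <- 300
  chrom <- sample(names(sizes), n, replace = TRUE, prob = c(4, 1) / 5)
  pos <- vapply(chrom, function(ch) sample(sizes[[ch]] - 20L, 1L), 1L)
  pk <- peak_set(data.table(chrom = chrom, start = pos, end = pos + 10L,
                            summit_offset = 0L,
                            name = paste0("p", seq_len(n))), threshold = 0)
  ann <- classify_peaks(pk, idx)
  for (i in seq_len(n)) {
    o <- oracle_classify(chrom[i], pos[i], genes, sizes)
    expect_equal(ann$category[i], o$category,
                 info = sprintf("%s:%d", chrom[i], pos[i]))
    if (o$category != "intergenic")
      expect_equal(ann$gene_id[i], o$gene_id,
                   info = sprintf("%s:%d", chrom[i], pos[i]))
  }
})

test_that("every peak gets exactly one label and counts are conserved", {
  sim <- small_sim()
  pk <- sim$peak_sets[[2]]
  ann <- classify_peaks(pk, sim$index)
  expect_equal(nrow(ann), nrow(pk))
  expect_true(all(ann$category %in% category_levels()))
  dist <- category_distribution(ann)
  expect_equal(sum(dist$count), nrow(pk))
  expect_equal(sum(dist$fraction), 1, tolerance = 1e-12)
  expect_equal(nrow(category_distribution(ann[0])), 0L)
})

test_that("strand reflection leaves the category count vector unchanged", {
  genes <- toy_genes(); sizes <- toy_sizes()
  L <- sizes[["chr1"]]
  # reflect chr1 about its midpoint and flip strands
  refl <- copy(genes)[chrom == "chr1"]
  refl[, `:=`(strand = ifelse(strand == "+", "-", "+"))]
  refl_dt <- data.table(
    gene_id = refl$gene_id, chrom = refl$chrom,
    strand = refl$strand,
    tx_start = L - refl$tx_end, tx_end = L - refl$tx_start,
    exon_starts = lapply(seq_len(nrow(refl)), function(i)
      sort(L - refl$exon_ends[[i]])),
    exon_ends = lapply(seq_len(nrow(refl)), function(i)
      sort(L - refl$exon_starts[[i]])))
  g2 <- gene_models(refl_dt)
  idx1 <- gene_region_index(genes[chrom == "chr1"],
                            sizes = sizes["chr1"])
  idx2 <- gene_region_index(g2, sizes = sizes["chr1"])
  set.seed(32)
  pos <- sample(L - 1L, 500)
  pk1 <- peak_set(data.table(chrom = "chr1", start = pos, end = pos + 1L,
                             summit_offset = 0L), threshold = 0)
  pk2 <- peak_set(data.table(chrom = "chr1", start = L - pos - 1L,
                             end = L - pos, summit_offset = 0L), threshold = 0)
  d1 <- category_distribution(classify_peaks(pk1, idx1))
  d2 <- category_distribution(classify_peaks(pk2, idx2))
  expect_equal(d1$count, d2$count)
})

test_that("peak-gene association conserves totals and obeys the distance rule", {
  idx <- toy_index()
  pk <- peak_set(data.table(chrom = "chr1",
                            start = c(53000L, 1000L, 145000L),
                            end = c(53010L, 1010L, 145010L),
                            summit_offset = 0L,
                            name = c("intronA", "farLeft", "nearUpstreamB")),
                 threshold = 0)
  a <- associate_peaks_to_genes(pk, idx)
  expect_equal(a[name == "intronA", gene_id], "gA")
  expect_true(is.na(a[name == "farLeft", gene_id]))
  # conservation: assigned + unassigned = total
  expect_equal(sum(!is.na(a$gene_id)) + sum(is.na(a$gene_id)), nrow(pk))
  # intergenic rescue within max_distance
  pk2 <- peak_set(data.table(chrom = "chr1", start = 145000L, end = 145010L,
                             summit_offset = 0L, name = "ig"), threshold = 0)
  # 145000 is > 20 kb right of gA TTS and inside nothing; 25 kb right of gB TSS(120000)
  a2 <- associate_peaks_to_genes(pk2, idx, max_distance = 30000L)
  expect_equal(a2$gene_id, "gB")
  a3 <- associate_peaks_to_genes(pk2, idx, max_distance = 1000L)
  expect_true(is.na(a3$gene_id))
})
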