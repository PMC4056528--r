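test_that("read_peaks_bed maps fields, flags sub-threshold peaks, errors on bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t12.5",
               "chr1\t300\t500\tp2\t5\t60\t140.5"), f)
  pk <- read_peaks_bed(f)
  expect_equal(pk$chrom, c("chr1", "chr1"))
  expect_equal(pk$start, c(100L, 300L))
  expect_equal(pk$end, c(200L, 500L))
  expect_equal(pk$neglog10_p, c(12.5, 5))
  expect_equal(pk$summit_offset, c(NA_integer_, 60L))
  expect_equal(pk$read_count, c(NA_real_, 140.5))
  expect_equal(pk$retained, c(TRUE, FALSE))     # flagged, not dropped
  expect_equal(nrow(filter_peaks(pk)), 1L)

  writeLines(character(), f)
  expect_equal(nrow(read_peaks_bed(f)), 0L)

  writeLines("chr1\t200\t100\tp1\t5", f)
  expect_error(read_peaks_bed(f), "start >= end at line 1")
  writeLines(c("chr1\t1\t2\tok\t3", "chr1\t10"), f)
  expect_error(read_peaks_bed(f), "line 2")
})

test_that("peak round-trip preserves all fields", {
  pk <- peak_set(data.table(chrom = "chr2", start = 10L, end = 400L,
                            name = "x", neglog10_p = 33.25,
                            summit_offset = 123L, read_count = 17.5))
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, f)
  pk2 <- read_peaks_bed(f)
  for (col in c("chrom", "start", "end", "name", "neglog10_p",
                "summit_offset", "read_count"))
    expect_equal(pk2[[col]], pk[[col]], info = col)
})

test_that("gene model readers handle bed12 and refflat dialects", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1160\tgX\t0\t+\t1000\t1160\t0\t2\t50,60,\t0,100,", f)
  g <- read_gene_models(f, "bed12")
  expect_equal(g$exon_starts[[1]], c(1000L, 1100L))
  expect_equal(g$exon_ends[[1]], c(1050L, 1160L))

  writeLines("chr1\t1000\t1160\tgX\t0\t+\t1000\t1160\t0\t2\t50,\t0,100,", f)
  expect_error(read_gene_models(f, "bed12"), "block count mismatch")
  writeLines("chr1\t1000\t1160\tgX\t0\t+\t1000\t1160\t0\t2\t50,61,\t0,100,", f)
  expect_error(read_gene_models(f, "bed12"), "inconsistent")

  writeLines("GeneY\tNM_1\tchr2\t-\t500\t900\t500\t900\t2\t500,700,\t600,900,", f)
  g <- read_gene_models(f, "refflat")
  expect_equal(g$strand, "-")
  expect_equal(g$tx_start, 500L)
  expect_equal(g$exon_ends[[1]], c(600L, 900L))

  # bed12 round trip
  f2 <- withr::local_tempfile()
  write_gene_models_bed12(toy_genes(), f2)
  g2 <- read_gene_models(f2, "bed12")
  expect_equal(g2$gene_id, toy_genes()$gene_id)
  expect_equal(g2$exon_starts, toy_genes()$exon_starts)
})

test_that("bedGraph reader sorts, rejects overlap, converts fixed-step WIG", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t10\t20\t4.0", "chr1\t0\t10\t2.0"), f)
  tr <- read_signal_bedgraph(f)
  expect_equal(tr$start, c(0L, 10L))
  expect_equal(track_interval_means(tr, data.table(chrom = "chr1",
                                                   start = 0L, end = 20L)), 3)
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"), f)
  expect_error(read_signal_bedgraph(f), "overlap")
  writeLines(c("fixedStep chrom=chr1 start=11 step=5 span=5", "1.5", "2.5"), f)
  tr <- read_signal_bedgraph(f)
  expect_equal(tr$start, c(10L, 15L))
  expect_equal(tr$value, c(1.5, 2.5))
  writeLines(c("variableStep chrom=chr1", "10 1"), f)
  expect_error(read_signal_bedgraph(f), "variable-step")
})

test_that("track interval means equal brute-force per-base averages", {
  set.seed(21)
  segs <- data.table(chrom = "chr1",
                     start = c(0L, 30L, 100L, 400L),
                     end = c(20L, 60L, 300L, 500L),
                     value = c(2, -1, 0.5, 4))
  tr <- signal_track(segs)
  base <- numeric(600)                   # uncovered bases are 0
  for (i in seq_len(nrow(segs)))
    base[(segs$start[i] + 1):segs$end[i]] <- segs$value[i]
  for (rep in 1:30) {
    s <- sample(0:590, 1); e <- sample((s + 1):600, 1)
    got <- track_interval_means(tr, data.table(chrom = "chr1", start = s, end = e))
    expect_equal(got, mean(base[(s + 1):e]), tolerance = 1e-12)
  }
})

test_that("MEME motif reader normalizes rows and validates alphabet", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "",
               "MOTIF test",
               "letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0",
               " 0.01 0.01 0.01 0.97",
               " 0.01 0.01 0.97 0.01",
               " 0.01 0.01 0.01 0.97",
               " 0.01 0.01 0.97 0.01",
               " 0.01 0.01 0.97 0.01",
               " 0.009 0.009 0.009 0.873"), f)   # last row sums to 0.9
  pwm <- read_motif_meme(f)
  expect_equal(pwm$width, 6L)
  expect_equal(pwm$consensus, "TGTGGT")
  expect_equal(unname(rowSums(pwm$probs)), rep(1, 6), tolerance = 1e-9)
  expect_equal(pwm$background, c(0.3, 0.2, 0.2, 0.3))

  writeLines(c("MEME version 4", "ALPHABET= ACGU", "MOTIF x"), f)
  expect_error(read_motif_meme(f), "alphabet")

  # round trip through the writer
  f2 <- withr::local_tempfile(fileext = ".meme")
  write_motif_meme(default_pwm(), f2)
  back <- read_motif_meme(f2)
  expect_equal(back$probs, default_pwm()$probs, tolerance = 1e-4)
  expect_equal(back$consensus, default_pwm()$consensus)
})

test_that("expression table reader resolves conditions and catches errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4", "g2\t5\t6\t7\t8", "g3\t0\t0\t1\t1"), f)
  ex <- read_expression_table(f, list(Scr = c("s1", "s2"),
                                      sh = c("s3", "s4")))
  expect_equal(dim(ex$values), c(3L, 4L))
  expect_equal(levels(ex$conditions), c("Scr", "sh"))
  expect_error(read_expression_table(f, list(Scr = c("s1", "s9"), sh = "s3")),
               "absent from header")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4", "g1\t1\tx\t3\t4"), f)
  expect_error(read_expression_table(f, list(A = c("s1", "s2"),
                                             B = c("s3", "s4"))),
               "non-numeric")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4", "g1\t1\t2\t3\t4"), f)
  expect_error(read_expression_table(f, list(A = c("s1", "s2"),
                                             B = c("s3", "s4"))),
               "duplicate.*g1")
})

test_that("uniform PWM row is preserved and invalid constructors error", {
  probs <- rbind(c(.25, .25, .25, .25), c(.25, .25, .25, .25),
                 c(.1, .2, .3, .4), c(.97, .01, .01, .01))
  pwm <- pwm_record(probs, pseudocount = 0)
  expect_equal(unname(pwm$probs[1, ]), rep(.25, 4))
  expect_error(pwm_record(probs[, 1:3]), "4 columns")
  expect_error(pwm_record(rbind(probs, c(.5, .5, .5, .5))), "sum to 1")
  expect_error(signal_track(data.table(chrom = "c", start = 5L, end = 5L,
                                       value = 1)), "start >= end")
  expect_error(peak_set(data.table(chrom = "c", start = 10L, end = 5L)),
               "start >= end")
})
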