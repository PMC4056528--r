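mk_expr <- function(mat, reps = 3) {
  colnames(mat) <- c(paste0("Scr_", 1:reps), paste0("sh_", 1:reps))
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  expression_matrix(mat, rep(c("Scr", "sh"), each = reps))
}

test_that("moderated t reduces to ordinary t for a single gene", {
  set.seed(81)
  x <- matrix(rnorm(6), 1)
  ex <- mk_expr(x)
  de <- moderated_t_de(ex, "sh", "Scr")
  tt <- t.test(x[1, 4:6], x[1, 1:3], var.equal = TRUE)
  expect_equal(de$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(de$p, tt$p.value, tolerance = 1e-9)
  expect_equal(de$log2fc, mean(x[1, 4:6]) - mean(x[1, 1:3]))
})

test_that("d0 -> Inf limit: constant gene variances give the pooled-sd t", {
  set.seed(82)
  n <- 400
  # all genes share the same true variance; estimated d0 should be large and
  # t should approach delta / (s0 * sqrt(2/3))
  x <- matrix(rnorm(n * 6, 0, 0.5), n)
  ex <- mk_expr(x)
  de <- moderated_t_de(ex, "sh", "Scr")
  d0 <- attr(de, "d0")
  s0 <- sqrt(attr(de, "s0_2"))
  expect_gt(d0, 4)                      # strong shrinkage
  approx_t <- de$log2fc / (s0 * sqrt(2 / 3))
  # with large d0, moderated t is dominated by the prior variance
  expect_gt(cor(de$t, approx_t), 0.99)
})

test_that("moderated t agrees with the limma oracle on simulated data", {
  set.seed(83)
  n <- 300
  base <- rnorm(n, 8, 1)
  sd_g <- sqrt(1 / rgamma(n, 4, 1))      # heterogeneous variances
  eff <- c(rep(1, 30), rep(-1, 20), rep(0, n - 50))
  x <- cbind(matrix(rnorm(n * 3, base, sd_g), n),
             matrix(rnorm(n * 3, base + eff, sd_g), n))
  ex <- mk_expr(x)
  de <- moderated_t_de(ex, "sh", "Scr")
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  # hyperparameters by a different method (limma: F-dist MLE): close, not equal
  expect_equal(attr(de, "s0_2"), fit$s2.prior, tolerance = 0.35)
  expect_gt(cor(de$t, fit$t[, 2]), 0.999)
  expect_gt(cor(-log10(de$p), -log10(fit$p.value[, 2])), 0.99)
})

test_that("moderated t is at least as sensitive as ordinary t at matched FDR", {
  set.seed(84)
  n <- 1000
  reps <- 20
  win <- 0
  for (r in seq_len(reps)) {
    sd_g <- sqrt(1 / rgamma(n, 3, 0.6))
    eff <- c(rep(1, 50), rep(0, n - 50))
    x <- cbind(matrix(rnorm(n * 3, 0, sd_g), n),
               matrix(rnorm(n * 3, eff, sd_g), n))
    ex <- mk_expr(x)
    de <- moderated_t_de(ex, "sh", "Scr")
    # ordinary t per gene
    tp <- vapply(seq_len(n), function(i)
      t.test(x[i, 4:6], x[i, 1:3], var.equal = TRUE)$p.value, 0)
    k <- 50
    hits_mod <- sum(order(de$p)[1:k] <= 50)
    hits_ord <- sum(order(tp)[1:k] <= 50)
    win <- win + (hits_mod >= hits_ord)
  }
  expect_gte(win / reps, 0.8)
})

test_that("gene classification applies both threshold readings", {
  de <- data.table(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(0, 1.0, -2, 1.6),
                   t = 0, p = c(.9, .001, .001, .001),
                   q = c(0.9, 0.01, 0.01, 0.01), df = 4)
  cl <- classify_genes(copy(de))
  expect_equal(cl$gene_class, c("nonresponsive", "up", "down", "up"))
  cl2 <- classify_genes(copy(de), mode = "log2")
  expect_equal(cl2$gene_class, c("nonresponsive", "nonresponsive", "down", "up"))
  cnt <- attr(cl, "counts")
  expect_equal(unname(as.vector(cnt)), c(2L, 1L, 1L))
  expect_equal(sum(cnt), nrow(de))
})

test_that("planted DE genes are recovered at default thresholds", {
  sim <- small_sim()
  de <- classify_genes(moderated_t_de(sim$expression, "shTF", "Scr"))
  m <- merge(de, sim$classes, by = "gene_id")
  recov <- m[true_class != "nonresponsive",
             mean(gene_class == true_class)]
  expect_gte(recov, 0.9)
  fp <- m[true_class == "nonresponsive", mean(gene_class != "nonresponsive")]
  expect_lte(fp, 0.1)
})

test_that("peaks-per-gene test reproduces the exact MWU example", {
  assoc <- data.table(gene_id = paste0("g", 1:6),
                      all = c(3, 5, 4, 1, 1, 2))
  classes <- data.table(gene_id = paste0("g", 1:6),
                        gene_class = rep(c("down", "nonresponsive"), each = 3))
  r <- peaks_per_gene_test(assoc, classes)
  expect_equal(r[gene_class == "down", p], 0.1)
  expect_equal(r[gene_class == "down", mean_peaks], 4)
  expect_true(is.na(r[gene_class == "nonresponsive", p]))
})

test_that("fold change by location recovers planted promoter gain", {
  set.seed(85)
  n <- 40
  pt <- data.table(
    gene_id = rep(c(paste0("d", 1:10), paste0("n", 1:10)), 2),
    category = rep(c("promoter", "intergenic"), each = 2 * 10),
    intensity_d0 = rnorm(2 * n / 2, 6, .2))
  pt[, intensity_d9 := intensity_d0 + rnorm(.N, 0, .2)]
  pt[category == "promoter" & grepl("^d", gene_id),
     intensity_d9 := intensity_d9 + 2]
  classes <- data.table(gene_id = c(paste0("d", 1:10), paste0("n", 1:10)),
                        gene_class = rep(c("down", "nonresponsive"), each = 10))
  r <- foldchange_by_location(pt, classes)
  expect_lt(r[category == "promoter" & gene_class == "down", p], 0.05)
  expect_equal(r[category == "promoter" & gene_class == "down", mean_log2fc],
               2, tolerance = 0.4)
  expect_gt(r[category == "intergenic" & gene_class == "down", p], 0.05)
})

test_that("gene conservation averages sites then peaks, excluding hitless peaks", {
  cons <- signal_track(data.table(chrom = "c", start = c(0L, 4L),
                                  end = c(4L, 100L), value = c(2, 0)))
  assoc <- data.table(name = c("p1", "p2", "p3"),
                      gene_id = c("g1", "g1", "g1"), category = "exon")
  hits <- data.table(name = c("p1", "p2", "p3"),
                     hit_start = c(0L, 10L, NA), hit_end = c(6L, 16L, NA),
                     hit_strand = "+", hit_score = 1, hit_p = 1e-5)
  pk <- peak_set(data.table(chrom = "c", start = c(0L, 8L, 30L),
                            end = c(8L, 20L, 40L),
                            name = c("p1", "p2", "p3")), threshold = 0)
  gc <- gene_conservation(assoc, hits, cons, pk)
  # site p1: (2*4 + 0*2)/6 = 4/3; site p2: 0; gene = mean(4/3, 0) = 2/3
  expect_equal(gc$mean_phylop, 2 / 3, tolerance = 1e-9)
  expect_equal(gc$n_sites, 2L)
})

test_that("length matching is greedy nearest with exhaustion error", {
  lens <- c(t1 = 1000, t2 = 5000, p1 = 900, p2 = 1100, p3 = 5200)
  m <- length_matched_controls(c("t1", "t2"), c("p1", "p2", "p3"), lens,
                               seed = 86)
  expect_equal(m[target == "t2", control], "p3")
  expect_true(m[target == "t1", control] %in% c("p1", "p2"))
  expect_equal(m[target == "t1", delta], 100)
  # pool = targets -> exact self match
  m2 <- length_matched_controls(c("t1", "t2"), c("t1", "t2"), lens)
  expect_equal(m2$delta, c(0, 0))
  expect_error(length_matched_controls(c("t1", "t2"), "p1", lens), "pool")
  # matched control length distributions agree (KS) on simulated pools
  set.seed(87)
  tg <- paste0("T", 1:100); pool <- paste0("P", 1:400)
  ln <- setNames(c(exp(rnorm(100, 8.5, .6)), exp(rnorm(400, 8.5, .6))),
                 c(tg, pool))
  mm <- length_matched_controls(tg, pool, ln)
  ks <- ks_two_sample(ln[mm$target], ln[mm$control])
  expect_gt(ks$p_value, 0.05)
})

test_that("conservation KS comparison validates group sizes", {
  expect_error(conservation_ks(c(1, 2), c(1, 2, 3)), "n >= 3")
  r <- conservation_ks(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("planted conservation offset is recovered end to end", {
  sim <- small_sim()
  combined <- peak_set(rbindlist(lapply(sim$peak_sets, function(p)
    as.data.table(p)[, .(chrom, start, end, name, neglog10_p,
                         summit_offset, read_count)])), threshold = 0)
  pfun <- exact_score_pvalue(sim$pwm)
  hits <- scan_sequences(sim$pwm, sim$genome, pfun = pfun)
  best <- best_site_per_peak(combined, hits)
  assoc <- associate_peaks_to_genes(combined, sim$index)
  gc <- gene_conservation(assoc, best, sim$conservation, combined)
  m <- merge(gc, sim$classes, by = "gene_id")
  diff <- m[true_class == "down", mean(mean_phylop)] -
    m[true_class == "nonresponsive", mean(mean_phylop)]
  expect_equal(diff, 1.0, tolerance = 0.1)
  ks <- conservation_ks(m[true_class == "down"], m[true_class == "nonresponsive"])
  expect_lt(ks$p_value, 0.05)
})
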