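# Knockdown differential expression (empirical-Bayes moderated t) and all
# binding <-> expression group comparisons: peaks per gene, per-category
# binding fold change, motif-site conservation with length-matched
# non-responsive controls, KS comparisons.

# moment-matching estimate of the scaled inverse-chi-square prior
# (d0, s0^2) from per-gene log sample variances with d residual df:
#   E[log s^2] = log s0^2 + digamma(d/2) - log(d/2)
#                - digamma(d0/2) + log(d0/2)
#   Var[log s^2] = trigamma(d/2) + trigamma(d0/2)
.fit_variance_prior <- function(s2, d) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2L) return(list(d0 = Inf, s0_2 = mean(s2)))
  ev <- var(z)
  target <- ev - trigamma(d / 2)
  if (target <= 1e-8) {
    d0 <- Inf
  } else {
    # invert trigamma(d0/2) = target
    f <- function(x) trigamma(x / 2) - target
    lo <- 1e-3
    hi <- 1e3
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 10
    d0 <- if (f(lo) < 0) Inf else uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  if (is.finite(d0)) {
    s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  } else {
    s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated two-sample t-test across genes
#'
#' Empirical-Bayes moderated t: per-gene pooled variances are shrunk toward
#' a prior `s0^2` with prior df `d0`, both estimated by moment matching on
#' the log variances. The posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` and the t statistic has `d0 + d` degrees
#' of freedom. `log2fc` is mean(condA) - mean(condB), so pass the
#' perturbation as `cond_a` and the control as `cond_b`.
#'
#' @param expr An [expression_matrix()] (log2 scale).
#' @param cond_a,cond_b Condition levels to compare (default: first two).
#' @return data.table: gene_id, log2fc, t, p, q (BH), df, plus attributes
#'   `d0`, `s0_2`.
#' @export
moderated_t_de <- function(expr, cond_a = NULL, cond_b = NULL) {
  lev <- levels(expr$conditions)
  if (is.null(cond_a)) cond_a <- lev[1]
  if (is.null(cond_b)) cond_b <- lev[2]
  ia <- which(expr$conditions == cond_a)
  ib <- which(expr$conditions == cond_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L) stop("moderated_t_de: >= 2 replicates per condition required")
  xa <- expr$values[, ia, drop = FALSE]
  xb <- expr$values[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  d <- na + nb - 2L
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / d
  if (all(s2 == 0)) {
    warning("moderated_t_de: zero variance in all genes; ordinary t undefined, p = 1")
    return(data.table(gene_id = expr$gene_ids, log2fc = ma - mb,
                      t = 0, p = 1, q = 1, df = d))
  }
  prior <- .fit_variance_prior(s2, d)
  if (length(expr$gene_ids) == 1L) {        # no shrinkage possible
    prior <- list(d0 = 0, s0_2 = 0)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  if (is.finite(d0)) {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
    df_post <- d0 + d
  } else {
    s2_post <- rep(s0_2, length(s2))
    df_post <- Inf
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tval <- (ma - mb) / se
  p <- 2 * pt(abs(tval), df = df_post, lower.tail = FALSE)
  out <- data.table(gene_id = expr$gene_ids, log2fc = ma - mb, t = tval,
                    p = p, q = bh_fdr(p), df = df_post)
  setattr(out, "d0", d0)
  setattr(out, "s0_2", s0_2)
  out[]
}

#' Classify genes as up / down / nonresponsive
#'
#' Default mode `"fold"` applies the fold-change reading of the threshold:
#' `|log2fc| >= log2(fc_threshold)` and BH q < `fdr_threshold`. Mode
#' `"log2"` applies the strict log2-units reading
#' (`|log2fc| >= fc_threshold`).
#'
#' @param de Output of [moderated_t_de()].
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param mode "fold" (default) or "log2".
#' @return The DE table with a `gene_class` column
#'   (up/down/nonresponsive) added; class counts as attribute `counts`.
#' @export
classify_genes <- function(de, fc_threshold = 1.5, fdr_threshold = 0.05,
                           mode = c("fold", "log2")) {
  mode <- match.arg(mode)
  cut <- if (mode == "fold") log2(fc_threshold) else fc_threshold
  de[, gene_class := fifelse(q < fdr_threshold & log2fc >= cut, "up",
                       fifelse(q < fdr_threshold & log2fc <= -cut, "down",
                               "nonresponsive"))]
  cnt <- table(factor(de$gene_class, levels = c("up", "down", "nonresponsive")))
  setattr(de, "counts", cnt)
  de[]
}

#' Peaks-per-gene comparison between gene classes
#'
#' Mean +/- SEM of the number of associated peaks per gene in each class,
#' with a two-sided Mann-Whitney test of each class against the
#' nonresponsive class. Genes with no associated peaks count 0. `subsets`
#' restricts the peak count to peaks present at a given time (columns of
#' `assoc` named by subset); default "all" uses every associated peak.
#'
#' @param assoc data.table with gene_id and one count column per subset
#'   (see [count_peaks_per_gene()]).
#' @param classes data.table gene_id, gene_class covering the assoc genes.
#' @param subsets Count columns to test (default all columns except gene_id).
#' @return data.table: subset, gene_class, n_genes, mean_peaks, sem, p
#'   (NA for the reference class).
#' @export
peaks_per_gene_test <- function(assoc, classes, subsets = NULL) {
  m <- merge(classes[, .(gene_id, gene_class)], assoc, by = "gene_id",
             all.x = TRUE)
  if (is.null(subsets)) subsets <- setdiff(names(assoc), "gene_id")
  for (s in subsets) m[is.na(get(s)), (s) := 0]
  res <- list()
  for (s in subsets) {
    ref <- m[gene_class == "nonresponsive"][[s]]
    for (cl in c("up", "down", "nonresponsive")) {
      x <- m[gene_class == cl][[s]]
      if (!length(x)) next
      p <- if (cl == "nonresponsive") NA_real_ else
        mann_whitney_u(x, ref)$p_value
      res[[length(res) + 1L]] <-
        data.table(subset = s, gene_class = cl, n_genes = length(x),
                   mean_peaks = mean(x),
                   sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
                   p = p)
    }
  }
  rbindlist(res)
}

#' Count associated peaks per gene
#'
#' Tabulates [associate_peaks_to_genes()] output into per-gene counts, one
#' column per named peak subset (e.g. all / d0 / d9).
#'
#' @param associations Named list of association tables (name -> column).
#' @param gene_ids Universe of genes (rows).
#' @return data.table: gene_id plus one count column per subset.
#' @export
count_peaks_per_gene <- function(associations, gene_ids) {
  out <- data.table(gene_id = gene_ids)
  for (nm in names(associations)) {
    a <- associations[[nm]]
    cnt <- a[!is.na(gene_id), .N, by = gene_id]
    out[, (nm) := 0L]
    out[cnt, (nm) := cnt$N, on = "gene_id"]
  }
  out
}

#' Binding fold change (late vs early) by genomic category and gene class
#'
#' Per associated peak, the log2 ratio of late to early normalized
#' intensity; summarized per (category, gene class) as mean +/- SEM with a
#' Mann-Whitney test against the nonresponsive class within the category.
#'
#' @param peak_table data.table with columns gene_id, category and the two
#'   intensity columns (normalized log2 units from [normalize_intensity()]
#'   are exponentiated back; ratio = log2((2^late - 1 + 1) / (2^early - 1 +
#'   1)) reduces to late - early in log2 units when intensities carry the
#'   +1 pseudocount, so the difference of intensities is used directly).
#' @param classes data.table gene_id, gene_class.
#' @param early_col,late_col Names of the intensity columns.
#' @return data.table: category, gene_class, n_peaks, mean_log2fc, sem, p.
#' @export
foldchange_by_location <- function(peak_table, classes,
                                   early_col = "intensity_d0",
                                   late_col = "intensity_d9") {
  pt_ <- merge(peak_table, classes[, .(gene_id, gene_class)], by = "gene_id")
  pt_[, l2fc := get(late_col) - get(early_col)]
  res <- list()
  for (cat_ in unique(pt_$category)) {
    sub <- pt_[category == cat_]
    ref <- sub[gene_class == "nonresponsive", l2fc]
    for (cl in c("up", "down", "nonresponsive")) {
      x <- sub[gene_class == cl, l2fc]
      if (!length(x)) next
      p <- if (cl == "nonresponsive" || !length(ref)) NA_real_ else
        mann_whitney_u(x, ref)$p_value
      res[[length(res) + 1L]] <-
        data.table(category = cat_, gene_class = cl, n_peaks = length(x),
                   mean_log2fc = mean(x),
                   sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
                   p = p)
    }
  }
  rbindlist(res)
}

#' Per-gene conservation of best motif sites
#'
#' Site score = mean conservation over the bases of the peak's best motif
#' hit; gene score = mean of site scores over the gene's associated peaks.
#' Peaks without a motif hit are excluded; genes with no motif-bearing
#' peaks are excluded and counted.
#'
#' @param association Table from [associate_peaks_to_genes()] (name,
#'   gene_id).
#' @param best_hits Table from [best_site_per_peak()] (name, hit
#'   coordinates) for the same peaks.
#' @param conservation A `signal_track` of per-base conservation scores.
#' @param peaks The `peak_set` (for chromosome lookup).
#' @return data.table: gene_id, mean_phylop, n_sites; attribute
#'   `n_excluded_genes`.
#' @export
gene_conservation <- function(association, best_hits, conservation, peaks) {
  m <- merge(association[, .(name, gene_id)], best_hits, by = "name")
  m <- merge(m, data.table(name = peaks$name, chrom = peaks$chrom), by = "name")
  total_genes <- length(unique(m[!is.na(gene_id), gene_id]))
  m <- m[!is.na(gene_id) & !is.na(hit_start)]
  if (nrow(m) == 0L) {
    out <- data.table(gene_id = character(), mean_phylop = numeric(),
                      n_sites = integer())
    setattr(out, "n_excluded_genes", total_genes)
    return(out)
  }
  m[, site_score := track_interval_means(
      conservation, data.table(chrom = chrom, start = hit_start, end = hit_end))]
  out <- m[, .(mean_phylop = mean(site_score), n_sites = .N), by = gene_id]
  setattr(out, "n_excluded_genes", total_genes - nrow(out))
  out[]
}

#' Length-matched control genes
#'
#' Greedy nearest-length matching without replacement: targets are
#' processed in decreasing length; each takes the pool gene with the
#' smallest |length difference| (ties randomized under the seed).
#'
#' @param target_ids Gene ids to match.
#' @param pool_ids Candidate control gene ids (must outnumber targets).
#' @param lengths Named numeric vector of gene lengths covering both sets.
#' @param seed Optional seed for tie randomization.
#' @return data.table: target, control, target_length, control_length,
#'   delta; attributes `max_delta`, `mean_delta`.
#' @export
length_matched_controls <- function(target_ids, pool_ids, lengths,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(pool_ids) < length(target_ids))
    stop("length_matched_controls: pool smaller than target set; unmatched: ",
         paste(target_ids[seq_len(length(target_ids) - length(pool_ids))],
               collapse = ", "))
  tl <- lengths[target_ids]
  if (anyNA(tl)) stop("length_matched_controls: missing target lengths")
  pool <- data.table(gene_id = pool_ids, len = as.numeric(lengths[pool_ids]))
  if (anyNA(pool$len)) stop("length_matched_controls: missing pool lengths")
  ord <- order(-tl)
  out <- vector("list", length(target_ids))
  for (k in ord) {
    dl <- abs(pool$len - tl[k])
    best <- which(dl == min(dl))
    pick <- if (length(best) > 1L) sample(best, 1L) else best
    out[[k]] <- data.table(target = target_ids[k], control = pool$gene_id[pick],
                           target_length = tl[k], control_length = pool$len[pick],
                           delta = dl[pick])
    pool <- pool[-pick]
  }
  res <- rbindlist(out)
  setattr(res, "max_delta", max(res$delta))
  setattr(res, "mean_delta", mean(res$delta))
  res[]
}

#' KS comparison of two conservation summaries
#'
#' Two-sample Kolmogorov-Smirnov test on gene-level mean conservation
#' scores; both groups need n >= 3.
#'
#' @param summary_a,summary_b [gene_conservation()] outputs (or numeric
#'   vectors of gene scores).
#' @return A `ct_test_result` (statistic = D).
#' @export
conservation_ks <- function(summary_a, summary_b) {
  xa <- if (is.numeric(summary_a)) summary_a else summary_a$mean_phylop
  xb <- if (is.numeric(summary_b)) summary_b else summary_b$mean_phylop
  if (length(xa) < 3L || length(xb) < 3L)
    stop("conservation_ks: both groups need n >= 3")
  ks_two_sample(xa, xb)
}
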