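# Random-background interval sampling and category-enrichment comparisons:
# observed peak category fractions vs sampled random intervals (or any
# reference fraction vector), and Fisher-exact comparison of two category
# count vectors with BH correction.

#' Sample random genomic intervals
#'
#' Fixed-length intervals with chromosome chosen proportional to its allowed
#' space and start uniform within it. `exclude` (chrom/start/end table)
#' removes genomic space before sampling, so draws are uniform over the
#' complement.
#'
#' @param sizes Named vector of chromosome sizes.
#' @param n Number of intervals.
#' @param length Interval length in bp (default 100, matching the random
#'   100-bp background convention).
#' @param seed Optional integer seed for reproducibility.
#' @param exclude Optional data.frame-like of intervals to exclude.
#' @return data.table: chrom, start, end.
#' @export
sample_random_intervals <- function(sizes, n, length = 100L, seed = NULL,
                                    exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  if (any(sizes < length))
    stop("sample_random_intervals: length exceeds chromosome size for ",
         paste(names(sizes)[sizes < length], collapse = ", "))
  # allowed start space per chromosome: [0, size - length] minus exclusions
  allowed <- lapply(names(sizes), function(ch) {
    lim <- as.integer(sizes[[ch]]) - length + 1L   # starts in [0, lim)
    segs <- data.table(start = 0L, end = lim)
    if (!is.null(exclude)) {
      ex <- as.data.table(exclude)[chrom == ch]
      if (nrow(ex)) {
        # a start s collides when [s, s+length) overlaps an excluded interval
        ex <- ex[, .(start = pmax(0L, as.integer(start) - length + 1L),
                     end = pmin(lim, as.integer(end)))][start < end]
        setorder(ex, start)
        ex[, grp := cumsum(start > shift(cummax(end), fill = -1L))]
        ex <- ex[, .(start = min(start), end = max(end)), by = grp]
        free <- data.table(start = c(0L, ex$end), end = c(ex$start, lim))
        segs <- free[start < end]
      }
    }
    segs[, chrom := ch]
    segs
  })
  allowed <- rbindlist(allowed)
  allowed[, space := end - start]
  total <- sum(as.numeric(allowed$space))
  if (total <= 0) stop("sample_random_intervals: exclusion leaves no allowed space")
  seg_idx <- sample.int(nrow(allowed), n, replace = TRUE,
                        prob = allowed$space / total)
  offs <- floor(runif(n) * allowed$space[seg_idx])
  data.table(chrom = allowed$chrom[seg_idx],
             start = as.integer(allowed$start[seg_idx] + offs),
             end = as.integer(allowed$start[seg_idx] + offs) + length)
}

#' Category enrichment against a background
#'
#' Classifies observed peaks and a background interval set with the same
#' index, and reports per-category observed/background fractions and their
#' ratio (> 1 = over-represented). The background may instead be given as a
#' precomputed fraction vector named by category.
#'
#' @param peaks A `peak_set` (classified internally).
#' @param background Background intervals (data.frame-like chrom/start/end)
#'   or a named numeric vector of fractions.
#' @param index A [gene_region_index()].
#' @return data.table: category, observed counts/fractions, background
#'   fractions, ratio (Inf flagged when the background fraction is 0).
#' @export
category_enrichment <- function(peaks, background, index) {
  obs <- category_distribution(classify_peaks(peaks, index))
  if (is.numeric(background)) {
    bg <- data.table(category = names(background),
                     bg_fraction = as.numeric(background), bg_count = NA_integer_)
  } else {
    bgdt <- as.data.table(background)
    bg_pts <- data.table(chrom = bgdt$chrom,
                         pos = (bgdt$start + bgdt$end) %/% 2L)
    bg_cls <- .classify_points(bg_pts, index)
    bgd <- category_distribution(bg_cls)
    bg <- bgd[, .(category, bg_fraction = fraction, bg_count = count)]
  }
  out <- merge(obs, bg, by = "category", all.x = TRUE, sort = FALSE)
  out[is.na(bg_fraction), bg_fraction := 0]
  out[, ratio := fifelse(bg_fraction > 0, fraction / bg_fraction,
                         fifelse(fraction > 0, Inf, NA_real_))]
  out[, category := factor(category, levels = .ct_categories)]
  setorder(out, category)[]
}

#' Compare two category count distributions (Fisher + BH)
#'
#' For each of the six categories, tests the 2x2 table (in-category vs rest,
#' group A vs group B) with [fisher_exact_2x2()], then applies [bh_fdr()]
#' across the categories.
#'
#' @param counts_a,counts_b Named integer vectors of per-category counts.
#' @return data.table: category, count_a, count_b, odds_ratio, p, q, note.
#' @export
compare_category_distributions <- function(counts_a, counts_b) {
  cats <- union(names(counts_a), names(counts_b))
  cats <- c(intersect(.ct_categories, cats), setdiff(cats, .ct_categories))
  ca <- setNames(rep(0L, length(cats)), cats)
  cb <- ca
  ca[names(counts_a)] <- as.integer(counts_a)
  cb[names(counts_b)] <- as.integer(counts_b)
  res <- lapply(cats, function(cc) {
    tab <- matrix(c(ca[[cc]], sum(ca) - ca[[cc]],
                    cb[[cc]], sum(cb) - cb[[cc]]), nrow = 2)
    tr <- fisher_exact_2x2(tab)
    data.table(category = cc, count_a = ca[[cc]], count_b = cb[[cc]],
               odds_ratio = tr$statistic, p = tr$p_value,
               note = if (!is.null(tr$note)) tr$note else "")
  })
  out <- rbindlist(res)
  out[, q := bh_fdr(p)]
  out[]
}
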