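# PWM log-odds scanning with exact p-values. Scores are in bits,
# sum_i log2(p'_i(x_i) / bg(x_i)) with pseudocount-regularized p'. The null
# score distribution under the background model is computed exactly by
# positionwise convolution on a discretized score grid, giving
# p(s) = Pr_bg[score >= s] for any threshold.

.base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# integer codes of a sequence string; non-ACGT -> NA
.encode_seq <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  unname(.base_codes[v])
}

#' Log-odds score of a word
#'
#' `sum_i log2(p'_i(word_i) / bg(word_i))` in bits, using the pseudocount-
#' regularized probabilities stored in the `pwm_record`. Words containing
#' ambiguous bases score NA.
#'
#' @param pwm A [pwm_record()].
#' @param word Character string of length `pwm$width`.
#' @return Numeric score (bits), NA for ambiguous words.
#' @export
log_odds_score <- function(pwm, word) {
  code <- .encode_seq(word)
  if (length(code) != pwm$width)
    stop("log_odds_score: word length != PWM width")
  if (anyNA(code)) return(NA_real_)
  sum(pwm$lods[cbind(seq_len(pwm$width), code)])
}

#' Exact p-value function for PWM scores
#'
#' Discretizes the per-position log-odds scores to a grid of `eps` bits and
#' convolves the positionwise score distributions under the background
#' model. Returns a function mapping a score (bits) to
#' `Pr_bg[score >= s]`; the returned p is conservative to within one grid
#' cell (queries are floored onto the grid).
#'
#' @param pwm A [pwm_record()].
#' @param eps Discretization step in bits (default 1e-3).
#' @return Function `score -> p-value` with attribute `eps`.
#' @export
exact_score_pvalue <- function(pwm, eps = 1e-3) {
  grid <- round(pwm$lods / eps)             # integer grid per cell
  dist <- 1                                  # delta at offset cur_lo
  cur_lo <- 0
  cur_len <- 1L
  bg <- pwm$background
  for (i in seq_len(pwm$width)) {
    g <- grid[i, ]
    new_lo <- cur_lo + min(g)
    new_len <- cur_len + (max(g) - min(g))
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- g[b] - min(g)
      idx <- seq_len(cur_len) + off
      new[idx] <- new[idx] + dist[seq_len(cur_len)] * bg[b]
    }
    dist <- new
    cur_lo <- new_lo
    cur_len <- new_len
  }
  sf <- rev(cumsum(rev(dist)))              # P(score_grid >= k), k = cur_lo..
  f <- function(score) {
    k <- floor(score / eps + 1e-9)          # conservative: floor onto grid
    i <- k - cur_lo + 1
    p <- ifelse(i <= 1, 1, ifelse(i > cur_len, 0, sf[pmax(pmin(i, cur_len), 1)]))
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
  attr(f, "eps") <- eps
  attr(f, "support") <- c(cur_lo, cur_lo + cur_len - 1L) * eps
  f
}

# vectorized per-position scores of an encoded sequence (integer codes,
# NA for ambiguous); returns scores at starts 1..(L - w + 1), NA where the
# window contains an ambiguous base
.scan_scores <- function(code, lods) {
  w <- nrow(lods)
  L <- length(code)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  sc <- numeric(n)
  for (i in seq_len(w)) {
    x <- code[i:(i + n - 1L)]
    contrib <- lods[i, ][x]                  # NA propagates
    sc <- sc + contrib
  }
  sc
}

#' Scan sequences for motif hits
#'
#' Scores every window on both strands of every input sequence and reports
#' hits with p-value below `p_threshold`. Minus-strand hits are scored by
#' scanning with the reverse-complement PWM, so a hit's score equals the
#' log-odds of the reverse complement of the genomic window. Windows
#' containing ambiguous bases are skipped.
#'
#' @param pwm A [pwm_record()].
#' @param sequences Named character vector or `DNAStringSet`.
#' @param p_threshold Hit threshold on the exact p-value (default 1e-4).
#' @param pfun Optional precomputed [exact_score_pvalue()] function.
#' @return data.table of hits: chrom, start, end (0-based half-open),
#'   strand, score, p_value, sorted by coordinate.
#' @export
scan_sequences <- function(pwm, sequences, p_threshold = 1e-4, pfun = NULL) {
  if (is.null(pfun)) pfun <- exact_score_pvalue(pwm)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  rc_lods <- pwm_revcomp(pwm)$lods
  hits <- list()
  for (ch in names(sequences)) {
    code <- .encode_seq(sequences[[ch]])
    for (str in c("+", "-")) {
      lods <- if (str == "+") pwm$lods else rc_lods
      sc <- .scan_scores(code, lods)
      if (!length(sc)) next
      pv <- rep(NA_real_, length(sc))
      ok <- !is.na(sc)
      pv[ok] <- pfun(sc[ok])
      keep <- which(ok & pv < p_threshold)
      if (length(keep))
        hits[[length(hits) + 1L]] <-
          data.table(chrom = ch, start = keep - 1L,
                     end = keep - 1L + pwm$width, strand = str,
                     score = sc[keep], p_value = pv[keep])
    }
  }
  if (!length(hits))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric()))
  out <- rbindlist(hits)
  setorder(out, chrom, start, strand)[]
}

#' Best motif hit within each peak
#'
#' The highest-scoring hit whose interval overlaps the peak interval; ties
#' are broken by distance of the hit center to the peak summit (midpoint
#' fallback), then by coordinate.
#'
#' @param peaks A `peak_set`.
#' @param hits Output of [scan_sequences()].
#' @return data.table, one row per peak: name, hit coordinates/score/p
#'   (NA where the peak contains no hit).
#' @export
best_site_per_peak <- function(peaks, hits) {
  pk <- data.table(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                   name = peaks$name, point = peak_points(peaks))
  empty <- data.table(name = pk$name, hit_start = NA_integer_,
                      hit_end = NA_integer_, hit_strand = NA_character_,
                      hit_score = NA_real_, hit_p = NA_real_)
  if (nrow(hits) == 0L || nrow(pk) == 0L) return(empty)
  h <- as.data.table(hits)
  setkey(h, chrom, start, end)
  setkey(pk, chrom, start, end)
  ov <- foverlaps(pk, h, by.x = c("chrom", "start", "end"), nomatch = NULL)
  if (nrow(ov) == 0L) return(empty)
  ov[, dcenter := abs((start + end) %/% 2L - point)]
  setorder(ov, name, -score, dcenter, start)
  best <- ov[, .SD[1L], by = name]
  out <- merge(empty[, .(name)],
               best[, .(name, hit_start = start, hit_end = end,
                        hit_strand = strand, hit_score = score,
                        hit_p = p_value)],
               by = "name", all.x = TRUE, sort = FALSE)
  out[match(pk$name, out$name)]
}

#' Summit-distance motif probability profiles by score tier
#'
#' Ranks peaks by `neglog10_p` into `n_tiers` tiers (tier 1 = top) and, per
#' tier, histograms the signed distance from the best motif hit center to
#' the peak summit (midpoint fallback), normalized to a probability per
#' tier. Peaks without a hit, or with |distance| > max_dist, are excluded.
#'
#' @param peaks A `peak_set`.
#' @param best_hits Output of [best_site_per_peak()] for these peaks.
#' @param n_tiers Number of score tiers (default 3: top/middle/bottom).
#' @param max_dist Maximum |distance| retained (default 500 bp).
#' @param bin_width Histogram bin width in bp (default 10).
#' @return data.table: tier (1 = top), bin_center, probability, n (peaks in
#'   tier with a usable hit). Tiers with no usable peaks are flagged via
#'   n = 0 rows absent and attribute `empty_tiers`.
#' @export
summit_distance_profile <- function(peaks, best_hits, n_tiers = 3L,
                                    max_dist = 500L, bin_width = 10L) {
  stopifnot(nrow(peaks) == nrow(best_hits))
  rk <- rank(-peaks$neglog10_p, ties.method = "first")
  tier <- ceiling(rk / (nrow(peaks) / n_tiers))
  tier <- pmin(pmax(tier, 1L), n_tiers)
  center <- (best_hits$hit_start + best_hits$hit_end) %/% 2L
  dist <- center - peak_points(peaks)
  dt <- data.table(tier = tier, distance = dist)
  dt <- dt[!is.na(distance) & abs(distance) <= max_dist]
  breaks <- seq(-max_dist - bin_width / 2, max_dist + bin_width / 2, by = bin_width)
  centers <- head(breaks, -1) + bin_width / 2
  prof <- rbindlist(lapply(seq_len(n_tiers), function(tt) {
    d <- dt[tier == tt, distance]
    if (!length(d)) return(NULL)
    cnt <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                    nbins = length(centers))
    data.table(tier = tt, bin_center = centers, probability = cnt / sum(cnt),
               n = length(d))
  }))
  if (is.null(prof) || nrow(prof) == 0L)
    prof <- data.table(tier = integer(), bin_center = numeric(),
                       probability = numeric(), n = integer())
  empty <- setdiff(seq_len(n_tiers), unique(prof$tier))
  setattr(prof, "empty_tiers", empty)
  prof[]
}
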