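# Metagene window analysis: per gene, ten 1-kb upstream windows, ten
# gene-body deciles, ten 1-kb downstream windows (30 windows, strand-
# oriented 5'->3'); mean IP/Input signal ratio per window; per-window
# rank-sum tests between gene groups; quintile binding-level bins.

#' Window indices of the 30-window metagene schema
#' @param flank_n Number of flank windows on each side (default 10).
#' @param n_deciles Number of gene-body windows (default 10).
#' @return Character vector of window labels, 5'->3':
#'   up_10..up_1, body_1..body_10, down_1..down_10.
#' @export
window_labels <- function(flank_n = 10L, n_deciles = 10L) {
  c(paste0("up_", rev(seq_len(flank_n))),
    paste0("body_", seq_len(n_deciles)),
    paste0("down_", seq_len(flank_n)))
}

#' Build the metagene window schema for one gene
#'
#' Gene-body deciles by integer splitting: the first `L %% n_deciles`
#' deciles (5'->3') are one base longer. Flanks are fixed `flank_kb`-kb
#' windows split into `flank_n` 1-kb pieces. For '-' genes windows are
#' indexed 5'->3', i.e. window up_1 lies genomically downstream of tx_end.
#' Windows are clipped to the chromosome; genes shorter than `n_deciles`
#' bases are rejected.
#'
#' @param gene One-row `gene_models`.
#' @param flank_kb Total flank span per side in kb (default 10).
#' @param n_deciles Number of body windows (default 10).
#' @param chrom_size Optional chromosome length for clipping.
#' @return data.table: window (label), start, end, chrom (clipped windows
#'   may be empty: start == end).
#' @export
build_window_schema <- function(gene, flank_kb = 10L, n_deciles = 10L,
                                chrom_size = NA_integer_) {
  g <- as.list(gene)
  L <- g$tx_end - g$tx_start
  if (L < n_deciles)
    stop("build_window_schema: gene ", g$gene_id, " shorter than ", n_deciles, " bases")
  flank_n <- as.integer(flank_kb)
  base_len <- L %/% n_deciles
  extra <- L %% n_deciles
  lens <- rep(base_len, n_deciles) + c(rep(1L, extra), rep(0L, n_deciles - extra))
  if (g$strand == "-") lens <- rev(lens)      # 5'->3' order genomically reversed
  bounds <- g$tx_start + cumsum(c(0L, lens))
  body <- data.table(start = bounds[-length(bounds)], end = bounds[-1])
  up <- data.table(start = g$tx_start - (flank_n:1) * 1000L,
                   end = g$tx_start - ((flank_n:1) - 1L) * 1000L)
  down <- data.table(start = g$tx_end + (seq_len(flank_n) - 1L) * 1000L,
                     end = g$tx_end + seq_len(flank_n) * 1000L)
  labs <- window_labels(flank_n, n_deciles)
  if (g$strand == "+") {
    sch <- rbind(up, body, down)
  } else {
    sch <- rbind(down[rev(seq_len(flank_n))], body[rev(seq_len(n_deciles))],
                 up[rev(seq_len(flank_n))])
  }
  sch[, window := labs]
  sch[, `:=`(start = pmax(start, 0L), chrom = g$chrom)]
  if (!is.na(chrom_size)) sch[, end := pmin(end, as.integer(chrom_size))]
  sch[, start := pmin(start, end)]
  sch[, .(chrom, window, start = as.integer(start), end = as.integer(end))]
}

#' Per-window IP/Input signal ratios for all genes
#'
#' For each gene and window, ratio = (mean IP + floor) / (mean Input +
#' floor); the floor (default 0.5) guards zero coverage. Fully clipped
#' (empty) windows get ratio 0 and are flagged. Genes shorter than the
#' decile count are excluded with a message.
#'
#' @param genes A `gene_models`.
#' @param ip,input `signal_track`s on the same genome.
#' @param floor Ratio floor (default 0.5).
#' @param flank_kb,n_deciles Schema parameters.
#' @param sizes Optional named chromosome sizes for clipping.
#' @return list: `profiles` (data.table genes x 30 windows of ratios, plus
#'   `level` = mean ratio), `excluded` (gene ids too short).
#' @export
window_signal_ratio <- function(genes, ip, input, floor = 0.5,
                                flank_kb = 10L, n_deciles = 10L,
                                sizes = NULL) {
  ok <- genes$tx_end - genes$tx_start >= n_deciles
  excluded <- genes$gene_id[!ok]
  if (length(excluded))
    message("window_signal_ratio: excluding ", length(excluded),
            " gene(s) shorter than ", n_deciles, " bases")
  gsub <- genes[ok]
  schemas <- rbindlist(lapply(seq_len(nrow(gsub)), function(i) {
    cs <- if (is.null(sizes)) NA_integer_ else sizes[[gsub$chrom[i]]]
    s <- build_window_schema(gsub[i], flank_kb, n_deciles, cs)
    s[, gene_id := gsub$gene_id[i]]
    s
  }))
  nonempty <- schemas$start < schemas$end
  ipm <- inm <- numeric(nrow(schemas))
  ipm[nonempty] <- track_interval_means(ip, schemas[nonempty])
  inm[nonempty] <- track_interval_means(input, schemas[nonempty])
  schemas[, ratio := fifelse(nonempty, (ipm + floor) / (inm + floor), 0)]
  labs <- window_labels(as.integer(flank_kb), n_deciles)
  schemas[, window := factor(window, levels = labs)]
  wide <- data.table::dcast(schemas, gene_id ~ window, value.var = "ratio")
  setnames(wide, c("gene_id", labs))
  wide[, level := rowMeans(.SD), .SDcols = labs]
  list(profiles = wide[match(gsub$gene_id, gene_id)], excluded = excluded)
}

#' Per-window rank-sum test between gene groups
#'
#' For each of the 30 windows, a two-sided Mann-Whitney/Wilcoxon rank-sum
#' test of the window ratios of `group_ids` versus `reference_ids`, with BH
#' correction across windows.
#'
#' @param profiles Profile table from [window_signal_ratio()].
#' @param group_ids,reference_ids Gene id vectors (non-empty, present in
#'   profiles).
#' @param exact_limit Passed to [mann_whitney_u()].
#' @return data.table: window, U, p, q, median_group, median_reference.
#' @export
group_window_test <- function(profiles, group_ids, reference_ids,
                              exact_limit = 8) {
  labs <- setdiff(names(profiles), c("gene_id", "level"))
  a_rows <- profiles[gene_id %in% group_ids]
  b_rows <- profiles[gene_id %in% reference_ids]
  if (nrow(a_rows) == 0L || nrow(b_rows) == 0L)
    stop("group_window_test: empty group after matching gene ids")
  res <- rbindlist(lapply(labs, function(w) {
    a <- a_rows[[w]]; b <- b_rows[[w]]
    if (length(unique(c(a, b))) == 1L) {      # all tied
      return(data.table(window = w, U = length(a) * length(b) / 2, p = 1,
                        median_group = median(a), median_reference = median(b)))
    }
    tr <- mann_whitney_u(a, b, exact_limit = exact_limit)
    data.table(window = w, U = tr$statistic, p = tr$p_value,
               median_group = median(a), median_reference = median(b))
  }))
  res[, q := bh_fdr(p)]
  res[]
}

#' Quantile binding-level bins
#'
#' Bins genes into `n_bins` quantile bins of the aggregate binding level
#' (mean of the 30 window ratios): bin "I" = top quantile, descending to
#' bin `n_bins` (roman numerals up to 10).
#'
#' @param profiles Profile table from [window_signal_ratio()].
#' @param n_bins Number of bins (default 5).
#' @return data.table: gene_id, level, bin (factor I..V high -> low).
#' @export
binding_level_bins <- function(profiles, n_bins = 5L) {
  if (nrow(profiles) < n_bins)
    stop("binding_level_bins: fewer genes than bins")
  roman <- as.character(utils::as.roman(seq_len(n_bins)))
  rk <- rank(-profiles$level, ties.method = "first")
  bin_idx <- ceiling(rk * n_bins / nrow(profiles))
  data.table(gene_id = profiles$gene_id, level = profiles$level,
             bin = factor(roman[bin_idx], levels = roman))
}
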