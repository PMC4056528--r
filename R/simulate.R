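# Synthetic study generator: genome, gene models, three time-point peak
# sets covering all seven presence/absence patterns with category-biased
# placement, IP/Input signal tracks, planted motifs with tier-dependent
# summit jitter, a conservation track with a planted offset at the motif
# sites of "down"-class genes, and a knockdown-vs-control expression
# matrix — all with machine-readable ground truth.

#' Simulation configuration
#'
#' Defaults describe the packaged toy study: 2 chromosomes x 5 Mb, 300
#' genes, 7 patterns x 6 categories x 70 peaks (~2,940 peaks), 2-fold
#' expression effects with 3 replicates per condition, and the coupled
#' "down"-gene effects (extra peaks, day-9 promoter intensity gain,
#' TSS-proximal IP enrichment, +1 conservation at motif sites) that the
#' integrative analyses are designed to detect.
#'
#' @param seed Master seed.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param gc GC content of the random genome.
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length_range Log-uniform transcript length range (bp).
#' @param peaks_per_cell Peaks per (pattern x category) cell.
#' @param peak_width Peak width in bp (summit at center).
#' @param coord_jitter Max per-time-point shift of a peak's interval (bp).
#' @param cluster_log2rc Named mean log2 read count per cluster id 1..7.
#' @param rc_sd SD of log2 read counts.
#' @param subthreshold_frac Fraction of peaks emitted below the -log10 p
#'   retention threshold (default 0).
#' @param down_gene_weight Placement weight multiplier for "down" genes
#'   (drives the peaks-per-gene contrast).
#' @param down_d9_gain Multiplier on day-9 read counts of promoter/upstream
#'   peaks of down genes (drives the fold-change contrast).
#' @param motif_jitter_sd Summit jitter SD (bp) for top/middle/bottom score
#'   tiers.
#' @param conservation_baseline_sd SD of the conservation baseline noise
#'   (mean 0).
#' @param conservation_offset Planted conservation offset at down-gene
#'   motif sites.
#' @param n_up,n_down Planted up/down gene counts.
#' @param expr_effect_log2 |log2 fold change| planted for up/down genes.
#' @param expr_noise_sd Expression noise SD (log2 units).
#' @param expr_reps Replicates per condition.
#' @param down_tss_amp,down_body_amp Extra day-9 IP signal at down genes:
#'   TSS Gaussian bump amplitude and flat gene-body elevation.
#' @param signal_bin Signal track bin width (bp).
#' @param library_sizes Per-time-point library sizes.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L, chrom_length = 5e6L, gc = 0.5,
                       n_genes = 300L, gene_length_range = c(2000L, 20000L),
                       peaks_per_cell = 70L, peak_width = 200L,
                       coord_jitter = 25L,
                       cluster_log2rc = c("1" = 9, "2" = 7, "3" = 7, "4" = 8,
                                          "5" = 7.5, "6" = 6.5, "7" = 5),
                       rc_sd = 0.8, subthreshold_frac = 0,
                       down_gene_weight = 6, down_d9_gain = 4,
                       motif_jitter_sd = c(top = 20, middle = 50, bottom = 100),
                       conservation_baseline_sd = 0.3,
                       conservation_offset = 1.0,
                       n_up = 60L, n_down = 25L,
                       expr_effect_log2 = 1.0, expr_noise_sd = 0.2,
                       expr_reps = 3L,
                       down_tss_amp = 3, down_body_amp = 0.5,
                       signal_bin = 10L,
                       library_sizes = c(1e7, 1e7, 1e7)) {
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Default packaged PWM (TGTGGT core)
#'
#' Width-10 PWM whose consensus contains the core TGTGGT: two moderately
#' informative flanking positions on each side and six 0.91-peaked core
#' positions. Wide enough that the consensus word reaches p < 1e-4 under a
#' uniform background (a 6-mer cannot: 0.25^6 ~ 2.4e-4).
#'
#' @param pseudocount Passed to [pwm_record()].
#' @return A [pwm_record()].
#' @export
default_pwm <- function(pseudocount = 0.01) {
  core <- c("T", "G", "T", "G", "G", "T")
  rows <- list()
  flank <- function(base) {
    r <- rep(0.15, 4); names(r) <- c("A", "C", "G", "T")
    r[base] <- 0.55
    r
  }
  peaked <- function(base) {
    r <- rep(0.03, 4); names(r) <- c("A", "C", "G", "T")
    r[base] <- 0.91
    r
  }
  rows <- c(list(flank("A"), flank("C")), lapply(core, peaked),
            list(flank("A"), flank("C")))
  probs <- do.call(rbind, rows)
  pwm_record(probs, pseudocount = pseudocount)
}

#' Simulate a random genome
#' @param config A [sim_config()].
#' @return `DNAStringSet` of iid-base chromosomes chr1..chrN.
#' @export
simulate_genome <- function(config) {
  if (config$n_chromosomes < 1L) stop("simulate_genome: need >= 1 chromosome")
  p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2, (1 - config$gc) / 2)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE,
                 prob = p), collapse = "")
  }, "")
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(config$n_chromosomes))))
}

#' Simulate non-overlapping gene models
#'
#' Log-uniform transcript lengths, 2-8 exons per gene, both strands,
#' placed left to right with random gaps so genes (and most of their
#' flanking windows) do not collide.
#'
#' @param config A [sim_config()].
#' @param sizes Named chromosome sizes.
#' @return A [gene_models()].
#' @export
simulate_genes <- function(config, sizes) {
  n <- config$n_genes
  lr <- log(config$gene_length_range)
  lens <- as.integer(round(exp(runif(n, lr[1], lr[2]))))
  chroms <- sample(names(sizes), n, replace = TRUE,
                   prob = as.numeric(sizes) / sum(as.numeric(sizes)))
  rows <- vector("list", n)
  k <- 0L
  for (ch in names(sizes)) {
    idx <- which(chroms == ch)
    if (!length(idx)) next
    need <- sum(lens[idx])
    free <- sizes[[ch]] - 50000L * 2L - need   # keep clear margins at both ends
    if (free < length(idx)) stop("simulate_genes: cannot place genes without overlap on ", ch)
    gaps <- as.numeric(stats::rmultinom(1, free, rep(1, length(idx) + 1L)))
    pos <- 50000L
    for (j in seq_along(idx)) {
      pos <- pos + as.integer(gaps[j])
      L <- lens[idx[j]]
      n_ex <- sample(2:8, 1L)
      # partition L into n_ex exons and n_ex - 1 introns, each >= 50 bp
      parts <- 2L * n_ex - 1L
      min_part <- 50L
      if (L < parts * min_part) n_ex <- max(1L, (L %/% (2L * min_part) + 1L) %/% 2L)
      parts <- 2L * n_ex - 1L
      cuts <- sort(sample.int(L - parts * min_part + parts - 1L, parts - 1L))
      seg <- diff(c(0L, cuts, L - parts * min_part + parts - 1L))
      seg <- seg - 1L + min_part
      seg[parts] <- L - sum(seg[-parts])
      bounds <- cumsum(c(0L, seg)) + pos
      es <- bounds[seq(1L, parts, by = 2L)]
      ee <- bounds[seq(2L, parts + 1L, by = 2L)]
      k <- k + 1L
      rows[[k]] <- data.table(gene_id = sprintf("gene_%03d", idx[j]),
                              chrom = ch, strand = sample(c("+", "-"), 1L),
                              tx_start = as.integer(pos),
                              tx_end = as.integer(pos + L),
                              exon_starts = list(as.integer(es)),
                              exon_ends = list(as.integer(ee)))
      pos <- pos + L
    }
  }
  gene_models(rbindlist(rows[seq_len(k)]))
}

#' Assign planted gene classes
#' @param config A [sim_config()].
#' @param genes A `gene_models`.
#' @return data.table: gene_id, true_class (up/down/nonresponsive).
#' @export
simulate_gene_classes <- function(config, genes) {
  ids <- genes$gene_id
  if (config$n_up + config$n_down > length(ids))
    stop("simulate_gene_classes: n_up + n_down exceeds gene count")
  pick <- sample(ids, config$n_up + config$n_down)
  data.table(gene_id = ids,
             true_class = fifelse(ids %in% pick[seq_len(config$n_up)], "up",
                           fifelse(ids %in% pick[config$n_up + seq_len(config$n_down)],
                                   "down", "nonresponsive")))
}

# all seven non-empty presence patterns over (d0, d9, d28), cluster order
.sim_patterns <- function() names(temporal_cluster_map())

# greedy non-overlap filter: keep candidate points whose [pt - pad, pt + pad)
# do not collide with each other or with `occupied` (data.table chrom,start,end)
.filter_nonoverlap <- function(cand, occupied, pad) {
  cand <- copy(cand)[, `:=`(start = pos - pad, end = pos + pad)]
  if (nrow(occupied)) {
    occ <- copy(occupied)
    setkey(occ, chrom, start, end)
    hit <- foverlaps(cand, occ, by.x = c("chrom", "start", "end"),
                     nomatch = NULL, which = TRUE)
    if (nrow(hit)) cand <- cand[-unique(hit$xid)]
  }
  if (!nrow(cand)) return(cand[, .(chrom, pos, gene_id, category)])
  # greedy sweep among the remaining candidates: keep the earlier of any
  # overlapping pair (rejected-vs-rejected chains resolved by top-up rounds)
  setorder(cand, chrom, start)
  cand[, prev_end := shift(cummax(end), fill = -2147483647L), by = chrom]
  cand[start >= prev_end, .(chrom, pos, gene_id, category)]
}

#' Simulate the three time-point peak sets
#'
#' Every (pattern x category) cell gets `peaks_per_cell` peaks. Genic-
#' category peaks choose a gene (down genes over-weighted by
#' `down_gene_weight`), draw a point uniformly in one of that gene's
#' category windows, and keep it only if the real classifier agrees with
#' the intended category (so truth labels are exact by construction);
#' intergenic peaks are uniform draws that classify intergenic. Placements
#' never overlap, so presence vectors are recoverable. Read counts are
#' lognormal per cluster; day-9 counts of promoter/upstream peaks of down
#' genes are multiplied by `down_d9_gain` when day 9 is in the pattern.
#'
#' @param config A [sim_config()].
#' @param genes A `gene_models`.
#' @param classes Output of [simulate_gene_classes()].
#' @param index A [gene_region_index()] over `genes`.
#' @param sizes Named chromosome sizes.
#' @return list: `peak_sets` (list of 3 `peak_set`s for d0/d9/d28),
#'   `truth` (per-region truth table).
#' @export
simulate_peaksets <- function(config, genes, classes, index, sizes) {
  patterns <- .sim_patterns()
  cats <- .ct_categories
  n_cell <- config$peaks_per_cell
  half <- config$peak_width %/% 2L
  pad <- half + config$coord_jitter + 5L
  gweight <- fifelse(classes$true_class == "down", config$down_gene_weight, 1)
  names(gweight) <- classes$gene_id
  win <- index$windows
  occupied <- data.table(chrom = character(), start = integer(), end = integer())
  placed <- list()
  for (cat_ in cats) {
    need <- n_cell * length(patterns)
    got <- list()
    n_got <- 0L
    for (round_ in 1:40) {
      if (n_got >= need) break
      n_try <- max(200L, 3L * (need - n_got))
      if (cat_ == "intergenic") {
        ch <- sample(names(sizes), n_try, replace = TRUE,
                     prob = as.numeric(sizes) / sum(as.numeric(sizes)))
        pos <- as.integer(floor(runif(n_try, pad, unlist(sizes[ch]) - pad)))
        cand <- data.table(chrom = ch, pos = pos, gene_id = NA_character_)
      } else {
        w <- win[category == cat_]
        if (!nrow(w)) stop("simulate_peaksets: no windows for category ", cat_)
        wt <- gweight[w$gene_id] * (w$end - w$start)
        wi <- sample.int(nrow(w), n_try, replace = TRUE, prob = wt / sum(wt))
        pos <- as.integer(floor(runif(n_try, w$start[wi], w$end[wi])))
        cand <- data.table(chrom = w$chrom[wi], pos = pos, gene_id = w$gene_id[wi])
      }
      cls <- .classify_points(cand[, .(chrom, pos)], index)
      keep <- cls$category == cat_ &
        (cat_ == "intergenic" |
           (!is.na(cls$gene_id) & cls$gene_id == cand$gene_id))
      cand <- cand[keep]
      if (!nrow(cand)) next
      cand[, category := cat_]
      ok <- .filter_nonoverlap(unique(cand, by = c("chrom", "pos")), occupied, pad)
      if (!nrow(ok)) next
      ok <- ok[seq_len(min(nrow(ok), need - n_got))]
      occupied <- rbind(occupied,
                        ok[, .(chrom, start = pos - pad, end = pos + pad)])
      got[[length(got) + 1L]] <- ok
      n_got <- n_got + nrow(ok)
    }
    if (n_got < need)
      stop("simulate_peaksets: could not place ", need, " peaks for category ",
           cat_, " (placed ", n_got, ")")
    cellpts <- rbindlist(got)
    cellpts[, pattern := rep(patterns, each = n_cell)]
    placed[[cat_]] <- cellpts
  }
  truth <- rbindlist(placed)
  truth[, region_name := sprintf("truth_%04d", seq_len(.N))]
  truth[, cluster_id := temporal_cluster_map()[pattern]]
  truth <- merge(truth, classes, by = "gene_id", all.x = TRUE, sort = FALSE)
  truth[is.na(true_class), true_class := "none"]
  # read counts per time point
  mu <- config$cluster_log2rc[as.character(truth$cluster_id)]
  for (t in 1:3) {
    present <- substr(truth$pattern, t, t) == "1"
    rc <- 2^(mu + rnorm(nrow(truth), 0, config$rc_sd))
    gain <- t == 2L & truth$true_class == "down" &
      truth$category %in% c("promoter", "upstream") &
      substr(truth$pattern, 2, 2) == "1"
    rc[gain] <- rc[gain] * config$down_d9_gain
    rc[!present] <- NA_real_
    truth[, (paste0("rc_d", c(0, 9, 28)[t])) := round(rc, 2)]
  }
  truth[, neglog10_p := pmax(10.5,
    10 + (log2(pmax(truth$rc_d0, truth$rc_d9, truth$rc_d28, na.rm = TRUE)) - 5) * 3 +
      rnorm(.N, 0, 2))]
  if (config$subthreshold_frac > 0) {
    sub <- runif(nrow(truth)) < config$subthreshold_frac
    truth[sub, neglog10_p := runif(sum(sub), 2, 9.5)]
  }
  time_cols <- c("rc_d0", "rc_d9", "rc_d28")
  peak_sets <- lapply(1:3, function(t) {
    pres <- substr(truth$pattern, t, t) == "1"
    sub <- truth[pres]
    shift_ <- sample(seq(-config$coord_jitter, config$coord_jitter),
                     nrow(sub), replace = TRUE)
    start <- sub$pos - half + shift_
    peak_set(data.table(chrom = sub$chrom, start = start,
                        end = start + config$peak_width,
                        name = paste0(sub$region_name, "_d", c(0, 9, 28)[t]),
                        neglog10_p = round(sub$neglog10_p, 3),
                        summit_offset = as.integer(sub$pos - start),
                        read_count = sub[[time_cols[t]]]))
  })
  list(peak_sets = peak_sets, truth = truth[])
}

# add a gaussian bump (area-parameterized) to a binned value vector
.add_bump <- function(vals, bin, center, sd, amp) {
  nb <- length(vals)
  lo <- max(1L, floor((center - 4 * sd) / bin) + 1L)
  hi <- min(nb, ceiling((center + 4 * sd) / bin))
  if (lo > hi) return(vals)
  x <- (seq(lo, hi) - 0.5) * bin
  vals[lo:hi] <- vals[lo:hi] + amp * exp(-((x - center)^2) / (2 * sd^2))
  vals
}

#' Simulate IP and Input signal tracks
#'
#' Input: noisy flat baseline (mean 1). IP per time point: the baseline
#' plus a Gaussian bump (sd 100 bp) at each peak summit present at that
#' time, amplitude proportional to the peak's read count, plus — at day 9 —
#' a TSS bump and a flat gene-body elevation for down-class genes.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_peaksets()].
#' @param genes A `gene_models`.
#' @param classes Gene class table.
#' @param sizes Named chromosome sizes.
#' @return list: `ip` (list of 3 `signal_track`s), `input` (`signal_track`).
#' @export
simulate_signal_tracks <- function(config, truth, genes, classes, sizes) {
  bin <- config$signal_bin
  mk_bins <- function(ch) {
    nb <- as.integer(ceiling(sizes[[ch]] / bin))
    data.table(chrom = ch, start = (seq_len(nb) - 1L) * bin,
               end = pmin(seq_len(nb) * bin, as.integer(sizes[[ch]])))
  }
  down_ids <- classes[true_class == "down", gene_id]
  input_segs <- list()
  ip_segs <- list(list(), list(), list())
  for (ch in names(sizes)) {
    bins <- mk_bins(ch)
    nb <- nrow(bins)
    base <- pmax(0, rnorm(nb, 1, 0.15))
    input_segs[[ch]] <- copy(bins)[, value := round(base, 4)]
    tr <- truth[chrom == ch]
    gch <- genes[chrom == ch & gene_id %in% down_ids]
    for (t in 1:3) {
      vals <- pmax(0, rnorm(nb, 1, 0.15))
      pres <- substr(tr$pattern, t, t) == "1"
      rc_col <- paste0("rc_d", c(0, 9, 28)[t])
      sub <- tr[pres]
      for (i in seq_len(nrow(sub)))
        vals <- .add_bump(vals, bin, sub$pos[i], 100,
                          amp = 2 + sub[[rc_col]][i] / 200)
      if (t == 2L && nrow(gch)) {
        tssv <- gene_tss(gch)
        for (i in seq_len(nrow(gch))) {
          vals <- .add_bump(vals, bin, tssv[i], 1000, config$down_tss_amp)
          b0 <- max(1L, gch$tx_start[i] %/% bin + 1L)
          b1 <- min(nb, as.integer(ceiling(gch$tx_end[i] / bin)))
          if (b0 <= b1) vals[b0:b1] <- vals[b0:b1] + config$down_body_amp
        }
      }
      ip_segs[[t]][[ch]] <- copy(bins)[, value := round(vals, 4)]
    }
  }
  list(ip = lapply(ip_segs, function(s) signal_track(rbindlist(s))),
       input = signal_track(rbindlist(input_segs)))
}

#' Plant motifs and simulate the conservation track
#'
#' Writes the PWM consensus word at each peak summit plus Gaussian jitter
#' whose SD depends on the peak's score tier (top/middle/bottom tertile of
#' -log10 p). The conservation track is baseline noise (mean 0, 200-bp
#' bins) with `conservation_offset` added over the motif bases of peaks
#' associated with down-class genes.
#'
#' @param config A [sim_config()].
#' @param genome `DNAStringSet` (modified copy returned).
#' @param truth Truth table from [simulate_peaksets()] (gains a
#'   `motif_offset` column).
#' @param pwm The PWM whose consensus is planted.
#' @param sizes Named chromosome sizes.
#' @return list: `genome` (edited), `truth` (with motif offsets),
#'   `conservation` (`signal_track`).
#' @export
simulate_conservation_and_motifs <- function(config, genome, truth, pwm,
                                             sizes) {
  w <- pwm$width
  half <- config$peak_width %/% 2L
  tier <- cut(rank(-truth$neglog10_p, ties.method = "first"),
              breaks = 3, labels = c("top", "middle", "bottom"))
  sdv <- config$motif_jitter_sd[as.character(tier)]
  max_off <- half - w %/% 2L - config$coord_jitter - 1L
  jit <- round(rnorm(nrow(truth), 0, sdv))
  # resample jitter that would push the site outside every peak instance
  for (r in 1:20) {
    bad <- abs(jit) > max_off
    if (!any(bad)) break
    jit[bad] <- round(rnorm(sum(bad), 0, sdv[bad]))
  }
  jit[abs(jit) > max_off] <- 0
  truth <- copy(truth)[, motif_offset := as.integer(jit)]
  site_start <- truth$pos + truth$motif_offset - w %/% 2L
  cons_word <- pwm$consensus
  for (ch in names(sizes)) {
    idx <- which(truth$chrom == ch)
    if (!length(idx)) next
    at <- IRanges::IRanges(start = site_start[idx] + 1L, width = w)
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]], at, as.character(rep(cons_word, length(idx))))
  }
  # conservation: baseline bins + offset over down-gene motif sites
  cb <- 200L
  segs <- lapply(names(sizes), function(ch) {
    nb <- as.integer(ceiling(sizes[[ch]] / cb))
    data.table(chrom = ch, start = (seq_len(nb) - 1L) * cb,
               end = pmin(seq_len(nb) * cb, as.integer(sizes[[ch]])),
               value = round(rnorm(nb, 0, config$conservation_baseline_sd), 4))
  })
  base <- rbindlist(segs)
  down_sites <- truth[true_class == "down",
                      .(chrom, start = pos + motif_offset - w %/% 2L)]
  down_sites[, end := start + w]
  if (nrow(down_sites)) {
    setkey(down_sites, chrom, start, end)
    base[, rid := .I]
    setkey(base, chrom, start, end)
    ov <- foverlaps(down_sites, base, by.x = c("chrom", "start", "end"),
                    nomatch = NULL)
    pieces <- list(base[!rid %in% ov$rid, .(chrom, start, end, value)])
    for (r in unique(ov$rid)) {
      b <- base[rid == r]
      cuts <- ov[rid == r]
      brk <- sort(unique(c(b$start, b$end,
                           pmax(cuts$i.start, b$start),
                           pmin(cuts$i.end, b$end))))
      seg <- data.table(chrom = b$chrom, start = brk[-length(brk)],
                        end = brk[-1], value = b$value)
      inside <- rep(FALSE, nrow(seg))
      for (j in seq_len(nrow(cuts)))
        inside <- inside | (seg$start >= cuts$i.start[j] & seg$end <= cuts$i.end[j])
      seg[inside, value := value + config$conservation_offset]
      pieces[[length(pieces) + 1L]] <- seg
    }
    base <- rbindlist(pieces)
  } else {
    base <- base[, .(chrom, start, end, value)]
  }
  list(genome = genome, truth = truth,
       conservation = signal_track(base[, .(chrom, start, end, value)]))
}

#' Simulate the knockdown expression matrix
#'
#' log2 intensities: per-gene baseline N(8, 1.5) plus the class effect
#' (knockdown minus control): down genes -effect, up genes +effect, plus
#' N(0, noise sd) per sample. Conditions "shTF" (knockdown) and "Scr"
#' (control), `expr_reps` replicates each.
#'
#' @param config A [sim_config()].
#' @param classes Gene class table from [simulate_gene_classes()].
#' @return An [expression_matrix()] with conditions Scr / shTF.
#' @export
simulate_expression <- function(config, classes) {
  n <- nrow(classes)
  reps <- config$expr_reps
  baseline <- rnorm(n, 8, 1.5)
  eff <- fifelse(classes$true_class == "up", config$expr_effect_log2,
                 fifelse(classes$true_class == "down",
                         -config$expr_effect_log2, 0))
  scr <- matrix(baseline, n, reps) +
    matrix(rnorm(n * reps, 0, config$expr_noise_sd), n, reps)
  sh <- matrix(baseline + eff, n, reps) +
    matrix(rnorm(n * reps, 0, config$expr_noise_sd), n, reps)
  vals <- cbind(scr, sh)
  colnames(vals) <- c(paste0("Scr_", seq_len(reps)), paste0("shTF_", seq_len(reps)))
  rownames(vals) <- classes$gene_id
  expression_matrix(vals, rep(c("Scr", "shTF"), each = reps))
}

#' Simulate the full study and write it to a directory
#'
#' Runs every generator stage under the config seed and writes:
#' genome.fa, genes.bed12, peaks_d0/d9/d28.bed, ip_d0/d9/d28.bedgraph,
#' input.bedgraph, conservation.bedgraph, motif.meme, expression.tsv,
#' truth_peaks.tsv, truth_genes.tsv and config.txt (key=value).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_study <- function(config = sim_config(), dir) {
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  sizes <- chrom_sizes(genome)
  genes <- simulate_genes(config, sizes)
  classes <- simulate_gene_classes(config, genes)
  index <- gene_region_index(genes, sizes = sizes)
  pk <- simulate_peaksets(config, genes, classes, index, sizes)
  pwm <- default_pwm()
  cm <- simulate_conservation_and_motifs(config, genome, pk$truth, pwm, sizes)
  tracks <- simulate_signal_tracks(config, cm$truth, genes, classes, sizes)
  expr <- simulate_expression(config, classes)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed12"),
    peaks = file.path(dir, paste0("peaks_", c("d0", "d9", "d28"), ".bed")),
    ip = file.path(dir, paste0("ip_", c("d0", "d9", "d28"), ".bedgraph")),
    input = file.path(dir, "input.bedgraph"),
    conservation = file.path(dir, "conservation.bedgraph"),
    motif = file.path(dir, "motif.meme"),
    expression = file.path(dir, "expression.tsv"),
    truth_peaks = file.path(dir, "truth_peaks.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    config = file.path(dir, "config.txt"))
  write_genome_fasta(cm$genome, paths$genome)
  write_gene_models_bed12(genes, paths$genes)
  for (t in 1:3) write_peaks_bed(pk$peak_sets[[t]], paths$peaks[t])
  for (t in 1:3) write_signal_bedgraph(tracks$ip[[t]], paths$ip[t])
  write_signal_bedgraph(tracks$input, paths$input)
  write_signal_bedgraph(cm$conservation, paths$conservation)
  write_motif_meme(pwm, paths$motif)
  write_expression_table(expr, paths$expression)
  tp <- copy(cm$truth)
  tp[, pattern := paste0("p", pattern)]   # keep "011" etc. textual on re-read
  fwrite(tp, paths$truth_peaks, sep = "\t")
  fwrite(classes, paths$truth_genes, sep = "\t")
  scalars <- config[vapply(config, function(x) length(x) == 1L &&
                             is.atomic(x), TRUE)]
  writeLines(paste0(names(scalars), "=", unlist(scalars)), paths$config)
  invisible(list(config = config, genome = cm$genome, sizes = sizes,
                 genes = genes, classes = classes, index = index,
                 peak_sets = pk$peak_sets, truth = cm$truth,
                 tracks = tracks, conservation = cm$conservation,
                 pwm = pwm, expression = expr, paths = paths))
}
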