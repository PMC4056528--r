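# Canonical in-memory genomic containers. All coordinates are 0-based
# half-open (BED convention) throughout the package; 1-based inputs
# (refFlat-like tables) are converted on read.

#' Construct a peak set
#'
#' A peak set is a `data.table` with one row per peak: `chrom`, `start`,
#' `end` (0-based half-open), `name`, `neglog10_p` (MACS-style -log10
#' p-value), `summit_offset` (0-based offset of the summit from `start`, NA
#' if unknown) and `read_count` (NA if unmeasured). Peaks below the
#' significance threshold are *flagged* (`retained = FALSE`), never silently
#' dropped; filtering is the explicit [filter_peaks()] step.
#'
#' @param df data.frame-like with at least chrom/start/end.
#' @param threshold Significance threshold on `neglog10_p` used to set the
#'   `retained` flag (default 10, i.e. P < 1e-10).
#' @return A `peak_set` (data.table).
#' @export
peak_set <- function(df, threshold = 10) {
  dt <- as.data.table(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(dt))) stop("peak_set: missing columns ", paste(setdiff(need, names(dt)), collapse = ", "))
  if (!"name" %in% names(dt)) dt[, name := paste0("peak_", .I)]
  if (!"neglog10_p" %in% names(dt)) dt[, neglog10_p := NA_real_]
  if (!"summit_offset" %in% names(dt)) dt[, summit_offset := NA_integer_]
  if (!"read_count" %in% names(dt)) dt[, read_count := NA_real_]
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), neglog10_p = as.numeric(neglog10_p),
            summit_offset = as.integer(summit_offset),
            read_count = as.numeric(read_count))]
  if (any(dt$start < 0L)) stop("peak_set: negative start")
  if (any(dt$start >= dt$end)) {
    bad <- which(dt$start >= dt$end)[1]
    stop(sprintf("peak_set: start >= end at row %d (%s:%d-%d)",
                 bad, dt$chrom[bad], dt$start[bad], dt$end[bad]))
  }
  so <- dt$summit_offset
  if (any(!is.na(so) & (so < 0L | so >= dt$end - dt$start)))
    stop("peak_set: summit_offset outside peak")
  if (any(!is.na(dt$neglog10_p) & dt$neglog10_p < 0))
    stop("peak_set: negative neglog10_p")
  dt[, retained := is.na(neglog10_p) | neglog10_p >= threshold]
  setattr(dt, "class", c("peak_set", class(data.table())))
  setattr(dt, "neglog10_p_threshold", threshold)
  dt[]
}

#' Drop peaks below the significance threshold
#'
#' Explicit filtering step retaining only peaks whose `retained` flag is set
#' (default threshold -log10 p >= 10, i.e. P < 1e-10).
#'
#' @param peaks A `peak_set`.
#' @return Filtered `peak_set`.
#' @export
filter_peaks <- function(peaks) {
  out <- peaks[retained == TRUE]
  setattr(out, "class", class(peaks))
  out[]
}

#' Classification point of each peak
#'
#' The genomic position at which a peak is classified: the summit when
#' present, else the interval midpoint (floor).
#'
#' @param peaks A `peak_set`.
#' @return Integer vector of positions.
#' @export
peak_points <- function(peaks) {
  as.integer(ifelse(is.na(peaks$summit_offset),
                    (peaks$start + peaks$end) %/% 2L,
                    peaks$start + peaks$summit_offset))
}

#' Construct gene models
#'
#' One row per transcript: `gene_id`, `chrom`, `strand` (+/-), `tx_start`,
#' `tx_end` (0-based half-open) and list-columns `exon_starts`/`exon_ends`.
#' Exons must be sorted, non-overlapping, start at `tx_start` and end at
#' `tx_end`.
#'
#' @param df data.frame-like with the columns above.
#' @return A `gene_models` data.table.
#' @export
gene_models <- function(df) {
  dt <- as.data.table(df)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(dt))) stop("gene_models: missing columns ", paste(setdiff(need, names(dt)), collapse = ", "))
  dt[, `:=`(gene_id = as.character(gene_id), chrom = as.character(chrom),
            strand = as.character(strand),
            tx_start = as.integer(tx_start), tx_end = as.integer(tx_end))]
  if (any(!dt$strand %in% c("+", "-"))) stop("gene_models: strand must be '+' or '-'")
  if (anyDuplicated(dt$gene_id)) stop("gene_models: duplicate gene_id")
  for (i in seq_len(nrow(dt))) {
    es <- as.integer(dt$exon_starts[[i]]); ee <- as.integer(dt$exon_ends[[i]])
    if (length(es) != length(ee) || length(es) == 0L)
      stop("gene_models: exon start/end length mismatch for ", dt$gene_id[i])
    if (any(es >= ee)) stop("gene_models: empty exon in ", dt$gene_id[i])
    if (is.unsorted(es, strictly = TRUE) || any(ee[-length(ee)] > es[-1]))
      stop("gene_models: exons unsorted/overlapping in ", dt$gene_id[i])
    if (es[1] != dt$tx_start[i] || ee[length(ee)] != dt$tx_end[i])
      stop("gene_models: exons do not span tx bounds in ", dt$gene_id[i])
  }
  setattr(dt, "class", c("gene_models", class(data.table())))
  dt[]
}

#' Transcription start site of each gene
#'
#' For '+' genes the TSS coordinate is `tx_start`; for '-' genes it is
#' `tx_end` (the half-open end, i.e. one past the first transcribed base).
#'
#' @param genes A `gene_models`.
#' @return Integer vector of TSS coordinates.
#' @export
gene_tss <- function(genes) {
  as.integer(ifelse(genes$strand == "+", genes$tx_start, genes$tx_end))
}

#' Construct a signal track
#'
#' Piecewise-constant base-wise signal: a data.table of `chrom`, `start`,
#' `end`, `value` with non-overlapping segments per chromosome, sorted.
#' Uncovered bases have implicit value 0.
#'
#' @param df data.frame-like with chrom/start/end/value.
#' @return A `signal_track` data.table keyed by chrom, start, end.
#' @export
signal_track <- function(df) {
  dt <- as.data.table(df)[, .(chrom = as.character(chrom),
                              start = as.integer(start),
                              end = as.integer(end),
                              value = as.numeric(value))]
  if (any(dt$start >= dt$end)) stop("signal_track: start >= end")
  if (any(!is.finite(dt$value))) stop("signal_track: non-finite value")
  setorder(dt, chrom, start)
  ov <- dt[, any(start[-1] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(ov)) {
    bad <- dt[chrom == ov$chrom[1]]
    i <- which(bad$start[-1] < bad$end[-nrow(bad)])[1]
    stop(sprintf("signal_track: overlapping segments on %s at %d-%d / %d-%d",
                 ov$chrom[1], bad$start[i], bad$end[i],
                 bad$start[i + 1], bad$end[i + 1]))
  }
  setkey(dt, chrom, start, end)
  setattr(dt, "class", c("signal_track", class(data.table())))
  dt[]
}

#' Mean signal over intervals
#'
#' Length-weighted mean of the track over each query interval; bases without
#' coverage contribute value 0 (read-density semantics). Vectorized over the
#' query table.
#'
#' @param track A `signal_track`.
#' @param intervals data.frame-like with chrom/start/end.
#' @return Numeric vector of means, one per query row.
#' @export
track_interval_means <- function(track, intervals) {
  q <- as.data.table(intervals)[, .(chrom = as.character(chrom),
                                    start = as.integer(start),
                                    end = as.integer(end))]
  if (any(q$start >= q$end)) stop("track_interval_means: empty query interval")
  q[, qid := .I]
  setkey(q, chrom, start, end)
  hits <- foverlaps(q, track, type = "any", nomatch = NULL)
  if (nrow(hits) == 0L) return(numeric(nrow(q)))
  hits[, wsum := value * (pmin(i.end, end) - pmax(i.start, start))]
  agg <- hits[, .(s = sum(wsum)), by = qid]
  out <- numeric(nrow(q))
  out[agg$qid] <- agg$s
  setorder(q, qid)
  out / (q$end - q$start)
}

#' Construct a position weight matrix record
#'
#' Per-position nucleotide probabilities (rows sum to 1) with a background
#' frequency vector. The pseudocount regularizes probabilities before
#' log-odds: `p' = (p + pc) / (1 + 4 pc)`. The bits-scale log-odds matrix
#' `log2(p'/bg)` is precomputed.
#'
#' @param probs width x 4 matrix, columns A, C, G, T.
#' @param background Length-4 background frequencies (default uniform).
#' @param pseudocount Regularizing pseudocount (default 0.01).
#' @return A `pwm_record` list: width, probs, background, pseudocount,
#'   lods (log-odds matrix), consensus.
#' @export
pwm_record <- function(probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("pwm_record: probs must have 4 columns (A,C,G,T)")
  if (nrow(probs) < 4) stop("pwm_record: width must be >= 4")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stop("pwm_record: rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("pwm_record: background must sum to 1")
  if (pseudocount < 0) stop("pwm_record: pseudocount must be >= 0")
  colnames(probs) <- c("A", "C", "G", "T")
  reg <- (probs + pseudocount) / (1 + 4 * pseudocount)
  lods <- log2(sweep(reg, 2, background, "/"))
  consensus <- paste(colnames(probs)[max.col(probs, ties.method = "first")],
                     collapse = "")
  structure(list(width = nrow(probs), probs = probs, background = background,
                 pseudocount = pseudocount, lods = lods,
                 consensus = consensus),
            class = "pwm_record")
}

#' Reverse-complement a PWM
#' @param pwm A `pwm_record`.
#' @return The reverse-complement `pwm_record`.
#' @export
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[rev(seq_len(pwm$width)), c("T", "G", "C", "A"), drop = FALSE]
  colnames(probs) <- c("A", "C", "G", "T")
  pwm_record(probs, background = pwm$background[c(4, 3, 2, 1)],
             pseudocount = pwm$pseudocount)
}

#' Construct an expression matrix
#'
#' log2-scale intensities, genes x samples, with a condition assignment per
#' sample. At least two samples per condition are required.
#'
#' @param values Numeric matrix with rownames = gene ids.
#' @param conditions Character/factor vector, one condition per column.
#' @return An `expression_matrix` list: values, gene_ids, samples, conditions.
#' @export
expression_matrix <- function(values, conditions) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression_matrix: rownames (gene ids) required")
  if (anyDuplicated(rownames(values)))
    stop("expression_matrix: duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (length(conditions) != ncol(values))
    stop("expression_matrix: one condition per sample required")
  conditions <- as.factor(conditions)
  if (any(table(conditions) < 2)) stop("expression_matrix: >= 2 samples per condition required")
  if (anyNA(values)) stop("expression_matrix: missing intensities")
  structure(list(values = values, gene_ids = rownames(values),
                 samples = colnames(values), conditions = conditions),
            class = "expression_matrix")
}
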