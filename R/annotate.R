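# Six-category genomic annotation of peaks. Windows follow the strand-aware
# scheme: promoter = TSS -1 kb .. +150 bp; upstream = TSS -20 kb .. -1 kb;
# TTS region = 150 bp inside the gene end through 1 kb downstream of the TTS;
# exon/intron from the exon structure; everything else intergenic. Precedence
# when windows of several genes cover the same base:
# promoter > tts_region > exon > intron > upstream, then nearest TSS.

#' Default annotation window parameters
#'
#' @param promoter_up Bases upstream of the TSS in the promoter (1000).
#' @param promoter_down Bases downstream of the TSS in the promoter (150).
#' @param upstream_far Outer bound of the upstream window (20000).
#' @param tts_near Bases inside the gene end in the TTS window (150).
#' @param tts_far Bases beyond the TTS in the TTS window (1000).
#' @return Named list of window parameters.
#' @export
annotation_params <- function(promoter_up = 1000L, promoter_down = 150L,
                              upstream_far = 20000L, tts_near = 150L,
                              tts_far = 1000L) {
  list(promoter_up = as.integer(promoter_up),
       promoter_down = as.integer(promoter_down),
       upstream_far = as.integer(upstream_far),
       tts_near = as.integer(tts_near),
       tts_far = as.integer(tts_far))
}

#' Category windows of a single gene
#'
#' Strand-aware windows for one gene model. For '-' genes the TSS is
#' `tx_end`, the TTS is `tx_start`, and all windows are mirrored. Windows
#' are clipped to `[0, chrom_size)`; windows that become empty after
#' clipping are dropped.
#'
#' @param gene One-row `gene_models` (or a list with the same fields).
#' @param params [annotation_params()].
#' @param chrom_size Optional chromosome length for right clipping.
#' @return data.table with columns chrom, start, end, category, gene_id, tss.
#' @export
gene_region_windows <- function(gene, params = annotation_params(),
                                chrom_size = NA_integer_) {
  g <- as.list(gene)
  es <- as.integer(g$exon_starts[[1]]); ee <- as.integer(g$exon_ends[[1]])
  plus <- g$strand == "+"
  tss <- if (plus) g$tx_start else g$tx_end
  tts <- if (plus) g$tx_end else g$tx_start
  if (plus) {
    promoter <- c(tss - params$promoter_up, tss + params$promoter_down)
    upstream <- c(tss - params$upstream_far, tss - params$promoter_up)
    ttsw <- c(tts - params$tts_near, tts + params$tts_far)
  } else {
    promoter <- c(tss - params$promoter_down, tss + params$promoter_up)
    upstream <- c(tss + params$promoter_up, tss + params$upstream_far)
    ttsw <- c(tts - params$tts_far, tts + params$tts_near)
  }
  win <- data.table(
    start = c(promoter[1], upstream[1], ttsw[1], es,
              if (length(es) > 1L) ee[-length(ee)]),
    end = c(promoter[2], upstream[2], ttsw[2], ee,
            if (length(es) > 1L) es[-1]),
    category = c("promoter", "upstream", "tts_region",
                 rep("exon", length(es)),
                 rep("intron", max(0L, length(es) - 1L))))
  win[, start := pmax(start, 0L)]
  if (!is.na(chrom_size)) win[, end := pmin(end, as.integer(chrom_size))]
  win <- win[start < end]
  win[, `:=`(chrom = g$chrom, gene_id = g$gene_id, tss = as.integer(tss))]
  win[, .(chrom, start = as.integer(start), end = as.integer(end),
          category, gene_id, tss)]
}

#' Build a gene-region index over all genes
#'
#' Concatenated category windows of every gene, keyed for point queries.
#'
#' @param genes A `gene_models`.
#' @param params [annotation_params()].
#' @param sizes Optional named vector of chromosome sizes for clipping.
#' @return A `gene_region_index` (list: windows, genes, params).
#' @export
gene_region_index <- function(genes, params = annotation_params(),
                              sizes = NULL) {
  wl <- lapply(seq_len(nrow(genes)), function(i) {
    cs <- if (is.null(sizes)) NA_integer_ else sizes[[genes$chrom[i]]]
    gene_region_windows(genes[i], params, chrom_size = cs)
  })
  win <- rbindlist(wl)
  prec <- c(promoter = 1L, tts_region = 2L, exon = 3L, intron = 4L,
            upstream = 5L)
  win[, prec := prec[category]]
  setkey(win, chrom, start, end)
  structure(list(windows = win, genes = genes, params = params,
                 sizes = sizes),
            class = "gene_region_index")
}

# classify a table of points (chrom, pos); returns category + gene_id + tss dist
.classify_points <- function(points, index) {
  q <- as.data.table(points)[, .(chrom = as.character(chrom),
                                 start = as.integer(pos),
                                 end = as.integer(pos) + 1L)]
  q[, qid := .I]
  setkey(q, chrom, start, end)
  known <- unique(index$windows$chrom)
  if (length(setdiff(unique(q$chrom), known)))
    warning("classify: chromosome(s) absent from index treated as intergenic: ",
            paste(setdiff(unique(q$chrom), known), collapse = ", "))
  hits <- foverlaps(q[chrom %in% known], index$windows,
                    by.x = c("chrom", "start", "end"), nomatch = NULL)
  res <- data.table(qid = seq_len(nrow(q)),
                    category = "intergenic", gene_id = NA_character_,
                    tss_distance = NA_integer_)
  if (nrow(hits)) {
    hits[, d_tss := abs(i.start - tss)]
    setorder(hits, qid, prec, d_tss, gene_id)
    best <- hits[, .SD[1L], by = qid]
    res[best$qid, `:=`(category = best$category, gene_id = best$gene_id,
                       tss_distance = as.integer(best$d_tss))]
  }
  res[order(qid)]
}

#' Classify peaks into the six genomic categories
#'
#' Each peak is classified at a single point: its summit when recorded, else
#' the interval midpoint (`mode = "point"`). `mode = "largest_overlap"`
#' instead assigns the category whose windows overlap the peak interval by
#' the most bases (same precedence on ties). Exactly one label per peak;
#' non-intergenic labels carry the classifying gene.
#'
#' @param peaks A `peak_set`.
#' @param index A [gene_region_index()].
#' @param mode "point" (default) or "largest_overlap".
#' @return data.table: peak name, category, gene_id, tss_distance.
#' @export
classify_peaks <- function(peaks, index, mode = c("point", "largest_overlap")) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0L)
    return(data.table(name = character(), category = character(),
                      gene_id = character(), tss_distance = integer()))
  if (mode == "point") {
    res <- .classify_points(data.table(chrom = peaks$chrom,
                                       pos = peak_points(peaks)), index)
    return(data.table(name = peaks$name, category = res$category,
                      gene_id = res$gene_id, tss_distance = res$tss_distance))
  }
  q <- data.table(chrom = peaks$chrom, start = peaks$start, end = peaks$end)
  q[, qid := .I]
  setkey(q, chrom, start, end)
  hits <- foverlaps(q, index$windows,
                    by.x = c("chrom", "start", "end"), nomatch = NULL)
  res <- data.table(qid = seq_len(nrow(q)), category = "intergenic",
                    gene_id = NA_character_, tss_distance = NA_integer_)
  if (nrow(hits)) {
    hits[, ov := pmin(i.end, end) - pmax(i.start, start)]
    hits[, d_tss := abs((i.start + i.end) %/% 2L - tss)]
    setorder(hits, qid, -ov, prec, d_tss, gene_id)
    best <- hits[, .SD[1L], by = qid]
    res[best$qid, `:=`(category = best$category, gene_id = best$gene_id,
                       tss_distance = as.integer(best$d_tss))]
  }
  res <- res[order(qid)]
  data.table(name = peaks$name, category = res$category,
             gene_id = res$gene_id, tss_distance = res$tss_distance)
}

#' Category counts and fractions
#'
#' @param annotation Output of [classify_peaks()] (or any table with a
#'   `category` column).
#' @return data.table: category, count, fraction over the six levels (empty
#'   input gives an empty table, not division by zero).
#' @export
category_distribution <- function(annotation) {
  if (nrow(annotation) == 0L)
    return(data.table(category = character(), count = integer(),
                      fraction = numeric()))
  counts <- annotation[, .N, by = category]
  out <- data.table(category = .ct_categories)
  out <- merge(out, counts, by = "category", all.x = TRUE, sort = FALSE)
  out[is.na(N), N := 0L]
  out[, .(category, count = N, fraction = N / sum(N))]
}

#' Associate peaks with genes
#'
#' Non-intergenic peaks map to their classifying gene. Intergenic peaks map
#' to the nearest TSS when within `max_distance`, else stay unassigned
#' (the default: `max_distance = 0`).
#'
#' @param peaks A `peak_set`.
#' @param index A [gene_region_index()].
#' @param max_distance Maximum point-to-TSS distance for rescuing intergenic
#'   peaks (default 0 = never).
#' @param annotation Optional precomputed [classify_peaks()] output.
#' @return data.table: name, gene_id (NA = unassigned), category.
#' @export
associate_peaks_to_genes <- function(peaks, index, max_distance = 0L,
                                     annotation = NULL) {
  if (is.null(annotation)) annotation <- classify_peaks(peaks, index)
  out <- copy(annotation)
  if (max_distance > 0L && any(out$category == "intergenic")) {
    tssdt <- data.table(chrom = index$genes$chrom, tss = gene_tss(index$genes),
                        gene_id = index$genes$gene_id)
    pts <- peak_points(peaks)
    ig <- which(out$category == "intergenic")
    for (i in ig) {
      cand <- tssdt[chrom == peaks$chrom[i]]
      if (!nrow(cand)) next
      cand[, d_tss := abs(tss - pts[i])]
      setorder(cand, d_tss, gene_id)
      if (cand$d_tss[1] <= max_distance) {
        out[i, gene_id := cand$gene_id[1]]
        out[i, tss_distance := as.integer(cand$d_tss[1])]
      }
    }
  }
  out[]
}
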