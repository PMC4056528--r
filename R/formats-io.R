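# Readers/writers for the external plain-text formats the pipeline touches:
# BED4/5/6(+summit), BED12, refFlat-like TSV, bedGraph (+ fixed-step WIG),
# MEME minimal motif format, TSV expression matrix, FASTA (via Biostrings).

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

.split_fields <- function(lines, path) {
  strsplit(lines, "\t", fixed = TRUE)
}

.is_comment <- function(lines) {
  grepl("^(#|track|browser)", lines) | !nzchar(trimws(lines))
}

#' Read peaks from a BED file
#'
#' Accepts BED with at least 5 columns: chrom, start, end, name, score.
#' With `score_is_neglog10p = TRUE` (default) the score column is the
#' MACS-style -log10 p-value. An optional 6th numeric column is the summit
#' offset relative to start, and an optional 7th the read count (a 6-column
#' file whose 6th column is `+`/`-`/`.` is treated as stranded BED6 and the
#' strand is ignored). Sub-threshold peaks are flagged, not dropped.
#'
#' @param path BED file path.
#' @param score_is_neglog10p Interpret column 5 as -log10 p (default TRUE).
#' @param threshold Retention threshold on -log10 p (default 10).
#' @return A [peak_set()].
#' @export
read_peaks_bed <- function(path, score_is_neglog10p = TRUE, threshold = 10) {
  lines <- .read_lines_checked(path)
  keep <- !.is_comment(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(peak_set(data.table(chrom = character(), start = integer(),
                               end = integer()), threshold = threshold))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop(sprintf("read_peaks_bed: malformed line %d in %s (need >= 5 fields, got %d)",
                 lineno[which(nf < 5L)[1]], path, min(nf)))
  f <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  score <- suppressWarnings(as.numeric(f(5)))
  bad <- which(is.na(start) | is.na(end) | is.na(score))
  if (length(bad))
    stop(sprintf("read_peaks_bed: malformed line %d in %s (non-numeric field)",
                 lineno[bad[1]], path))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("read_peaks_bed: start >= end at line %d in %s",
                 lineno[bad[1]], path))
  fopt <- function(i) vapply(fields, function(x)
    if (length(x) >= i) x[[i]] else NA_character_, "")
  summit <- rep(NA_integer_, length(lines))
  rc <- rep(NA_real_, length(lines))
  col6 <- fopt(6)
  have6 <- !is.na(col6)
  if (any(have6) && !all(col6[have6] %in% c("+", "-", ".")))
    summit <- suppressWarnings(as.integer(col6))
  rc <- suppressWarnings(as.numeric(fopt(7)))
  summit[!is.na(summit) & summit < 0L] <- NA_integer_   # -1 sentinel = absent
  rc[!is.na(rc) & rc < 0] <- NA_real_
  dt <- data.table(chrom = f(1), start = start, end = end, name = f(4),
                   neglog10_p = if (score_is_neglog10p) score else NA_real_,
                   summit_offset = summit, read_count = rc)
  if (!score_is_neglog10p) dt[, score := score]
  peak_set(dt, threshold = threshold)
}

#' Write peaks to BED
#'
#' Columns: chrom, start, end, name, -log10 p, summit offset, read count.
#' Round-trips through [read_peaks_bed()].
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.table(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    peaks$neglog10_p,
                    ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset),
                    ifelse(is.na(peaks$read_count), -1, peaks$read_count))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models (BED12 or refFlat-like)
#'
#' `dialect = "bed12"`: standard BED12 with blockCount/blockSizes/blockStarts
#' (0-based half-open). `dialect = "refflat"`: tab format
#' geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds with comma-separated exon lists; refFlat
#' coordinates are already 0-based half-open as deposited by UCSC.
#'
#' @param path Input path.
#' @param dialect "bed12" (default) or "refflat".
#' @return A [gene_models()].
#' @export
read_gene_models <- function(path, dialect = c("bed12", "refflat")) {
  dialect <- match.arg(dialect)
  lines <- .read_lines_checked(path)
  keep <- !.is_comment(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("read_gene_models: no records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  f <- function(i) vapply(fields, `[[`, "", i)
  if (dialect == "bed12") {
    if (any(lengths(fields) < 12L))
      stop(sprintf("read_gene_models: line %d has < 12 fields",
                   lineno[which(lengths(fields) < 12L)[1]]))
    txs <- as.integer(f(2)); txe <- as.integer(f(3))
    nblocks <- as.integer(f(10))
    sizes <- strsplit(f(11), ",", fixed = TRUE)
    starts <- strsplit(f(12), ",", fixed = TRUE)
    es <- vector("list", length(lines)); ee <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      sz <- as.integer(sizes[[i]]); st <- as.integer(starts[[i]])
      if (length(sz) != nblocks[i] || length(st) != nblocks[i])
        stop(sprintf("read_gene_models: block count mismatch at line %d (blockCount %d, %d sizes, %d starts)",
                     lineno[i], nblocks[i], length(sz), length(st)))
      es[[i]] <- txs[i] + st
      ee[[i]] <- txs[i] + st + sz
      if (st[1] != 0L || es[[i]][nblocks[i]] + sz[nblocks[i]] != txe[i])
        stop(sprintf("read_gene_models: block arithmetic inconsistent at line %d",
                     lineno[i]))
    }
    gene_models(data.table(gene_id = f(4), chrom = f(1), strand = f(6),
                           tx_start = txs, tx_end = txe,
                           exon_starts = es, exon_ends = ee))
  } else {
    if (any(lengths(fields) < 11L))
      stop(sprintf("read_gene_models: refflat line %d has < 11 fields",
                   lineno[which(lengths(fields) < 11L)[1]]))
    es <- lapply(strsplit(f(10), ",", fixed = TRUE), as.integer)
    ee <- lapply(strsplit(f(11), ",", fixed = TRUE), as.integer)
    gene_models(data.table(gene_id = f(1), chrom = f(3), strand = f(4),
                           tx_start = as.integer(f(5)), tx_end = as.integer(f(6)),
                           exon_starts = es, exon_ends = ee))
  }
}

#' Write gene models as BED12
#' @param genes A `gene_models`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    paste(genes$chrom[i], genes$tx_start[i], genes$tx_end[i],
          genes$gene_id[i], 0, genes$strand[i],
          genes$tx_start[i], genes$tx_end[i], "0",
          length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read a bedGraph (or fixed-step WIG) signal track
#'
#' bedGraph: chrom, start, end, value (0-based half-open). Fixed-step WIG
#' blocks (`fixedStep chrom=... start=... step=... [span=...]`, 1-based) are
#' converted to bedGraph segments on read; variable-step WIG is rejected.
#' Overlapping segments are a validation error.
#'
#' @param path Input path.
#' @return A [signal_track()].
#' @export
read_signal_bedgraph <- function(path) {
  lines <- .read_lines_checked(path)
  keep <- !.is_comment(lines)
  lines <- lines[keep]
  if (any(grepl("^variableStep", lines)))
    stop("read_signal_bedgraph: variable-step WIG is not supported; convert to bedGraph")
  fs <- grep("^fixedStep", lines)
  if (length(fs)) {
    segs <- list()
    bounds <- c(fs, length(lines) + 1L)
    for (i in seq_along(fs)) {
      hdr <- lines[fs[i]]
      getp <- function(k, default = NA) {
        m <- regmatches(hdr, regexec(paste0(k, "=([^ \t]+)"), hdr))[[1]]
        if (length(m) < 2) default else m[2]
      }
      chrom <- getp("chrom")
      start1 <- as.integer(getp("start"))
      step <- as.integer(getp("step", "1"))
      span <- as.integer(getp("span", "1"))
      vals <- as.numeric(lines[(fs[i] + 1L):(bounds[i + 1L] - 1L)])
      st <- start1 - 1L + step * (seq_along(vals) - 1L)
      segs[[i]] <- data.table(chrom = chrom, start = st, end = st + span,
                              value = vals)
    }
    return(signal_track(rbindlist(segs)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) == 0L)
    return(signal_track(data.table(chrom = character(), start = integer(),
                                   end = integer(), value = numeric())))
  if (any(lengths(fields) < 4L))
    stop("read_signal_bedgraph: need 4 columns in ", path)
  f <- function(i) vapply(fields, `[[`, "", i)
  signal_track(data.table(chrom = f(1), start = as.integer(f(2)),
                          end = as.integer(f(3)), value = as.numeric(f(4))))
}

#' Write a signal track as bedGraph
#' @param track A `signal_track`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_signal_bedgraph <- function(track, path) {
  fwrite(as.data.table(track)[, .(chrom, start, end, value)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a MEME minimal-format motif
#'
#' Parses the first MOTIF block's letter-probability matrix and the
#' background letter frequencies (uniform if absent). Rows are renormalized
#' to sum to 1 (within 1e-9) before pseudocount regularization in
#' [pwm_record()]. Alphabets other than ACGT are rejected.
#'
#' @param path MEME minimal format file.
#' @param pseudocount Passed to [pwm_record()] (default 0.01).
#' @return A [pwm_record()].
#' @export
read_motif_meme <- function(path, pseudocount = 0.01) {
  lines <- .read_lines_checked(path)
  al <- grep("^ALPHABET", lines, value = TRUE)
  if (length(al) && !grepl("ACGT", al[1]))
    stop("read_motif_meme: unsupported alphabet (need ACGT): ", al[1])
  background <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) && bg_i[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      bmap <- setNames(as.numeric(toks[seq(2, 8, 2)]), toks[seq(1, 7, 2)])
      if (!all(c("A", "C", "G", "T") %in% names(bmap)))
        stop("read_motif_meme: unsupported alphabet in background line")
      background <- unname(bmap[c("A", "C", "G", "T")])
      background <- background / sum(background)
    }
  }
  mi <- grep("^MOTIF", lines)
  if (!length(mi)) stop("read_motif_meme: no MOTIF block in ", path)
  li <- grep("^letter-probability matrix", lines)
  li <- li[li > mi[1]][1]
  if (is.na(li)) stop("read_motif_meme: no letter-probability matrix")
  rows <- list()
  i <- li + 1L
  while (i <= length(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 4L || anyNA(vals)) break
    rows[[length(rows) + 1L]] <- vals
    i <- i + 1L
  }
  probs <- do.call(rbind, rows)
  if (is.null(probs) || nrow(probs) < 4)
    stop("read_motif_meme: matrix too short (width >= 4 required)")
  probs <- probs / rowSums(probs)          # renormalize rows to sum 1
  pwm_record(probs, background = background, pseudocount = pseudocount)
}

#' Write a PWM in MEME minimal format
#' @param pwm A `pwm_record`.
#' @param path Output path.
#' @param name Motif name (default "motif_1").
#' @return Invisibly, the path.
#' @export
write_motif_meme <- function(pwm, path, name = "motif_1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       pwm$background[1], pwm$background[2],
                       pwm$background[3], pwm$background[4]), "",
               paste("MOTIF", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 100 E= 0",
                       pwm$width)), con)
  writeLines(apply(pwm$probs, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                     r[1], r[2], r[3], r[4])), con)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column gene id, remaining columns numeric sample intensities
#' (log2 scale). `condition_map` is a named list mapping condition name to
#' the sample (column) names belonging to it; every mapped sample must be
#' present in the header.
#'
#' @param path TSV path with header.
#' @param condition_map Named list of character vectors of sample names.
#' @return An [expression_matrix()] restricted to the mapped samples.
#' @export
read_expression_table <- function(path, condition_map) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1))
  ids <- dt[[1]]
  if (anyDuplicated(ids))
    stop("read_expression_table: duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(mat)) {
    badcol <- names(dt)[-1][!vapply(dt[, -1, with = FALSE], is.numeric, TRUE)][1]
    badrow <- which(is.na(suppressWarnings(as.numeric(dt[[badcol]]))))[1]
    stop(sprintf("read_expression_table: non-numeric value in column %s (gene %s)",
                 badcol, ids[badrow]))
  }
  rownames(mat) <- ids
  samples <- unlist(condition_map, use.names = FALSE)
  missing <- setdiff(samples, colnames(mat))
  if (length(missing))
    stop("read_expression_table: samples in condition_map absent from header: ",
         paste(missing, collapse = ", "))
  cond <- rep(names(condition_map), lengths(condition_map))
  expression_matrix(mat[, samples, drop = FALSE], cond)
}

#' Write an expression matrix as TSV
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_expression_table <- function(expr, path) {
  dt <- data.table(gene_id = expr$gene_ids)
  dt <- cbind(dt, as.data.table(expr$values))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80)
  invisible(path)
}

#' Chromosome sizes of a genome
#' @param genome A `DNAStringSet` or named numeric vector.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_sizes <- function(genome) {
  if (is.numeric(genome)) return(vapply(genome, as.integer, 1L))
  setNames(Biostrings::width(genome), names(genome))
}
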