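# Cross-time-point consensus regions and presence/absence clustering.
# Peaks overlapping by >= 1 bp across the T peak sets are merged by single
# linkage; each consensus region carries a presence vector over time points
# and a per-time intensity: log2(1 + sum(read counts) * 1e7 / library size),
# i.e. the base-2 log of summed read counts per 10 million reads, with a
# pseudocount of 1 so times with no peak map to 0.

#' Depth-normalized log2 intensity
#'
#' `log2(1 + read_count * 1e7 / library_size)`: read counts are scaled to a
#' 10-million-read library before the log; the pseudocount of 1 sends zero
#' reads to exactly 0.
#'
#' @param read_count Read count(s), >= 0.
#' @param library_size Sequencing depth the counts came from (> 0).
#' @return Numeric vector of intensities.
#' @examples
#' normalize_intensity(1023, 1e7)  # log2(1024) = 10
#' @export
normalize_intensity <- function(read_count, library_size = 1e7) {
  if (any(library_size <= 0)) stop("normalize_intensity: library_size must be > 0")
  if (any(read_count < 0, na.rm = TRUE)) stop("normalize_intensity: negative read_count")
  log2(1 + read_count * 1e7 / library_size)
}

#' Merge per-time peak sets into consensus regions
#'
#' Single-linkage merge of peaks overlapping by at least `min_overlap` bases
#' across all time points. Each region records which time points contribute
#' a peak (presence vector), the per-time intensity
#' (via [normalize_intensity()] on the summed member read counts), and the
#' member peak names.
#'
#' @param peak_sets List of T `peak_set`s, one per time point, in temporal
#'   order.
#' @param library_sizes Numeric vector of T library sizes (default 1e7 each).
#' @param time_labels Labels for the time points (default d0, d9, d28 when
#'   T = 3, else t1..tT).
#' @param min_overlap Minimum overlap in bases to link two peaks (default 1).
#' @return data.table of consensus regions: chrom, start, end, summit (the
#'   summit of the strongest member peak, for point classification),
#'   region_id, presence (e.g. "101"), per-time intensity columns, n_peaks,
#'   member list-column.
#' @export
build_consensus <- function(peak_sets, library_sizes = NULL,
                            time_labels = NULL, min_overlap = 1L) {
  T_ <- length(peak_sets)
  if (T_ < 1L) stop("build_consensus: need at least one peak set")
  if (is.null(library_sizes)) library_sizes <- rep(1e7, T_)
  if (is.null(time_labels))
    time_labels <- if (T_ == 3L) c("d0", "d9", "d28") else paste0("t", seq_len(T_))
  all_pk <- rbindlist(lapply(seq_len(T_), function(t) {
    p <- peak_sets[[t]]
    data.table(chrom = p$chrom, start = p$start, end = p$end,
               name = p$name, read_count = p$read_count,
               summit_abs = peak_points(p), time_idx = t)
  }))
  if (nrow(all_pk) == 0L)
    stop("build_consensus: no peaks in any set")
  setorder(all_pk, chrom, start, end)
  # single-linkage sweep: new component when gap >= (1 - min_overlap) bases
  all_pk[, cummax_end := cummax(end), by = chrom]
  all_pk[, prev_end := shift(cummax_end), by = chrom]
  all_pk[, newgrp := is.na(prev_end) | (start - prev_end > -min_overlap)]
  all_pk[, grp := cumsum(newgrp), by = chrom]
  all_pk[, region_id := .GRP, by = .(chrom, grp)]
  reg <- all_pk[, .(chrom = chrom[1], start = min(start), end = max(end),
                    summit = summit_abs[which.max(fifelse(is.na(read_count),
                                                          -1, read_count))],
                    members = list(name),
                    n_peaks = .N), by = region_id]
  pres <- all_pk[, .(present = TRUE), by = .(region_id, time_idx)]
  rc <- all_pk[, .(rc = sum(read_count, na.rm = TRUE)), by = .(region_id, time_idx)]
  pres_mat <- matrix(FALSE, nrow(reg), T_)
  rc_mat <- matrix(0, nrow(reg), T_)
  ridx <- match(pres$region_id, reg$region_id)
  pres_mat[cbind(ridx, pres$time_idx)] <- TRUE
  rc_mat[cbind(match(rc$region_id, reg$region_id), rc$time_idx)] <- rc$rc
  inten <- sapply(seq_len(T_), function(t)
    normalize_intensity(rc_mat[, t], library_sizes[t]))
  inten <- matrix(inten, nrow = nrow(reg))
  reg[, presence := apply(pres_mat, 1, function(v) paste(as.integer(v), collapse = ""))]
  for (t in seq_len(T_))
    reg[, (paste0("intensity_", time_labels[t])) := inten[, t]]
  reg[, region_id := sprintf("region_%d", seq_len(.N))]
  setattr(reg, "time_labels", time_labels)
  setorder(reg, chrom, start)[]
}

#' Canonical presence-pattern cluster numbering (T = 3)
#'
#' Bijection between the seven non-empty presence patterns over (d0, d9,
#' d28) and cluster ids 1..7: 1 = 111, 2 = 110, 3 = 101, 4 = 011, 5 = 001,
#' 6 = 010, 7 = 100.
#'
#' @return Named integer vector: pattern string -> cluster id.
#' @export
temporal_cluster_map <- function() {
  c("111" = 1L, "110" = 2L, "101" = 3L, "011" = 4L,
    "001" = 5L, "010" = 6L, "100" = 7L)
}

#' Assign presence/absence cluster ids
#'
#' @param regions Output of [build_consensus()] with T = 3 presence strings.
#' @return The regions table with a `cluster_id` column added.
#' @export
assign_temporal_clusters <- function(regions) {
  map <- temporal_cluster_map()
  if (any(!regions$presence %in% names(map))) {
    bad <- setdiff(unique(regions$presence), names(map))
    stop("assign_temporal_clusters: invalid presence pattern(s): ",
         paste(bad, collapse = ", "), " (T = 3, at least one time present)")
  }
  regions[, cluster_id := map[presence]]
  regions[]
}

#' Per-cluster intensity summary
#'
#' Mean +/- SEM of the per-time intensities within each cluster, with the
#' region count. SEM = sd / sqrt(n); clusters with n = 1 report SEM 0 and
#' are flagged. Empty clusters are omitted.
#'
#' @param regions Clustered regions from [assign_temporal_clusters()].
#' @return data.table: cluster_id, time, n, mean_intensity, sem, single_region
#'   flag.
#' @export
cluster_summary <- function(regions) {
  labs <- attr(regions, "time_labels")
  if (is.null(labs))
    labs <- sub("^intensity_", "", grep("^intensity_", names(regions), value = TRUE))
  long <- rbindlist(lapply(labs, function(l)
    data.table(cluster_id = regions$cluster_id, time = l,
               intensity = regions[[paste0("intensity_", l)]])))
  out <- long[, .(n = .N,
                  mean_intensity = mean(intensity),
                  sem = if (.N > 1L) sd(intensity) / sqrt(.N) else 0,
                  single_region = .N == 1L),
              by = .(cluster_id, time)]
  out[, time := factor(time, levels = labs)]
  setorder(out, cluster_id, time)[]
}

#' Write consensus regions as BED6-plus
#'
#' BED6 (name = region id, score = cluster id, strand = '.') plus presence
#' string and per-time intensities.
#'
#' @param regions Clustered regions.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_consensus_bed <- function(regions, path) {
  labs <- attr(regions, "time_labels")
  cols <- paste0("intensity_", labs)
  out <- data.table(regions$chrom, regions$start, regions$end,
                    regions$region_id, regions$cluster_id, ".",
                    regions$presence)
  for (cc in cols) out[[cc]] <- regions[[cc]]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
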