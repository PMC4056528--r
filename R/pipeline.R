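# End-to-end orchestration: read inputs named by a plain key=value config,
# run annotate -> temporal clustering -> enrichment -> motif scan ->
# metagene -> integration, and emit one TSV per figure-level analysis plus
# a run manifest (config snapshot, input checksums, seed, timings).

#' Read a plain key=value config file
#'
#' Lines of `key=value`; blank lines and `#` comments ignored. Values that
#' parse as numbers become numeric.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- .read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)\\s*$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("read_config: malformed line: ", lines[bad][1])
  vals <- lapply(kv, function(m) {
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, `[[`, "", 2))
}

#' Default pipeline configuration
#'
#' Analysis thresholds, each traceable to the study design:
#' peak retention -log10 p >= 10 (P < 1e-10), motif p < 1e-4, fold-change
#' threshold 1.5 with FDR < 0.05, library normalization to 10 million
#' reads.
#'
#' @param input_dir Directory holding the input files (layout of
#'   [simulate_study()]).
#' @param output_dir Report directory.
#' @param seed Seed for the random-background sampling.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(input_dir, output_dir, seed = 1L) {
  list(input_dir = input_dir, output_dir = output_dir, seed = seed,
       peak_neglog10p = 10, motif_p = 1e-4, fc_threshold = 1.5,
       fdr_threshold = 0.05, library_size = 1e7, ratio_floor = 0.5,
       background_length = 100L)
}

.stage_names <- c("annotate", "cluster", "enrich", "scan", "p2g", "integrate")

#' Run the full analysis pipeline
#'
#' Executes the stages on a [simulate_study()]-layout input directory (or
#' any directory with the same file names) and writes the report tables:
#' category_distribution, category_enrichment, summit_profile,
#' consensus_regions, cluster_summary, cluster_category, de_table,
#' peaks_per_gene, category_comparison, foldchange_by_location,
#' window_profiles, window_tests, conservation (all .tsv), plus
#' manifest.txt.
#'
#' @param config List from [pipeline_config()] or a key=value file path.
#' @param stages Stages to run (default all; later stages fail fast if a
#'   dependency was skipped).
#' @return Invisibly, a list: manifest, tables (named list of data.tables).
#' @export
run_pipeline <- function(config, stages = .stage_names) {
  if (is.character(config)) config <- read_config(config)
  ind <- config$input_dir
  outd <- config$output_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)
  need <- c("genome.fa", "genes.bed12", "peaks_d0.bed", "peaks_d9.bed",
            "peaks_d28.bed", "ip_d9.bedgraph", "input.bedgraph",
            "conservation.bedgraph", "motif.meme", "expression.tsv")
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing))
    stop("run_pipeline: missing input file(s): ", paste(missing, collapse = ", "))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  tables <- list()
  emit <- function(name, dt) {
    tables[[name]] <<- dt
    fwrite(dt, file.path(outd, paste0(name, ".tsv")), sep = "\t")
  }

  genome <- read_genome_fasta(file.path(ind, "genome.fa"))
  sizes <- chrom_sizes(genome)
  genes <- read_gene_models(file.path(ind, "genes.bed12"), "bed12")
  labels <- c("d0", "d9", "d28")
  peaksets <- lapply(labels, function(l)
    filter_peaks(read_peaks_bed(file.path(ind, paste0("peaks_", l, ".bed")),
                                threshold = config$peak_neglog10p)))
  names(peaksets) <- labels
  index <- gene_region_index(genes, sizes = sizes)
  tick("load")

  annotations <- NULL
  if ("annotate" %in% stages) {
    annotations <- lapply(peaksets, classify_peaks, index = index)
    dist <- rbindlist(lapply(labels, function(l) {
      d <- category_distribution(annotations[[l]])
      d[, time := l]
      d
    }))
    emit("category_distribution", dist)
    tick("annotate")
  }

  regions <- NULL
  if ("cluster" %in% stages) {
    regions <- assign_temporal_clusters(build_consensus(
      peaksets, library_sizes = rep(config$library_size, 3),
      time_labels = labels))
    emit("consensus_regions",
         regions[, .(chrom, start, end, summit, region_id, cluster_id,
                     presence, intensity_d0, intensity_d9, intensity_d28,
                     n_peaks)])
    emit("cluster_summary", cluster_summary(regions))
    tick("cluster")
  }

  if ("enrich" %in% stages) {
    if (is.null(annotations)) stop("run_pipeline: 'enrich' needs the 'annotate' stage")
    set.seed(config$seed)
    enr <- rbindlist(lapply(labels, function(l) {
      bg <- sample_random_intervals(sizes, n = nrow(peaksets[[l]]),
                                    length = config$background_length)
      e <- category_enrichment(peaksets[[l]], bg, index)
      e[, time := l]
      e
    }))
    emit("category_enrichment", enr)
    if (!is.null(regions)) {
      cl_ann <- classify_peaks(
        peak_set(regions[, .(chrom, start, end, name = region_id,
                             summit_offset = summit - start)],
                 threshold = 0), index)
      cl_cat <- data.table(region_id = cl_ann$name, category = cl_ann$category,
                           cluster_id = regions$cluster_id)
      bg <- sample_random_intervals(sizes, n = nrow(regions),
                                    length = config$background_length)
      bgd <- category_distribution(
        .classify_points(data.table(chrom = bg$chrom,
                                    pos = (bg$start + bg$end) %/% 2L), index))
      cc <- cl_cat[, .N, by = .(cluster_id, category)]
      cc[, fraction := N / sum(N), by = cluster_id]
      bgd[, cluster_id := 0L]               # cluster 0 = random background
      emit("cluster_category",
           rbind(cc[, .(cluster_id, category, count = N, fraction)],
                 bgd[, .(cluster_id, category, count, fraction)]))
    }
    tick("enrich")
  }

  hits <- best3 <- NULL
  pwm <- read_motif_meme(file.path(ind, "motif.meme"))
  if ("scan" %in% stages) {
    pfun <- exact_score_pvalue(pwm)
    hits <- scan_sequences(pwm, genome, p_threshold = config$motif_p,
                           pfun = pfun)
    fwrite(hits, file.path(outd, "motif_hits.bed"), sep = "\t",
           col.names = FALSE)
    combined <- peak_set(rbindlist(lapply(peaksets, function(p)
      as.data.table(p)[, .(chrom, start, end, name, neglog10_p,
                           summit_offset, read_count)])),
      threshold = config$peak_neglog10p)
    best3 <- best_site_per_peak(combined, hits)
    prof <- summit_distance_profile(peaksets$d9,
                                    best_site_per_peak(peaksets$d9, hits))
    emit("summit_profile", prof)
    tables$combined_peaks <- combined
    tick("scan")
  }

  profiles <- NULL
  if ("p2g" %in% stages) {
    ip <- read_signal_bedgraph(file.path(ind, "ip_d9.bedgraph"))
    input <- read_signal_bedgraph(file.path(ind, "input.bedgraph"))
    wsr <- window_signal_ratio(genes, ip, input, floor = config$ratio_floor,
                               sizes = sizes)
    profiles <- wsr$profiles
    emit("window_profiles", profiles)
    tick("p2g")
  }

  if ("integrate" %in% stages) {
    if (is.null(annotations)) stop("run_pipeline: 'integrate' needs the 'annotate' stage")
    if (is.null(regions)) stop("run_pipeline: 'integrate' needs the 'cluster' stage")
    if (is.null(best3)) stop("run_pipeline: 'integrate' needs the 'scan' stage")
    if (is.null(profiles)) stop("run_pipeline: 'integrate' needs the 'p2g' stage")
    expr <- read_expression_table(
      file.path(ind, "expression.tsv"),
      .expression_condition_map(file.path(ind, "expression.tsv")))
    de <- classify_genes(moderated_t_de(expr, "shTF", "Scr"),
                         fc_threshold = config$fc_threshold,
                         fdr_threshold = config$fdr_threshold)
    emit("de_table", de)
    classes <- de[, .(gene_id, gene_class)]

    combined <- tables$combined_peaks
    assoc_all <- associate_peaks_to_genes(combined, index)
    assoc_t <- lapply(labels, function(l)
      associate_peaks_to_genes(peaksets[[l]], index,
                               annotation = annotations[[l]]))
    names(assoc_t) <- labels
    counts <- count_peaks_per_gene(
      c(list(all = assoc_all), assoc_t), genes$gene_id)
    emit("peaks_per_gene", peaks_per_gene_test(counts, classes))

    catcmp <- rbindlist(lapply(c("up", "down"), function(cl) {
      ga <- classes[gene_class == cl, gene_id]
      gb <- classes[gene_class == "nonresponsive", gene_id]
      ca <- table(assoc_all[gene_id %in% ga, category])
      cb <- table(assoc_all[gene_id %in% gb, category])
      r <- compare_category_distributions(ca, cb)
      r[, gene_class := cl]
      r
    }))
    emit("category_comparison", catcmp)

    reg_ann <- classify_peaks(
      peak_set(regions[, .(chrom, start, end, name = region_id,
                           summit_offset = summit - start)],
               threshold = 0), index)
    reg_tab <- data.table(gene_id = reg_ann$gene_id,
                          category = reg_ann$category,
                          intensity_d0 = regions$intensity_d0,
                          intensity_d9 = regions$intensity_d9)
    emit("foldchange_by_location",
         foldchange_by_location(reg_tab[!is.na(gene_id)], classes))

    wtests <- rbindlist(lapply(c("up", "down"), function(cl) {
      r <- group_window_test(profiles, classes[gene_class == cl, gene_id],
                             classes[gene_class == "nonresponsive", gene_id])
      r[, gene_class := cl]
      r
    }))
    emit("window_tests", wtests)
    emit("binding_bins", binding_level_bins(profiles))

    cons <- read_signal_bedgraph(file.path(ind, "conservation.bedgraph"))
    gc_all <- gene_conservation(assoc_all, best3, cons, combined)
    glen <- setNames(genes$tx_end - genes$tx_start, genes$gene_id)
    set.seed(config$seed + 1L)
    ks_rows <- rbindlist(lapply(c("down", "up"), function(cl) {
      tg <- intersect(classes[gene_class == cl, gene_id], gc_all$gene_id)
      pool <- intersect(classes[gene_class == "nonresponsive", gene_id],
                        gc_all$gene_id)
      if (length(tg) < 3L || length(pool) < length(tg))
        return(data.table(gene_class = cl, n = length(tg), D = NA_real_,
                          p = NA_real_, mean_target = NA_real_,
                          mean_control = NA_real_))
      mc <- length_matched_controls(tg, pool, glen)
      a <- gc_all[gene_id %in% tg]
      b <- gc_all[gene_id %in% mc$control]
      ks <- conservation_ks(a, b)
      data.table(gene_class = cl, n = length(tg), D = ks$statistic,
                 p = ks$p_value, mean_target = mean(a$mean_phylop),
                 mean_control = mean(b$mean_phylop))
    }))
    emit("conservation_genes", gc_all)
    emit("conservation_ks", ks_rows)
    tick("integrate")
  }

  manifest <- c(
    sprintf("seed=%s", config$seed),
    sprintf("input_dir=%s", ind),
    sprintf("output_dir=%s", outd),
    paste0("stage_seconds_", names(timings), "=", unlist(timings)),
    paste0("md5_", need, "=", tools::md5sum(file.path(ind, need))),
    paste0("threshold_", c("peak_neglog10p", "motif_p", "fc_threshold",
                           "fdr_threshold"), "=",
           c(config$peak_neglog10p, config$motif_p, config$fc_threshold,
             config$fdr_threshold)))
  writeLines(manifest, file.path(outd, "manifest.txt"))
  invisible(list(manifest = manifest, tables = tables))
}

# infer the Scr/shTF condition map from an expression table header
.expression_condition_map <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]][-1]
  conds <- sub("_[0-9]+$", "", hdr)
  split(hdr, conds)
}
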