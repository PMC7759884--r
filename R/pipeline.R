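# End-to-end orchestration: qc -> k-mer survey -> assembly -> GC-depth
# profiling -> stray extraction -> contaminant labelling -> read
# decontamination -> re-survey/re-assembly -> SSRs -> report. Every stage
# is also reachable as a CLI subcommand so intermediates stay inspectable.

#' Pipeline configuration
#'
#' Bundles per-stage settings. Inputs are either a simulation (the
#' `simulate` section) or paired FASTQ paths. Contaminant labelling needs
#' either an external tabular hit file plus a taxon-category map, or (for
#' simulated data) references against which hits are fabricated.
#'
#' @param simulate a [simulation_config()], or `NULL` when reading FASTQ.
#' @param fastq1,fastq2 paired FASTQ paths (ignored when simulating).
#' @param qc a [qc_config()].
#' @param kmer_k k-mer size for the spectrum (default 17).
#' @param assembly an [assembly_config()].
#' @param regions list of [stray_region()]s to extract.
#' @param hits_path optional tabular hit file for stray contigs.
#' @param taxon_map named character vector mapping taxon labels to
#'   `"host"` / `"microbe"`.
#' @param db_k contaminant database k-mer size (default 17).
#' @param share_threshold read-removal k-mer share threshold (default 0.5).
#' @param ssr an [ssr_config()].
#' @param seed global seed (overrides the simulation seed).
#' @param out_dir output directory for intermediates, or `NULL` to keep
#'   everything in memory.
#' @param plots write spectrum and GC-depth PNGs (requires `out_dir`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            fastq1 = NULL, fastq2 = NULL,
                            qc = qc_config(),
                            kmer_k = 17L,
                            assembly = assembly_config(),
                            regions = list(
                              stray_region(57, 80, 0, 20,
                                           label = "high_gc_low_depth")),
                            hits_path = NULL,
                            taxon_map = NULL,
                            db_k = 17L,
                            share_threshold = 0.5,
                            ssr = ssr_config(),
                            seed = NULL,
                            out_dir = NULL,
                            plots = FALSE) {
  cfg <- list(simulate = simulate, fastq1 = fastq1, fastq2 = fastq2,
              qc = qc, kmer_k = as.integer(kmer_k), assembly = assembly,
              regions = regions, hits_path = hits_path,
              taxon_map = taxon_map, db_k = as.integer(db_k),
              share_threshold = share_threshold, ssr = ssr, seed = seed,
              out_dir = out_dir, plots = plots)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$fastq1) || is.null(cfg$fastq2))
      stop("pipeline validation error: no simulation and no FASTQ inputs")
    missing <- c(cfg$fastq1, cfg$fastq2, cfg$hits_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop("pipeline validation error: missing input file(s): ",
           paste(missing, collapse = ", "))
    if (is.null(cfg$hits_path))
      stop("pipeline validation error: FASTQ input requires hits_path ",
           "and taxon_map for contaminant labelling")
  } else {
    validate_simulation_config(cfg$simulate)
    if (!is.null(cfg$seed)) cfg$simulate$seed <- as.integer(cfg$seed)
  }
  if (!is.null(cfg$hits_path) && is.null(cfg$taxon_map))
    stop("pipeline validation error: hits_path requires a taxon_map")
  invisible(cfg)
}

stage_log <- function(log, stage, ...) {
  entry <- list(...)
  log[[stage]] <- entry
  log
}

#' Run the full survey pipeline
#'
#' Executes, in order: read acquisition (simulation or FASTQ), quality
#' filtering, pre-decontamination k-mer survey, unitig assembly and
#' GC-depth profiling, stray-region extraction, contaminant labelling,
#' contaminant-database construction, read decontamination, post-filter
#' re-survey and re-assembly, SSR detection, and report arithmetic. The
#' run is deterministic given the seed; with `out_dir` set, intermediates
#' are written as plain text.
#'
#' @param config a [pipeline_config()].
#' @return list of class `survey_report`; see the elements `qc`,
#'   `estimate_pre`, `estimate_post`, `assembly_pre`, `assembly_post`,
#'   `decontamination`, `ssr`, `arithmetic`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- validate_pipeline_config(config)
  log <- list()
  truth <- NULL
  references <- NULL

  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    if (!is.null(cfg$seed)) sim_cfg$seed <- as.integer(cfg$seed)
    sim <- simulate_sample(sim_cfg)
    pairs <- sim$pairs
    truth <- sim$host$truth
    references <- c(host = sim$host$haplotype_a, sim$contaminant_genomes)
    log <- stage_log(log, "simulate", pairs = nrow(pairs),
                     genomes = length(references))
  } else {
    pairs <- read_fastq(cfg$fastq1, cfg$fastq2)
    log <- stage_log(log, "input", pairs = nrow(pairs))
  }

  flags <- filter_pairs(pairs, cfg$qc)
  stopifnot(sum(flags$keep) + sum(!is.na(flags$reason)) == nrow(pairs))
  clean <- pairs[flags$keep, , drop = FALSE]
  qc <- qc_summary(pairs, flags)
  log <- stage_log(log, "qc", raw = nrow(pairs), clean = nrow(clean),
                   discarded = as.list(qc$discarded))

  hist_pre <- count_kmers(clean, cfg$kmer_k)
  est_pre <- genome_estimate(hist_pre)
  log <- stage_log(log, "kmer_pre", occurrences = n_occurrences(hist_pre),
                   main_peak = est_pre$main_peak_depth)

  contigs <- build_unitigs(clean, cfg$assembly)
  contigs <- annotate_gc_depth(contigs, clean, cfg$assembly$k)
  stats_pre <- contig_stats(contigs, cfg$assembly$min_contig_length_stats)
  dens_pre <- gc_depth_density(
    contigs, min_length = cfg$assembly$min_contig_length_profile)
  stray <- extract_stray(dens_pre$points, cfg$regions)
  log <- stage_log(log, "assembly_pre", contigs = nrow(contigs),
                   profiled = nrow(dens_pre$points), stray = nrow(stray))

  stray_contigs <- contigs[contigs$id %in% unique(stray$id), , drop = FALSE]
  if (!is.null(cfg$hits_path)) {
    hits <- read_blast_tab(cfg$hits_path)
    taxon_map <- cfg$taxon_map
  } else {
    hits <- synthetic_hits(stray_contigs, references)
    taxon_map <- stats::setNames(
      c("host", rep("microbe", length(references) - 1L)),
      names(references))
  }
  labels <- label_contigs(hits, taxon_map, contig_ids = stray_contigs$id)
  microbe_ids <- labels$id[labels$category == "microbe"]
  db <- build_db(contigs[contigs$id %in% microbe_ids, , drop = FALSE],
                 k = cfg$db_k)
  log <- stage_log(log, "label", stray_contigs = nrow(stray_contigs),
                   microbe = length(microbe_ids),
                   db_kmers = length(db$kmers))

  filt <- filter_contaminant_reads(clean, db, cfg$share_threshold)
  stopifnot(nrow(filt$kept) + nrow(filt$removed) == nrow(clean))
  log <- stage_log(log, "decontaminate",
                   removed_pairs = filt$report$removed_pairs,
                   removed_bases = filt$report$removed_bases)

  qc_post <- qc_summary(filt$kept,
                        data.frame(keep = rep(TRUE, nrow(filt$kept)),
                                   reason = NA_character_))
  hist_post <- count_kmers(filt$kept, cfg$kmer_k)
  est_post <- genome_estimate(hist_post)
  contigs_post <- build_unitigs(filt$kept, cfg$assembly)
  contigs_post <- annotate_gc_depth(contigs_post, filt$kept,
                                    cfg$assembly$k)
  stats_post <- contig_stats(contigs_post,
                             cfg$assembly$min_contig_length_stats)
  dens_post <- gc_depth_density(
    contigs_post, min_length = cfg$assembly$min_contig_length_profile)
  log <- stage_log(log, "resurvey", contigs = nrow(contigs_post),
                   main_peak = est_post$main_peak_depth)

  ssr_records <- find_ssrs(contigs_post, cfg$ssr)
  ssr_sum <- summarize_ssrs(ssr_records)
  log <- stage_log(log, "ssr", records = nrow(ssr_records))

  arithmetic <- report_arithmetic(
    revised_pre_mb = est_pre$revised_genome_size / 1e6,
    revised_post_mb = est_post$revised_genome_size / 1e6,
    assembly_total_bases = stats_post$total_length,
    removed_bases = filt$report$removed_bases,
    total_bases = filt$report$total_bases)

  report <- structure(list(
    qc = qc, qc_post = qc_post,
    estimate_pre = est_pre, estimate_post = est_post,
    assembly_pre = stats_pre, assembly_post = stats_post,
    decontamination = filt$report,
    stray = stray, labels = labels,
    ssr = ssr_sum, arithmetic = arithmetic,
    truth = truth, log = log), class = "survey_report")

  if (!is.null(cfg$out_dir)) {
    write_report_files(report, cfg, clean, filt, contigs, contigs_post,
                       hist_pre, hist_post, dens_pre, dens_post,
                       ssr_records)
  }
  report
}

write_report_files <- function(report, cfg, clean, filt, contigs,
                               contigs_post, hist_pre, hist_post,
                               dens_pre, dens_post, ssr_records) {
  d <- cfg$out_dir
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  write_kmer_histogram(hist_pre, file.path(d, "kmer_hist_pre.tsv"))
  write_kmer_histogram(hist_post, file.path(d, "kmer_hist_post.tsv"))
  write_fasta(contigs, file.path(d, "contigs_pre.fasta"))
  write_fasta(contigs_post, file.path(d, "contigs_post.fasta"))
  write_tsv(dens_pre$points, file.path(d, "gc_depth_pre.tsv"))
  write_tsv(dens_post$points, file.path(d, "gc_depth_post.tsv"))
  write_tsv(report$stray, file.path(d, "stray_contigs.tsv"))
  write_tsv(ssr_records, file.path(d, "ssr_records.tsv"))
  write_fastq(filt$kept, file.path(d, "decontaminated_1.fastq"),
              file.path(d, "decontaminated_2.fastq"))
  jsonlite::write_json(report_as_list(report),
                       file.path(d, "survey_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(cfg$plots)) {
    grDevices::png(file.path(d, "kmer_spectrum.png"), 800, 600)
    plot_kmer_spectrum(hist_pre)
    grDevices::dev.off()
    grDevices::png(file.path(d, "gc_depth.png"), 800, 600)
    plot_gc_depth(dens_pre, cfg$regions)
    grDevices::dev.off()
  }
  invisible(d)
}

report_as_list <- function(report) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  keep <- setdiff(names(report), c("truth", "stray", "labels"))
  strip(report[keep])
}

#' Survey report arithmetic
#'
#' The derived numbers a survey report prints: genome-size overestimation
#' attributable to contaminants (difference between the contaminated and
#' decontaminated revised sizes, absolute and as a percentage of the
#' decontaminated size), genome coverage of the assembly (assembly total
#' over revised genome size), and the contamination percentage (removed
#' over total clean bases).
#'
#' @param revised_pre_mb revised genome size before decontamination (Mb).
#' @param revised_post_mb revised genome size after decontamination (Mb).
#' @param assembly_total_bases assembled bases (post-decontamination).
#' @param removed_bases,total_bases decontamination volumes in bases (or
#'   any common unit).
#' @return list with `overestimation_mb`, `overestimation_pct`,
#'   `coverage_pct`, `contamination_pct` plus formatted labels.
#' @export
report_arithmetic <- function(revised_pre_mb, revised_post_mb,
                              assembly_total_bases, removed_bases,
                              total_bases) {
  over_mb <- revised_pre_mb - revised_post_mb
  over_pct <- if (revised_post_mb > 0) 100 * over_mb / revised_post_mb else 0
  cov_pct <- if (revised_post_mb > 0)
    100 * (assembly_total_bases / 1e6) / revised_post_mb else 0
  cont_pct <- if (total_bases > 0) 100 * removed_bases / total_bases else 0
  list(overestimation_mb = over_mb,
       overestimation_pct = over_pct,
       coverage_pct = cov_pct,
       contamination_pct = cont_pct,
       overestimation_label = sprintf("%.2f Mb (%s%%)", over_mb,
                                      format_percent(over_pct)),
       coverage_label = sprintf("%.2f%%", cov_pct),
       contamination_label = paste0(format_percent(cont_pct), "%"))
}

#' @export
print.survey_report <- function(x, ...) {
  cat("== genome survey report ==\n")
  print(x$qc)
  cat("pre-decontamination estimate:  ")
  print(x$estimate_pre)
  cat("post-decontamination estimate: ")
  print(x$estimate_post)
  cat("assembly (post): ")
  print(x$assembly_post)
  cat(sprintf("contamination: %s%% of clean bases removed\n",
              x$decontamination$removed_pct_label))
  cat(sprintf("overestimation: %s | coverage: %s\n",
              x$arithmetic$overestimation_label,
              x$arithmetic$coverage_label))
  cat(sprintf("SSRs: %d\n", x$ssr$total))
  invisible(x)
}
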