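# End-to-end orchestration: configuration, the full analysis pipeline and its
# report bundle.

#' Build a pipeline configuration
#'
#' Collects input paths, analysis toggles and parameters. Referenced files
#' must exist at load time; parameters are checked against their documented
#' ranges.
#'
#' @param reference Reference FASTA (single sequence).
#' @param sam_forward SAM of reads aligned against the forward genome.
#' @param sam_reverse Optional SAM of reads aligned against the
#'   reverse-complemented genome (dual-strand protocol).
#' @param fastq Optional FASTQ of all basecalled reads (used for retention
#'   accounting).
#' @param out_dir Output directory.
#' @param bed Optional BED of regions for stratified error rates.
#' @param mods Optional modification-call TSV (`read_id`, `read_pos`,
#'   `mod_type`).
#' @param events Optional per-base event-count TSV for translocation-speed
#'   analysis.
#' @param analyses Which analysis stages to run.
#' @param species Dataset label.
#' @param min_quality Reads below this mean quality are excluded from the
#'   analyses but counted in retention reports (default 10).
#' @param max_clip_fraction Soft-clip filter threshold (default 0.5).
#' @param window_fraction Genome-window size as a fraction of genome length.
#' @param quality_window,quality_stride Quality calibration windows.
#' @param fit_range Quality range for the quadratic model fit.
#' @param thresholds Retention thresholds.
#' @param coverage_window,min_coverage_windows Relative-coverage parameters.
#' @param gc_min_support Minimum reads per GC bin.
#' @param harmful_k,harmful_top Harmful k-mer parameters.
#' @param repeat_max_reads Repeat assessment is restricted to this many reads
#'   (keeps the quadratic repeat-by-read work bounded on deep runs).
#' @param repeat_min_count Minimum assessments per reported accuracy cell.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference, sam_forward, sam_reverse = NULL,
                            fastq = NULL, out_dir = "nanoscape_out",
                            bed = NULL, mods = NULL, events = NULL,
                            analyses = c("profile", "quality", "gc",
                                         "repeats", "kmers", "signal"),
                            species = "sample",
                            min_quality = 10, max_clip_fraction = 0.5,
                            window_fraction = 0.01,
                            quality_window = 100L, quality_stride = 25L,
                            fit_range = c(7, 30), thresholds = 7:12,
                            coverage_window = 100L, min_coverage_windows = 1000L,
                            gc_min_support = 100L,
                            harmful_k = 5L, harmful_top = 10L,
                            repeat_max_reads = 2000L, repeat_min_count = 100L) {
  for (p in c(reference, sam_forward, sam_reverse, fastq, bed, mods, events)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  stopifnot(min_quality >= 0, max_clip_fraction >= 0, max_clip_fraction <= 1,
            window_fraction > 0, window_fraction <= 1, harmful_k >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  do.call(pipeline_config, yaml::read_yaml(path))
}

.log_stage <- function(stage, t0) {
  message(sprintf("[nanoscape] %-10s %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

.write_tsv <- function(x, path) data.table::fwrite(x, path, sep = "\t")

#' Run the full error-landscape pipeline
#'
#' Executes alignment loading (dual-strand selection, clip and quality
#' filtering) followed by the enabled analysis stages, writing one named
#' TSV/JSON artifact per analysis plus a `summary.json` with the headline
#' numbers (global error rates, homopolymer attribution, perfect k-mer
#' skewness and seed sizes, transition-bias tests, retention trade-off).
#' Per-record parse failures are skipped, counted and reported; re-running
#' with identical inputs reproduces identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return The report bundle (named list), invisibly; all artifacts are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  report <- list(species = config$species)

  reference <- read_reference_fasta(config$reference)
  fwd <- parse_alignments(config$sam_forward, reference, "forward")
  skipped <- nrow(attr(fwd, "skipped"))
  rev <- if (!is.null(config$sam_reverse)) {
    r <- parse_alignments(config$sam_reverse, reference, "reverse")
    skipped <- skipped + nrow(attr(r, "skipped"))
    r
  } else list()
  best <- select_best_strand(fwd, rev)
  flt <- filter_softclipped(best, config$max_clip_fraction)
  reads_all <- flt$kept
  tab_all <- read_error_table(reads_all)
  keep_q <- tab_all$mean_quality >= config$min_quality
  reads <- reads_all[keep_q]
  tab <- tab_all[keep_q]
  report$counts <- list(
    parsed = length(fwd) + length(rev), skipped_records = skipped,
    after_strand_selection = length(best),
    discarded_clip_filter = length(flt$discarded),
    below_min_quality = sum(!keep_q), analysed = length(reads))
  message(sprintf("[nanoscape] %d reads analysed (%d parsed, %d skipped records)",
                  length(reads), report$counts$parsed, skipped))
  .log_stage("load", t0)
  if (length(reads) == 0L) stop("no reads left to analyse")

  run <- run_bundle(reference, reads, config$species)
  on <- function(a) a %in% config$analyses

  if (on("profile")) {
    .write_tsv(tab, file.path(config$out_dir, "read_errors.tsv"))
    pooled <- pool_error_counts(lapply(reads, decompose_errors))
    report$global <- list(
      alignment_length = pooled$alignment_length,
      mismatch_pct = 100 * pooled$mismatch_rate,
      insertion_pct = 100 * pooled$insertion_rate,
      deletion_pct = 100 * pooled$deletion_rate,
      global_error_pct = 100 * pooled$global_error_rate)
    mods <- if (!is.null(config$mods)) data.table::fread(config$mods) else NULL
    sm <- substitution_matrix(reads, mods)
    sm_long <- data.table::rbindlist(lapply(names(sm), function(s) {
      ab <- substitution_abundance(sm[[s]]); ab$stratum <- s; ab
    }))
    .write_tsv(sm_long, file.path(config$out_dir, "substitution_matrix.tsv"))
    tt <- transition_transversion_test(reads)
    report$transition_test <- as.list(stats::setNames(tt$p_value, tt$comparison))
    .write_tsv(genome_window_error(reads, reference, config$window_fraction),
               file.path(config$out_dir, "window_errors.tsv"))
    .log_stage("profile", t0)
  }

  if (on("gc")) {
    .write_tsv(error_vs_gc(tab, config$gc_min_support),
               file.path(config$out_dir, "error_vs_gc.tsv"))
    .write_tsv(relative_coverage_by_gc(reads, reference, config$coverage_window,
                                       config$min_coverage_windows),
               file.path(config$out_dir, "coverage_vs_gc.tsv"))
    if (!is.null(config$bed)) {
      rer <- region_error_rates(reads, read_bed(config$bed), reference)
      if (!is.null(rer)) {
        report$region_error_pct <- 100 * rer$global_error_rate
      }
    }
    .log_stage("gc", t0)
  }

  if (on("quality")) {
    pts <- window_quality_error(reads, config$quality_window, config$quality_stride)
    .write_tsv(pts, file.path(config$out_dir, "quality_error.tsv"))
    qm <- tryCatch(fit_quality_error_model(pts, config$fit_range),
                   error = function(e) NULL)
    if (!is.null(qm)) {
      jsonlite::write_json(qm[c("a", "b", "c", "r_squared", "fit_range")],
                           file.path(config$out_dir, "quality_model.json"),
                           auto_unbox = TRUE, digits = NA)
      report$quality_model <- qm[c("a", "b", "c", "r_squared")]
    }
    ret <- read_retention_by_threshold(tab_all, config$thresholds)
    .write_tsv(ret, file.path(config$out_dir, "retention.tsv"))
    report$retention_loss <- attr(ret, "loss")
    .log_stage("quality", t0)
  }

  if (on("repeats")) {
    sub <- reads[seq_len(min(config$repeat_max_reads, length(reads)))]
    for (kind in c("homopolymer", "heteropolymer", "trinucleotide")) {
      occ <- find_repeats(reference, kind)
      .write_tsv(occ, file.path(config$out_dir, paste0("repeats_", kind, ".tsv")))
      .write_tsv(repeat_length_distribution(reference, kind),
                 file.path(config$out_dir, paste0("repeat_lengths_", kind, ".tsv")))
      if (kind == "homopolymer") {
        att <- attribute_errors_to_homopolymers(reads, occ, reference)
        .write_tsv(att, file.path(config$out_dir, "homopolymer_attribution.tsv"))
        report$homopolymer_attribution <- as.list(
          stats::setNames(att$ratio_pct, att$error_type))
        ass <- assess_repeats(sub, occ, reference)
        .write_tsv(repeat_accuracy_by_length(ass, min_count = config$repeat_min_count),
                   file.path(config$out_dir, "homopolymer_accuracy.tsv"))
        .write_tsv(length_deviation_profile(ass),
                   file.path(config$out_dir, "homopolymer_deviation.tsv"))
      } else {
        # heavier per-occurrence string matching: assess on a smaller subset
        sub2 <- sub[seq_len(min(500L, length(sub)))]
        ass <- assess_repeats(sub2, occ, reference)
        if (kind == "trinucleotide" && nrow(ass)) {
          ass$group <- vapply(ass$motif, classify_trinucleotide, character(1))
          acc <- repeat_accuracy_by_length(ass, by = "group",
                                           min_count = config$repeat_min_count)
        } else {
          acc <- repeat_accuracy_by_length(ass, min_count = config$repeat_min_count)
        }
        .write_tsv(acc, file.path(config$out_dir, paste0("accuracy_", kind, ".tsv")))
        if (nrow(ass)) {
          .write_tsv(length_deviation_profile(ass),
                     file.path(config$out_dir, paste0("deviation_", kind, ".tsv")))
        }
      }
    }
    .log_stage("repeats", t0)
  }

  if (on("kmers")) {
    lens <- vapply(reads, longest_perfect_kmer, integer(1))
    pk <- perfect_kmer_distribution(lens)
    .write_tsv(pk$curve, file.path(config$out_dir, "perfect_kmer_curve.tsv"))
    report$perfect_kmers <- c(pk$stats[c("mode", "mean", "median", "sd",
                                         "scp_mode", "scp_median")],
                              list(seed_95 = seed_size_at_confidence(lens, 0.95),
                                   seed_99 = seed_size_at_confidence(lens, 0.99)))
    jsonlite::write_json(report$perfect_kmers,
                         file.path(config$out_dir, "perfect_kmer_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    gcc <- run$gc_class
    tabs <- list()
    for (et in c("mismatch", "insertion", "deletion")) {
      for (sd in c("before", "after")) {
        hk <- harmful_kmers(reads, et, sd, k = config$harmful_k,
                            top = config$harmful_top,
                            exclude_homopolymeric = et == "deletion",
                            reference = reference, gc_class = gcc)
        tabs[[paste(et, sd, sep = "_")]] <- hk
      }
    }
    hk_long <- data.table::rbindlist(lapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      if (nrow(t) == 0L) return(NULL)
      data.table::data.table(context = nm, kmer = t$kmer, count = t$count)
    }))
    .write_tsv(hk_long, file.path(config$out_dir, "harmful_kmers.tsv"))
    del_before <- tabs[["deletion_before"]]
    if (nrow(del_before)) {
      aut <- build_automaton(merge_harmful_tables(list(del_before)))
      automaton_to_dot(aut, file.path(config$out_dir, "automaton.dot"))
      automaton_to_json(aut, file.path(config$out_dir, "automaton.json"))
      pcm <- position_count_matrix(del_before)
      .write_tsv(data.table::as.data.table(pcm, keep.rownames = "base"),
                 file.path(config$out_dir, "deletion_before_pcm.tsv"))
    }
    .log_stage("kmers", t0)
  }

  if (on("signal") && !is.null(config$events)) {
    ev <- read_event_table(config$events)
    .write_tsv(error_vs_speed(reads, ev, reference),
               file.path(config$out_dir, "speed_errors.tsv"))
    .log_stage("signal", t0)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .log_stage("done", t0)
  invisible(report)
}
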