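# Error decomposition and profiling: per-column classification, substitution
# bias, genome-window profiles, GC-bias analyses, region-stratified rates.

# Per-column classification codes.
.COL_MATCH <- 0L; .COL_MISMATCH <- 1L; .COL_INS <- 2L; .COL_DEL <- 3L; .COL_AMBIG <- 4L

# Classify every alignment column of a read. Base-pair columns where either
# base is N are "ambiguous": they count in alignment length but are neither
# match nor mismatch (no defined base identity).
ar_column_class <- function(x) {
  cls <- rep.int(.COL_MATCH, ar_ncol(x))
  ins <- x$ref == .GAP
  del <- x$read == .GAP
  cls[ins] <- .COL_INS
  cls[del] <- .COL_DEL
  bp <- !ins & !del
  amb <- bp & (x$ref == .N | x$read == .N)
  cls[bp & !amb & x$ref != x$read] <- .COL_MISMATCH
  cls[amb] <- .COL_AMBIG
  cls
}

#' Construct an error-count summary
#'
#' @param matches,mismatches,insertions,deletions Column counts.
#' @param ambiguous Base-pair columns involving `N` (neither match nor
#'   mismatch).
#' @return An `error_counts` object with per-type rates over the total
#'   alignment length and the global error rate
#'   (mismatches + insertions + deletions) / alignment length.
#' @export
error_counts <- function(matches = 0, mismatches = 0, insertions = 0,
                         deletions = 0, ambiguous = 0) {
  len <- matches + mismatches + insertions + deletions + ambiguous
  if (len == 0) stop("empty alignment: error rates undefined")
  structure(list(
    matches = matches, mismatches = mismatches, insertions = insertions,
    deletions = deletions, ambiguous = ambiguous, alignment_length = len,
    match_rate = matches / len, mismatch_rate = mismatches / len,
    insertion_rate = insertions / len, deletion_rate = deletions / len,
    global_error_rate = (mismatches + insertions + deletions) / len
  ), class = "error_counts")
}

#' @export
print.error_counts <- function(x, ...) {
  cat(sprintf(
    "<error_counts> %d columns: mm %.3f%%, ins %.3f%%, del %.3f%% (global %.3f%%)\n",
    x$alignment_length, 100 * x$mismatch_rate, 100 * x$insertion_rate,
    100 * x$deletion_rate, 100 * x$global_error_rate))
  invisible(x)
}

#' Sum error counts over several alignments
#'
#' @param counts List of `error_counts`.
#' @return Pooled `error_counts`.
#' @export
pool_error_counts <- function(counts) {
  s <- function(f) sum(vapply(counts, `[[`, numeric(1), f))
  error_counts(s("matches"), s("mismatches"), s("insertions"), s("deletions"),
               s("ambiguous"))
}

#' Decompose an alignment into error counts
#'
#' Column-wise classification: equal non-gap bases are matches, differing
#' non-gap bases mismatches, reference gaps insertions, read gaps deletions.
#' Adjacent indel runs count column-wise (a 3-base deletion is 3 deletion
#' errors). Rates are relative to the total alignment length.
#'
#' @param read An `aligned_read`.
#' @return An `error_counts`.
#' @export
decompose_errors <- function(read) {
  if (ar_ncol(read) == 0L) stop("empty alignment: error rates undefined")
  tab <- tabulate(ar_column_class(read) + 1L, nbins = 5L)
  error_counts(tab[1L], tab[2L], tab[3L], tab[4L], tab[5L])
}

#' Per-read error summary table
#'
#' One row per read: clip bookkeeping, error decomposition, aligned-read GC
#' percent and mean Phred quality of aligned bases. This is the substrate for
#' per-read binned figures and retention analyses.
#'
#' @param reads List of `aligned_read`.
#' @return A `data.table` with columns `read_id`, `read_length`, `clip_left`,
#'   `clip_right`, `alignment_length`, `matches`, `mismatches`, `insertions`,
#'   `deletions`, `global_error_rate`, `mismatch_rate`, `insertion_rate`,
#'   `deletion_rate`, `gc_percent`, `mean_quality`.
#' @export
read_error_table <- function(reads) {
  rows <- lapply(reads, function(x) {
    ec <- decompose_errors(x)
    q <- x$qual[ar_read_cols(x)]
    data.table::data.table(
      read_id = x$read_id, read_length = x$read_length,
      clip_left = x$clip_left, clip_right = x$clip_right,
      alignment_length = ec$alignment_length, matches = ec$matches,
      mismatches = ec$mismatches, insertions = ec$insertions,
      deletions = ec$deletions, global_error_rate = ec$global_error_rate,
      mismatch_rate = ec$mismatch_rate, insertion_rate = ec$insertion_rate,
      deletion_rate = ec$deletion_rate,
      gc_percent = 100 * gc_fraction(x$read[ar_read_cols(x)]),
      mean_quality = mean(q, na.rm = TRUE)
    )
  })
  data.table::rbindlist(rows)
}

# --- Substitution bias ------------------------------------------------------

.BASE_CHARS <- c("A", "C", "G", "T")

#' Substitution count matrices, optionally stratified by modification calls
#'
#' Tallies mismatch columns by (genome base, read base) over `{A,C,G,T}`
#' (columns involving `N` are excluded). When per-base modification calls are
#' supplied, a mismatch whose read base carries a call is tallied in the
#' corresponding `modified:<type>` stratum and all remaining mismatches in
#' `unmodified`; otherwise a single `all` stratum is returned.
#'
#' @param reads List of `aligned_read`.
#' @param modification_calls Optional `data.frame` with columns `read_id`,
#'   `read_pos` (0-based position in the original read, clips included) and
#'   `mod_type`. A call addressing a position at or beyond the read length is
#'   rejected.
#' @return Named list of 4x4 count matrices (genome base in rows, read base in
#'   columns, zero diagonal), one per stratum.
#' @export
substitution_matrix <- function(reads, modification_calls = NULL) {
  use_mods <- !is.null(modification_calls)
  if (use_mods) {
    mc <- data.table::as.data.table(modification_calls)
    stopifnot(all(c("read_id", "read_pos", "mod_type") %in% names(mc)))
    rl <- data.table::data.table(
      read_id = vapply(reads, `[[`, character(1), "read_id"),
      .len = vapply(reads, `[[`, integer(1), "read_length"))
    bad <- mc[rl, on = "read_id"][read_pos >= .len | read_pos < 0]
    if (nrow(bad)) {
      stop("modification call beyond read length: read ", bad$read_id[1L],
           " position ", bad$read_pos[1L])
    }
    strata <- c("unmodified", paste0("modified:", sort(unique(mc$mod_type))))
  } else {
    strata <- "all"
  }
  empty <- matrix(0, 4, 4, dimnames = list(genome = .BASE_CHARS, read = .BASE_CHARS))
  mats <- stats::setNames(rep(list(empty), length(strata)), strata)

  for (x in reads) {
    cls <- ar_column_class(x)
    mm <- which(cls == .COL_MISMATCH)
    if (!length(mm)) next
    gi <- match(strsplit(rawToChar(x$ref[mm]), "")[[1L]], .BASE_CHARS)
    ri <- match(strsplit(rawToChar(x$read[mm]), "")[[1L]], .BASE_CHARS)
    stratum_of <- rep.int(strata[1L], length(mm))
    if (use_mods) {
      calls <- mc[mc$read_id == x$read_id]
      if (nrow(calls)) {
        rp <- ar_read_positions(x)[mm]
        hit <- match(rp, calls$read_pos)
        stratum_of[!is.na(hit)] <- paste0("modified:", calls$mod_type[hit[!is.na(hit)]])
      }
    }
    for (s in unique(stratum_of)) {
      sel <- stratum_of == s
      mats[[s]] <- mats[[s]] + table(factor(gi[sel], 1:4), factor(ri[sel], 1:4))
    }
  }
  lapply(mats, function(m) { m <- unclass(m); dimnames(m) <- dimnames(empty); m })
}

#' Relative abundance of the twelve substitution pairs
#'
#' @param mat A 4x4 substitution count matrix.
#' @return A `data.table` (genome base, read base, count, fraction summing
#'   to 1 over the off-diagonal pairs).
#' @export
substitution_abundance <- function(mat) {
  dt <- data.table::as.data.table(as.table(mat))
  names(dt) <- c("genome_base", "read_base", "count")
  dt <- dt[dt$genome_base != dt$read_base, ]
  tot <- sum(dt$count)
  dt$fraction <- if (tot > 0) dt$count / tot else NA_real_
  dt[]
}

# Per-read substitution pair counts: matrix reads x 12 (named pairs), plus
# per-read substitution totals. Used by the transition/transversion test.
.per_read_pair_counts <- function(reads) {
  pairs <- outer(.BASE_CHARS, .BASE_CHARS, paste0)
  keep <- which(!diag(4) == 1)
  pair_names <- pairs[keep]
  m <- matrix(0L, length(reads), length(pair_names),
              dimnames = list(NULL, pair_names))
  for (k in seq_along(reads)) {
    x <- reads[[k]]
    cls <- ar_column_class(x)
    mm <- which(cls == .COL_MISMATCH)
    if (!length(mm)) next
    g <- strsplit(rawToChar(x$ref[mm]), "")[[1L]]
    r <- strsplit(rawToChar(x$read[mm]), "")[[1L]]
    tb <- table(factor(paste0(g, r), levels = pair_names))
    m[k, ] <- as.integer(tb)
  }
  m
}

#' Test whether transitions outnumber transversions
#'
#' For each read with at least one substitution, its per-pair A<->G (resp.
#' C<->T) transition rate (the pooled fraction divided by the two ordered
#' pairs) is compared with its mean per-pair transversion rate (total
#' transversion fraction divided by the eight transversion pairs), using an
#' unequal-variance two-sample t-test across reads. The per-pair scaling makes
#' the two populations comparable under a substitution process that is uniform
#' over the twelve pairs. Two comparisons are returned, one per transition
#' pair.
#'
#' @param reads List of `aligned_read`.
#' @return A `data.table` with columns `comparison`, `statistic`, `p_value`,
#'   `n_reads`, `mean_transition`, `mean_transversion`, and attribute
#'   `flagged` set to `TRUE` when fewer than two reads carry substitutions
#'   (no test performed).
#' @export
transition_transversion_test <- function(reads) {
  m <- .per_read_pair_counts(reads)
  tot <- rowSums(m)
  use <- tot > 0
  out <- data.table::data.table(
    comparison = c("AG_vs_transversions", "CT_vs_transversions"),
    statistic = NA_real_, p_value = NA_real_, n_reads = sum(use),
    mean_transition = NA_real_, mean_transversion = NA_real_)
  if (sum(use) < 2L) {
    attr(out, "flagged") <- TRUE
    return(out)
  }
  m <- m[use, , drop = FALSE]; tot <- tot[use]
  # per-pair rates: each transition spans two ordered pairs, transversions eight
  ag <- (m[, "AG"] + m[, "GA"]) / tot / 2
  ct <- (m[, "CT"] + m[, "TC"]) / tot / 2
  tv <- (tot - (m[, "AG"] + m[, "GA"] + m[, "CT"] + m[, "TC"])) / tot / 8
  for (i in 1:2) {
    tr <- if (i == 1L) ag else ct
    ht <- stats::t.test(tr, tv, var.equal = FALSE)
    data.table::set(out, i, "statistic", unname(ht$statistic))
    data.table::set(out, i, "p_value", ht$p.value)
    data.table::set(out, i, "mean_transition", mean(tr))
    data.table::set(out, i, "mean_transversion", mean(tv))
  }
  attr(out, "flagged") <- FALSE
  out
}

# --- Genome windows and GC bias ---------------------------------------------

#' Per-window error profile along the forward genome
#'
#' The genome is tiled into windows of `ceiling(window_fraction * L)` bases.
#' Every alignment column is anchored at a forward-genome position (insertions
#' at the preceding reference base) and each window's per-type error rate is
#' the number of errors anchored in it over the aligned columns anchored in
#' it. Windows covered by no read get `NA` rates.
#'
#' @param reads List of `aligned_read`.
#' @param reference The `reference_genome` the reads are mapped to.
#' @param window_fraction Window size as a fraction of genome length
#'   (default 0.01).
#' @return A `data.table` with `window_start`, `window_end` (0-based
#'   half-open), `columns`, `mismatch_rate`, `insertion_rate`,
#'   `deletion_rate`.
#' @export
genome_window_error <- function(reads, reference, window_fraction = 0.01) {
  L <- reference$length
  wsize <- max(1L, as.integer(ceiling(window_fraction * L)))
  nwin <- as.integer(ceiling(L / wsize))
  cols <- numeric(nwin); mm <- numeric(nwin); ins <- numeric(nwin); del <- numeric(nwin)
  for (x in reads) {
    a <- ar_anchor_forward(x, L)
    w <- a %/% wsize + 1L
    cls <- ar_column_class(x)
    cols <- cols + tabulate(w, nwin)
    mm <- mm + tabulate(w[cls == .COL_MISMATCH], nwin)
    ins <- ins + tabulate(w[cls == .COL_INS], nwin)
    del <- del + tabulate(w[cls == .COL_DEL], nwin)
  }
  data.table::data.table(
    window_start = (seq_len(nwin) - 1L) * wsize,
    window_end = pmin(seq_len(nwin) * wsize, L),
    columns = cols,
    mismatch_rate = ifelse(cols > 0, mm / cols, NA_real_),
    insertion_rate = ifelse(cols > 0, ins / cols, NA_real_),
    deletion_rate = ifelse(cols > 0, del / cols, NA_real_)
  )
}

#' Per-read error rates binned by read GC content
#'
#' Each read's GC percent (over its aligned bases, `N` excluded) is rounded to
#' the nearest integer; per bin, the unweighted mean of per-read rates is
#' reported. Bins supported by fewer than `min_support` reads are suppressed.
#'
#' @param reads List of `aligned_read`, or a table from [read_error_table()].
#' @param min_support Minimum reads per bin (default 1).
#' @return A `data.table` with `gc_percent`, `n_reads`, and mean
#'   `mismatch_rate`, `insertion_rate`, `deletion_rate`, `global_error_rate`.
#' @export
error_vs_gc <- function(reads, min_support = 1L) {
  stopifnot(min_support >= 1L)
  tab <- if (data.table::is.data.table(reads)) reads else read_error_table(reads)
  tab <- data.table::copy(tab)
  tab[, gc_bin := as.integer(round(gc_percent))]
  out <- tab[, list(
    n_reads = .N,
    mismatch_rate = mean(mismatch_rate),
    insertion_rate = mean(insertion_rate),
    deletion_rate = mean(deletion_rate),
    global_error_rate = mean(global_error_rate)
  ), keyby = list(gc_percent = gc_bin)]
  out[out$n_reads >= min_support, ]
}

#' Relative depth of coverage by window GC content
#'
#' The genome is tiled into non-overlapping windows (default 100 bases); each
#' window's depth is its mean per-base aligned-column depth and its relative
#' coverage that depth divided by the genome-wide mean per-base depth (1.0
#' everywhere means no GC bias). Windows are binned by integer GC percent;
#' bins with fewer than `min_windows` windows are suppressed.
#'
#' @param reads List of `aligned_read`.
#' @param reference The `reference_genome`.
#' @param window Window size in bases (default 100).
#' @param min_windows Minimum windows per reported GC bin (default 1000).
#' @return A `data.table` with `gc_percent`, `n_windows`,
#'   `relative_coverage`; attribute `mean_depth` carries the genome-wide mean
#'   per-base depth.
#' @export
relative_coverage_by_gc <- function(reads, reference, window = 100L,
                                    min_windows = 1000L) {
  stopifnot(window >= 1L)
  L <- reference$length
  nwin <- as.integer(ceiling(L / window))
  depth_cols <- numeric(nwin)
  for (x in reads) {
    a <- ar_anchor_forward(x, L)[ar_ref_cols(x)]
    depth_cols <- depth_cols + tabulate(a %/% window + 1L, nwin)
  }
  widths <- pmin(seq_len(nwin) * window, L) - (seq_len(nwin) - 1L) * window
  mean_depth <- sum(depth_cols) / L
  if (mean_depth == 0) {
    warning("no aligned columns: relative coverage undefined")
    out <- data.table::data.table(gc_percent = integer(0), n_windows = integer(0),
                                  relative_coverage = numeric(0))
    attr(out, "mean_depth") <- 0
    return(out)
  }
  gcp <- vapply(seq_len(nwin), function(i) {
    s <- (i - 1L) * window
    gc_fraction(reference$raw_fwd[(s + 1L):min(s + window, L)])
  }, numeric(1))
  dt <- data.table::data.table(
    gc_percent = as.integer(round(100 * gcp)),
    rel = (depth_cols / widths) / mean_depth)
  out <- dt[!is.nan(dt$gc_percent), list(n_windows = .N, relative_coverage = mean(rel)),
            keyby = "gc_percent"]
  out <- out[out$n_windows >= min_windows, ]
  attr(out, "mean_depth") <- mean_depth
  out
}

#' Read BED intervals
#'
#' @param path BED file (0-based half-open). Only the first three columns are
#'   used.
#' @return A `data.table` with `chrom`, `start`, `end`. Malformed intervals
#'   (`end <= start`) are rejected with their line number.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, select = 1:3,
                          col.names = c("chrom", "start", "end"))
  bad <- which(dt$end <= dt$start)
  if (length(bad)) stop("malformed BED interval at line ", bad[1L], ": end <= start")
  dt
}

#' Pooled error rates inside a region set
#'
#' Columns whose forward-genome anchor lies in any interval are pooled and
#' summarised as one `error_counts` (the weighted mean over regions, weights
#' being aligned columns).
#'
#' @param reads List of `aligned_read`.
#' @param regions A `data.table`/`data.frame` with 0-based half-open `start`,
#'   `end` columns (e.g. from [read_bed()]), on the forward genome.
#' @param reference The `reference_genome`.
#' @return An `error_counts`, or `NULL` (with a warning) when no column falls
#'   in the regions.
#' @export
region_error_rates <- function(reads, regions, reference) {
  L <- reference$length
  if (nrow(regions) == 0L) {
    warning("empty region set: no columns pooled")
    return(NULL)
  }
  if (any(regions$end <= regions$start)) stop("malformed interval: end <= start")
  mask <- logical(L)
  for (i in seq_len(nrow(regions))) {
    mask[(max(0L, regions$start[i]) + 1L):min(L, regions$end[i])] <- TRUE
  }
  tab <- numeric(5)
  for (x in reads) {
    a <- ar_anchor_forward(x, L)
    keep <- mask[a + 1L]
    if (!any(keep)) next
    tab <- tab + tabulate(ar_column_class(x)[keep] + 1L, nbins = 5L)
  }
  if (sum(tab) == 0) {
    warning("no aligned columns in regions")
    return(NULL)
  }
  error_counts(tab[1L], tab[2L], tab[3L], tab[4L], tab[5L])
}
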