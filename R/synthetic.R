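# Synthetic data with exact ground truth: reference genomes with controllable
# GC and repeat content, reads with parameterised error processes (substitution
# bias, GC-dependent scaling, homopolymer length resampling, quality strings
# tied to the true per-base error probability), matching dual-strand SAM,
# event tables and modification calls.

# Run code under a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Specify the synthetic error model
#'
#' The generator works column-wise: every alignment column of a read is,
#' independently, an insertion with probability `p * w_ins`, a deletion with
#' `p * w_del`, a mismatch with `p * w_sub` and a match otherwise, where the
#' per-read total error probability `p` is drawn as `10^(-q/10)` from a
#' per-read quality level `q ~ Normal(q_mean, q_sd_read)` (clamped to
#' `q_range`) and the weights are the nominal rates normalised. `q_mean` is
#' calibrated numerically so that the expected `p` equals
#' `substitution_rate + insertion_rate + deletion_rate` exactly. The emitted
#' per-base Phred quality is `round(-10 log10(p)) + quality_offset`, so with
#' `quality_offset = 0` qualities are perfectly Phred-calibrated and a
#' positive offset reproduces the overevaluated-quality signature of real
#' basecallers.
#'
#' Inside reference homopolymer runs of length `>= hp_min_len` the column
#' process is replaced by a length-resampling model: the observed run length
#' is `max(0, L + delta)` with
#' `delta ~ Poisson(hp_lambda_ins * (L - hp_min_len + 1)) -
#'          Poisson(hp_lambda_del * (L - hp_min_len + 1))`,
#' except that with probability `hp_tail_prob` the run instead gains
#' `1 + Geometric(hp_tail_geom)` extra copies (the heavy overestimation tail).
#' Shorter runs see the ordinary column process.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Nominal per-column
#'   probabilities (defaults 0.02, 0.015, 0.025).
#' @param transition_multiplier Relative weight of the transition partner
#'   (A<->G, C<->T) among substitution targets (1 = unbiased).
#' @param gc_error_slope Additive total-error-rate change per GC percent of
#'   the read's true segment away from 50% (default 0).
#' @param q_sd_read Spread of per-read quality levels in Phred units.
#' @param q_range Clamp for the per-read quality level.
#' @param q_integer Round the per-read quality level to an integer *before*
#'   deriving the error probability, so that the emitted Phred score satisfies
#'   `P = 10^(-Q/10)` exactly (the cleanest setting for calibration
#'   properties). Off by default: the continuous level keeps the expected
#'   pooled rates exactly at their nominal values.
#' @param quality_offset Added to emitted qualities (identity model = 0).
#' @param hp_min_len Minimum homopolymer length handled by the length model
#'   (`Inf` disables it).
#' @param hp_lambda_ins,hp_lambda_del Per-excess-length Poisson intensities of
#'   the length noise (deletion-dominant by default).
#' @param hp_tail_prob,hp_tail_geom Heavy overestimation tail parameters.
#' @param clip_len Soft-clip length simulated at each read end (default 0).
#' @param speed_coupling Event-density divisor on deleted stretches (>1 means
#'   deleted bases translocate faster), used when event tables are emitted.
#' @param mod_call_rate Fraction of read C bases receiving a 5mC call when
#'   modification calls are emitted.
#' @return An `error_model_spec`.
#' @export
error_model <- function(substitution_rate = 0.02, insertion_rate = 0.015,
                        deletion_rate = 0.025, transition_multiplier = 1,
                        gc_error_slope = 0, q_sd_read = 1.5,
                        q_range = c(3, 60), q_integer = FALSE,
                        quality_offset = 0,
                        hp_min_len = 5L, hp_lambda_ins = 0.08,
                        hp_lambda_del = 0.22, hp_tail_prob = 0.01,
                        hp_tail_geom = 0.5, clip_len = 0L,
                        speed_coupling = 2, mod_call_rate = 0.02) {
  total <- substitution_rate + insertion_rate + deletion_rate
  stopifnot(substitution_rate >= 0, insertion_rate >= 0, deletion_rate >= 0,
            total < 1, total > 0)
  # calibrate q_mean so E[10^(-q/10)] over the clamped normal equals `total`
  target_q <- -10 * log10(total)
  ep <- function(qm) {
    f <- function(q) 10^(-pmin(pmax(q, q_range[1L]), q_range[2L]) / 10) *
      stats::dnorm(q, qm, q_sd_read)
    stats::integrate(f, qm - 8 * q_sd_read - 1, qm + 8 * q_sd_read + 1,
                     rel.tol = 1e-10)$value - total
  }
  q_mean <- if (q_sd_read > 0) {
    # the exact unclamped solution is target_q + sd^2 ln(10)/20; bracket it
    hi <- target_q + 0.2 * q_sd_read^2 + 2
    stats::uniroot(ep, c(target_q - 1, hi), tol = 1e-10)$root
  } else target_q
  structure(list(
    substitution_rate = substitution_rate, insertion_rate = insertion_rate,
    deletion_rate = deletion_rate, total_rate = total,
    w_sub = substitution_rate / total, w_ins = insertion_rate / total,
    w_del = deletion_rate / total,
    transition_multiplier = transition_multiplier,
    gc_error_slope = gc_error_slope,
    q_mean = q_mean, q_sd_read = q_sd_read, q_range = q_range,
    q_integer = q_integer, quality_offset = quality_offset,
    hp_min_len = hp_min_len, hp_lambda_ins = hp_lambda_ins,
    hp_lambda_del = hp_lambda_del, hp_tail_prob = hp_tail_prob,
    hp_tail_geom = hp_tail_geom, clip_len = as.integer(clip_len),
    speed_coupling = speed_coupling, mod_call_rate = mod_call_rate
  ), class = "error_model_spec")
}

#' Generate a reference genome with controllable GC and repeat content
#'
#' Bases are i.i.d. within blocks; when `gc_block_sd > 0`, each block of
#' `gc_block_size` bases draws its own GC fraction from
#' `Normal(gc_fraction, gc_block_sd)` (clamped to `[0.05, 0.95]`), giving the
#' genome-scale GC heterogeneity real genomes show and making read GC vary.
#' Repeats can be planted explicitly via `repeat_spec`, a list of
#' `list(motif =, copies =, count =)` entries whose occurrences overwrite
#' random non-overlapping positions.
#'
#' @param length Genome length in bases.
#' @param gc_fraction Target GC content in `(0, 1)`.
#' @param seed Integer seed; fixed seed gives a byte-identical genome.
#' @param gc_block_size,gc_block_sd Block GC heterogeneity (defaults: one
#'   homogeneous block).
#' @param repeat_spec Optional planted repeats (see above).
#' @param name Sequence name.
#' @return A `reference_genome`.
#' @export
generate_reference <- function(length, gc_fraction = 0.5, seed = 1L,
                               gc_block_size = length, gc_block_sd = 0,
                               repeat_spec = NULL, name = "synthetic_ref") {
  stopifnot(gc_fraction > 0, gc_fraction < 1, length >= 1)
  .with_seed(seed, {
    nblock <- as.integer(ceiling(length / gc_block_size))
    gcs <- pmin(pmax(stats::rnorm(nblock, gc_fraction, gc_block_sd), 0.05), 0.95)
    chunks <- character(nblock)
    for (b in seq_len(nblock)) {
      n <- min(gc_block_size, length - (b - 1L) * gc_block_size)
      p <- c((1 - gcs[b]) / 2, gcs[b] / 2, gcs[b] / 2, (1 - gcs[b]) / 2)
      chunks[b] <- paste(sample(.BASE_CHARS, n, replace = TRUE, prob = p),
                         collapse = "")
    }
    s <- paste(chunks, collapse = "")
    if (!is.null(repeat_spec)) {
      ch <- strsplit(s, "")[[1L]]
      used <- logical(length)
      for (rs in repeat_spec) {
        unit <- strsplit(rs$motif, "")[[1L]]
        w <- base::length(unit) * rs$copies
        if (w > length) stop("planted repeat longer than genome")
        placed <- 0L
        tries <- 0L
        while (placed < rs$count && tries < 100L * rs$count) {
          tries <- tries + 1L
          pos <- sample.int(length - w - 1L, 1L) + 1L   # keep 1 base margin
          span <- (pos - 1L):(pos + w)                  # include guard flanks
          if (any(used[span])) next
          ch[pos:(pos + w - 1L)] <- rep_len(unit, w)
          # guard bases differ from the repeat ends so the planted length is exact
          ch[pos - 1L] <- setdiff(.BASE_CHARS, unit[base::length(unit)])[1L]
          ch[pos + w] <- setdiff(.BASE_CHARS, unit[1L])[1L]
          used[span] <- TRUE
          placed <- placed + 1L
        }
        if (placed < rs$count) stop("could not place all planted repeats")
      }
      s <- paste(ch, collapse = "")
    }
    reference_genome(name, s)
  })
}

# Sample read lengths from a truncated log-normal via inverse CDF.
.sample_read_lengths <- function(n, meanlog, sdlog, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  pmax(2L, as.integer(round(stats::qlnorm(u, meanlog, sdlog))))
}

# Render one read from its true oriented reference segment.
# Returns the SAM fields, FASTQ fields, truth counts and (optionally) the
# per-homopolymer-run truth observations.
.render_read <- function(seg_raw, model, gc_pct, want_hp_truth) {
  len <- length(seg_raw)
  # per-read quality level and total column error probability
  q_r <- pmin(pmax(stats::rnorm(1L, model$q_mean, model$q_sd_read),
                   model$q_range[1L]), model$q_range[2L])
  if (isTRUE(model$q_integer)) q_r <- round(q_r)
  p_tot <- 10^(-q_r / 10) + model$gc_error_slope * (gc_pct - 50)
  p_tot <- min(max(p_tot, 1e-9), 0.5)
  q_emit <- as.integer(max(0L, min(93L, round(-10 * log10(p_tot)) +
                                     model$quality_offset)))

  p_ins <- p_tot * model$w_ins
  p_del_ref <- p_tot * model$w_del / (1 - p_ins)
  p_mm_ref <- p_tot * model$w_sub / (1 - p_ins)

  seg_int <- as.integer(seg_raw)
  r <- rle(seg_int)
  run_id <- rep.int(seq_along(r$lengths), r$lengths)
  run_len_at <- rep.int(r$lengths, r$lengths)
  big <- is.finite(model$hp_min_len) & run_len_at >= model$hp_min_len

  u <- stats::runif(len)
  ev <- integer(len)                       # 0 match, 1 mismatch, 2 deletion
  ev[u < p_del_ref] <- 2L
  ev[u >= p_del_ref & u < p_del_ref + p_mm_ref] <- 1L
  ev[big] <- 0L
  nins <- stats::rgeom(len, 1 - p_ins)
  nins[big] <- 0L
  nins[1L] <- 0L
  ins_is_hp <- integer(len)                # motif-content insertions per position

  # homopolymer length resampling for big runs
  if (any(big)) {
    bruns <- which(r$lengths >= model$hp_min_len)
    ends <- cumsum(r$lengths)
    for (b in bruns) {
      L <- r$lengths[b]
      fpos <- ends[b] - L + 1L; lpos <- ends[b]
      excess <- L - model$hp_min_len + 1
      if (stats::runif(1L) < model$hp_tail_prob) {
        delta <- 1L + stats::rgeom(1L, model$hp_tail_geom)
      } else {
        delta <- stats::rpois(1L, model$hp_lambda_ins * excess) -
                 stats::rpois(1L, model$hp_lambda_del * excess)
      }
      if (delta < 0L) {
        ndel <- min(-delta, L)
        ev[(lpos - ndel + 1L):lpos] <- 2L
      } else if (delta > 0L) {
        ins_is_hp[lpos] <- delta           # motif copies inserted before last base
      }
    }
    nins <- nins + ins_is_hp
  }

  # mismatch target bases under the transition-biased substitution matrix
  mm_idx <- which(ev == 1L)
  base_int <- as.integer(charToRaw(paste(.BASE_CHARS, collapse = "")))
  seg_b <- match(seg_int, base_int)        # 1..4, NA for N
  drop_mm <- mm_idx[is.na(seg_b[mm_idx])]
  if (length(drop_mm)) { ev[drop_mm] <- 0L; mm_idx <- setdiff(mm_idx, drop_mm) }
  mut <- integer(length(mm_idx))
  if (length(mm_idx)) {
    tm <- model$transition_multiplier
    # substitution target weights per genome base (columns A,C,G,T; 0 on diagonal)
    Wm <- matrix(1, 4, 4); diag(Wm) <- 0
    Wm[1L, 3L] <- tm; Wm[3L, 1L] <- tm    # A<->G
    Wm[2L, 4L] <- tm; Wm[4L, 2L] <- tm    # C<->T
    Wm <- Wm / rowSums(Wm)
    cw <- t(apply(Wm, 1L, cumsum))
    uu <- stats::runif(length(mm_idx))
    gb <- seg_b[mm_idx]
    mut <- max.col(cw[gb, , drop = FALSE] >= uu, ties.method = "first")
  }

  # assemble columns: per ref base, nins insertion columns then its bp/del column
  blk <- nins + 1L
  refcol_pos <- cumsum(blk)
  ncols <- refcol_pos[len]
  refcol <- rep.int(.GAP, ncols)
  refcol[refcol_pos] <- seg_raw
  readcol <- rep.int(.GAP, ncols)
  bp <- ev != 2L
  read_ref_bases <- seg_raw
  if (length(mm_idx)) read_ref_bases[mm_idx] <- as.raw(base_int[mut])
  readcol[refcol_pos[bp]] <- read_ref_bases[bp]
  n_ins_total <- ncols - len
  if (n_ins_total > 0L) {
    ins_cols <- setdiff(seq_len(ncols), refcol_pos)
    # content: motif base for homopolymer surplus, random otherwise
    owner <- rep.int(seq_len(len), blk)[ins_cols]   # ref base each insertion precedes? (by block)
    hp_owner <- ins_is_hp[owner] > 0L
    content <- integer(n_ins_total)
    content[hp_owner] <- seg_int[owner[hp_owner]]
    if (any(!hp_owner)) {
      content[!hp_owner] <- base_int[sample.int(4L, sum(!hp_owner), replace = TRUE)]
    }
    readcol[ins_cols] <- as.raw(content)
  }

  read_is_base <- readcol != .GAP
  read_seq_raw <- readcol[read_is_base]
  n_read <- length(read_seq_raw)

  hp_truth <- NULL
  if (want_hp_truth) {
    ends <- cumsum(r$lengths)
    cand <- which(r$lengths >= 2L & seq_along(r$lengths) > 1L &
                    seq_along(r$lengths) < length(r$lengths))
    if (length(cand)) {
      rbc <- cumsum(read_is_base)
      rr <- rle(as.integer(read_seq_raw))
      rr_of <- rep.int(seq_along(rr$lengths), rr$lengths)
      obs <- integer(length(cand))
      for (qi in seq_along(cand)) {
        b <- cand[qi]
        fpos <- ends[b] - r$lengths[b] + 1L; lpos <- ends[b]
        cf <- refcol_pos[fpos]; cl <- refcol_pos[lpos]
        r1 <- if (cf > 1L) rbc[cf - 1L] + 1L else 1L
        r2 <- rbc[cl]
        if (r2 < r1) { obs[qi] <- 0L; next }
        ri <- rr_of[r1]:rr_of[r2]
        hit <- ri[rr$values[ri] == r$values[b]]
        obs[qi] <- if (length(hit)) max(rr$lengths[hit]) else 0L
      }
      hp_truth <- data.table::data.table(
        seg_first = ends[cand] - r$lengths[cand] + 1L,   # 1-based in segment
        motif_int = r$values[cand],
        ref_length = r$lengths[cand],
        observed_length = obs)
    }
  }

  colop <- rep.int("I", ncols)
  colop[refcol_pos[bp]] <- "M"
  colop[refcol_pos[!bp]] <- "D"
  cr <- rle(colop)
  cigar <- paste0(cr$lengths, cr$values, collapse = "")

  list(refcol = refcol, readcol = readcol, cigar = cigar,
       read_seq_raw = read_seq_raw, q_emit = q_emit, p_tot = p_tot,
       n_mm = length(mm_idx), n_del = sum(ev == 2L), n_ins = n_ins_total,
       ncols = ncols, ev = ev, hp_truth = hp_truth)
}

#' Simulate a sequencing run with exact ground truth
#'
#' Reads are sampled uniformly from both strands of the reference; errors are
#' drawn per the model (see [error_model()]); qualities reflect the true
#' per-base error probability through the quality model; reads are written to
#' FASTQ and their alignments to two SAM files mirroring the dual-strand
#' protocol: forward-strand reads against the forward genome and
#' reverse-strand reads against the reverse-complemented genome, never
#' read-reverse-complemented. Truth tables carry exact per-read error counts
#' and, for the first `truth_repeat_reads` reads, the true observed length of
#' every reference homopolymer run (length >= 2) fully inside the read.
#'
#' @param reference A `reference_genome`.
#' @param model An `error_model_spec`.
#' @param n_reads Number of reads.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; a fixed seed reproduces every output file
#'   byte-identically.
#' @param read_meanlog,read_sdlog Log-normal read-length parameters (defaults:
#'   median 10 kb, sdlog 0.55).
#' @param read_range Truncation range for read lengths (default 500-100000).
#' @param truth_repeat_reads Record homopolymer truth for this many reads
#'   (default 0).
#' @param emit_events Write a per-base event-count table (translocation-speed
#'   analysis; event density is coupled to deletions via
#'   `model$speed_coupling`).
#' @param emit_mods Write a modification-call table (5mC calls on a fraction
#'   of read C bases).
#' @return A list with file `paths`, the `truth_reads` and `truth_repeats`
#'   tables, and the realised `config`.
#' @export
simulate_run <- function(reference, model = error_model(), n_reads = 100L,
                         out_dir = tempfile("nanoscape_run_"), seed = 1L,
                         read_meanlog = log(10000), read_sdlog = 0.55,
                         read_range = c(500, 100000),
                         truth_repeat_reads = 0L,
                         emit_events = FALSE, emit_mods = FALSE) {
  stopifnot(inherits(reference, "reference_genome"),
            inherits(model, "error_model_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  L <- reference$length
  paths <- list(
    reference = file.path(out_dir, "reference.fasta"),
    fastq = file.path(out_dir, "reads.fastq"),
    sam_forward = file.path(out_dir, "forward.sam"),
    sam_reverse = file.path(out_dir, "reverse.sam"),
    truth_reads = file.path(out_dir, "truth_reads.tsv"),
    truth_repeats = file.path(out_dir, "truth_repeats.tsv"),
    events = if (emit_events) file.path(out_dir, "events.tsv") else NULL,
    mods = if (emit_mods) file.path(out_dir, "mods.tsv") else NULL)

  writeLines(c(paste0(">", reference$name),
               substring(reference$sequence,
                         seq(1L, L, 70L), pmin(seq(1L, L, 70L) + 69L, L))),
             paths$reference)

  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", reference$name, "\tLN:", L))
  fq <- file(paths$fastq, "w"); fw <- file(paths$sam_forward, "w")
  rv <- file(paths$sam_reverse, "w")
  on.exit({ close(fq); close(fw); close(rv) }, add = TRUE)
  writeLines(header, fw); writeLines(header, rv)
  ev_con <- NULL; mod_con <- NULL
  if (emit_events) {
    ev_con <- file(paths$events, "w")
    on.exit(close(ev_con), add = TRUE)
    writeLines("read_id\tref_pos\tn_samples", ev_con)
  }
  if (emit_mods) {
    mod_con <- file(paths$mods, "w")
    on.exit(close(mod_con), add = TRUE)
    writeLines("read_id\tread_pos\tmod_type\tprobability", mod_con)
  }

  truth_rows <- vector("list", n_reads)
  hp_rows <- vector("list", n_reads)

  .with_seed(seed, {
    lens <- .sample_read_lengths(n_reads, read_meanlog, read_sdlog,
                                 read_range[1L], min(read_range[2L], L))
    lens <- pmin(lens, L)
    strands <- stats::runif(n_reads) < 0.5
    starts <- as.integer(floor(stats::runif(n_reads) * (L - lens + 1)))

    for (i in seq_len(n_reads)) {
      id <- sprintf("read_%06d", i)
      oriented <- if (strands[i]) reference$raw_fwd else reference$raw_rev
      seg <- oriented[(starts[i] + 1L):(starts[i] + lens[i])]
      gc_pct <- 100 * gc_fraction(seg)
      rr <- .render_read(seg, model, gc_pct,
                         want_hp_truth = i <= truth_repeat_reads)

      qual_chars <- strrep(intToUtf8(rr$q_emit + 33L), length(rr$read_seq_raw))
      seq_str <- rawToChar(rr$read_seq_raw)
      cigar <- rr$cigar
      clip <- model$clip_len
      if (clip > 0L) {
        cl <- paste(sample(.BASE_CHARS, clip, replace = TRUE), collapse = "")
        cr2 <- paste(sample(.BASE_CHARS, clip, replace = TRUE), collapse = "")
        seq_str <- paste0(cl, seq_str, cr2)
        qual_chars <- paste0(strrep(intToUtf8(rr$q_emit + 33L), clip), qual_chars,
                             strrep(intToUtf8(rr$q_emit + 33L), clip))
        cigar <- paste0(clip, "S", cigar, clip, "S")
      }

      writeLines(c(paste0("@", id), seq_str, "+", qual_chars), fq)
      rec <- paste(id, "0", reference$name, starts[i] + 1L, "60", cigar,
                   "*", "0", "0", seq_str, qual_chars, sep = "\t")
      writeLines(rec, if (strands[i]) fw else rv)

      if (emit_mods && model$mod_call_rate > 0) {
        cpos <- which(rr$read_seq_raw == charToRaw("C")) - 1L + clip
        call <- cpos[stats::runif(length(cpos)) < model$mod_call_rate]
        if (length(call)) {
          writeLines(paste(id, call, "5mC", "0.9", sep = "\t"), mod_con)
        }
      }
      if (emit_events) {
        mean_samp <- 4000 / 450
        samp <- 1L + stats::rpois(lens[i], mean_samp - 1)
        del_pos <- rr$ev == 2L
        if (any(del_pos) && model$speed_coupling != 1) {
          samp[del_pos] <- 1L + stats::rpois(sum(del_pos),
                                             pmax(mean_samp / model$speed_coupling - 1, 0))
        }
        opos <- starts[i]:(starts[i] + lens[i] - 1L)
        fpos <- if (strands[i]) opos else L - 1L - opos
        writeLines(paste(id, fpos, samp, sep = "\t"), ev_con)
      }

      truth_rows[[i]] <- data.table::data.table(
        read_id = id, orientation = if (strands[i]) "forward" else "reverse",
        ref_start = starts[i], seg_length = lens[i],
        alignment_length = rr$ncols, mismatches = rr$n_mm,
        insertions = rr$n_ins, deletions = rr$n_del,
        true_error_prob = rr$p_tot, emitted_quality = rr$q_emit,
        gc_percent = gc_pct)

      if (!is.null(rr$hp_truth)) {
        ht <- rr$hp_truth
        # map segment coordinates and motif to the forward genome
        if (strands[i]) {
          fstart <- starts[i] + ht$seg_first - 1L
          motif <- strsplit(rawToChar(as.raw(ht$motif_int)), "")[[1L]]
        } else {
          fstart <- L - (starts[i] + ht$seg_first - 1L + ht$ref_length)
          comp <- stats::setNames(c("T", "G", "C", "A"), .BASE_CHARS)
          motif <- unname(comp[strsplit(rawToChar(as.raw(ht$motif_int)), "")[[1L]]])
        }
        hp_rows[[i]] <- data.table::data.table(
          read_id = id, start = fstart, motif = motif,
          ref_length = ht$ref_length, observed_length = ht$observed_length,
          correct = ht$observed_length == ht$ref_length)
      }
    }
  })

  truth_reads <- data.table::rbindlist(truth_rows)
  truth_repeats <- data.table::rbindlist(hp_rows)
  data.table::fwrite(truth_reads, paths$truth_reads, sep = "\t")
  if (nrow(truth_repeats)) {
    data.table::fwrite(truth_repeats, paths$truth_repeats, sep = "\t")
  }

  list(paths = paths, truth_reads = truth_reads, truth_repeats = truth_repeats,
       config = list(n_reads = n_reads, seed = seed, model = model,
                     read_meanlog = read_meanlog, read_sdlog = read_sdlog,
                     read_range = read_range,
                     truth_repeat_reads = truth_repeat_reads))
}

#' Compare truth statistics with pipeline estimates
#'
#' @param truth Named numeric vector of true values.
#' @param estimate Named numeric vector of estimated values (same names).
#' @param tolerance Named or scalar absolute tolerance per statistic.
#' @return A `data.table` with `statistic`, `truth`, `estimate`,
#'   `abs_deviation`, `rel_deviation`, `tolerance`, `pass`.
#' @export
truth_comparison <- function(truth, estimate, tolerance = 0.005) {
  if (!setequal(names(truth), names(estimate))) {
    stop("truth and estimate name mismatch")
  }
  nm <- names(truth)
  tol <- if (length(tolerance) == 1L) rep(tolerance, length(nm)) else tolerance[nm]
  est <- estimate[nm]
  out <- data.table::data.table(
    statistic = nm, truth = as.numeric(truth), estimate = as.numeric(est),
    abs_deviation = abs(as.numeric(est) - as.numeric(truth)))
  out$rel_deviation <- ifelse(out$truth != 0, out$abs_deviation / abs(out$truth), NA_real_)
  out$tolerance <- as.numeric(tol)
  out$pass <- out$abs_deviation <= out$tolerance
  out
}

#' The package's default synthetic study fixture
#'
#' A 5 Mb reference with block-wise GC heterogeneity (GC 50% +/- 8% per 10 kb
#' block) sequenced to roughly 30X with the default error model plus a 4x
#' transition bias and a GC-error slope of 4e-4 per GC percent; homopolymer
#' truth is recorded for the first 2000 reads. This is the run every
#' end-to-end recovery check in the package is measured on.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving the whole fixture.
#' @param scale Linear scale factor on genome size and read count (1 = the
#'   full 5 Mb / 30X fixture); smaller values give proportionally smaller
#'   runs with the same model.
#' @return As [simulate_run()], plus the `reference` object.
#' @export
default_fixture <- function(out_dir, seed = 1L, scale = 1) {
  glen <- as.integer(round(5e6 * scale))
  reference <- generate_reference(glen, 0.5, seed = seed,
                                  gc_block_size = 10000L, gc_block_sd = 0.08)
  model <- error_model(transition_multiplier = 4, gc_error_slope = 4e-4)
  run <- simulate_run(reference, model, n_reads = as.integer(round(13000 * scale)),
                      out_dir = out_dir, seed = seed + 1L,
                      truth_repeat_reads = min(2000L, as.integer(round(13000 * scale))))
  run$reference <- reference
  run
}
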