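# Alignment I/O: reference handling, SAM parsing, per-base column expansion,
# dual-strand best-alignment selection and soft-clip filtering.

# Byte codes used in expanded alignment columns. The gap byte is "-".
.GAP <- as.raw(0x2D)
.N <- charToRaw("N")

#' Reverse-complement a DNA sequence
#'
#' Standard Watson-Crick complement followed by reversal. `N` maps to `N`.
#' Reads are kept in sequencing orientation throughout the package; it is the
#' reference genome that gets reverse-complemented when a read derives from
#' the reverse strand, so that substitution errors are labelled with the base
#' actually read by the pore.
#'
#' @param seq A character string over `{A,C,G,T,N}` (upper case).
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("ACGTCATTGC")  # "GCAATGACGT"
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("unknown character '", substr(seq, bad, bad), "' at position ", bad)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Load a reference genome from a FASTA file
#'
#' Only single-sequence references are supported (the analyses are anchored on
#' one coordinate frame). The sequence is upper-cased.
#'
#' @param path FASTA file.
#' @return A `reference_genome` object.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) stop("expected exactly one reference sequence, found ", length(set))
  reference_genome(sub("\\s.*$", "", names(set)[1L]), toupper(as.character(set[[1L]])))
}

#' Construct a reference genome object
#'
#' @param name Sequence name (used to match SAM `RNAME`).
#' @param sequence Upper-case base string over `{A,C,G,T,N}`.
#' @return A list of class `reference_genome` with fields `name`, `sequence`,
#'   `length`, plus cached byte representations of the forward and
#'   reverse-complemented strand.
#' @export
reference_genome <- function(name, sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) stop("invalid reference character at position ", bad)
  structure(
    list(
      name = name,
      sequence = sequence,
      length = nchar(sequence),
      raw_fwd = charToRaw(sequence),
      raw_rev = charToRaw(reverse_complement(sequence))
    ),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome>", x$name, "-", x$length, "bp, GC",
      sprintf("%.1f%%", 100 * gc_fraction(x$sequence)), "\n")
  invisible(x)
}

#' GC fraction of a sequence
#'
#' G+C over A+C+G+T; `N` is excluded from the denominator.
#'
#' @param seq Character string or raw byte vector.
#' @return Fraction in `[0, 1]`, or `NaN` for a sequence with no called bases.
#' @export
gc_fraction <- function(seq) {
  r <- if (is.raw(seq)) seq else charToRaw(seq)
  gc <- sum(r == charToRaw("G")) + sum(r == charToRaw("C"))
  at <- sum(r == charToRaw("A")) + sum(r == charToRaw("T"))
  gc / (gc + at)
}

#' Read a FASTQ file into a per-read table
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return A `data.table` with columns `read_id`, `length`, `mean_quality`
#'   (arithmetic mean of per-base Phred values).
#' @export
read_fastq_summary <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- Biostrings::quality(set)
  ids <- sub("\\s.*$", "", names(set))
  mq <- vapply(seq_along(set), function(i) {
    mean(utf8ToInt(as.character(quals[[i]])) - 33L)
  }, numeric(1))
  data.table::data.table(read_id = ids, length = Biostrings::width(set), mean_quality = mq)
}

# --- AlignedRead ------------------------------------------------------------

#' Construct an aligned read from expanded columns
#'
#' The expanded alignment is stored as three parallel per-column vectors:
#' reference byte, read byte (gap = `-`) and Phred quality (`NA` where the
#' read has a gap, i.e. at deletion columns). Coordinates are 0-based
#' half-open in the oriented genome (the forward genome for `orientation =
#' "forward"`, the reverse-complemented genome otherwise).
#'
#' @param read_id Read identifier.
#' @param orientation `"forward"` or `"reverse"`: which strand copy of the
#'   genome the read was aligned against.
#' @param ref_name Reference sequence name.
#' @param ref_start 0-based offset of the first aligned reference base in the
#'   oriented genome.
#' @param ref,read Raw vectors of equal length: per-column bytes.
#' @param qual Integer vector of per-column Phred values (`NA` at read gaps).
#' @param clip_left,clip_right Clipped bases (soft + hard) at either read end.
#' @param read_length Original read length including clips.
#' @return An `aligned_read` object.
#' @export
aligned_read <- function(read_id, orientation, ref_name, ref_start,
                         ref, read, qual, clip_left = 0L, clip_right = 0L,
                         read_length = NULL) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  stopifnot(is.raw(ref), is.raw(read), length(ref) == length(read),
            length(qual) == length(ref))
  if (any(ref == .GAP & read == .GAP)) stop("column with gap in both ref and read")
  n_read_bases <- sum(read != .GAP)
  if (is.null(read_length)) read_length <- n_read_bases + clip_left + clip_right
  x <- list(
    read_id = read_id, orientation = orientation, ref_name = ref_name,
    ref_start = as.integer(ref_start),
    ref = ref, read = read, qual = as.integer(qual),
    clip_left = as.integer(clip_left), clip_right = as.integer(clip_right),
    read_length = as.integer(read_length)
  )
  class(x) <- "aligned_read"
  x
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read> %s [%s] %s:%d, %d columns, clips %d+%d/%d\n",
              x$read_id, x$orientation, x$ref_name, x$ref_start,
              length(x$ref), x$clip_left, x$clip_right, x$read_length))
  invisible(x)
}

# Number of alignment columns.
ar_ncol <- function(x) length(x$ref)

# Logical vectors: which columns consume reference / read bases.
ar_ref_cols <- function(x) x$ref != .GAP
ar_read_cols <- function(x) x$read != .GAP

# 0-based oriented-genome position of each column's anchor. Base-pair and
# deletion columns anchor at their own reference base; insertion columns at
# the preceding reference base (leftmost convention), clamped to ref_start
# for insertions before the first aligned base.
ar_anchor_oriented <- function(x) {
  pmax(x$ref_start + cumsum(ar_ref_cols(x)) - 1L, x$ref_start)
}

#' Map per-column anchors to forward-genome coordinates
#'
#' Reads aligned against the reverse-complemented genome keep their columns in
#' that oriented frame; genome-window and region aggregation needs forward
#' coordinates. Position `p` in the oriented genome of length `L` maps to
#' `L - 1 - p` on the forward strand.
#'
#' @param x An `aligned_read`.
#' @param genome_length Length of the reference genome.
#' @return Integer vector of 0-based forward-genome anchor positions, one per
#'   alignment column.
#' @export
ar_anchor_forward <- function(x, genome_length) {
  a <- ar_anchor_oriented(x)
  if (x$orientation == "reverse") genome_length - 1L - a else a
}

# Per-column 0-based position in the original read (clips included); NA at
# deletion columns.
ar_read_positions <- function(x) {
  p <- rep(NA_integer_, ar_ncol(x))
  rc <- ar_read_cols(x)
  p[rc] <- x$clip_left + seq_len(sum(rc)) - 1L
  p
}

# The read bases (sequencing orientation, clips excluded) as a string.
ar_read_string <- function(x) rawToChar(x$read[ar_read_cols(x)])

# --- SAM parsing ------------------------------------------------------------

# Decode one CIGAR string into parallel op/length vectors; NULL when invalid.
.parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (sum(nchar(toks)) != nchar(cigar) || length(toks) == 0L) return(NULL)
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(sub(".$", "", toks)))
}

#' Parse SAM alignments into expanded per-base alignments
#'
#' Consumes a SAM file (or pre-read lines) of reads aligned against one strand
#' copy of the reference, with the aligner's read reverse-complementing
#' disabled, and reconstructs every record's per-column alignment from its
#' CIGAR: `M`/`=`/`X` consume both sequences, `I` produces an insertion column
#' (reference gap), `D`/`N` a deletion column (read gap), `S`/`H` are recorded
#' as clip lengths. Mismatches are resolved by comparing the read base to the
#' reference slice. Secondary, supplementary and unmapped records are skipped;
#' malformed records are skipped with diagnostics collected in the
#' `"skipped"` attribute of the result.
#'
#' @param sam Path to a SAM file, or a character vector of SAM lines.
#' @param reference A `reference_genome`. Must be the strand copy the records
#'   were aligned against (pass the forward genome for `orientation =
#'   "forward"`, and the same genome for `"reverse"`: the reverse-complemented
#'   byte cache is used internally).
#' @param orientation `"forward"` or `"reverse"`.
#' @return List of `aligned_read` objects, with attribute `skipped`: a
#'   `data.table` of (line, reason) for rejected records.
#' @export
parse_alignments <- function(sam, reference, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(reference, "reference_genome"))
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam
  body <- which(!startsWith(lines, "@"))
  ref_raw <- if (orientation == "forward") reference$raw_fwd else reference$raw_rev
  glen <- reference$length

  out <- vector("list", length(body))
  n_out <- 0L
  skipped_line <- integer(0)
  skipped_reason <- character(0)
  skip <- function(i, why) {
    skipped_line <<- c(skipped_line, i)
    skipped_reason <<- c(skipped_reason, why)
  }

  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) { skip(i, "fewer than 11 fields"); next }
    flag <- suppressWarnings(as.integer(f[2L]))
    pos <- suppressWarnings(as.integer(f[4L]))
    if (is.na(flag) || is.na(pos)) { skip(i, "non-numeric FLAG or POS"); next }
    if (bitwAnd(flag, 4L) != 0L) next                      # unmapped
    if (bitwAnd(flag, 256L) != 0L || bitwAnd(flag, 2048L) != 0L) next  # secondary/suppl.
    if (f[10L] == "*") { skip(i, "missing read sequence"); next }
    cig <- .parse_cigar(f[6L])
    if (is.null(cig)) { skip(i, "unparsable CIGAR"); next }
    op <- cig$op; len <- cig$len

    seq_len_ops <- sum(len[op %in% c("M", "=", "X", "I", "S")])
    if (seq_len_ops != nchar(f[10L])) { skip(i, "CIGAR/sequence length mismatch"); next }

    n_ops <- length(op)
    lead_clip <- 0L; trail_clip <- 0L; lead_soft <- 0L; trail_soft <- 0L
    a <- 1L
    while (a <= n_ops && op[a] %in% c("S", "H")) {
      lead_clip <- lead_clip + len[a]
      if (op[a] == "S") lead_soft <- lead_soft + len[a]
      a <- a + 1L
    }
    b <- n_ops
    while (b >= a && op[b] %in% c("S", "H")) {
      trail_clip <- trail_clip + len[b]
      if (op[b] == "S") trail_soft <- trail_soft + len[b]
      b <- b - 1L
    }
    if (b < a) { skip(i, "alignment with no aligned columns"); next }
    op_mid <- op[a:b]; len_mid <- len[a:b]
    if (any(op_mid %in% c("S", "H"))) { skip(i, "internal clip operation"); next }

    colop <- rep.int(op_mid, len_mid)
    refc <- colop %in% c("M", "=", "X", "D", "N")
    readc <- colop %in% c("M", "=", "X", "I")
    nref <- sum(refc)
    ref_start <- pos - 1L
    if (ref_start < 0L || ref_start + nref > glen) { skip(i, "alignment beyond reference end"); next }

    ncols <- length(colop)
    refcol <- rep.int(.GAP, ncols)
    refcol[refc] <- ref_raw[seq.int(ref_start + 1L, length.out = nref)]
    read_raw <- charToRaw(f[10L])
    aligned_read_raw <- read_raw[seq.int(lead_soft + 1L, length.out = sum(readc))]
    readcol <- rep.int(.GAP, ncols)
    readcol[readc] <- aligned_read_raw
    qualcol <- rep.int(NA_integer_, ncols)
    if (f[11L] != "*") {
      q <- utf8ToInt(f[11L]) - 33L
      if (length(q) != nchar(f[10L])) { skip(i, "quality/sequence length mismatch"); next }
      qualcol[readc] <- q[seq.int(lead_soft + 1L, length.out = sum(readc))]
    }

    n_out <- n_out + 1L
    out[[n_out]] <- aligned_read(
      read_id = f[1L], orientation = orientation, ref_name = f[3L],
      ref_start = ref_start, ref = refcol, read = readcol, qual = qualcol,
      clip_left = lead_clip, clip_right = trail_clip,
      read_length = nchar(f[10L]) + (lead_clip - lead_soft) + (trail_clip - trail_soft)
    )
  }
  out <- out[seq_len(n_out)]
  attr(out, "skipped") <- data.table::data.table(line = skipped_line, reason = skipped_reason)
  out
}

#' Keep each read's best alignment across the two genome strands
#'
#' The dual-strand protocol aligns unmodified reads once against the forward
#' genome and once against its reverse complement; each read keeps the
#' alignment with the lower global error rate. Ties break toward the forward
#' orientation (deterministic and aligner-score independent). Reads present in
#' only one list keep that alignment.
#'
#' @param forward,reverse Lists of `aligned_read` parsed against the
#'   corresponding genome orientation.
#' @return A list with one `aligned_read` per distinct `read_id`.
#' @export
select_best_strand <- function(forward, reverse) {
  if (length(forward) == 0L) return(reverse)
  if (length(reverse) == 0L) return(forward)
  fid <- vapply(forward, `[[`, character(1), "read_id")
  rid <- vapply(reverse, `[[`, character(1), "read_id")
  out <- forward
  only_r <- !(rid %in% fid)
  out <- c(out, reverse[only_r])
  both <- which(rid %in% fid)
  if (length(both)) {
    fidx <- match(rid[both], fid)
    for (j in seq_along(both)) {
      fe <- decompose_errors(forward[[fidx[j]]])$global_error_rate
      re <- decompose_errors(reverse[[both[j]]])$global_error_rate
      if (re < fe) out[[fidx[j]]] <- reverse[[both[j]]]
    }
  }
  out
}

#' Discard reads dominated by soft clips
#'
#' A read is discarded when its total clipped length exceeds
#' `max_clip_fraction` of the original read length (strict inequality: a read
#' clipped on exactly half its length is kept). Hard clips count like soft
#' clips: both represent unaligned read sequence.
#'
#' @param reads List of `aligned_read`.
#' @param max_clip_fraction Maximum tolerated clipped fraction (default 0.5).
#' @return List with elements `kept` and `discarded` (an exhaustive, disjoint
#'   partition of the input).
#' @export
filter_softclipped <- function(reads, max_clip_fraction = 0.5) {
  if (length(reads) == 0L) return(list(kept = reads, discarded = list()))
  frac <- vapply(reads, function(x) (x$clip_left + x$clip_right) / x$read_length, numeric(1))
  list(kept = reads[frac <= max_clip_fraction], discarded = reads[frac > max_clip_fraction])
}

#' Bundle a reference and its selected alignments
#'
#' @param reference A `reference_genome`.
#' @param reads List of `aligned_read` (one best alignment per read).
#' @param species Optional label.
#' @return A `run_bundle` with a `gc_class` of `"low"` when reference GC < 50%
#'   and `"high"` otherwise.
#' @export
run_bundle <- function(reference, reads, species = "synthetic") {
  ids <- vapply(reads, `[[`, character(1), "read_id")
  if (anyDuplicated(ids)) stop("duplicate read_id in bundle: ", ids[duplicated(ids)][1L])
  structure(
    list(reference = reference, reads = reads, species = species,
         gc_class = if (gc_fraction(reference$sequence) < 0.5) "low" else "high"),
    class = "run_bundle"
  )
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("<run_bundle> %s: %d reads on %s (%s GC)\n",
              x$species, length(x$reads), x$reference$name, x$gc_class))
  invisible(x)
}
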