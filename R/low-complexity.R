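# Low-complexity repeats: detection of homopolymers, heteropolymers and
# trinucleotide repeats on the reference, per-read assessment of their
# rendering, error attribution and length-deviation profiles.

#' Find maximal low-complexity repeats on the forward strand
#'
#' Three kinds are supported:
#' * `homopolymer`: `k >= 2` consecutive copies of one base;
#' * `heteropolymer`: `k >= 2` consecutive copies of a two-base unit `XY`
#'   with `X != Y` (total length `2k`; a trailing odd base is ignored, so
#'   `ACACA` counts as `AC` x2);
#' * `trinucleotide`: `k >= 2` consecutive copies of a 3-base unit `XYZ`,
#'   excluding pure single-base units (`XXX`); occurrences are reported per
#'   phase, so overlapping occurrences of rotated motifs all appear.
#'
#' Every reported occurrence is maximal: it cannot be extended by another
#' whole unit copy on either side. Runs containing `N` are not reported.
#'
#' @param reference A `reference_genome` or a plain base string.
#' @param kind One of `"homopolymer"`, `"heteropolymer"`, `"trinucleotide"`.
#' @return A `data.table` with `kind`, `motif`, `start`, `end` (0-based
#'   half-open, forward genome), `copies`, `length`.
#' @export
find_repeats <- function(reference, kind = c("homopolymer", "heteropolymer",
                                             "trinucleotide")) {
  kind <- match.arg(kind)
  seq <- if (inherits(reference, "reference_genome")) reference$sequence else reference
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  empty <- data.table::data.table(kind = character(0), motif = character(0),
                                  start = integer(0), end = integer(0),
                                  copies = integer(0), length = integer(0))
  if (kind == "homopolymer") {
    if (n == 0L) return(empty)
    r <- rle(s)
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= 2L & r$values != "N"
    if (!any(keep)) return(empty)
    len <- r$lengths[keep]
    return(data.table::data.table(
      kind = kind, motif = r$values[keep],
      start = (ends[keep] - len), end = ends[keep],
      copies = len, length = len))
  }

  period_regions <- function(p) {
    # maximal stretches of TRUE in p; region [i, j] means period holds there
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }

  if (kind == "heteropolymer") {
    if (n < 4L) return(empty)
    p <- s[1:(n - 2L)] == s[3:n]
    reg <- period_regions(p)
    rows <- vector("list", nrow(reg))
    for (q in seq_len(nrow(reg))) {
      i <- reg[q, 1L]; len <- reg[q, 2L] + 2L - i + 1L
      x <- s[i]; y <- s[i + 1L]
      if (x == y || x == "N" || y == "N") next
      k <- len %/% 2L
      if (k < 2L) next
      rows[[q]] <- data.table::data.table(
        kind = kind, motif = paste0(x, y),
        start = i - 1L, end = i - 1L + 2L * k, copies = k, length = 2L * k)
    }
    out <- data.table::rbindlist(rows)
    return(if (nrow(out)) out[order(out$start)] else empty)
  }

  # trinucleotide
  if (n < 6L) return(empty)
  p <- s[1:(n - 3L)] == s[4:n]
  reg <- period_regions(p)
  rows <- list()
  for (q in seq_len(nrow(reg))) {
    i <- reg[q, 1L]; reg_end <- reg[q, 2L] + 3L
    for (o in 0:2) {
      st <- i + o
      avail <- reg_end - st + 1L
      k <- avail %/% 3L
      if (k < 2L) next
      m <- s[st:(st + 2L)]
      if (m[1L] == m[2L] && m[2L] == m[3L]) next      # pure homopolymer unit
      if (any(m == "N")) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        kind = kind, motif = paste(m, collapse = ""),
        start = st - 1L, end = st - 1L + 3L * k, copies = k, length = 3L * k)
    }
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) out[order(out$start)] else empty
}

#' Occurrence counts per motif class and length
#'
#' Counts repeat occurrences on the forward strand only. For heteropolymers,
#' symmetric dinucleotides (e.g. `AC` and `CA`) are pooled; for trinucleotide
#' repeats the strong/weak group of [classify_trinucleotide()] is used as the
#' class.
#'
#' @param reference A `reference_genome` or base string.
#' @param kind Repeat kind.
#' @return A `data.table` with `motif_class`, `length`, `n`.
#' @export
repeat_length_distribution <- function(reference, kind = "homopolymer") {
  occ <- find_repeats(reference, kind)
  if (nrow(occ) == 0L) {
    return(data.table::data.table(motif_class = character(0), length = integer(0),
                                  n = integer(0)))
  }
  cls <- switch(kind,
    homopolymer = occ$motif,
    heteropolymer = vapply(occ$motif, function(m) {
      ch <- sort(strsplit(m, "")[[1L]])
      paste0(ch[1L], ch[2L], "/", ch[2L], ch[1L])
    }, character(1)),
    trinucleotide = vapply(occ$motif, classify_trinucleotide, character(1)))
  occ$motif_class <- cls
  occ[, list(n = .N), keyby = list(motif_class, length)]
}

#' Classify a trinucleotide motif into strong/weak groups
#'
#' Bases are grouped as strong `S = {C, G}` and weak `W = {A, T}`; the motif's
#' group is set by its number of strong bases: 3 -> `S-only`, 2 -> `mostly-S`,
#' 1 -> `mostly-W`, 0 -> `W-only` (e.g. the `W-only` group gathers AAT, ATA,
#' TAA, ATT, TAT, TTA).
#'
#' @param motif A 3-base string over `{A,C,G,T}`.
#' @return One of `"S-only"`, `"mostly-S"`, `"mostly-W"`, `"W-only"`.
#' @export
classify_trinucleotide <- function(motif) {
  ch <- strsplit(motif, "")[[1L]]
  if (length(ch) != 3L || !all(ch %in% .BASE_CHARS)) {
    stop("invalid trinucleotide motif: ", motif)
  }
  c("W-only", "mostly-W", "mostly-S", "S-only")[sum(ch %in% c("C", "G")) + 1L]
}

# Vectorised reverse complement for 1-3 base motifs (hot path: every
# occurrence of every reverse-orientation read).
.revcomp_motif <- function(m) {
  comp <- chartr("ACGTN", "TGCAN", m)
  n <- nchar(comp)
  out <- comp
  i2 <- n == 2L
  if (any(i2)) out[i2] <- paste0(substr(comp[i2], 2L, 2L), substr(comp[i2], 1L, 1L))
  i3 <- n == 3L
  if (any(i3)) {
    out[i3] <- paste0(substr(comp[i3], 3L, 3L), substr(comp[i3], 2L, 2L),
                      substr(comp[i3], 1L, 1L))
  }
  out
}

#' Assess how reads render repeat occurrences
#'
#' For each repeat occurrence fully covered by a read's aligned span, the
#' observed rendering is measured. For homopolymers the observed length is the
#' maximal run of the motif base in the read overlapping the occurrence
#' (adjacent same-base read context extends it, making the measure invariant
#' to where the aligner placed indels); the occurrence is correct iff that run
#' has exactly the reference length. For heteropolymers and trinucleotide
#' repeats, the observed length is the longest unit-aligned repetition of the
#' motif in the read overlapping the occurrence (in motif units times unit
#' length), and correctness additionally requires the read segment under the
#' occurrence to be exactly `copies` motif copies. Occurrences not fully
#' spanned by the read are skipped.
#'
#' Reverse-orientation reads are assessed in their oriented frame: the
#' occurrence interval is mirrored and the motif reverse-complemented, which
#' leaves length and correctness invariant.
#'
#' @param reads List of `aligned_read`, or a single `aligned_read`.
#' @param occurrences Occurrence table from [find_repeats()] (single kind).
#' @param reference The `reference_genome`.
#' @return A `data.table` with `read_id`, `kind`, `motif`, `start`,
#'   `ref_length`, `observed_length`, `correct`, and per-occurrence error
#'   counts `mismatches`, `insertions`, `deletions` within the occurrence
#'   interval.
#' @export
assess_repeats <- function(reads, occurrences, reference) {
  if (inherits(reads, "aligned_read")) reads <- list(reads)
  L <- reference$length
  kind <- if (nrow(occurrences)) occurrences$kind[1L] else "homopolymer"
  res <- lapply(reads, function(x) .assess_one_read(x, occurrences, L, kind))
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(
      read_id = character(0), kind = character(0), motif = character(0),
      start = integer(0), ref_length = integer(0), observed_length = integer(0),
      correct = logical(0), mismatches = integer(0), insertions = integer(0),
      deletions = integer(0))
  }
  out
}

#' @rdname assess_repeats
#' @param read An `aligned_read`.
#' @param occ A single-row occurrence table.
#' @export
assess_repeat <- function(read, occ, reference) {
  assess_repeats(list(read), occ, reference)
}

.assess_one_read <- function(x, occ, L, kind) {
  if (nrow(occ) == 0L) return(NULL)
  # occurrence interval in the read's oriented frame
  if (x$orientation == "reverse") {
    os <- L - occ$end; oe <- L - occ$start
  } else {
    os <- occ$start; oe <- occ$end
  }
  nref <- sum(ar_ref_cols(x))
  span_lo <- x$ref_start; span_hi <- x$ref_start + nref
  keep <- which(os >= span_lo & oe <= span_hi)
  if (!length(keep)) return(NULL)
  os <- os[keep]; oe <- oe[keep]
  ord <- order(os)
  os <- os[ord]; oe <- oe[ord]; keep <- keep[ord]
  motif <- if (x$orientation == "reverse") .revcomp_motif(occ$motif[keep]) else occ$motif[keep]

  anchors <- ar_anchor_oriented(x)
  cls <- ar_column_class(x)
  readc <- ar_read_cols(x)
  rbi <- cumsum(readc)
  errind <- cls == .COL_MISMATCH
  mmcum <- c(0L, cumsum(errind))
  inscum <- c(0L, cumsum(cls == .COL_INS))
  delcum <- c(0L, cumsum(cls == .COL_DEL))

  # column range per occurrence: first column anchored >= os, last <= oe-1
  c1 <- findInterval(os - 1L, anchors) + 1L
  c2 <- findInterval(oe - 1L, anchors)
  # read-base index range covered
  rbi0 <- c(0L, rbi)
  r1 <- rbi0[c1] + 1L
  r2 <- rbi0[pmin(c2, length(rbi)) + 1L]

  read_bases <- x$read[readc]
  runs <- rle(as.integer(read_bases))
  run_ends <- cumsum(runs$lengths)
  run_of <- rep.int(seq_along(runs$lengths), runs$lengths)

  n <- length(os)
  observed <- integer(n)
  correct <- logical(n)
  mm <- mmcum[c2 + 1L] - mmcum[c1]
  ins <- inscum[c2 + 1L] - inscum[c1]
  del <- delcum[c2 + 1L] - delcum[c1]

  if (kind == "homopolymer") {
    mbyte <- as.integer(charToRaw(paste(substr(motif, 1L, 1L), collapse = "")))
    for (i in seq_len(n)) {
      if (r2[i] < r1[i]) { observed[i] <- 0L; next }
      ri <- run_of[r1[i]]:run_of[r2[i]]
      hit <- ri[runs$values[ri] == mbyte[i]]
      observed[i] <- if (length(hit)) max(runs$lengths[hit]) else 0L
    }
    correct <- observed == (oe - os)
  } else {
    rs <- rawToChar(read_bases)
    mlen <- nchar(motif)
    for (i in seq_len(n)) {
      if (r2[i] < r1[i]) {            # occurrence entirely deleted in read
        observed[i] <- 0L
        correct[i] <- FALSE
        next
      }
      flank <- 3L * mlen[i]
      w1 <- max(1L, r1[i] - flank); w2 <- min(nchar(rs), r2[i] + flank)
      seg <- substr(rs, r1[i], r2[i])
      ctx <- substr(rs, w1, w2)
      mres <- gregexpr(paste0("(?:", motif[i], ")+"), ctx)[[1L]]
      obs <- 0L
      if (mres[1L] != -1L) {
        mstart <- w1 + as.integer(mres) - 1L
        mlen_match <- attr(mres, "match.length")
        mend <- mstart + mlen_match - 1L
        ov <- mstart <= r2[i] & mend >= r1[i]
        if (any(ov)) obs <- max(mlen_match[ov])
      }
      observed[i] <- obs
      correct[i] <- obs == (oe[i] - os[i]) &&
        seg == strrep(motif[i], (oe[i] - os[i]) / mlen[i])
    }
  }

  data.table::data.table(
    read_id = x$read_id, kind = kind,
    motif = if (x$orientation == "reverse") .revcomp_motif(motif) else motif,
    start = if (x$orientation == "reverse") L - oe else os,
    ref_length = oe - os, observed_length = observed, correct = correct,
    mismatches = mm, insertions = ins, deletions = del)
}

#' Fraction of correctly sequenced repeats by reference length
#'
#' @param assessments Table from [assess_repeats()], optionally carrying extra
#'   stratum columns.
#' @param by Optional character vector of stratum columns (e.g. `"motif"`).
#' @param min_count Strata/length cells with fewer assessments are suppressed
#'   (default 1).
#' @return A `data.table` with the stratum columns, `ref_length`, `n`,
#'   `accuracy`.
#' @export
repeat_accuracy_by_length <- function(assessments, by = NULL, min_count = 1L) {
  grp <- c(by, "ref_length")
  out <- assessments[, list(n = .N, accuracy = mean(correct)), keyby = grp]
  out[out$n >= min_count, ]
}

#' Length-deviation profile of repeat renderings
#'
#' Distribution of observed minus reference length per reference length:
#' quartiles and extremes, suitable for semi-log box plots.
#'
#' @param assessments Table from [assess_repeats()].
#' @return A `data.table` with `ref_length`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max` of the deviation, and `mean_deviation`.
#' @export
length_deviation_profile <- function(assessments) {
  assessments[, {
    d <- observed_length - ref_length
    qs <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(n = .N, min = min(d), q1 = qs[1L], median = qs[2L], q3 = qs[3L],
         max = max(d), mean_deviation = mean(d))
  }, keyby = "ref_length"]
}

#' Attribute errors to homopolymeric regions
#'
#' An error is homopolymer-attributed iff its forward-genome anchor lies in a
#' homopolymer interval; insertions additionally count when anchored at the
#' base immediately before the interval (aligners place boundary insertions
#' ambiguously). Reported as H (errors in homopolymers), A (all errors) and
#' the ratio H/A per error type and globally.
#'
#' @param reads List of `aligned_read`.
#' @param occurrences Homopolymer occurrence table from [find_repeats()].
#' @param reference The `reference_genome`.
#' @return A `data.table` with rows mismatches/insertions/deletions/global and
#'   columns `H`, `A`, `ratio_pct`.
#' @export
attribute_errors_to_homopolymers <- function(reads, occurrences, reference) {
  stopifnot(all(occurrences$kind == "homopolymer"))
  L <- reference$length
  mask <- logical(L)       # homopolymer bases
  mask_ins <- logical(L)   # insertion anchors: interval plus left boundary base
  for (i in seq_len(nrow(occurrences))) {
    s <- occurrences$start[i]; e <- occurrences$end[i]
    mask[(s + 1L):e] <- TRUE
    mask_ins[max(1L, s):e] <- TRUE
  }
  H <- c(mismatches = 0, insertions = 0, deletions = 0)
  A <- c(mismatches = 0, insertions = 0, deletions = 0)
  for (x in reads) {
    a <- ar_anchor_forward(x, L) + 1L
    cls <- ar_column_class(x)
    for (j in 1:3) {
      code <- c(.COL_MISMATCH, .COL_INS, .COL_DEL)[j]
      sel <- cls == code
      A[j] <- A[j] + sum(sel)
      m <- if (code == .COL_INS) mask_ins else mask
      H[j] <- H[j] + sum(m[a[sel]])
    }
  }
  out <- data.table::data.table(
    error_type = c("mismatches", "insertions", "deletions", "global"),
    H = c(H, sum(H)), A = c(A, sum(A)))
  out$ratio_pct <- ifelse(out$A > 0, 100 * out$H / out$A, NA_real_)
  out
}
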