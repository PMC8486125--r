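# Translocation-speed analysis from per-reference-base signal event counts.

#' Translocation speed of bases through the pore
#'
#' `S = N / E * R` for `N` bases covered by `E` raw-signal samples at sampling
#' rate `R` (4000 samples/s for current devices). The expected speed for the
#' R9.4 chemistry is roughly constant at 450 bases per second.
#'
#' @param n_bases Number of reference bases traversed (`>= 1`).
#' @param n_samples Raw-signal samples assigned to them (`> 0`).
#' @param sampling_rate Samples per second (default 4000).
#' @return Speed in bases per second.
#' @export
translocation_speed <- function(n_bases, n_samples, sampling_rate = 4000) {
  stopifnot(all(n_bases >= 1))
  if (any(n_samples <= 0)) stop("n_samples must be positive")
  n_bases / n_samples * sampling_rate
}

#' Read a per-base event-count table
#'
#' The table a signal resquiggler emits: one row per (read, reference base)
#' with the number of raw samples assigned to that base.
#'
#' @param path TSV with columns `read_id`, `ref_pos` (0-based forward-genome
#'   position), `n_samples`.
#' @param sampling_rate Samples per second (default 4000).
#' @return A `data.table` with attribute `sampling_rate`.
#' @export
read_event_table <- function(path, sampling_rate = 4000) {
  dt <- data.table::fread(path)
  stopifnot(all(c("read_id", "ref_pos", "n_samples") %in% names(dt)))
  if (any(dt$n_samples < 1)) stop("n_samples must be >= 1")
  data.table::setattr(dt, "sampling_rate", sampling_rate)
  dt
}

#' Error rates by translocation speed
#'
#' Each read's reference span is tiled into windows of `window` reference
#' bases; a window's speed comes from its summed event samples
#' (reference-anchored: deleted bases still count toward `N`), and its error
#' rates from the read's alignment columns anchored in it. Windows without
#' full event coverage are skipped. Window points are then binned by speed.
#'
#' @param reads List of `aligned_read`.
#' @param events Event table (see [read_event_table()]).
#' @param reference The `reference_genome`.
#' @param window Window length in reference bases (default 25).
#' @param bin_width Speed bin width in bases/second (default 50).
#' @return A `data.table` with `speed` (bin midpoint), `support` (windows) and
#'   mean `mismatch_rate`, `insertion_rate`, `deletion_rate`,
#'   `global_error_rate` per bin.
#' @export
error_vs_speed <- function(reads, events, reference, window = 25L,
                           bin_width = 50) {
  rate <- attr(events, "sampling_rate")
  if (is.null(rate)) rate <- 4000
  L <- reference$length
  ev <- split(events, by = "read_id", keep.by = FALSE)
  acc <- vector("list", length(reads))
  for (k in seq_along(reads)) {
    x <- reads[[k]]
    e <- ev[[x$read_id]]
    if (is.null(e)) next
    samp <- stats::setNames(e$n_samples, e$ref_pos)
    a <- ar_anchor_forward(x, L)
    lo <- min(a); hi <- max(a)
    nwin <- (hi - lo + 1L) %/% window
    if (nwin < 1L) next
    cls <- ar_column_class(x)
    rows <- vector("list", nwin)
    for (wi in seq_len(nwin)) {
      ws <- lo + (wi - 1L) * window; we <- ws + window - 1L
      s <- samp[as.character(ws:we)]
      if (anyNA(s)) next                   # window without full event coverage
      sel <- a >= ws & a <= we
      ncols <- sum(sel)
      if (ncols == 0L) next
      cw <- cls[sel]
      rows[[wi]] <- data.table::data.table(
        speed = translocation_speed(window, sum(s), rate),
        mm = sum(cw == .COL_MISMATCH) / ncols,
        ins = sum(cw == .COL_INS) / ncols,
        del = sum(cw == .COL_DEL) / ncols,
        glob = sum(cw != .COL_MATCH & cw != .COL_AMBIG) / ncols)
    }
    acc[[k]] <- data.table::rbindlist(rows)
  }
  dt <- data.table::rbindlist(acc)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(speed = numeric(0), support = integer(0),
                                  mismatch_rate = numeric(0),
                                  insertion_rate = numeric(0),
                                  deletion_rate = numeric(0),
                                  global_error_rate = numeric(0)))
  }
  dt[, list(support = .N, mismatch_rate = mean(mm), insertion_rate = mean(ins),
            deletion_rate = mean(del), global_error_rate = mean(glob)),
     keyby = list(speed = (floor(speed / bin_width) + 0.5) * bin_width)]
}
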