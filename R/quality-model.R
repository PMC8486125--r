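# Quality-score handling: Phred conversions, window quality/error calibration,
# quadratic error model, threshold/retention trade-off.

#' Phred score to error probability and back
#'
#' `Q = -10 log10(P)`, so `P = 10^(-Q/10)`: a Phred score of 10 corresponds to
#' a 10% error probability, 20 to 1%.
#'
#' @param Q Phred score(s), `>= 0`.
#' @return Error probabilities in `(0, 1]`.
#' @export
phred_error_probability <- function(Q) {
  if (any(Q < 0)) stop("negative Phred score")
  10^(-Q / 10)
}

#' @rdname phred_error_probability
#' @param P Error probabilities in `(0, 1]`; `P = 0` is rejected.
#' @export
phred_from_probability <- function(P) {
  if (any(P <= 0)) stop("error probability must be > 0")
  -10 * log10(P)
}

#' Quality/error calibration points from sliding read windows
#'
#' Windows of `window` read bases slide along each aligned read with the given
#' stride; deletion columns enclosed in a window contribute to its error count
#' but carry no quality. Per window the arithmetic mean Phred quality (rounded
#' to 0.1) and the error rate over its alignment columns are computed; windows
#' are then aggregated by rounded quality. Reads shorter than the window
#' contribute a single whole-read window. With
#' `quality_mean = "probability"`, the window quality is `-10 log10` of the
#' mean per-base error probability instead (the domain basecallers use for
#' read-level scores).
#'
#' @param reads List of `aligned_read` (with per-base qualities).
#' @param window Window size in read bases (default 100).
#' @param stride Slide step in read bases (default 25; 1 recovers full
#'   base-by-base sliding).
#' @param quality_mean `"arithmetic"` (default) or `"probability"`.
#' @return A `data.table` with `mean_quality` (rounded to 0.1),
#'   `observed_error_rate` (pooled errors over pooled columns for the bin) and
#'   `support` (number of windows).
#' @export
window_quality_error <- function(reads, window = 100L, stride = 25L,
                                 quality_mean = c("arithmetic", "probability")) {
  quality_mean <- match.arg(quality_mean)
  acc <- vector("list", length(reads))
  for (k in seq_along(reads)) {
    x <- reads[[k]]
    readc <- ar_read_cols(x)
    n_rb <- sum(readc)
    if (n_rb == 0L) next
    rb_cols <- which(readc)
    w <- min(window, n_rb)
    starts <- if (n_rb <= window) 1L else seq.int(1L, n_rb - window + 1L, by = stride)
    c1 <- rb_cols[starts]
    c2 <- rb_cols[starts + w - 1L]
    cls <- ar_column_class(x)
    err <- cls == .COL_MISMATCH | cls == .COL_INS | cls == .COL_DEL
    errcum <- c(0L, cumsum(err))
    qv <- x$qual
    if (quality_mean == "arithmetic") {
      qcum <- c(0, cumsum(ifelse(is.na(qv), 0, qv)))
      qmean <- (qcum[c2 + 1L] - qcum[c1]) / w
    } else {
      pcum <- c(0, cumsum(ifelse(is.na(qv), 0, 10^(-qv / 10))))
      qmean <- -10 * log10((pcum[c2 + 1L] - pcum[c1]) / w)
    }
    acc[[k]] <- data.table::data.table(
      q = round(qmean, 1L),
      errors = errcum[c2 + 1L] - errcum[c1],
      cols = c2 - c1 + 1L)
  }
  dt <- data.table::rbindlist(acc)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(mean_quality = numeric(0),
                                  observed_error_rate = numeric(0),
                                  support = integer(0)))
  }
  dt[, list(observed_error_rate = sum(errors) / sum(cols), support = .N),
     keyby = list(mean_quality = q)]
}

#' Fit the quadratic quality/error model
#'
#' Weighted least squares of the observed error percentage on quality,
#' `E = a Q^2 + b Q + c` with weights equal to bin support, restricted to the
#' fit range (the range where nanopore scores are informative).
#'
#' @param points Calibration table from [window_quality_error()].
#' @param fit_range Quality range used for the fit (default `c(7, 30)`).
#' @return A `quality_error_model`: list with `a`, `b`, `c` (percent scale),
#'   `r_squared`, `fit_range`, `n_points`.
#' @export
fit_quality_error_model <- function(points, fit_range = c(7, 30)) {
  pts <- points[points$mean_quality >= fit_range[1L] &
                points$mean_quality <= fit_range[2L], ]
  if (length(unique(pts$mean_quality)) < 3L) {
    stop("need at least 3 distinct quality values in [",
         fit_range[1L], ", ", fit_range[2L], "]")
  }
  E <- 100 * pts$observed_error_rate
  Q <- pts$mean_quality
  fit <- stats::lm(E ~ Q + I(Q^2), weights = pts$support)
  ss_res <- sum(pts$support * stats::residuals(fit)^2)
  mw <- stats::weighted.mean(E, pts$support)
  ss_tot <- sum(pts$support * (E - mw)^2)
  structure(list(
    a = unname(stats::coef(fit)["I(Q^2)"]),
    b = unname(stats::coef(fit)["Q"]),
    c = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = 1 - ss_res / ss_tot,
    fit_range = fit_range, n_points = nrow(pts)
  ), class = "quality_error_model")
}

#' @export
print.quality_error_model <- function(x, ...) {
  cat(sprintf("<quality_error_model> E(%%) = %.4f Q^2 %+.3f Q %+.3f  (R^2 = %.3f, Q in [%g, %g])\n",
              x$a, x$b, x$c, x$r_squared, x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' Predicted error percentage at given qualities
#'
#' @param object A `quality_error_model`.
#' @param Q Quality scores.
#' @param ... Unused.
#' @export
predict.quality_error_model <- function(object, Q, ...) {
  object$a * Q^2 + object$b * Q + object$c
}

#' Read retention and error trade-off across quality thresholds
#'
#' For each threshold, reads with mean quality at or above it are kept; the
#' kept fraction (relative to the lowest threshold) and the mean error rate of
#' kept reads are reported. The attribute `loss` carries the (error-loss,
#' read-loss) pair between `loss_thresholds` (default 7 and 10): each is the
#' between-threshold difference divided by the value at the lower threshold.
#'
#' @param reads List of `aligned_read` or a [read_error_table()] table.
#' @param thresholds Quality thresholds (default `7:12`).
#' @param loss_thresholds Two thresholds for the loss pair (default
#'   `c(7, 10)`).
#' @param quality_mean `"arithmetic"` (default) or `"probability"` per-read
#'   mean quality.
#' @return A `data.table` with `threshold`, `n_kept`, `reads_kept`,
#'   `mean_error`.
#' @export
read_retention_by_threshold <- function(reads, thresholds = 7:12,
                                        loss_thresholds = c(7, 10),
                                        quality_mean = c("arithmetic", "probability")) {
  quality_mean <- match.arg(quality_mean)
  tab <- if (data.table::is.data.table(reads)) reads else read_error_table(reads)
  mq <- if (quality_mean == "arithmetic") {
    tab$mean_quality
  } else if ("mean_quality_prob" %in% names(tab)) {
    tab$mean_quality_prob
  } else {
    tab$mean_quality
  }
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(t) {
    keep <- mq >= t
    data.table::data.table(
      threshold = t, n_kept = sum(keep),
      mean_error = if (any(keep)) mean(tab$global_error_rate[keep]) else NA_real_)
  })
  out <- data.table::rbindlist(rows)
  base_n <- out$n_kept[1L]
  out$reads_kept <- if (base_n > 0) out$n_kept / base_n else NA_real_
  lo <- out[out$threshold == loss_thresholds[1L]]
  hi <- out[out$threshold == loss_thresholds[2L]]
  loss <- if (nrow(lo) == 1L && nrow(hi) == 1L && lo$n_kept > 0) {
    list(read_loss = (lo$n_kept - hi$n_kept) / lo$n_kept,
         error_loss = (lo$mean_error - hi$mean_error) / lo$mean_error)
  } else NULL
  data.table::setcolorder(out, c("threshold", "n_kept", "reads_kept", "mean_error"))
  attr(out, "loss") <- loss
  out
}
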