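# Perfect k-mer statistics, seed-size bounds, harmful k-mer mining and the
# layered letter automaton over top error-context k-mers.

#' Length of the longest error-free stretch of a read
#'
#' The longest run of consecutive match columns (no mismatch and no indel
#' column inside; clipped ends are excluded by construction). This bounds the
#' seed sizes exact mapping algorithms can rely on.
#'
#' @param read An `aligned_read`.
#' @return Length in bases (0 when no column matches).
#' @export
longest_perfect_kmer <- function(read) {
  if (ar_ncol(read) == 0L) stop("empty alignment")
  cls <- ar_column_class(read)
  r <- rle(cls == .COL_MATCH)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Pearson skewness coefficients
#'
#' `SCP_mode = (mean - mode) / sd` and `SCP_median = 3 (mean - median) / sd`,
#' characterising the asymmetry of a distribution from printed summaries.
#'
#' @param mean,mode,median,sd Distribution summaries.
#' @return The coefficient.
#' @export
scp_mode <- function(mean, mode, sd) (mean - mode) / sd

#' @rdname scp_mode
#' @export
scp_median <- function(mean, median, sd) 3 * (mean - median) / sd

#' Distribution of longest perfect k-mers over reads
#'
#' For each `k`, the fraction of reads whose longest error-free stretch is at
#' least `k` (a non-increasing curve), together with summary statistics of the
#' length distribution: mode (most frequent binned length, smallest value on
#' ties), mean, median, standard deviation and the two Pearson skewness
#' coefficients.
#'
#' @param lengths Integer vector of per-read longest perfect stretches.
#' @param bin_width Histogram bin width for the mode (default 1).
#' @return A list with `curve` (`data.table` of `k`, `fraction`) and `stats`
#'   (list with `mode`, `mean`, `median`, `sd`, `scp_mode`, `scp_median`,
#'   `degenerate` flag set when `sd` is 0).
#' @export
perfect_kmer_distribution <- function(lengths, bin_width = 1L) {
  stopifnot(length(lengths) >= 1L)
  n <- length(lengths)
  kmax <- max(lengths)
  cnt <- tabulate(lengths + 1L, nbins = kmax + 1L)       # counts of 0..kmax
  ge <- rev(cumsum(rev(cnt)))                            # reads with length >= k
  curve <- data.table::data.table(k = 0:kmax, fraction = ge / n)
  bins <- (lengths %/% bin_width) * bin_width
  bt <- table(bins)
  mode <- as.numeric(names(bt)[which.max(bt)])           # smallest on ties
  m <- mean(lengths); md <- stats::median(lengths); s <- stats::sd(lengths)
  degenerate <- is.na(s) || s == 0
  stats <- list(
    mode = mode, mean = m, median = md, sd = s,
    scp_mode = if (degenerate) NA_real_ else scp_mode(m, mode, s),
    scp_median = if (degenerate) NA_real_ else scp_median(m, md, s),
    degenerate = degenerate)
  list(curve = curve, stats = stats)
}

#' Largest seed size available at a confidence level
#'
#' The largest `k` such that at least `confidence` of the reads contain an
#' error-free stretch of length `>= k` (the floor-convention lower quantile of
#' the longest-stretch distribution).
#'
#' @param lengths Per-read longest perfect stretches.
#' @param confidence In `(0, 1)`, e.g. 0.95.
#' @return Seed size in bases.
#' @export
seed_size_at_confidence <- function(lengths, confidence) {
  if (length(lengths) == 0L) stop("no reads")
  stopifnot(confidence > 0, confidence < 1)
  n <- length(lengths)
  kmax <- max(lengths)
  if (kmax == 0L) return(0L)
  cnt <- tabulate(lengths + 1L, nbins = kmax + 1L)
  ge <- rev(cumsum(rev(cnt))) / n                        # fraction >= k, k = 0..kmax
  ok <- which(ge >= confidence) - 1L
  max(ok)
}

# Map error-type name to the internal column class code.
.error_code <- function(error_type) {
  switch(error_type, mismatch = .COL_MISMATCH, insertion = .COL_INS,
         deletion = .COL_DEL, stop("unknown error type: ", error_type))
}

#' Mine harmful k-mers: read contexts of error positions
#'
#' For every error column of the requested type, the `k` read bases (gap
#' columns skipped) immediately before or after the error are extracted and
#' counted. Runs of consecutive deletion columns count as one gap event whose
#' flanking read bases provide the context. Contexts truncated by the read
#' ends are skipped. With `exclude_homopolymeric = TRUE`, errors anchored
#' inside a reference homopolymer (length >= 2) are skipped, isolating
#' sequence-specific errors from the homopolymer effect.
#'
#' @param reads List of `aligned_read`.
#' @param error_type `"mismatch"`, `"insertion"` or `"deletion"`.
#' @param side `"before"` or `"after"` the error position.
#' @param k Context length (default 5: the number of bases in the pore that
#'   shape the signal for the R9.4 chemistry).
#' @param top Retain the most frequent `top` k-mers (default 10); ties break
#'   alphabetically for determinism.
#' @param exclude_homopolymeric Skip errors in reference homopolymers.
#' @param reference `reference_genome`; required when
#'   `exclude_homopolymeric = TRUE`.
#' @param gc_class Optional `"low"`/`"high"` label stored on the table so
#'   per-class weights survive merging across datasets.
#' @return A `harmful_kmer_table`: `data.table` of `kmer`, `count` sorted by
#'   decreasing count, with attributes `error_type`, `side`, `k`, `gc_class`,
#'   `total_sites`.
#' @export
harmful_kmers <- function(reads, error_type = c("deletion", "mismatch", "insertion"),
                          side = c("before", "after"), k = 5L, top = 10L,
                          exclude_homopolymeric = FALSE, reference = NULL,
                          gc_class = NA_character_) {
  error_type <- match.arg(error_type)
  side <- match.arg(side)
  stopifnot(k >= 1L)
  code <- .error_code(error_type)
  hp_mask <- NULL
  if (exclude_homopolymeric) {
    if (is.null(reference)) stop("reference required to exclude homopolymeric errors")
    occ <- find_repeats(reference, "homopolymer")
    hp_mask <- logical(reference$length)
    for (i in seq_len(nrow(occ))) hp_mask[(occ$start[i] + 1L):occ$end[i]] <- TRUE
  }

  ctxs <- vector("list", length(reads))
  for (w in seq_along(reads)) {
    x <- reads[[w]]
    cls <- ar_column_class(x)
    readc <- ar_read_cols(x)
    rbi <- cumsum(readc)
    n_rb <- rbi[length(rbi)]
    rs <- rawToChar(x$read[readc])

    if (code == .COL_DEL) {
      r <- rle(cls == .COL_DEL)
      ends <- cumsum(r$lengths)
      site_cols <- (ends - r$lengths + 1L)[r$values]      # first column of each gap run
    } else {
      site_cols <- which(cls == code)
    }
    if (!length(site_cols)) next
    if (!is.null(hp_mask)) {
      a <- ar_anchor_forward(x, reference$length)[site_cols]
      site_cols <- site_cols[!hp_mask[a + 1L]]
      if (!length(site_cols)) next
    }
    if (code == .COL_DEL) {
      j <- rbi[site_cols]                                  # read bases before the gap
      lo <- if (side == "before") j - k + 1L else j + 1L
    } else {
      p <- rbi[site_cols]                                  # read position of the error base
      lo <- if (side == "before") p - k else p + 1L
    }
    hi <- lo + k - 1L
    ok <- lo >= 1L & hi <= n_rb
    if (!any(ok)) next
    ctxs[[w]] <- substring(rs, lo[ok], hi[ok])
  }
  all_ctx <- unlist(ctxs, use.names = FALSE)
  tb <- sort(table(all_ctx), decreasing = TRUE)
  dt <- data.table::data.table(kmer = names(tb), count = as.integer(tb))
  if (nrow(dt)) dt <- dt[order(-count, kmer)][seq_len(min(top, nrow(dt)))]
  else dt <- data.table::data.table(kmer = character(0), count = integer(0))
  data.table::setattr(dt, "error_type", error_type)
  data.table::setattr(dt, "side", side)
  data.table::setattr(dt, "k", as.integer(k))
  data.table::setattr(dt, "gc_class", gc_class)
  data.table::setattr(dt, "total_sites", length(all_ctx))
  data.table::setattr(dt, "class", c("harmful_kmer_table", class(dt)))
  dt
}

#' Merge harmful k-mer tables across datasets
#'
#' @param tables List of `harmful_kmer_table` sharing the same `k`. Counts
#'   are tallied per GC class (`count_low` / `count_high`).
#' @return A merged `data.table` with `kmer`, `count_low`, `count_high`,
#'   `count`, sorted by decreasing total count; attribute `k` retained.
#' @export
merge_harmful_tables <- function(tables) {
  ks <- vapply(tables, attr, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("inconsistent k across tables: ", paste(unique(ks), collapse = ", "))
  parts <- lapply(tables, function(t) {
    gcc <- attr(t, "gc_class")
    data.table::data.table(kmer = t$kmer, count = t$count,
                           gc_class = if (is.na(gcc)) "low" else gcc)
  })
  dt <- data.table::rbindlist(parts)
  out <- dt[, list(count_low = sum(count[gc_class == "low"]),
                   count_high = sum(count[gc_class == "high"])), by = "kmer"]
  out$count <- out$count_low + out$count_high
  out <- out[order(-count, kmer)]
  data.table::setattr(out, "k", ks[1L])
  out[]
}

#' Per-position base count matrix of a k-mer table
#'
#' The count-matrix form of a sequence logo: for each position 1..k, counts of
#' A/C/G/T weighted by k-mer counts. Every column sums to the total weight.
#'
#' @param table A `harmful_kmer_table` or merged table with `kmer`, `count`.
#' @return A 4 x k matrix (rows A, C, G, T).
#' @export
position_count_matrix <- function(table) {
  if (nrow(table) == 0L) stop("empty k-mer table")
  k <- nchar(table$kmer[1L])
  m <- matrix(0, 4L, k, dimnames = list(.BASE_CHARS, paste0("pos", seq_len(k))))
  for (i in seq_len(nrow(table))) {
    ch <- strsplit(table$kmer[i], "")[[1L]]
    for (j in seq_len(k)) m[ch[j], j] <- m[ch[j], j] + table$count[i]
  }
  m
}

# --- Layered automaton ------------------------------------------------------

#' Build the layered automaton over a set of harmful k-mers
#'
#' A minimal deterministic layered automaton (prefix trie with states of equal
#' residual suffix language merged) over the retained k-mers. Nodes live in
#' layers `0..k`; edges go from layer `i` to `i + 1`, carry one letter and a
#' weight per GC class (the counts of the k-mers they support). Before any
#' pruning, edge weights at each layer sum to the total k-mer weight, and the
#' automaton's language is exactly the input k-mer set. The pruning threshold
#' is applied at export time only (`prune_automaton()`); the full automaton is
#' retained.
#'
#' @param tables A merged table from [merge_harmful_tables()], a single
#'   `harmful_kmer_table`, or a list of tables (merged internally).
#' @param min_node_weight Display threshold stored on the automaton
#'   (default 4).
#' @return A `harmful_kmer_automaton`: list with `k`, `nodes` (`id`, `layer`,
#'   `weight`, `weight_low`, `weight_high`: total incoming weight),
#'   `edges` (`from`, `to`, `letter`, `weight_low`, `weight_high`, `weight`),
#'   `initial`, `final`, `min_node_weight`.
#' @export
build_automaton <- function(tables, min_node_weight = 4L) {
  tab <- if (data.table::is.data.table(tables)) tables else merge_harmful_tables(tables)
  if (!"count_low" %in% names(tab)) {
    tab <- data.table::data.table(kmer = tab$kmer, count_low = tab$count,
                                  count_high = 0L, count = tab$count)
  }
  if (nrow(tab) == 0L) stop("no k-mers to build automaton from")
  kl <- unique(nchar(tab$kmer))
  if (length(kl) != 1L) stop("inconsistent k-mer lengths")
  k <- kl

  kmers <- tab$kmer
  wlo <- tab$count_low; whi <- tab$count_high

  # states per layer: groups of prefixes with identical residual suffix sets
  prefix_state <- vector("list", k + 1L)   # named: prefix -> state id
  node_layer <- integer(0); node_id <- character(0)
  next_id <- 0L
  new_node <- function(layer) {
    next_id <<- next_id + 1L
    node_layer[next_id] <<- layer
    node_id[next_id] <<- paste0("n", next_id - 1L)
    next_id
  }
  state_of_prefix <- list()
  for (i in 0:k) {
    pf <- unique(substr(kmers, 1L, i))
    res_key <- vapply(pf, function(p) {
      suf <- sort(substring(kmers[startsWith(kmers, p)], i + 1L))
      paste(suf, collapse = "|")
    }, character(1))
    states <- split(pf, res_key)
    ids <- vapply(names(states), function(kk) new_node(i), integer(1))
    # "#" sentinel: the empty layer-0 prefix is not addressable as a name
    m <- stats::setNames(rep(ids, lengths(states)), paste0("#", unlist(states)))
    prefix_state[[i + 1L]] <- m
  }

  ef <- integer(0); et <- integer(0); el <- character(0)
  ewlo <- numeric(0); ewhi <- numeric(0)
  for (i in 0:(k - 1L)) {
    pref <- substr(kmers, 1L, i)
    nxt <- substr(kmers, 1L, i + 1L)
    letter <- substr(kmers, i + 1L, i + 1L)
    from <- prefix_state[[i + 1L]][paste0("#", pref)]
    to <- prefix_state[[i + 2L]][paste0("#", nxt)]
    key <- paste(from, to, letter)
    agg <- rowsum(cbind(wlo, whi), key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    ef <- c(ef, vapply(parts, function(p) as.integer(p[1L]), integer(1)))
    et <- c(et, vapply(parts, function(p) as.integer(p[2L]), integer(1)))
    el <- c(el, vapply(parts, `[[`, character(1), 3L))
    ewlo <- c(ewlo, agg[, 1L]); ewhi <- c(ewhi, agg[, 2L])
  }
  edges <- data.table::data.table(
    from = ef, to = et, letter = el,
    weight_low = ewlo, weight_high = ewhi, weight = ewlo + ewhi)
  edges <- edges[order(edges$from, edges$letter), ]

  inc <- function(wcol) {
    v <- numeric(next_id)
    agg <- rowsum(wcol, edges$to)
    v[as.integer(rownames(agg))] <- agg[, 1L]
    v
  }
  nodes <- data.table::data.table(
    id = seq_len(next_id), layer = node_layer[seq_len(next_id)],
    weight_low = inc(edges$weight_low), weight_high = inc(edges$weight_high))
  nodes$weight <- nodes$weight_low + nodes$weight_high

  structure(list(
    k = k, nodes = nodes, edges = edges,
    initial = unname(prefix_state[[1L]][[1L]]),
    final = unname(unique(prefix_state[[k + 1L]])),
    min_node_weight = min_node_weight
  ), class = "harmful_kmer_automaton")
}

#' @export
print.harmful_kmer_automaton <- function(x, ...) {
  cat(sprintf("<harmful_kmer_automaton> k = %d: %d nodes, %d edges, total weight %g\n",
              x$k, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$weight[x$edges$from == x$initial])))
  invisible(x)
}

#' Enumerate the words accepted by the automaton
#'
#' @param aut A `harmful_kmer_automaton`.
#' @return Character vector of accepted k-mers (the language; before pruning
#'   this equals the input k-mer set).
#' @export
automaton_language <- function(aut) {
  words <- data.table::data.table(node = aut$initial, word = "")
  for (i in seq_len(aut$k)) {
    words <- merge(words, aut$edges[, c("from", "to", "letter")],
                   by.x = "node", by.y = "from", allow.cartesian = TRUE)
    words <- data.table::data.table(node = words$to,
                                    word = paste0(words$word, words$letter))
  }
  sort(words$word[words$node %in% aut$final])
}

#' Prune low-weight nodes for display
#'
#' Removes nodes whose total incoming weight is below the threshold, together
#' with their incident edges (the initial node is always kept).
#'
#' @param aut A `harmful_kmer_automaton`.
#' @param min_node_weight Threshold; defaults to the one stored on the
#'   automaton.
#' @return A pruned `harmful_kmer_automaton`.
#' @export
prune_automaton <- function(aut, min_node_weight = aut$min_node_weight) {
  keep <- aut$nodes$id[aut$nodes$weight >= min_node_weight | aut$nodes$id == aut$initial]
  edges <- aut$edges[aut$edges$from %in% keep & aut$edges$to %in% keep, ]
  out <- aut
  out$nodes <- aut$nodes[aut$nodes$id %in% keep, ]
  out$edges <- edges
  out$final <- intersect(aut$final, keep)
  out
}

#' Export an automaton to Graphviz DOT
#'
#' @param aut A `harmful_kmer_automaton`.
#' @param path Optional file to write to.
#' @param prune Apply the display pruning threshold first (default TRUE).
#' @return The DOT text, invisibly when written to a file.
#' @export
automaton_to_dot <- function(aut, path = NULL, prune = TRUE) {
  a <- if (prune) prune_automaton(aut) else aut
  lines <- c("digraph harmful_kmers {", "  rankdir=LR;")
  for (i in seq_len(nrow(a$nodes))) {
    nd <- a$nodes[i]
    shape <- if (nd$id %in% a$final) "doublecircle" else "circle"
    lines <- c(lines, sprintf("  n%d [label=\"%g\", shape=%s];", nd$id, nd$weight, shape))
  }
  for (i in seq_len(nrow(a$edges))) {
    e <- a$edges[i]
    lines <- c(lines, sprintf("  n%d -> n%d [label=\"%s (%g+%g)\"];",
                              e$from, e$to, e$letter, e$weight_low, e$weight_high))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Export an automaton to JSON
#'
#' @inheritParams automaton_to_dot
#' @export
automaton_to_json <- function(aut, path = NULL, prune = FALSE) {
  a <- if (prune) prune_automaton(aut) else aut
  obj <- list(k = a$k, initial = a$initial, final = a$final,
              nodes = a$nodes, edges = a$edges,
              min_node_weight = a$min_node_weight)
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
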