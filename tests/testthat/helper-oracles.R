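# Brute-force oracles and small constructors, written as plain character/loop
# code so they stay independent of the package's vectorised implementations.

# Build an aligned_read from gapped strings ("-" = gap).
make_ar <- function(ref_str, read_str, qual = 30L, read_id = "r1",
                    orientation = "forward", ref_start = 0L,
                    clip_left = 0L, clip_right = 0L) {
  ref <- charToRaw(ref_str)
  read <- charToRaw(read_str)
  q <- rep(as.integer(qual), length.out = nchar(read_str))
  q[read == charToRaw("-")] <- NA_integer_
  aligned_read(read_id, orientation, "ref", ref_start, ref, read, q,
               clip_left, clip_right)
}

# Per-column classification by explicit looping.
brute_classify <- function(ref_str, read_str) {
  rc <- strsplit(ref_str, "")[[1]]
  dc <- strsplit(read_str, "")[[1]]
  out <- c(match = 0L, mismatch = 0L, insertion = 0L, deletion = 0L,
           ambiguous = 0L)
  for (i in seq_along(rc)) {
    if (rc[i] == "-") {
      out["insertion"] <- out["insertion"] + 1L
    } else if (dc[i] == "-") {
      out["deletion"] <- out["deletion"] + 1L
    } else if (rc[i] == "N" || dc[i] == "N") {
      out["ambiguous"] <- out["ambiguous"] + 1L
    } else if (rc[i] == dc[i]) {
      out["match"] <- out["match"] + 1L
    } else {
      out["mismatch"] <- out["mismatch"] + 1L
    }
  }
  out
}

# Longest error-free stretch by checking every window.
brute_longest_perfect <- function(ref_str, read_str) {
  rc <- strsplit(ref_str, "")[[1]]
  dc <- strsplit(read_str, "")[[1]]
  ok <- rc != "-" & dc != "-" & rc == dc & rc != "N"
  best <- 0L
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

# Random gapped alignment pair (no column with gap in both).
rand_alignment <- function(n = 40) {
  bases <- c("A", "C", "G", "T")
  ref <- character(n); read <- character(n)
  for (i in seq_len(n)) {
    u <- runif(1)
    if (u < 0.08) {               # insertion
      ref[i] <- "-"; read[i] <- sample(bases, 1)
    } else if (u < 0.18) {        # deletion
      ref[i] <- sample(bases, 1); read[i] <- "-"
    } else if (u < 0.30) {        # mismatch (possibly same base -> match)
      ref[i] <- sample(bases, 1); read[i] <- sample(bases, 1)
    } else {
      ref[i] <- sample(bases, 1); read[i] <- ref[i]
    }
  }
  list(ref = paste(ref, collapse = ""), read = paste(read, collapse = ""))
}

# Brute-force maximal repeat scan, by explicit character loops.
brute_find_repeats <- function(s, kind) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  res <- list()
  add <- function(motif, start0, len) {
    res[[length(res) + 1]] <<- data.frame(motif = motif, start = start0,
                                          end = start0 + len, length = len)
  }
  if (kind == "homopolymer") {
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && ch[j + 1] == ch[i]) j <- j + 1L
      if (j - i + 1L >= 2L && ch[i] != "N") add(ch[i], i - 1L, j - i + 1L)
      i <- j + 1L
    }
  } else if (kind == "heteropolymer") {
    for (i in seq_len(max(0L, n - 3L))) {
      if (ch[i] == ch[i + 1]) next
      if (ch[i] == "N" || ch[i + 1] == "N") next
      # i must start a maximal period-2 region
      if (i > 1L && i + 1L <= n && ch[i - 1] == ch[i + 1]) next
      e <- i + 1L
      while (e + 1L <= n && ch[e + 1L] == ch[e - 1L]) e <- e + 1L
      k <- (e - i + 1L) %/% 2L
      if (k >= 2L) add(paste0(ch[i], ch[i + 1]), i - 1L, 2L * k)
    }
  } else {
    for (i in seq_len(max(0L, n - 5L))) {
      m <- ch[i:(i + 2L)]
      if (m[1] == m[2] && m[2] == m[3]) next
      if (any(m == "N")) next
      # count unit copies starting at i
      k <- 1L
      while (i + 3L * k + 2L <= n &&
             all(ch[(i + 3L * k):(i + 3L * k + 2L)] == m)) k <- k + 1L
      if (k < 2L) next
      # not extendable left by a whole unit
      if (i >= 4L && all(ch[(i - 3L):(i - 1L)] == m)) next
      add(paste(m, collapse = ""), i - 1L, 3L * k)
    }
  }
  if (!length(res)) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$motif), , drop = FALSE]
}

# Tiny single-record SAM, for parse tests.
sam_line <- function(id, pos1, cigar, seq, qual = NULL, flag = 0L,
                     rname = "ref") {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  paste(id, flag, rname, pos1, "60", cigar, "*", "0", "0", seq, qual,
        sep = "\t")
}
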