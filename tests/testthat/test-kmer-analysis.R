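test_that("longest perfect stretch matches a brute-force window scan", {
  full <- make_ar(strrep("ACGT", 75), strrep("ACGT", 75))
  expect_equal(longest_perfect_kmer(full), 300L)

  # the dual-strand worked example: mismatches at columns 3, 5, 9
  ref <- reference_genome("g", "ACGTCATTGC")
  x <- parse_alignments(sam_line("r1", 1, "10M", "GCCAAGACCT"), ref, "reverse")[[1]]
  expect_equal(longest_perfect_kmer(x), 3L)

  alt <- make_ar(strrep("A", 10), strrep("AC", 5))
  expect_equal(longest_perfect_kmer(alt), 1L)

  set.seed(601)
  ok <- TRUE
  for (i in 1:1000) {
    al <- rand_alignment(n = sample(5:80, 1))
    got <- longest_perfect_kmer(make_ar(al$ref, al$read))
    want <- brute_longest_perfect(al$ref, al$read)
    if (got != want) ok <- FALSE
  }
  expect_true(ok)
})

test_that("Pearson skewness coefficients reproduce printed summaries", {
  expect_equal(round(scp_mode(242, 212, 242), 2), 0.12)
  expect_equal(round(scp_median(242, 487, 242), 0), -3)
  expect_equal(round(scp_median(224, 353, 224), 1), -1.7)

  d <- perfect_kmer_distribution(c(3L, 3L, 3L))
  expect_true(d$stats$degenerate)
  expect_true(is.na(d$stats$scp_mode))
})

test_that("the cumulative perfect k-mer curve is a non-increasing sigmoid", {
  set.seed(602)
  lens <- as.integer(rlnorm(500, log(200), 0.5))
  d <- perfect_kmer_distribution(lens)
  expect_true(all(diff(d$curve$fraction) <= 0))
  expect_equal(d$curve$fraction[d$curve$k == 0], 1)
  expect_equal(d$curve$fraction[d$curve$k == 1], mean(lens >= 1))
  # mode via unit bins, smallest value on ties
  dd <- perfect_kmer_distribution(c(2L, 2L, 5L, 5L, 9L))
  expect_equal(dd$stats$mode, 2)
})

test_that("seed sizes follow the lower quantile of the longest-stretch distribution", {
  expect_equal(seed_size_at_confidence(c(100L, 200L, 300L), 0.95), 100L)
  set.seed(603)
  lens <- as.integer(rgeom(2000, 0.05))
  k95 <- seed_size_at_confidence(lens, 0.95)
  k99 <- seed_size_at_confidence(lens, 0.99)
  expect_lte(k99, k95)
  # brute-force check: largest k with >= 95% of reads at or above it
  frac_ge <- function(k) mean(lens >= k)
  expect_gte(frac_ge(k95), 0.95)
  expect_lt(frac_ge(k95 + 1), 0.95)
  expect_error(seed_size_at_confidence(integer(0), 0.95), "no reads")
})

test_that("mean longest run matches the i.i.d. asymptotic at 5% error", {
  set.seed(604)
  n <- 10000L; e <- 0.05
  longest <- replicate(200, {
    ok <- runif(n) > e
    r <- rle(ok)
    max(c(0L, r$lengths[r$values]))
  })
  p <- 1 - e
  asym <- log(n * e, base = 1 / p) + 0.5772157 / log(1 / p) - 0.5
  expect_lt(abs(mean(longest) - asym) / asym, 0.10)
})

test_that("harmful k-mers extract read contexts around errors", {
  # one deletion, preceded in the read by TACGG
  x <- make_ar("ATACGGCTT", "ATACGG-TT")
  hk <- harmful_kmers(list(x), "deletion", "before", k = 5, top = 10)
  expect_equal(hk$kmer, "TACGG")
  expect_equal(hk$count, 1L)

  # error too close to the read start: no context
  y <- make_ar("ATACG", "AT-CG")
  expect_equal(nrow(harmful_kmers(list(y), "deletion", "before", k = 5)), 0L)

  # consecutive deletion columns count as one extraction site
  z <- make_ar("AACGTTTGCA", "AACGT--GCA")
  hk2 <- harmful_kmers(list(z), "deletion", "before", k = 5)
  expect_equal(hk2$count, 1L)
  expect_equal(hk2$kmer, "AACGT")

  # mismatch context on the other side
  m <- make_ar("AAACGTACGTA", "AAACGAACGTA")
  hk3 <- harmful_kmers(list(m), "mismatch", "after", k = 5)
  expect_equal(hk3$kmer, "ACGTA")
})

test_that("motif-seeded deletions dominate the harmful k-mer table", {
  set.seed(605)
  bases <- c("A", "C", "G", "T")
  reads <- lapply(1:300, function(i) {
    ref <- sample(bases, 120, replace = TRUE)
    # plant GAA at fixed spots, delete the base right after each
    for (s in c(20, 50, 80)) ref[s:(s + 2)] <- c("G", "A", "A")
    read <- ref
    read[c(21, 51, 81) + 2] <- "-"
    make_ar(paste(ref, collapse = ""), paste(read, collapse = ""),
            read_id = paste0("r", i))
  })
  hk <- harmful_kmers(reads, "deletion", "before", k = 5, top = 10)
  expect_true(all(grepl("GAA$", hk$kmer[1:3])))
})

test_that("homopolymeric errors can be excluded from context mining", {
  refg <- reference_genome("ref", "ACGTAAAACGTT")
  # deletion inside the A-run and one outside (in CGT context)
  x <- parse_alignments(sam_line("r1", 1, "5M1D6M", "ACGTAAACGTT"), refg, "forward")[[1]]
  all_k <- harmful_kmers(list(x), "deletion", "before", k = 3)
  expect_equal(sum(all_k$count), 1L)
  none <- harmful_kmers(list(x), "deletion", "before", k = 3,
                        exclude_homopolymeric = TRUE, reference = refg)
  expect_equal(nrow(none), 0L)
})

test_that("the layered automaton is minimal, conservative and prunable", {
  tab <- data.table::data.table(
    kmer = c("CAGAA", "CAGAT", "GAGAA", "TTTTT"),
    count = c(5L, 4L, 6L, 2L))
  data.table::setattr(tab, "k", 5L)
  data.table::setattr(tab, "gc_class", "low")
  data.table::setattr(tab, "class", c("harmful_kmer_table", class(tab)))
  aut <- build_automaton(merge_harmful_tables(list(tab)))

  # language equality before pruning, checked over the whole 5-mer space
  lang <- automaton_language(aut)
  all_words <- apply(expand.grid(rep(list(c("A","C","G","T")), 5)), 1, paste, collapse = "")
  expect_setequal(lang, tab$kmer)
  expect_true(all(xor(all_words %in% lang, !all_words %in% tab$kmer)))

  # per-layer weight conservation
  for (l in 0:4) {
    from_layer <- aut$nodes$id[aut$nodes$layer == l]
    expect_equal(sum(aut$edges$weight[aut$edges$from %in% from_layer]), sum(tab$count))
  }

  # pruning removes exactly the nodes under the threshold
  pr <- prune_automaton(aut, 4)
  dropped <- setdiff(aut$nodes$id, pr$nodes$id)
  expect_true(all(aut$nodes$weight[aut$nodes$id %in% dropped] < 4))
  expect_true(all(pr$nodes$weight >= 4 | pr$nodes$id == pr$initial))

  # a weight-1 linear k-mer vanishes entirely at threshold 4
  single <- data.table::data.table(kmer = "CAGAA", count = 1L)
  data.table::setattr(single, "k", 5L)
  aut1 <- build_automaton(single)
  expect_equal(nrow(aut1$edges), 5L)
  expect_true(all(aut1$edges$weight == 1))
  pr1 <- prune_automaton(aut1, 4)
  expect_equal(nrow(pr1$edges), 0L)
  expect_equal(pr1$nodes$id, pr1$initial)

  # suffix sharing: CAA + GAA merge after the first letter
  two <- data.table::data.table(kmer = c("CAA", "GAA"), count = c(5L, 5L))
  data.table::setattr(two, "k", 3L)
  aut2 <- build_automaton(two)
  expect_lte(nrow(aut2$nodes) - 1L, 5L)
  expect_setequal(automaton_language(aut2), two$kmer)

  # exports are well-formed
  dot <- automaton_to_dot(aut)
  expect_match(dot, "digraph")
  js <- jsonlite::fromJSON(automaton_to_json(aut))
  expect_equal(js$k, 5L)
  expect_error(build_automaton(list(tab, structure(data.table::data.table(
    kmer = "AAA", count = 1L), k = 3L))), "inconsistent k")
})

test_that("position count matrices weight bases by k-mer counts", {
  tab <- data.table::data.table(kmer = "CCCCC", count = 3L)
  m <- position_count_matrix(tab)
  expect_equal(unname(m["C", ]), rep(3, 5))
  tab2 <- data.table::data.table(kmer = c("ACGTA", "CCGTA"), count = c(2L, 2L))
  m2 <- position_count_matrix(tab2)
  expect_equal(unname(m2["A", 1]), 2)
  expect_equal(unname(m2["C", 1]), 2)
  expect_true(all(colSums(m2) == 4))
})
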