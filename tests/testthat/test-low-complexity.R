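test_that("find_repeats follows the maximal-occurrence definitions", {
  hp <- find_repeats("AATTTC", "homopolymer")
  expect_equal(hp$motif, c("A", "T"))
  expect_equal(hp$start, c(0L, 2L))
  expect_equal(hp$end, c(2L, 5L))

  het <- find_repeats("ACACAC", "heteropolymer")
  expect_equal(nrow(het), 1L)
  expect_equal(het$motif, "AC")
  expect_equal(het$copies, 3L)
  expect_equal(het$end - het$start, 6L)

  # trailing odd base ignored: ACACA counts as AC x2
  het2 <- find_repeats("GACACAG", "heteropolymer")
  expect_equal(het2$copies, 2L)
  expect_equal(het2$length, 4L)

  # pure homopolymers excluded from trinucleotide repeats
  expect_equal(nrow(find_repeats("AAAAAA", "trinucleotide")), 0L)
  tri <- find_repeats("GAGTAGTAGC", "trinucleotide")
  expect_true("AGT" %in% tri$motif)
  tri2 <- find_repeats("AATAATAAT", "trinucleotide")
  expect_true(all(c("AAT", "ATA", "TAA") %in% tri2$motif))
})

test_that("find_repeats matches a brute-force scan on random sequences", {
  set.seed(501)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    for (kind in c("homopolymer", "heteropolymer", "trinucleotide")) {
      got <- find_repeats(s, kind)
      want <- brute_find_repeats(s, kind)
      got <- got[order(got$start, got$motif)]
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$motif, want$motif)
      expect_equal(got$length, want$length)
      # maximality: same-motif occurrences never touch or overlap
      if (nrow(got) > 1) {
        by_m <- split(got, got$motif)
        for (g in by_m) {
          if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
        }
      }
    }
  }
})

test_that("assess_repeats measures observed homopolymer runs", {
  refg <- reference_genome("ref", "GCTTTAG")
  occ <- find_repeats(refg, "homopolymer")

  # rendered exactly
  x <- parse_alignments(sam_line("r1", 1, "7M", "GCTTTAG"), refg, "forward")[[1]]
  a <- assess_repeats(x, occ, refg)
  expect_true(a$correct)
  expect_equal(a$observed_length, 3L)

  # one deletion: AAAA-like underestimation
  refg2 <- reference_genome("ref", "GAAAAC")
  occ2 <- find_repeats(refg2, "homopolymer")
  y <- parse_alignments(sam_line("r1", 1, "3M1D2M", "GAAAC"), refg2, "forward")[[1]]
  a2 <- assess_repeats(y, occ2, refg2)
  expect_equal(a2$observed_length, 3L)
  expect_false(a2$correct)
  expect_equal(a2$deletions, 1L)

  # three insertions: AA rendered as AAAAA (overestimation)
  refg3 <- reference_genome("ref", "GAAC")
  occ3 <- find_repeats(refg3, "homopolymer")
  z <- parse_alignments(sam_line("r1", 1, "2M3I2M", "GAAAAAC"), refg3, "forward")[[1]]
  a3 <- assess_repeats(z, occ3, refg3)
  expect_equal(a3$observed_length, 5L)
  expect_false(a3$correct)

  # occurrence not fully spanned by the read -> skipped
  w <- parse_alignments(sam_line("r1", 4, "4M", "TTAG"), refg, "forward")[[1]]
  expect_equal(nrow(assess_repeats(w, occ, refg)), 0L)
})

test_that("heteropolymer and trinucleotide assessments use exact-copy rules", {
  refg <- reference_genome("ref", "GACACACT")
  occ <- find_repeats(refg, "heteropolymer")
  x <- parse_alignments(sam_line("r1", 1, "8M", "GACACACT"), refg, "forward")[[1]]
  a <- assess_repeats(x, occ, refg)
  expect_true(a$correct)
  expect_equal(a$observed_length, 6L)

  # a substituted base inside the repeat breaks correctness
  y <- parse_alignments(sam_line("r1", 1, "8M", "GACGCACT"), refg, "forward")[[1]]
  expect_false(assess_repeats(y, occ, refg)$correct)

  # an extra unit copy is an overestimation, not correct
  z <- parse_alignments(sam_line("r1", 1, "4M2I4M", "GACACACACT"), refg, "forward")[[1]]
  az <- assess_repeats(z, occ, refg)
  expect_equal(az$observed_length, 8L)
  expect_false(az$correct)

  refg2 <- reference_genome("ref", "GCAGCAGCAT")
  occt <- find_repeats(refg2, "trinucleotide")
  xt <- parse_alignments(sam_line("r1", 1, "10M", "GCAGCAGCAT"), refg2, "forward")[[1]]
  at <- assess_repeats(xt, occt, refg2)
  expect_true(all(at$correct[at$ref_length == 9L]))
})

test_that("reverse-orientation reads assess identically to forward ones", {
  refg <- generate_reference(5000, 0.5, seed = 91)
  run <- simulate_run(refg, error_model(0.001, 0.001, 0.001, hp_min_len = Inf),
                      n_reads = 40, seed = 92,
                      out_dir = file.path(tempdir(), "revass"),
                      read_meanlog = log(2000), read_sdlog = 0.1,
                      truth_repeat_reads = 40L)
  reads <- select_best_strand(
    parse_alignments(run$paths$sam_forward, refg, "forward"),
    parse_alignments(run$paths$sam_reverse, refg, "reverse"))
  occ <- find_repeats(refg, "homopolymer")
  ass <- assess_repeats(reads, occ, refg)
  tr <- run$truth_repeats
  j <- merge(tr, ass, by = c("read_id", "start"), suffixes = c(".t", ".m"))
  expect_gt(nrow(j), 100)
  expect_equal(j$observed_length.t, j$observed_length.m)
  expect_equal(j$ref_length.t, j$ref_length.m)
})

test_that("accuracy by length recovers the generative length-noise curve", {
  # length noise only: no column errors, so the model-implied correctness
  # probability P(delta = 0) is exact
  mod <- error_model(1e-5, 1e-5, 1e-5, hp_min_len = 5L,
                     hp_lambda_ins = 0.08, hp_lambda_del = 0.22,
                     hp_tail_prob = 0.01)
  refg <- generate_reference(
    300000, 0.5, seed = 93,
    repeat_spec = list(list(motif = "A", copies = 6, count = 300),
                       list(motif = "T", copies = 7, count = 300),
                       list(motif = "G", copies = 8, count = 200)))
  run <- simulate_run(refg, mod, n_reads = 250, seed = 94,
                      out_dir = file.path(tempdir(), "hpcurve"),
                      read_meanlog = log(8000), read_sdlog = 0.25,
                      truth_repeat_reads = 0L)
  reads <- select_best_strand(
    parse_alignments(run$paths$sam_forward, refg, "forward"),
    parse_alignments(run$paths$sam_reverse, refg, "reverse"))
  occ <- find_repeats(refg, "homopolymer")
  ass <- assess_repeats(reads, occ, refg)
  acc <- repeat_accuracy_by_length(ass, min_count = 400L)

  p_correct <- function(L) {
    ex <- L - 5 + 1
    l1 <- 0.08 * ex; l2 <- 0.22 * ex
    skellam0 <- exp(-(l1 + l2)) * besselI(2 * sqrt(l1 * l2), 0)
    ifelse(L < 5, 1, 0.99 * skellam0)
  }
  expect_true(all(diff(acc$accuracy[acc$ref_length >= 5]) <= 0.02))
  for (i in seq_len(nrow(acc))) {
    L <- acc$ref_length[i]
    p <- p_correct(L)
    se <- sqrt(max(p * (1 - p), 1e-6) / acc$n[i])
    expect_lt(abs(acc$accuracy[i] - p), 3 * se + 0.005)
  }
})

test_that("length-deviation profiles summarise observed minus expected", {
  perfect <- data.table::data.table(ref_length = rep(2:5, each = 10),
                                    observed_length = rep(2:5, each = 10),
                                    correct = TRUE)
  dp <- length_deviation_profile(perfect)
  expect_true(all(dp$median == 0 & dp$min == 0 & dp$max == 0))

  biased <- data.table::data.table(
    ref_length = rep(c(4L, 6L, 8L), each = 99),
    observed_length = c(rep(4L, 99), rep(5L, 99), rep(7L, 99)))
  dp2 <- length_deviation_profile(biased)
  expect_equal(dp2$median, c(0, -1, -1))

  # heavy overestimation tail: upper whisker far above the median
  set.seed(7)
  tail_obs <- 2L + ifelse(runif(500) < 0.05, 2L + rgeom(500, 0.2), 0L)
  heavy <- data.table::data.table(ref_length = 2L, observed_length = tail_obs)
  dp3 <- length_deviation_profile(heavy)
  expect_equal(dp3$median, 0)
  expect_gt(dp3$max, 5)
})

test_that("errors are attributed to homopolymer intervals with conservation", {
  refg <- reference_genome("ref", "GAAAACTTG")
  occ <- find_repeats(refg, "homopolymer")
  # mismatch inside the A-run, deletion inside the T-run: everything inside
  x <- parse_alignments(sam_line("r1", 1, "7M1D1M", "GAATACTG"), refg, "forward")[[1]]
  att <- attribute_errors_to_homopolymers(list(x), occ, refg)
  expect_equal(att$ratio_pct[att$error_type == "global"], 100)

  # 2 errors, 1 inside -> 50%
  refg2 <- reference_genome("ref", "GAAAACTTGCCA")
  occ2 <- find_repeats(refg2, "homopolymer")
  y <- parse_alignments(sam_line("r1", 1, "12M", "GATAACTTTCCA"), refg2, "forward")[[1]]
  att2 <- attribute_errors_to_homopolymers(list(y), occ2, refg2)
  expect_equal(att2$ratio_pct[att2$error_type == "global"], 50)

  # conservation: H <= A and A equals the pooled error counts
  refg3 <- generate_reference(20000, 0.5, seed = 95)
  run <- simulate_run(refg3, error_model(), n_reads = 30, seed = 96,
                      out_dir = file.path(tempdir(), "attr"),
                      read_meanlog = log(3000), read_sdlog = 0.2)
  reads <- select_best_strand(
    parse_alignments(run$paths$sam_forward, refg3, "forward"),
    parse_alignments(run$paths$sam_reverse, refg3, "reverse"))
  occ3 <- find_repeats(refg3, "homopolymer")
  att3 <- attribute_errors_to_homopolymers(reads, occ3, refg3)
  pooled <- pool_error_counts(lapply(reads, decompose_errors))
  expect_equal(att3$A[att3$error_type == "mismatches"], pooled$mismatches)
  expect_equal(att3$A[att3$error_type == "deletions"], pooled$deletions)
  expect_true(all(att3$H <= att3$A))
})

test_that("trinucleotide strong/weak classification follows base groups", {
  expect_equal(classify_trinucleotide("ATT"), "W-only")
  expect_equal(classify_trinucleotide("GCG"), "S-only")
  expect_equal(classify_trinucleotide("ACG"), "mostly-S")
  expect_equal(classify_trinucleotide("ACT"), "mostly-W")
  for (m in c("AAT", "ATA", "TAA", "ATT", "TAT", "TTA")) {
    expect_equal(classify_trinucleotide(m), "W-only")
  }
  expect_error(classify_trinucleotide("AXT"), "invalid")
  expect_error(classify_trinucleotide("AC"), "invalid")
})

test_that("repeat length distributions pool symmetric units and decay geometrically", {
  d <- repeat_length_distribution("AATTTC", "homopolymer")
  expect_equal(d$n[d$motif_class == "A" & d$length == 2], 1L)
  expect_equal(d$n[d$motif_class == "T" & d$length == 3], 1L)

  dh <- repeat_length_distribution("ACACCA", "heteropolymer")
  expect_equal(nrow(dh), 1L)
  expect_equal(dh$length, 4L)
  expect_match(dh$motif_class, "AC/CA")

  # i.i.d. uniform sequence: homopolymer counts decay by about 1/4 per base
  refg <- generate_reference(1000000, 0.5, seed = 97)
  dd <- repeat_length_distribution(refg, "homopolymer")
  tot <- dd[, list(n = sum(n)), keyby = "length"]
  for (L in 2:5) {
    ratio <- tot$n[tot$length == L + 1] / tot$n[tot$length == L]
    expect_lt(abs(ratio - 0.25), 3 * sqrt(0.25 * 0.75 / tot$n[tot$length == L]) + 0.02)
  }
})
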