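test_that("the dual-strand worked example yields the sequencing-orientation labels", {
  G <- "ACGTCATTGC"
  R <- "GCCAAGACCT"
  ref <- reference_genome("g", G)

  # read unchanged, genome reverse-complemented: labels A/C, T/A, G/C
  x <- parse_alignments(sam_line("r1", 1, "10M", R), ref, "reverse")[[1]]
  expect_equal(decompose_errors(x)$global_error_rate, 0.30)
  ab <- substitution_abundance(substitution_matrix(list(x))$all)
  seen <- sort(paste0(ab$genome_base[ab$count > 0], "/", ab$read_base[ab$count > 0]))
  expect_identical(seen, sort(c("A/C", "T/A", "G/C")))

  # the conventional route (read reverse-complemented, forward genome) labels
  # the complementary strand instead: C/G, A/T, T/G -- same rate, different errors
  y <- parse_alignments(sam_line("r1", 1, "10M", reverse_complement(R)),
                        ref, "forward")[[1]]
  expect_equal(decompose_errors(y)$global_error_rate, 0.30)
  ab2 <- substitution_abundance(substitution_matrix(list(y))$all)
  seen2 <- sort(paste0(ab2$genome_base[ab2$count > 0], "/", ab2$read_base[ab2$count > 0]))
  expect_identical(seen2, sort(c("C/G", "A/T", "T/G")))
})

test_that("decompose_errors matches a brute-force column classifier", {
  set.seed(401)
  for (i in 1:1000) {
    al <- rand_alignment(n = sample(5:60, 1))
    x <- make_ar(al$ref, al$read)
    ec <- decompose_errors(x)
    bc <- brute_classify(al$ref, al$read)
    expect_equal(ec$matches, unname(bc["match"]))
    expect_equal(ec$mismatches, unname(bc["mismatch"]))
    expect_equal(ec$insertions, unname(bc["insertion"]))
    expect_equal(ec$deletions, unname(bc["deletion"]))
  }
})

test_that("error counts follow the column classification rules", {
  x <- make_ar("A-TG", "AC-G")
  ec <- decompose_errors(x)
  expect_equal(ec$insertions, 1)
  expect_equal(ec$deletions, 1)
  expect_equal(ec$global_error_rate, 0.5)
  expect_equal(decompose_errors(make_ar(strrep("A", 50), strrep("A", 50)))$global_error_rate, 0)
  expect_error(decompose_errors(make_ar("", "")), "empty")
})

test_that("counts are conserved between per-read and pooled views", {
  set.seed(77)
  reads <- lapply(1:30, function(i) {
    al <- rand_alignment(50)
    make_ar(al$ref, al$read, read_id = paste0("r", i))
  })
  pooled <- pool_error_counts(lapply(reads, decompose_errors))
  tab <- read_error_table(reads)
  expect_equal(pooled$mismatches, sum(tab$mismatches))
  expect_equal(pooled$insertions, sum(tab$insertions))
  expect_equal(pooled$deletions, sum(tab$deletions))
  expect_equal(pooled$alignment_length, sum(tab$alignment_length))
})

test_that("modification calls stratify the substitution matrix", {
  x <- make_ar("ACGT", "ATGT", read_id = "m1")    # C->T at read position 1
  calls <- data.frame(read_id = "m1", read_pos = 1L, mod_type = "5mC")
  sm <- substitution_matrix(list(x), calls)
  expect_named(sm, c("unmodified", "modified:5mC"))
  expect_equal(sm[["modified:5mC"]]["C", "T"], 1)
  expect_equal(sum(sm[["unmodified"]]), 0)
  bad <- data.frame(read_id = "m1", read_pos = 99L, mod_type = "5mC")
  expect_error(substitution_matrix(list(x), bad), "beyond read length")
  expect_equal(sum(substitution_matrix(list(make_ar("ACGT", "ACGT")))$all), 0)
})

# Build reads with substitution pair counts drawn from given pair weights,
# bypassing the generator: a pure multinomial oracle for the test's null.
.reads_with_pairs <- function(n_reads, n_sub, weights) {
  pairs <- c("AC","AG","AT","CA","CG","CT","GA","GC","GT","TA","TC","TG")
  lapply(seq_len(n_reads), function(i) {
    pk <- sample(pairs, n_sub, replace = TRUE, prob = weights)
    ref <- paste(substr(pk, 1, 1), collapse = "")
    read <- paste(substr(pk, 2, 2), collapse = "")
    # pad with matches so rates are sane
    make_ar(paste0(ref, strrep("A", 30)), paste0(read, strrep("A", 30)),
            read_id = paste0("r", i))
  })
}

test_that("transition bias is detected and the uniform null is controlled", {
  set.seed(55)
  w <- rep(1, 12); names(w) <- c("AC","AG","AT","CA","CG","CT","GA","GC","GT","TA","TC","TG")
  wb <- w; wb[c("AG","GA","CT","TC")] <- 4    # transitions 4x more likely
  biased <- .reads_with_pairs(500, 8, wb)
  tt <- transition_transversion_test(biased)
  expect_false(attr(tt, "flagged"))
  expect_lt(tt$p_value[1], 0.01)
  expect_lt(tt$p_value[2], 0.01)
  expect_gt(tt$mean_transition[1], tt$mean_transversion[1])

  # null: uniform substitutions; false-positive rate controlled at alpha = 0.01
  hits <- 0L
  for (rep in 1:200) {
    nullreads <- .reads_with_pairs(120, 16, w)
    p <- transition_transversion_test(nullreads)$p_value
    if (any(p < 0.01)) hits <- hits + 1L
  }
  expect_lte(hits / 200, 0.05)

  # degenerate: single read with substitutions -> flagged, no p-value
  single <- transition_transversion_test(.reads_with_pairs(1, 5, w))
  expect_true(attr(single, "flagged"))
  expect_true(all(is.na(single$p_value)))
  clean <- transition_transversion_test(list(make_ar("AAAA", "AAAA")))
  expect_true(attr(clean, "flagged"))
})

test_that("genome windows tile the reference and recover uniform rates", {
  refg <- generate_reference(1000, 0.5, seed = 1)
  # arithmetic: fraction 0.01 of 1000 bp -> 100 windows of 10 bp
  gw <- genome_window_error(list(), refg, 0.01)
  expect_equal(nrow(gw), 100L)
  expect_equal(unique(gw$window_end - gw$window_start), 10L)
  expect_true(all(is.na(gw$mismatch_rate)))   # uncovered windows are missing

  refg2 <- generate_reference(50000, 0.5, seed = 2)
  run <- simulate_run(refg2, error_model(0, 0, 0.02, q_sd_read = 0, hp_min_len = Inf),
                      n_reads = 200, seed = 3,
                      out_dir = file.path(tempdir(), "gw"),
                      read_meanlog = log(5000), read_sdlog = 0.2)
  reads <- select_best_strand(
    parse_alignments(run$paths$sam_forward, refg2, "forward"),
    parse_alignments(run$paths$sam_reverse, refg2, "reverse"))
  gw <- genome_window_error(reads, refg2, 0.01)
  se <- sqrt(0.02 * 0.98 / gw$columns)
  expect_true(all(abs(gw$deletion_rate - 0.02) <= 3 * se))
  expect_true(all(gw$mismatch_rate <= 3 * sqrt(0.25 / gw$columns)))
})

test_that("per-read GC bins recover a linear GC-error trend", {
  set.seed(11)
  refg <- generate_reference(2e6, 0.5, seed = 21, gc_block_size = 2000,
                             gc_block_sd = 0.12)
  run <- simulate_run(refg, error_model(gc_error_slope = 4e-4, q_sd_read = 0,
                                        hp_min_len = Inf),
                      n_reads = 5000, seed = 22,
                      out_dir = file.path(tempdir(), "gcslope"),
                      read_meanlog = log(1500), read_sdlog = 0.25)
  reads <- select_best_strand(
    parse_alignments(run$paths$sam_forward, refg, "forward"),
    parse_alignments(run$paths$sam_reverse, refg, "reverse"))
  bins <- error_vs_gc(reads, min_support = 30L)
  sel <- bins[bins$gc_percent >= 30 & bins$gc_percent <= 70, ]
  fit <- stats::lm(global_error_rate ~ gc_percent, data = sel,
                   weights = sel$n_reads)
  slope <- unname(coef(fit)["gc_percent"])
  expect_gt(slope, 0)
  expect_lt(abs(slope - 4e-4) / 4e-4, 0.25)

  # support suppression
  one <- list(make_ar(strrep("AC", 30), strrep("AC", 30)))
  expect_equal(error_vs_gc(one, 1L)$gc_percent, 50L)
  expect_equal(nrow(error_vs_gc(one, 2L)), 0L)
})

test_that("relative coverage is flat without GC bias and flags empty input", {
  refg <- generate_reference(200000, 0.5, seed = 31, gc_block_size = 5000,
                             gc_block_sd = 0.06)
  run <- simulate_run(refg, error_model(hp_min_len = Inf), n_reads = 400,
                      seed = 32, out_dir = file.path(tempdir(), "cov"),
                      read_meanlog = log(4000), read_sdlog = 0.2)
  reads <- select_best_strand(
    parse_alignments(run$paths$sam_forward, refg, "forward"),
    parse_alignments(run$paths$sam_reverse, refg, "reverse"))
  cov <- relative_coverage_by_gc(reads, refg, min_windows = 50L)
  expect_gt(nrow(cov), 3)
  # mean relative coverage per bin stays near the unbiased expectation of 1
  expect_true(all(abs(cov$relative_coverage - 1) < 0.25))
  expect_warning(out <- relative_coverage_by_gc(list(), refg), "undefined")
  expect_equal(nrow(out), 0L)
})

test_that("region-stratified rates pool columns by forward anchor", {
  refg <- reference_genome("ref", strrep("ACGT", 25))
  x <- parse_alignments(sam_line("r1", 1, "100M", strrep("ACGT", 25)),
                        refg, "forward")[[1]]
  whole <- region_error_rates(list(x), data.frame(start = 0L, end = 100L), refg)
  expect_equal(whole$alignment_length, 100)
  expect_warning(region_error_rates(list(x), data.frame(start = integer(0), end = integer(0)), refg),
                 "empty region")
  expect_error(region_error_rates(list(x), data.frame(start = 10L, end = 5L), refg),
               "end <= start")

  # two disjoint regions with different simulated rates pool as a weighted mean
  ref2 <- reference_genome("ref", strrep("A", 200))
  mm1 <- paste0(strrep("C", 10), strrep("A", 90))    # 10% mismatch in [0,100)
  mm2 <- paste0(strrep("A", 60), strrep("C", 40))    # 40% mismatch in [100,200)
  y <- parse_alignments(sam_line("r1", 1, "200M", paste0(mm1, mm2)), ref2, "forward")[[1]]
  pool <- region_error_rates(list(y), data.frame(start = c(0L, 100L), end = c(100L, 200L)), ref2)
  expect_equal(pool$mismatch_rate, (10 + 40) / 200)
  left <- region_error_rates(list(y), data.frame(start = 0L, end = 100L), ref2)
  expect_equal(left$mismatch_rate, 0.10)
})
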