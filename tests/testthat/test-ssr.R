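test_that("canonical motif classification groups rotations of primitive units", {
  expect_equal(canonical_motif("TC"), "CT")
  expect_equal(canonical_motif("GAT"), "ATG")
  expect_true(is.na(canonical_motif("ATAT")))   # = "AT" x 2
  expect_true(is.na(canonical_motif("AA")))
  expect_error(canonical_motif("AX"), "non-ACGT")
  expect_error(canonical_motif("ACGTACG"), "1-6 bp")

  # the 12 primitive 2-mers collapse to exactly 6 classes
  two <- do.call(paste0, expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")))
  canon <- vapply(two, canonical_motif, character(1))
  expect_equal(sum(!is.na(canon)), 12)
  expect_equal(length(unique(na.omit(canon))), 6)
})

test_that("class counts equal the aperiodic-necklace closed form for all k", {
  for (k in 1:6) {
    expect_equal(motif_class_count(k), oracle_necklace_count(k))
  }
  expect_equal(motif_class_count(2), 6)
  expect_equal(motif_class_count(3), 20)
})

test_that("detect_ssrs finds constructed repeats under the 5-repetition rule", {
  loci <- detect_ssrs(c(u = "GGACACACACACTT"))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 2L)
  expect_equal(loci$end, 12L)
  expect_equal(loci$unit, "AC")
  expect_equal(loci$n_repeats, 5L)

  expect_equal(nrow(detect_ssrs(c(u = "ACACACAC"))), 0)        # 4 repeats
  expect_equal(nrow(detect_ssrs(c(u = strrep("A", 40)))), 0)   # mononucleotide
  # N breaks a repeat
  broken <- paste0(strrep("AG", 4), "N", strrep("AG", 4))
  expect_equal(nrow(detect_ssrs(c(u = broken))), 0)
})

test_that("planted repeats with clean flanks are recovered exactly", {
  # homopolymer flanks chosen so the boundary cannot extend the repeat run:
  # left flank base differs from the unit's last base, right flank base from
  # the unit's first base (homopolymers themselves are never reported)
  cases <- list(c("AC", 7), c("AGC", 5), c("ATCG", 6), c("ACGTC", 5),
                c("ACGTCG", 5))
  for (cs in cases) {
    unit <- cs[1]; reps <- as.integer(cs[2]); k <- nchar(unit)
    left <- if (substr(unit, k, k) == "T") "G" else "T"
    right <- if (substr(unit, 1, 1) == "G") "T" else "G"
    s <- paste0(strrep(left, 30), strrep(unit, reps), strrep(right, 30))
    loci <- detect_ssrs(setNames(s, "u"))
    expect_equal(nrow(loci), 1)
    expect_equal(loci$start, 30L)
    expect_equal(loci$end, 30L + k * reps)
    expect_equal(loci$unit, unit)
    expect_equal(loci$n_repeats, reps)
  }
})

test_that("every reported locus re-validates and loci never overlap", {
  set.seed(6)
  seqs <- setNames(vapply(1:40, function(i) {
    s <- rand_seq(800)
    # splice in a couple of repeats to exercise the detector
    substr(s, 101, 100 + 12) <- strrep("AT", 6)
    substr(s, 401, 400 + 18) <- strrep("CTG", 6)
    s
  }, ""), sprintf("u%02d", 1:40))
  loci <- detect_ssrs(seqs)
  expect_gt(nrow(loci), 40)
  for (j in seq_len(nrow(loci))) {
    s <- seqs[[loci$unigene_id[j]]]
    expect_identical(substr(s, loci$start[j] + 1, loci$end[j]),
                     strrep(loci$unit[j], loci$n_repeats[j]))
    expect_true(is_primitive(loci$unit[j]))
    expect_gte(loci$n_repeats[j], 5)
  }
  for (id in unique(loci$unigene_id)) {
    l <- loci[loci$unigene_id == id, ]
    if (nrow(l) > 1) {
      l <- l[order(l$start), ]
      expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
    }
  }
})

test_that("the detector matches the backtracking-regex oracle", {
  set.seed(7)
  for (i in 1:60) {
    s <- rand_seq(1000)
    if (i %% 3 == 0) substr(s, 201, 215) <- strrep("TCA", 5)
    if (i %% 4 == 0) substr(s, 501, 512) <- strrep("GA", 6)
    got <- detect_ssrs(setNames(s, "u"))[c("start", "end", "unit",
                                           "n_repeats")]
    rownames(got) <- NULL
    want <- oracle_ssr(s)
    expect_equal(got, want)
  }
})

test_that("summaries tally planted loci exactly", {
  seqs <- c(a = paste0(strrep("G", 20), strrep("AC", 6), strrep("T", 20)),
            b = paste0(strrep("G", 20), strrep("ATC", 5), strrep("T", 20)))
  loci <- detect_ssrs(seqs)
  sm <- summarize_ssrs(loci, sum(nchar(seqs)))
  expect_equal(sm$n_loci[sm$unit_length == "2"], 1)
  expect_equal(sm$bp[sm$unit_length == "2"], 12)
  expect_equal(sm$n_loci[sm$unit_length == "3"], 1)
  expect_equal(sm$bp[sm$unit_length == "all"], 27)
  expect_equal(sm$percent[sm$unit_length == "all"],
               percent_of(27, sum(nchar(seqs))))
  none <- summarize_ssrs(detect_ssrs(c(u = rand_seq(50))), 1000)
  expect_true(all(none$n_loci == 0) && all(none$bp == 0))
  expect_error(summarize_ssrs(loci, 0), "must be > 0")
})

test_that("marker selection applies uniqueness, flank and product filters", {
  set.seed(8)
  # period-8 flanks carry no 2-6 bp tandem of >= 3 repetitions
  clean <- paste0(strrep("ACGTTGCA", 19), strrep("AGC", 6),
                  strrep("TGCAACGT", 29))
  dup1 <- paste0(rand_seq(100), strrep("TC", 8), rand_seq(100))
  near_end <- paste0(strrep("CT", 7), rand_seq(200))
  seqs <- c(clean = clean, dup1 = dup1, dup2 = dup1, near_end = near_end)
  loci <- detect_ssrs(seqs)
  mk <- select_marker_loci(loci, seqs, min_flank_bp = 50)
  expect_true(all(!mk$unique[mk$unigene_id %in% c("dup1", "dup2")]))
  expect_true(all(!mk$eligible[mk$unigene_id %in% c("dup1", "dup2")]))
  ne <- mk[mk$unigene_id == "near_end", ]
  expect_true(all(!ne$eligible))
  expect_true(all(mk$eligible[mk$unigene_id == "clean"]))
  expect_error(select_marker_loci(loci, seqs[-1]), "unknown unigene")
})

test_that("a repeat in the flank disqualifies a marker locus", {
  s <- paste0(strrep("ACGTTGCA", 15), strrep("AGC", 6), strrep("AT", 4),
              strrep("TGCAACGT", 15))
  loci <- detect_ssrs(setNames(s, "u"), min_repeats = 5)
  expect_equal(loci$unit, "AGC")
  mk <- select_marker_loci(loci, setNames(s, "u"), min_flank_bp = 40)
  expect_false(mk$flank_repeat_free)
  expect_false(mk$eligible)
})

test_that("the validated locus panel summarizes by status and motif length", {
  s <- summarize_table1()
  expect_equal(unname(s$status["polymorphic"]), 14L)
  expect_equal(unname(s$status["monomorphic"]), 4L)
  expect_equal(unname(s$status["null_allele"]), 5L)
  expect_equal(unname(s$motif_length[c("2", "3", "4")]), c(8L, 14L, 1L))
  empty <- summarize_table1(load_table1()[0, ])
  expect_true(all(empty$status == 0) && all(empty$motif_length == 0))
})
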