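test_that("generators are byte-identical under a fixed seed and spec", {
  spec <- synthetic_spec(n_unigenes = 40, seed = 7)
  a <- generate_unigenes(spec)
  b <- generate_unigenes(spec)
  expect_identical(a, b)

  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  write_fasta(a$unigenes, fa); write_fasta(b$unigenes, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))

  expect_identical(generate_counts(spec, a), generate_counts(spec, b))
  expect_identical(generate_term_map(spec, a), generate_term_map(spec, b))
  r1 <- generate_reads(a$unigenes, 500, seed = 3)
  r2 <- generate_reads(a$unigenes, 500, seed = 3)
  expect_identical(r1, r2)
})

test_that("an empty spec yields empty artifacts", {
  spec <- synthetic_spec(n_unigenes = 0, seed = 1)
  sim <- generate_unigenes(spec)
  expect_length(sim$unigenes, 0)
  expect_equal(nrow(sim$truth$genes), 0)
  counts <- generate_counts(spec, sim)
  expect_equal(nrow(counts), 0)
  expect_equal(nrow(generate_reads(character(0), 0)), 0)
})

test_that("planted SSRs appear verbatim at the stated offset", {
  spec <- synthetic_spec(
    n_unigenes = 3, seed = 11,
    planted_ssrs = list(list(unigene = 1, unit = "AC", n_repeats = 7,
                             offset = 10)))
  sim <- generate_unigenes(spec)
  expect_identical(substr(sim$unigenes[[1]], 11, 24), strrep("AC", 7))
  expect_equal(sim$truth$ssrs$start, 10L)
  expect_equal(sim$truth$ssrs$end, 24L)
})

test_that("a planted repeat overflowing its unigene rejects the spec", {
  spec <- synthetic_spec(
    n_unigenes = 2, length_range = c(100, 100), seed = 5,
    planted_ssrs = list(list(unigene = 2, unit = "AGC", n_repeats = 10,
                             offset = 95)))
  expect_error(generate_unigenes(spec), "overflow")
})

test_that("planted ORFs are intact in-frame ATG..stop spans", {
  spec <- synthetic_spec(n_unigenes = 120, planted_orf_fraction = 0.5,
                         seed = 21)
  sim <- generate_unigenes(spec)
  orfs <- sim$truth$orfs
  expect_gt(nrow(orfs), 5)
  stops <- c("TAA", "TAG", "TGA")
  for (j in seq_len(nrow(orfs))) {
    s <- sim$unigenes[[orfs$unigene_id[j]]]
    cds <- substr(s, orfs$start[j] + 1, orfs$end[j] + 3)
    if (orfs$strand[j] == "-") cds <- revcomp(cds)
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_identical(cods[1], "ATG")
    expect_true(cods[length(cods)] %in% stops)
    expect_false(any(cods[-length(cods)] %in% stops))
  }
})

test_that("with de_fraction = 0 every true fold change is zero", {
  spec <- synthetic_spec(n_unigenes = 100, de_fraction = 0, seed = 2)
  g <- generate_unigenes(spec)$truth$genes
  expect_true(all(g$direction == 0))
  expect_identical(g$expr1, g$expr2)
})

test_that("Poisson count means match their expectations over replicates", {
  spec <- synthetic_spec(n_unigenes = 2000, dispersion = 0, seed = 42)
  sim <- generate_unigenes(spec)
  n_rep <- 200
  first <- generate_counts(spec, sim, seed = 1000)
  mu <- attr(first, "mu")
  tot1 <- first$count1
  for (rep in 2:n_rep) {
    tot1 <- tot1 + generate_counts(spec, sim, seed = 1000 + rep)$count1
  }
  mean1 <- tot1 / n_rep
  se <- sqrt(mu[, "mu1"] / n_rep)
  expect_true(all(abs(mean1 - mu[, "mu1"]) <= 5 * pmax(se, 1e-9)))
  # realized library sizes are the actual column sums, not the targets
  expect_identical(unname(attr(first, "library_sizes")["N1"]),
                   sum(first$count1))
})

test_that("reads are exact substrings when error-free, and errors match the rate", {
  spec <- synthetic_spec(n_unigenes = 30, seed = 9)
  sim <- generate_unigenes(spec)
  rd <- generate_reads(sim$unigenes, 300, error_rate = 0, seed = 4)
  for (j in seq_len(nrow(rd))) {
    piece <- substr(sim$unigenes[[rd$origin[j]]], rd$start[j] + 1,
                    rd$start[j] + 75)
    if (rd$strand[j] == "-") piece <- revcomp(piece)
    expect_identical(rd$seq[j], piece)
  }

  rd <- generate_reads(sim$unigenes, 10000, error_rate = 0.01, seed = 8)
  mism <- vapply(seq_len(nrow(rd)), function(j) {
    piece <- substr(sim$unigenes[[rd$origin[j]]], rd$start[j] + 1,
                    rd$start[j] + 75)
    if (rd$strand[j] == "-") piece <- revcomp(piece)
    sum(utf8ToInt(rd$seq[j]) != utf8ToInt(piece))
  }, numeric(1))
  frac <- sum(mism) / (nrow(rd) * 75)
  se <- sqrt(0.01 * 0.99 / (nrow(rd) * 75))
  expect_lt(abs(frac - 0.01), 5 * se)
})

test_that("zero depth and too-short unigenes are handled", {
  expect_equal(nrow(generate_reads(c(u = strrep("ACGT", 50)), 0)), 0)
  expect_warning(
    rd <- generate_reads(c(long = strrep("ACGT", 50), short = "ACGTACGT"),
                         50, seed = 2),
    "shorter than read_length")
  expect_true(all(rd$origin == "long"))
})
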