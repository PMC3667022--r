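test_that("the single-term probability matches hand-computed values", {
  expect_equal(ac_term(1, 1, 1e6, 1e6), 0.25, tolerance = 1e-12)
  expect_equal(ac_term(0, 0, 12345, 12345), 0.5, tolerance = 1e-12)
  # exact reference via the negative-binomial reparameterization
  set.seed(1)
  for (i in 1:50) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    N1 <- sample(1e5:5e6, 1); N2 <- sample(1e5:5e6, 1)
    expect_equal(ac_term(x, y, N1, N2), oracle_ac_term(x, y, N1, N2),
                 tolerance = 1e-10)
  }
  # stable far into large counts
  expect_true(is.finite(ac_term(60000, 61000, 3e6, 2e6)))
  expect_error(ac_term(-1, 0, 10, 10), "non-negative")
})

test_that("two-sided p-values agree with direct tail summation", {
  ratios <- list(c(1e6, 1e6), c(3e6, 2e6), c(5e5, 2e6))
  set.seed(2)
  for (NN in ratios) {
    for (i in 1:60) {
      x <- sample(0:80, 1); y <- sample(0:80, 1)
      expect_equal(ac_pvalue(x, y, NN[1], NN[2]),
                   oracle_ac_pvalue(x, y, NN[1], NN[2]),
                   tolerance = 1e-10)
    }
  }
  # large-count stability
  expect_equal(ac_pvalue(50000, 50500, 2e6, 2e6),
               oracle_ac_pvalue(50000, 50500, 2e6, 2e6), tolerance = 1e-8)
})

test_that("balanced observations give p = 1 and terms obey the swap duality", {
  for (x in c(0, 1, 7, 40)) {
    expect_equal(ac_pvalue(x, x, 1e6, 1e6), 1)
  }
  # conditioning asymmetry of the published form: swapping samples rescales
  # the single term by the library-size ratio
  set.seed(3)
  for (i in 1:25) {
    x <- sample(0:60, 1); y <- sample(0:60, 1)
    N1 <- sample(1e5:4e6, 1); N2 <- sample(1e5:4e6, 1)
    expect_equal(ac_term(x, y, N1, N2) * N2, ac_term(y, x, N2, N1) * N1,
                 tolerance = 1e-10)
  }
})

test_that("p decreases monotonically away from the tail-equal point", {
  for (x in c(3, 12, 30)) {
    for (NN in list(c(1e6, 1e6), c(2e6, 5e5))) {
      p <- ac_pvalue(rep(x, 81), 0:80, NN[1], NN[2])
      peak <- which.max(p)
      expect_true(all(diff(p[peak:length(p)]) <= 1e-12))
      if (peak > 1) expect_true(all(diff(p[1:peak]) >= -1e-12))
    }
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(4)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the combined FDR + fold-change rule gates direction calls", {
  expect_equal(classify_direction(0.0005, 2.3), "up_in_2")
  expect_equal(classify_direction(0.0005, -2.3), "up_in_1")
  expect_equal(classify_direction(0.0005, 0.5), "not_significant")
  expect_equal(classify_direction(0.01, 5), "not_significant")
  expect_equal(classify_direction(0.0001, Inf), "up_in_2")
})

test_that("dge_table is null on identical libraries and conserves its summary", {
  set.seed(5)
  lens <- setNames(sample(300:2000, 40), sprintf("g%02d", 1:40))
  counts <- setNames(rpois(40, 50), names(lens))
  res <- dge_table(counts, counts, lens)
  expect_s3_class(res, "dge_result")
  expect_equal(unname(res$summary["total"]), 0)
  expect_equal(res$table$p, rep(1, 40), tolerance = 1e-9)

  spec <- synthetic_spec(n_unigenes = 300, library_sizes = c(5e4, 5e4),
                         seed = 6)
  sim <- generate_unigenes(spec)
  ct <- generate_counts(spec, sim)
  res <- dge_table(setNames(ct$count1, ct$unigene_id),
                   setNames(ct$count2, ct$unigene_id),
                   setNames(sim$truth$genes$length, ct$unigene_id))
  expect_equal(unname(res$summary["total"]),
               unname(res$summary["up_in_1"] + res$summary["up_in_2"]))
  tab <- as.data.frame(res)
  expect_true(all(tab$q >= tab$p))
  both_zero <- tab$x == 0 & tab$y == 0
  expect_true(all(tab$p[both_zero] == 1))
  expect_true(all(tab$direction[both_zero] == "not_significant"))
  expect_output(print(res), "differentially regulated")
})

test_that("mismatched unigene sets are rejected", {
  expect_error(dge_table(c(a = 1, b = 2), c(a = 1, c = 2),
                         c(a = 100, b = 100, c = 100)),
               "different unigene sets")
})
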