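test_that("truth sampling is reproducible and respects fractions", {
  t1 <- sample_truth(500, seed = 11)
  t2 <- sample_truth(500, seed = 11)
  expect_identical(t1, t2)
  t3 <- sample_truth(500, seed = 12)
  expect_false(identical(t1, t3))
  expect_equal(sum(t1$status == "interaction"), 25)  # 5% of 500
  expect_equal(sum(t1$status == "DE"), 50)           # 10% of 500
  expect_true(all(t1$dispersion > 0))
})

test_that("a zero non-null fraction yields a pure null generator", {
  tr <- sample_truth(100, effect_config(frac_de = 0, frac_interaction = 0),
                     seed = 5)
  expect_true(all(truth_beta(tr) == 0))
  expect_true(all(tr$status == "null"))
})

test_that("inconsistent fractions are rejected", {
  expect_error(sample_truth(10, effect_config(frac_de = 0.8,
                                              frac_interaction = 0.4),
                            seed = 1), "sum")
  expect_error(sample_truth(10, effect_config(frac_de = -0.1), seed = 1))
})

test_that("injected class labels satisfy the classification rule", {
  tr <- sample_truth(2000, effect_config(frac_interaction = 0.3), seed = 21)
  b <- truth_beta(tr)
  int <- which(tr$status == "interaction")
  expect_gt(length(int), 100)
  for (g in int) {
    cb <- tr$combo[g]
    expected <- expected_combined_lfc(b[g, ], cb)
    expect_identical(classify_interaction(expected, b[g, cb]), tr$class[g])
  }
  # the canonical A+ pattern: positive mains, negative interaction
  expect_identical(
    classify_interaction(expected_combined_lfc(
      c(Salinity = 1, Sediment = 0, Flow = 1, `Salinity:Sediment` = 0,
        `Salinity:Flow` = -0.5, `Sediment:Flow` = 0,
        `Salinity:Sediment:Flow` = 0), "Salinity:Flow"), -0.5),
    "A+")
})

test_that("count simulation is deterministic and respects the mean model", {
  tr <- sample_truth(80, effect_config(frac_de = 0, frac_interaction = 0),
                     seed = 3)
  d <- make_design()
  tx1 <- simulate_counts(tr, d, seed = 9)
  tx2 <- simulate_counts(tr, d, seed = 9)
  expect_identical(tx1, tx2)

  # Poisson limit, mu = 100: per-gene sample means stay within 3*sqrt(100/64)
  tr$beta0 <- log2(100)
  tr$dispersion <- 0
  tr$batch_loading <- 0
  sf <- rep(1, 64)
  tx <- simulate_counts(tr, d, size_factors = sf, seed = 31)
  gc_ <- summarise_to_gene(tx)
  gene_means <- rowMeans(gc_$counts)
  # Monte-Carlo: nearly all genes within the 3-sigma band for xbar(64),
  # and the grand mean much tighter
  expect_gte(mean(abs(gene_means - 100) < 3 * sqrt(100 / 64)), 0.97)
  expect_lt(abs(mean(gene_means) - 100), 3 * sqrt(100 / (64 * 80)))
})

test_that("doubling one size factor doubles that sample's expected counts", {
  tr <- sample_truth(400, effect_config(frac_de = 0, frac_interaction = 0),
                     seed = 3)
  tr$beta0 <- log2(200); tr$dispersion <- 0; tr$batch_loading <- 0
  d <- make_design()
  sf <- rep(1, 64); sf2 <- sf; sf2[1] <- 2
  tx1 <- simulate_counts(tr, d, size_factors = sf, seed = 8)
  tx2 <- simulate_counts(tr, d, size_factors = sf2, seed = 8)
  m1 <- colSums(summarise_to_gene(tx1)$counts)
  m2 <- colSums(summarise_to_gene(tx2)$counts)
  expect_equal(unname(m2[1] / m1[1]), 2, tolerance = 0.05)
  expect_equal(unname(m2[-1]), unname(m1[-1]), tolerance = 0.05)
})

test_that("non-positive size factors are rejected", {
  tr <- sample_truth(5, seed = 1)
  d <- make_design()
  expect_error(simulate_counts(tr, d, size_factors = rep(-1, 64), seed = 1),
               "positive")
})

test_that("positive dispersion produces overdispersed counts", {
  tr <- sample_truth(1000, effect_config(frac_de = 0, frac_interaction = 0),
                     seed = 17)
  tr$beta0 <- log2(500)           # high-mean genes
  tr$dispersion <- 0.2
  tr$batch_loading <- 0
  d <- make_design()
  tx <- simulate_counts(tr, d, size_factors = rep(1, 64), seed = 18)
  m <- summarise_to_gene(tx)$counts
  vmr <- apply(m, 1L, var) / rowMeans(m)
  expect_gt(mean(vmr > 1), 0.99)
  expect_gt(median(vmr), 10)      # ~ 1 + alpha * mu = 101
})

test_that("isoform structure maps each transcript to one gene", {
  tr <- sample_truth(50, seed = 2)
  tx <- simulate_counts(tr, make_design(), seed = 2)
  expect_true(all(table(tx$transcript_id) == 1))
  expect_true(all(tx$effective_length >= 300 & tx$effective_length <= 5000))
  expect_setequal(unique(tx$gene_id), tr$gene_id)
})
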