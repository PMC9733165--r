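test_that("expected combined LFC sums the lower-order terms", {
  beta <- c(Intercept = 5, Salinity = 2, Sediment = 0.5, Flow = 1,
            `Salinity:Sediment` = -0.5, `Salinity:Flow` = -0.5,
            `Sediment:Flow` = -0.5, `Salinity:Sediment:Flow` = 0.2)
  expect_equal(expected_combined_lfc(beta, "Salinity:Flow"), 3)
  expect_equal(expected_combined_lfc(beta, "Salinity:Sediment"), 2.5)
  # three-way: all three mains plus all three pairwise terms
  expect_equal(expected_combined_lfc(beta, "Salinity:Sediment:Flow"),
               2 + 0.5 + 1 - 0.5 - 0.5 - 0.5)
  beta0 <- beta * 0
  for (cb in c("Salinity:Flow", "Salinity:Sediment", "Sediment:Flow",
               "Salinity:Sediment:Flow"))
    expect_equal(expected_combined_lfc(beta0, cb), 0)
  expect_error(expected_combined_lfc(beta, "Salinity:Depth"), "unknown")
})

test_that("three-way mains (1,1,1) with pairwise (-0.5 each) expect 1.5", {
  beta <- c(Salinity = 1, Sediment = 1, Flow = 1,
            `Salinity:Sediment` = -0.5, `Salinity:Flow` = -0.5,
            `Sediment:Flow` = -0.5, `Salinity:Sediment:Flow` = 0.4)
  expect_equal(expected_combined_lfc(beta, "Salinity:Sediment:Flow"), 1.5)
})

test_that("the classification rule covers all four sign quadrants", {
  expect_identical(classify_interaction(2, 1), "S+")
  expect_identical(classify_interaction(2, -1), "A+")
  expect_identical(classify_interaction(-2, 1), "A-")
  expect_identical(classify_interaction(-2, -1), "S-")
  # exhaustive grid over magnitudes and signs
  for (e in c(-3, -0.5, 0.5, 3)) for (i in c(-2, -0.1, 0.1, 2)) {
    cls <- classify_interaction(e, i)
    expect_identical(cls, if (e > 0) {
      if (i > 0) "S+" else "A+"
    } else {
      if (i > 0) "A-" else "S-"
    })
    # sign symmetry: negating both inputs swaps S+<->S- and A+<->A-
    flipped <- classify_interaction(-e, -i)
    expect_identical(flipped, chartr("+-", "-+", cls))
  }
})

test_that("near-zero expectation classifies deviations as synergistic", {
  expect_identical(classify_interaction(0, 0.5), "S+")
  expect_identical(classify_interaction(1e-9, -0.5), "S-")
  expect_error(classify_interaction(1, 1e-9), "eps")
})

test_that("tabulation follows the class/combination layout and conserves calls", {
  calls <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    combo = c("Salinity:Flow", "Salinity:Flow", "Sediment:Flow",
              "Salinity:Sediment:Flow", "Salinity:Flow", "Salinity:Sediment"),
    class = c("A+", "A-", "A-", "A-", "S-", "A+"),
    stringsAsFactors = FALSE)
  tab <- tabulate_interactions(calls)
  expect_equal(colnames(tab),
               c("Salinity:Flow", "Salinity:Sediment", "Sediment:Flow",
                 "Salinity:Sediment:Flow"))
  expect_equal(rownames(tab), c("S+", "S-", "A+", "A-", "Total"))
  expect_equal(unname(tab["Total", ]), c(3L, 1L, 1L, 1L))
  expect_equal(sum(tab["Total", ]), nrow(calls))
  expect_equal(unname(tab[, "Salinity:Flow"]), c(0L, 1L, 1L, 1L, 3L))
  empty <- tabulate_interactions(calls[0, ])
  expect_true(all(empty == 0L))
})

test_that("interaction calls on a noiseless fit recover injected classes", {
  tr <- sample_truth(400, effect_config(frac_de = 0, frac_interaction = 0.5),
                     seed = 33)
  b <- truth_beta(tr)
  rownames(b) <- tr$gene_id
  # noiseless surrogate fit: exact coefficients, tiny SEs
  fake_fit <- structure(list(
    beta = cbind(Intercept = tr$beta0, b),
    se = matrix(1e-10, nrow(b), ncol(b) + 1,
                dimnames = list(tr$gene_id, c("Intercept", colnames(b)))),
    padj = matrix(0, nrow(b), ncol(b), dimnames = list(tr$gene_id,
                                                       colnames(b)))),
    class = "facstress_fit")
  calls <- call_interactions(fake_fit, fdr = 0.1)
  int <- tr[tr$status == "interaction", ]
  m <- merge(int, calls, by.x = c("gene_id", "combo"),
             by.y = c("gene_id", "combo"))
  expect_equal(nrow(m), nrow(int))
  expect_true(all(m$class.x == m$class.y))

  # sign-flip equivariance of the whole pipeline on noiseless inputs
  flip <- fake_fit
  flip$beta[, -1] <- -flip$beta[, -1]
  calls_f <- call_interactions(flip, fdr = 0.1)
  mrg <- merge(calls, calls_f, by = c("gene_id", "combo"))
  expect_equal(nrow(mrg), nrow(calls))
  expect_identical(chartr("+-", "-+", mrg$class.x), mrg$class.y)
})

test_that("exclusive intersections form a partition of the union", {
  out <- exclusive_intersections(list(A = c("g1", "g2"), B = "g2"))
  expect_setequal(out$signature, c("A", "A&B"))
  expect_equal(out$count[out$signature == "A"], 1L)
  expect_equal(out$genes[out$signature == "A&B"][[1]], "g2")

  # property: disjoint, covering, matching a brute-force signature oracle
  set.seed(91)
  for (rep_i in 1:20) {
    k <- sample(2:6, 1)
    universe <- sprintf("g%02d", 1:30)
    sets <- lapply(seq_len(k), function(i)
      sample(universe, sample(0:20, 1)))
    names(sets) <- LETTERS[seq_len(k)]
    out <- exclusive_intersections(sets)
    all_genes <- unlist(out$genes)
    expect_equal(sum(out$count), length(unique(unlist(sets))))
    expect_false(anyDuplicated(all_genes) > 0)
    expect_setequal(all_genes, unique(unlist(sets)))
    for (j in seq_len(nrow(out))) {
      members <- strsplit(out$signature[j], "&", fixed = TRUE)[[1]]
      for (gene in out$genes[[j]]) {
        oracle <- names(sets)[vapply(sets, function(s) gene %in% s,
                                     logical(1))]
        expect_setequal(members, oracle)
      }
    }
  }
  expect_error(exclusive_intersections(rep(list(c("a")), 17)), "16")
})

test_that("seven sets give at most 127 exclusive regions", {
  set.seed(92)
  sets <- lapply(1:7, function(i) sample(sprintf("g%03d", 1:200), 120))
  names(sets) <- paste0("T", 1:7)
  out <- exclusive_intersections(sets)
  expect_lte(nrow(out), 127L)
})

test_that("treatment dendrograms use Euclidean distance, average linkage", {
  lfc <- cbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  tree <- lfc_treatment_tree(lfc)
  d <- dist(t(lfc))
  expect_equal(as.numeric(d)[1], 5)           # a vs b
  expect_equal(tree$height[1], 0)             # identical columns merge first
  expect_setequal(labels(as.dendrogram(tree)), c("a", "b", "c"))
  # invariant to gene (row) permutation
  tree2 <- lfc_treatment_tree(lfc[c(2, 1), ])
  expect_equal(tree$height, tree2$height)
  expect_error(lfc_treatment_tree(lfc[, 1, drop = FALSE]), "two")
  lfc[1, 1] <- NA
  expect_error(lfc_treatment_tree(lfc), "issing")
})
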