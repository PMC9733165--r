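# Shared fixtures: small transcript tables and simulation shortcuts.

# Hand-built transcript table: 2 genes, gene A with two isoforms.
toy_tx <- function() {
  data.frame(
    transcript_id = c("A.1", "A.2", "B.1"),
    gene_id = c("A", "A", "B"),
    effective_length = c(1000, 500, 800),
    s1 = c(10, 10, 5),
    s2 = c(20, 0, 5),
    stringsAsFactors = FALSE)
}

# Run simulate + preprocess + fit (+ optional later stages) on one seed.
sim_study <- function(n_genes, seed, effects = effect_config(),
                      stages = c("simulate", "preprocess", "fit",
                                 "interactions")) {
  run_pipeline(run_config(n_genes = n_genes, effects = effects,
                          stages = stages),
               out_dir = NULL, seed = seed)
}

# Term-wise truth matrix (genes x factorial terms) from a truth table.
truth_beta <- function(truth) {
  cols <- grep("^beta_", names(truth), value = TRUE)
  m <- as.matrix(truth[, cols])
  colnames(m) <- sub("^beta_", "", cols)
  rownames(m) <- truth$gene_id
  m
}

# Brute-force BH step-up, independent of stats::p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exhaustive hypergeometric upper tail via binomial coefficients.
hyper_oracle <- function(N, K, n, k) {
  i <- k:min(n, K)
  i <- i[(n - i) <= (N - K)]
  if (length(i) == 0L) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
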