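# Independent oracles and small in-code fixtures shared across tests.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j,
# computed literally from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Hypergeometric upper tail by explicit enumeration of the overlap values.
hyper_tail_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Shared-target filter by literal group-by counting.
shared_oracle <- function(pairs, m) {
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    keep[i] <- length(unique(pairs$mirna[pairs$gene == pairs$gene[i]])) >= m
  }
  pairs[keep, , drop = FALSE]
}

# A tiny deterministic count matrix with both groups represented.
toy_counts <- function() {
  count_matrix(matrix(c(10, 20, 30, 15,
                        40, 35, 25, 50,
                        5, 8, 12, 7), nrow = 3, byrow = TRUE),
               feature_ids = c("f1", "f2", "f3"),
               sample_ids = c("s1", "s2", "s3", "s4"))
}

toy_samples <- function() {
  sample_table(c("s1", "s2", "s3", "s4"),
               c("case", "case", "control", "control"))
}

# Random prediction table over small universes, for property tests.
random_prediction_table <- function(n_mirnas = 5, n_genes = 8, n_tools = 8,
                                    p = 0.25) {
  mirnas <- paste0("m", seq_len(n_mirnas))
  genes <- paste0("g", seq_len(n_genes))
  tools <- paste0("T", seq_len(n_tools))
  grid <- expand.grid(mirna = mirnas, gene = genes, tool = tools,
                      stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < p, , drop = FALSE]
  pair_table(grid$mirna, grid$gene, grid$tool, kind = "prediction")
}

# Hand-made synthetic_truth for the prediction/validation generators.
make_truth <- function(pairs) {
  structure(list(de_genes = setNames(rep(-2, length(unique(pairs$gene))),
                                     unique(pairs$gene)),
                 de_mirnas = setNames(rep(2, length(unique(pairs$mirna))),
                                      unique(pairs$mirna)),
                 true_pairs = pairs,
                 size_factors = numeric()),
            class = "synthetic_truth")
}
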