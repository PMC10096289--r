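# Independent oracles used across the suite. These re-derive expected values
# by brute force and deliberately avoid the code paths they check.

# Literal transcription of the correlation-weighted average: build the
# Spearman matrix pairwise, floor off-diagonals, sum rows of (R - I),
# normalize, average.
oracle_weighted_average <- function(X, floor = 0.01) {
  n <- ncol(X)
  R <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        ri <- rank(X[, i]); rj <- rank(X[, j])
        R[i, j] <- if (stats::sd(ri) == 0 || stats::sd(rj) == 0) 0 else
          stats::cor(ri, rj)
      }
    }
  }
  Rf <- pmax(R, floor)
  diag(Rf) <- 0
  raw <- rowSums(Rf)
  w <- raw / sum(raw)
  list(vector = as.numeric(X %*% w), weights = w)
}

# AUROC by exhaustive pair counting: (concordant + half ties) / pairs.
oracle_auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Random signature list over a shared panel.
make_signatures <- function(n, G, gene = "GX", kind = "knockdown",
                            cells = NULL, conditions = NULL, seed = 1) {
  set.seed(seed)
  panel <- gene_panel(sprintf("g%02d", seq_len(G)))
  if (is.null(cells)) cells <- rep("A", n)
  if (is.null(conditions)) conditions <- paste0("c", seq_len(n))
  lapply(seq_len(n), function(i) {
    signature(rnorm(G), gene, kind, cells[i], conditions[i],
              sprintf("s%02d", i), panel)
  })
}

small_bundle <- function(seed = 1, ...) {
  gen_bundle(synthetic_config(G = 20, n_targets = 8, n_compounds = 30,
                              n_positives = 40, seed = seed, ...))
}
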