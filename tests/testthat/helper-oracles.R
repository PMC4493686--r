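# Independent brute-force oracles used by the tests. These deliberately
# re-derive quantities from first principles (double loops, textbook
# formulas) and never call the implementation paths they check.

# Pearson correlation from the textbook covariance formula.
brute_pearson <- function(a, b) {
  n <- length(a)
  sab <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
  sab / sqrt(sum((a - mean(a))^2) / (n - 1)) / sqrt(sum((b - mean(b))^2) / (n - 1))
}

# Connectivity score of candidate v against node set S in an edge table.
brute_score <- function(edges, S, v) {
  sum(edges$weight[(edges$gene1 == v & edges$gene2 %in% S) |
                     (edges$gene2 == v & edges$gene1 %in% S)])
}

# Exhaustive greedy expansion: at each step evaluate every candidate's score
# and take the lexicographically smallest argmax.
brute_greedy <- function(edges, universe, seeds, k) {
  S <- intersect(seeds, universe)
  added <- character(0)
  for (step in seq_len(min(k, length(universe) - length(S)))) {
    cand <- setdiff(universe, S)
    sc <- vapply(cand, function(v) brute_score(edges, S, v), numeric(1))
    best <- sort(cand[sc == max(sc)])[1]
    added <- c(added, best)
    S <- c(S, best)
  }
  added
}

# Direct per-cell kNN imputation following the definition: RMS distance over
# shared observed columns, inverse-distance weights over the k nearest
# candidates observed at the target column.
brute_impute_cell <- function(m, g, j, k, eps = 1e-6, min_shared = 3) {
  cand <- setdiff(seq_len(nrow(m)), g)
  d <- rep(NA_real_, nrow(m))
  for (h in cand) {
    shared <- which(!is.na(m[g, ]) & !is.na(m[h, ]))
    if (length(shared) >= min_shared && !is.na(m[h, j])) {
      d[h] <- sqrt(sum((m[g, shared] - m[h, shared])^2) / length(shared))
    }
  }
  use <- which(!is.na(d))
  use <- use[order(d[use], rownames(m)[use])]
  use <- head(use, k)
  w <- 1 / (d[use] + eps)
  w <- w / sum(w)
  sum(w * m[use, j])
}

# Tiny random expression tibble.
rand_expr <- function(n_genes, n_samples, seed, missing_rate = 0) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    if (missing_rate > 0) m[runif(length(m)) < missing_rate] <- NA
    tibble::as_tibble(cbind(tibble::tibble(gene = rownames(m)),
                            as.data.frame(m)))
  })
}

expr_mat <- function(x) {
  m <- as.matrix(x[, -1])
  rownames(m) <- x$gene
  storage.mode(m) <- "double"
  m
}
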