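# Brute-force AUC by pair counting over all positive-negative pairs
# (ties count one half).
auc_pair_counting <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Permutation oracle for comparing two paired score vectors: within each
# case, swap which model produced which score with probability 1/2, and
# recompute the AUC difference. Two-sided p-value with the +1 correction.
delong_permutation_p <- function(labels, a, b, n_perm = 1e4, seed = 1) {
  obs <- abs(auc_rank(labels, a) - auc_rank(labels, b))
  n <- length(labels)
  hits <- 0L
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    sw <- stats::runif(n) < 0.5
    a2 <- ifelse(sw, b, a); b2 <- ifelse(sw, a, b)
    if (abs(auc_rank(labels, a2) - auc_rank(labels, b2)) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Midrank AUC without any package internals (used inside the permutation
# oracle where speed matters).
auc_rank <- function(labels, scores) {
  r <- rank(scores, ties.method = "average")
  m <- sum(labels == 1); n <- sum(labels == 0)
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}
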