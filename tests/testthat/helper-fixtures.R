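# Shared fixtures, all generated in code.

small_cohort <- function(n = 120, seed = 1, ...) {
  generate_cohort(cohort_spec(n_records = n, seed = seed, ...))
}

# rank-based AUC of scores against 0/1 labels (independent of any model fit)
auc_score <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exhaustive-enumeration optimum of the within-cluster distance objective
enumerate_sse_optimum <- function(X, k) {
  n <- nrow(X)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    ch <- as.integer(grid[i, ])
    if (length(unique(ch)) < k) next
    best <- min(best, as.numeric(sse_fitness(ch, X, k)))
  }
  best
}

# brute-force Rand index by explicit pair enumeration
rand_index_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / total
}

# tiny complete feature table wrapping a numeric matrix
matrix_table <- function(X, labels = NULL) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  feature_table(X, labels = labels)
}
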