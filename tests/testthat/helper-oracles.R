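# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, exact integer arithmetic) and never
# call the implementation paths they check.

# pairwise nucleotide diversity by explicit double loop
oracle_pi <- function(haps, L) {
  n <- nrow(haps)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(haps[i, ] != haps[j, ])
  }
  tot / (n * (n - 1) / 2) / L
}

# Tajima's D from first principles (constants recomputed independently)
oracle_tajima <- function(haps) {
  n <- nrow(haps)
  S <- sum(apply(haps, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k <- oracle_pi(haps, 1)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact unsigned Stirling numbers of the first kind (integer recurrence)
oracle_stirling <- function(n) {
  row <- 1
  if (n == 0) return(row)
  for (m in 1:n) {
    row <- c(0, row) + (m - 1) * c(row, 0)
  }
  row  # k = 0..n
}

# squared Pearson correlation of allele indicators
oracle_r2 <- function(a, b) stats::cor(a, b)^2

# Benjamini-Hochberg by definition: q_i = min over j with p_j >= p_i of
# p_j * m / rank_j (computed the slow way)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  r <- numeric(m)
  for (i in seq_len(m)) {
    ge <- which(p >= p[i] - 1e-15)
    cand <- vapply(ge, function(j) {
      p[j] * m / rank(p, ties.method = "max")[j]
    }, numeric(1))
    r[i] <- min(1, min(cand))
  }
  r
}

# small deterministic genotype matrix builder
toy_genotypes <- function(geno, fragment = "F", pos = NULL,
                          ref = NULL, alt = NULL) {
  m <- ncol(geno)
  genotype_matrix(geno, data.frame(
    fragment = fragment, pos = pos %||% seq_len(m) * 10L,
    ref = ref %||% rep("A", m), alt = alt %||% rep("G", m),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
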