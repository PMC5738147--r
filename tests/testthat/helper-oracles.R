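# Independent oracles used to cross-check the implementation.

# brute-force pattern classifier: tests the four one-off forms explicitly
oracle_classify <- function(p) {
  if (p[2] == p[3] && p[3] == p[4] && p[1] != p[2]) return(1L)
  if (p[1] == p[3] && p[3] == p[4] && p[2] != p[1]) return(2L)
  if (p[1] == p[2] && p[2] == p[4] && p[3] != p[1]) return(3L)
  if (p[1] == p[2] && p[2] == p[3] && p[4] != p[1]) return(4L)
  5L
}

all_256_patterns <- function() {
  nuc <- c("A", "C", "G", "T")
  g <- expand.grid(d = nuc, c = nuc, b = nuc, a = nuc,
                   stringsAsFactors = FALSE)
  as.matrix(g[, c("a", "b", "c", "d")])
}

# Z statistics via the multinomial covariance matrix and a contrast vector:
# Sigma = M (diag(q) - q q'), z = c'X / sqrt(c' Sigma c)
oracle_z <- function(X) {
  M <- sum(X)
  q <- X / M
  Sigma <- M * (diag(q) - tcrossprod(q))
  z_for <- function(cv) {
    den <- sqrt(drop(t(cv) %*% Sigma %*% cv))
    if (den == 0) 0 else sum(cv * X) / den
  }
  c(z1 = z_for(c(1, -1, 0, 0, 0)), z2 = z_for(c(0, 0, 1, -1, 0)))
}

# series-expansion matrix exponential with scaling and squaring
oracle_expm <- function(A, nterms = 30L) {
  s <- max(0L, ceiling(log2(max(1, norm(A, "1")))))
  B <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(nterms)) {
    term <- term %*% B / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# JC69 probability that two tips separated by path length d differ
jc_diff_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# random 4-taxon alignment with given column count (uniform iid nucleotides)
random_quartet_aln <- function(n, taxa = c("A", "B", "C", "D")) {
  matrix(sample(c("A", "C", "G", "T"), 4 * n, replace = TRUE),
         nrow = 4, dimnames = list(taxa, NULL))
}
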