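# Independent oracles used across the suite. These deliberately share no
# code with the package: the matcher is a position-by-position loop over its
# own IUPAC table, and the Fisher oracle is a direct hypergeometric tail
# summation over binomial coefficients.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# counts overlapping matches; a subject N matches nothing
naive_count <- function(seq, motif) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  if (length(m) > length(s)) return(0L)
  hits <- 0L
  for (off in seq_len(length(s) - length(m) + 1L)) {
    ok <- TRUE
    for (j in seq_along(m)) {
      if (!(s[off + j - 1L] %in% oracle_iupac[[m[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# P(X >= k), X ~ hypergeometric(N, n, K), by explicit tail summation
oracle_tail <- function(k, K, n, N) {
  i <- seq(from = k, to = min(n, K))
  if (!length(i)) return(0)
  sum(choose(n, i) * choose(N - n, K - i)) / choose(N, K)
}

random_acgtn <- function(len, p_n = 0.02) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

random_iupac_motif <- function(len) {
  pool <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
  prob <- c(rep(0.2, 4), rep(0.025, 6), rep(0.0125, 4), 0.0)
  prob[15] <- 1 - sum(prob[1:14])
  paste(sample(pool, len, replace = TRUE, prob = prob), collapse = "")
}

# valid random 2x2 enrichment table with background size N
random_table <- function(N_max = 60) {
  pick <- function(v) v[sample.int(length(v), 1L)]  # safe for length 1
  N <- pick(2:N_max)
  K <- pick(1:N)
  n <- pick(0:N)
  # hypergeometric support: max(0, K+n-N) <= k <= min(K, n)
  k <- pick(seq(max(0, K + n - N), min(K, n)))
  list(k = k, K = K, n = n, N = N)
}
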