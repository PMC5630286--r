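# Independent oracles: kept deliberately separate from the package's code
# paths (direct combinatorial enumeration; quadratic dynamic programming).

# Upper-tail Fisher P by direct enumeration of all 2x2 tables with the
# observed margins, using binomial coefficients only.
fisher_tail_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m <- a + c; N <- r1 + r2
  if (N == 0) return(1)
  xs <- max(0, m - r2):min(r1, m)
  probs <- choose(r1, xs) * choose(r2, m - xs) / choose(N, m)
  sum(probs[xs >= a])
}

# Vectorized version over parallel count vectors (same formula).
fisher_tail_oracle_vec <- function(a, b, c, d) {
  mapply(fisher_tail_oracle, a, b, c, d)
}

# Upper-tail hypergeometric by explicit enumeration of draw outcomes.
hyper_tail_oracle <- function(N, K, n, k) {
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

# Quadratic affine-gap Smith-Waterman returning the optimal local score.
# Gap of length L costs gap_open + L * gap_ext, matching align_scoring().
sw_local_oracle <- function(p, s, scoring = align_scoring()) {
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(pc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)     # gap in subject (consumes pattern)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in pattern (consumes subject)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (pc[i] == sc[j]) scoring$match else scoring$mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] - scoring$gap_open - scoring$gap_ext,
                             X[i, j + 1] - scoring$gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - scoring$gap_open - scoring$gap_ext,
                             Y[i + 1, j] - scoring$gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Score implied by an align_mrna() coordinate map: aligned columns scored
# as match/mismatch, jumps between consecutive map rows as affine gaps.
score_from_map <- function(map, p, s, scoring = align_scoring()) {
  if (!nrow(map)) return(0)
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  total <- sum(ifelse(pc[map$mouse_pos] == sc[map$human_pos],
                      scoring$match, scoring$mismatch))
  if (nrow(map) > 1L) {
    dp <- diff(map$mouse_pos) - 1L   # pattern positions skipped between columns
    ds <- diff(map$human_pos) - 1L   # subject positions skipped between columns
    # affine penalty per run of skipped positions on either sequence
    pen <- function(len) ifelse(len > 0, scoring$gap_open + len * scoring$gap_ext, 0)
    total <- total - sum(pen(dp)) - sum(pen(ds))
  }
  total
}
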