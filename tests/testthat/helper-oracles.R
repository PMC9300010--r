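# Independent oracles used across tests.  These deliberately re-derive
# results by brute force or from first principles, sharing no code with the
# package internals they check.

# Exhaustive maximum-weight monotone-chain search over all anchor subsets.
# Chains must be strictly increasing in idx_a, strictly monotone in idx_b,
# with at most max_gap skipped genes per genome between consecutive anchors;
# score = sum of anchor scores - gap_penalty * skipped genes (both sides).
oracle_best_chain <- function(a, max_gap, gap_penalty) {
  n <- nrow(a)
  best <- 0
  pow2 <- 2^(seq_len(n) - 1L)
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, pow2) > 0)
    o <- idx[order(a$idx_a[idx])]
    if (anyDuplicated(a$idx_a[o])) next
    if (length(o) == 1L) {
      best <- max(best, a$score[o])
      next
    }
    db <- diff(a$idx_b[o])
    if (any(db == 0)) next
    if (!(all(db > 0) || all(db < 0))) next
    ga <- diff(a$idx_a[o]) - 1L
    gb <- abs(db) - 1L
    if (any(ga > max_gap) || any(gb > max_gap)) next
    best <- max(best, sum(a$score[o]) - gap_penalty * sum(ga + gb))
  }
  best
}

random_anchor_set <- function(n, span = 25L) {
  data.frame(gene_a = paste0("a", seq_len(n)), gene_b = paste0("b", seq_len(n)),
             species_a = "A", species_b = "B",
             chr_a = "c1", idx_a = sample.int(span, n),
             chr_b = "c1", idx_b = sample.int(span, n),
             score = round(runif(n, 0.5, 1), 3), stringsAsFactors = FALSE)
}

# Package's best single-chain score over both orientations (what the DP
# chaining optimises before block extraction).
dp_best_chain <- function(a, max_gap, gap_penalty) {
  a <- a[order(a$idx_a, a$idx_b), , drop = FALSE]
  max(reedwgd:::.chain_dir(a, +1L, max_gap, gap_penalty)$score,
      reedwgd:::.chain_dir(a, -1L, max_gap, gap_penalty)$score)
}

# Hypergeometric upper tail by exhaustive subset enumeration: the fraction
# of n-subsets of an N-gene universe (first K genes annotated) containing at
# least k annotated genes.
oracle_hyper_upper <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Mismatch count at 4D sites from raw CDS strings, using a hand-listed
# table of the eight four-fold codon families of the standard code.
oracle_4d_mismatch <- function(a, b) {
  fams <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  n <- nchar(a)
  ca <- substring(a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(b, seq(1L, n, 3L), seq(3L, n, 3L))
  sel <- substr(ca, 1L, 2L) == substr(cb, 1L, 2L) & substr(ca, 1L, 2L) %in% fams
  c(n_4d = sum(sel),
    n_diff = sum(substr(ca[sel], 3L, 3L) != substr(cb[sel], 3L, 3L)))
}

jc_correct <- function(p) -0.75 * log(1 - 4 * p / 3)
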