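# Brute-force enumeration oracles, independent of the implementations they
# check.

# Mann-Whitney U: full permutation distribution over group assignments
mwExactOracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u), mean(us >= u)))
}

# Wilcoxon signed rank: enumerate all 2^n sign assignments
signedRankOracle <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
}

# Fisher: hypergeometric enumeration, point-probability method (same
# relative tolerance as the reference implementation uses for ties)
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a, c1, n - c1, r1)
  pObs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
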