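# Independent statistical oracles used to check the package's test
# machinery against first-principles computations.

# BH adjusted p-values from the rejection definition: the adjusted value of
# p_i is the smallest level alpha at which the step-up procedure rejects i.
bh_oracle <- function(p) {
  n <- length(p)
  cand <- sort(unique(c(1, pmin(1, as.vector(outer(p, seq_len(n),
                                                   function(pi, k) pi * n / k))))))
  rejected_at <- function(alpha) {
    ps <- sort(p)
    ok <- which(ps <= alpha * seq_len(n) / n + 1e-12)
    if (length(ok) == 0) return(rep(FALSE, n))
    p <= ps[max(ok)]
  }
  vapply(seq_len(n), function(i) {
    min(cand[vapply(cand, function(a) rejected_at(a)[i], logical(1))])
  }, numeric(1))
}

# Exact Wilcoxon signed-rank p by enumeration of all 2^n sign patterns of
# the non-zero differences (valid with or without ties in |d|).
signed_rank_oracle <- function(x, y, alternative = c("two.sided", "greater",
                                                     "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  W <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    sum(r[signs == 1])
  }, numeric(1))
  p_ge <- mean(W >= w)
  p_le <- mean(W <= w)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# All permutations of 1..n (n <= 6), generated recursively.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Adjusted Rand index between two partitions, from the pair-counting
# definition.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_index - expected)
}

# One-sided (enrichment) hypergeometric p by direct tail summation.
hyper_tail_oracle <- function(k, m, n, s) {
  js <- k:min(m, s)
  sum(choose(m, js) * choose(n, s - js)) / choose(m + n, s)
}
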