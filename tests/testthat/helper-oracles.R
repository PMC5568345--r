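# Brute-force oracles, independent of the package implementations.

# step-up BH: adj_i = min over j with p_j >= p_i of m * p_(j) / rank(j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)))
  }
  pmin(adj_sorted, 1)[match(seq_len(m), o)]
}

# geNorm stability: mean over partners of sd of pairwise log2 ratios
genorm_oracle <- function(q) {
  vapply(seq_len(nrow(q)), function(j) {
    sds <- c()
    for (k in seq_len(nrow(q))) {
      if (k == j) next
      sds <- c(sds, stats::sd(log2(q[j, ] / q[k, ])))
    }
    mean(sds)
  }, numeric(1))
}

# upper-tail hypergeometric by explicit combinatorics
hyper_oracle <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

# classical first PLS component by power iteration on M M' (M = X'Y)
pls1_oracle <- function(X, Y, iter = 5000) {
  Xs <- scale(X); Ys <- scale(Y)
  M <- crossprod(Xs, Ys)
  A <- tcrossprod(M)
  w <- rep(1 / sqrt(ncol(Xs)), ncol(Xs))
  for (i in seq_len(iter)) {
    w_new <- A %*% w
    w_new <- w_new / sqrt(sum(w_new^2))
    if (max(abs(w_new - w)) < 1e-14) { w <- w_new; break }
    w <- w_new
  }
  drop(w)
}

balanced_design <- function(n_sows_per_breed = 4, n_fet = 4, seed = 1) {
  generateDesign(n_sows_per_breed, n_fet, seed = seed)
}
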