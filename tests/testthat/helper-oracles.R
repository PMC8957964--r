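# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# knn imputation by explicit loops: for each missing entry, rank all other
# probes by Euclidean distance over co-observed samples (ties by probe
# order), keep those observed at the target sample, average the k nearest.
brute_knn_impute <- function(beta, k) {
  p <- nrow(beta)
  n <- ncol(beta)
  out <- beta
  for (i in seq_len(p)) {
    for (s in seq_len(n)) {
      if (!is.na(beta[i, s])) next
      d <- rep(Inf, p)
      for (j in seq_len(p)) {
        if (j == i) next
        co <- !is.na(beta[i, ]) & !is.na(beta[j, ])
        if (!any(co)) next
        d[j] <- sqrt(sum((beta[i, co] - beta[j, co])^2))
      }
      cand <- which(!is.na(beta[, s]) & is.finite(d))
      if (length(cand) == 0) {
        out[i, s] <- mean(beta[i, ], na.rm = TRUE)
        next
      }
      cand <- cand[order(d[cand], cand)]
      nb <- cand[seq_len(min(k, length(cand)))]
      out[i, s] <- mean(beta[nb, s])
    }
  }
  out
}

# Spearman correlation from the rank formula (average ranks for ties)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# textbook paired t statistic and two-sided p
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Benjamini-Hochberg step-up applied by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# small complete beta matrix with dimnames
toy_beta <- function(p, n, seed = 1) {
  set.seed(seed)
  matrix(runif(p * n), nrow = p,
         dimnames = list(sprintf("cg%08d", seq_len(p)),
                         sprintf("S%04d", seq_len(n))))
}

# minimal annotation covering a beta matrix, all autosomal, SNP-free
toy_annotation <- function(beta) {
  data.frame(probe_id = rownames(beta),
             chr = "1", pos = seq_len(nrow(beta)),
             gene = "", region_group = "Body", cgi_relation = "open_sea",
             snp_flag = FALSE, stringsAsFactors = FALSE)
}
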