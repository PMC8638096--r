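# Independent oracles and small generators shared across the test files.

# Brute-force Fisher p-value by enumerating every 2x2 table with the observed
# margins, with probabilities computed from log-binomial coefficients only
# (no dhyper/phyper, independent of the implementation path). Ties in the
# two-sided sum use the conventional relative 1e-7 band.
enum_fisher_p <- function(m1, t1, m2, t2, sidedness = "two-sided") {
  if (t1 == 0 || t2 == 0) return(1)
  k <- m1 + m2
  n <- t1 + t2
  support <- max(0, k - t2):min(k, t1)
  logp <- lchoose(t1, support) + lchoose(t2, k - support) - lchoose(n, k)
  probs <- exp(logp)
  p0 <- probs[support == m1]
  if (sidedness == "two-sided") {
    min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
  } else {
    v1 <- m1 / t1
    v2 <- m2 / t2
    lower1 <- sum(probs[support <= m1])
    lower2 <- sum(probs[(k - support) <= m2])
    min(1, if (v1 < v2) lower1 else if (v2 < v1) lower2 else max(lower1, lower2))
  }
}

# every distinct (m1, t1, m2, t2) with grand total <= n_max
all_tables_upto <- function(n_max) {
  out <- vector("list", 2048)
  i <- 0
  for (t1 in 0:n_max) for (t2 in 0:(n_max - t1)) {
    for (m1 in 0:t1) for (m2 in 0:t2) {
      i <- i + 1
      if (i > length(out)) out <- c(out, vector("list", length(out)))
      out[[i]] <- c(m1, t1, m2, t2)
    }
  }
  do.call(rbind, out[seq_len(i)])
}

# random count matrix + matching positive/TBD labelling for property tests
random_case <- function(n_mut = 8, n_samples = 4, min_mut = 1) {
  cm <- random_count_matrix(n_mut, n_samples)
  list(counts = cm, positives = define_positive(cm, positive_rule(min_mut)))
}

count_label <- function(st) table(factor(st$status,
  c("positive", "negative", "unknown", "TBD")))

`%||%` <- function(a, b) if (is.null(a)) b else a
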