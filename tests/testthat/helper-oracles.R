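# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths.

# random symmetric non-negative integer matrix
rand_sym_counts <- function(n, lambda = 5) {
  x <- matrix(rpois(n * n, lambda), n)
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  x
}

# centered scaled-density table computed directly from the definition:
# q'(k, l) = S(k, l) / (l - k + 1)^gamma - mean over same-length intervals
oracle_quality_table <- function(counts, gamma, min_len = 2L,
                                 max_len = nrow(counts)) {
  n <- nrow(counts)
  q <- list()
  for (len in min_len:max_len) {
    vals <- sapply(seq_len(n - len + 1L), function(k) {
      idx <- k:(k + len - 1L)
      s <- sum(counts[idx, idx][upper.tri(diag(len))])
      s / len^gamma
    })
    q[[as.character(len)]] <- vals - mean(vals)
  }
  q
}

# exhaustive optimum over every set of non-overlapping intervals with
# length in [min_len, max_len], scoring by the centered quality table
oracle_best_partition <- function(counts, gamma, min_len = 2L,
                                  max_len = nrow(counts)) {
  n <- nrow(counts)
  q <- oracle_quality_table(counts, gamma, min_len, max_len)
  best_from <- function(start) {   # best total over bins start..n (1-based)
    if (start > n - min_len + 1L) return(0)
    best <- best_from(start + 1L)  # leave bin 'start' uncovered
    for (len in min_len:min(max_len, n - start + 1L)) {
      val <- q[[as.character(len)]][start]
      cand <- val + best_from(start + len)
      if (cand > best) best <- cand
    }
    best
  }
  best_from(1L)
}

# exact Mann-Whitney by full enumeration of group assignments
oracle_mww <- function(xs, ys) {
  n <- length(xs); m <- length(ys)
  pooled <- c(xs, ys)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2L, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p_two_sided = min(1, 2 * min(p_le, p_ge)),
       p_greater = p_ge, p_less = p_le)
}

# VI of two label vectors from the contingency table (standard definition,
# independent of the breakpoint-based implementation)
oracle_vi_labels <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  pj <- tab / n
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (pj[i, j] > 0)
      mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
  }
  as.numeric(h(pa) + h(pb) - 2 * mi)
}

# label vector over a window from a set of breakpoints
labels_from_breaks <- function(breaks, w_start, w_end) {
  cuts <- c(w_start, breaks, w_end)
  rep(seq_len(length(cuts) - 1L), diff(cuts))
}

# random contiguous-block partition of a window, as breakpoints
rand_partition_breaks <- function(w_start, w_end, mean_block = 5) {
  pos <- w_start
  breaks <- integer(0)
  repeat {
    pos <- pos + 1L + rpois(1, mean_block - 1)
    if (pos >= w_end) break
    breaks <- c(breaks, pos)
  }
  breaks
}
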