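# Independent brute-force oracles used across tests. These deliberately
# avoid the code paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# upper-tail hypergeometric by exact combinatorial enumeration
oracle_hyper_upper <- function(N, K, n, observed) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= observed])
}

# two-sided Fisher p: sum of point probabilities <= that of the observed
# table, over all tables with the observed margins
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, N - r1, c1)
  p_obs <- dhyper(a, r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney by enumeration of all group assignments
# (no ties); returns list(U, p)
oracle_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Benjamini-Hochberg by the step-up definition q(i) = min_{j >= i} m p(j)/j
oracle_bh <- function(p) {
  ok <- which(!is.na(p))
  ps <- p[ok]
  m <- length(ps)
  o <- order(ps)
  q_sorted <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, m * ps[o[i]] / i)
    q_sorted[i] <- min(1, prev)
  }
  out <- rep(NA_real_, length(p))
  out[ok[o]] <- q_sorted
  out
}

# all-pairs interval overlap scan (0-based half-open)
oracle_assign <- function(peaks, promoters) {
  out <- list()
  for (nm in unique(peaks$tf_name)) {
    pk <- peaks[peaks$tf_name == nm, ]
    hit <- logical(nrow(promoters))
    for (i in seq_len(nrow(pk))) {
      hit <- hit | (promoters$chrom == pk$chrom[i] &
                      pmax(promoters$start, pk$start[i]) <
                        pmin(promoters$end, pk$end[i]))
    }
    out[[nm]] <- sort(promoters$gene_id[hit])
  }
  out
}

# tiny stack with Gaussian spots at given (z, y, x) centres
make_spot_stack <- function(dim_zyx, centres, sigma = 1.5, amplitude = 100,
                            background = 0) {
  a <- array(background, dim_zyx)
  for (i in seq_len(nrow(centres))) {
    for (z in seq_len(dim_zyx[1])) for (y in seq_len(dim_zyx[2]))
      for (x in seq_len(dim_zyx[3])) {
        d2 <- (z - centres[i, 1])^2 + (y - centres[i, 2])^2 +
          (x - centres[i, 3])^2
        a[z, y, x] <- a[z, y, x] + amplitude * exp(-d2 / (2 * sigma^2))
      }
  }
  a
}

# exact-recovery check for one simulated stack
recovered_exactly <- function(img, res) {
  truth <- sort(as.integer(table(img$truth$spots$cell)))
  res$outside_count == 0 &&
    length(res$per_cell_counts) == length(truth) &&
    all(sort(as.integer(res$per_cell_counts)) == truth)
}
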