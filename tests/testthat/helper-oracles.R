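# Brute-force oracles, independent of the implementation paths they check.

# union of covered base pairs, rebuilt from a per-base occupancy vector
bf_merge <- function(gr, gap = 0) {
  out <- list()
  for (cc in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == cc]
    L <- max(GenomicRanges::end(g)) + gap + 2
    covered <- logical(L)
    for (i in seq_along(g))
      covered[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
    # positions within `gap` of covered bases on both sides join runs
    if (gap > 0) {
      idx <- which(covered)
      for (p in which(!covered)) {
        left <- idx[idx < p]; right <- idx[idx > p]
        if (length(left) && length(right) &&
            (min(right) - max(left) - 1) <= gap)
          covered[p] <- TRUE
      }
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (any(keep))
      out[[cc]] <- GenomicRanges::GRanges(
        cc, IRanges::IRanges(starts[keep], ends[keep]))
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  res <- suppressWarnings(do.call(c, unname(out)))  # differing seqlevels
  sort(res)
}

# base-by-base overlap count of two single intervals
bf_overlap_bp <- function(a, b) {
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))) return(0L)
  length(intersect(GenomicRanges::start(a):GenomicRanges::end(a),
                   GenomicRanges::start(b):GenomicRanges::end(b)))
}

# exact two-sided rank-sum p by enumerating all group assignments
bf_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n, m)
  w_all <- apply(combs, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  mu <- m * (length(y)) / 2
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
}

# exhaustive posterior marginals for a tiny Bernoulli HMM
bf_hmm_marginals <- function(pi, A, E, x) {
  K <- length(pi); T_ <- nrow(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  emis <- function(k, t) prod(ifelse(x[t, ] == 1, E[k, ], 1 - E[k, ]))
  probs <- apply(paths, 1, function(p) {
    pr <- pi[p[1]] * emis(p[1], 1)
    for (t in seq_len(T_)[-1]) pr <- pr * A[p[t - 1], p[t]] * emis(p[t], t)
    pr
  })
  tot <- sum(probs)
  marg <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K))
    marg[t, k] <- sum(probs[paths[, t] == k]) / tot
  list(marginals = marg, loglik = log(tot))
}

# log-space forward recursion written independently of the package core
bf_forward_loglik <- function(pi, A, E, x) {
  T_ <- nrow(x); K <- length(pi)
  le <- function(t) {
    vapply(seq_len(K), function(k)
      sum(log(ifelse(x[t, ] == 1, E[k, ], 1 - E[k, ]))), 0)
  }
  la <- log(pi) + le(1)
  for (t in seq_len(T_)[-1]) {
    la <- vapply(seq_len(K), function(k) {
      v <- la + log(A[, k])
      mx <- max(v)
      mx + log(sum(exp(v - mx)))
    }, 0) + le(t)
  }
  mx <- max(la)
  mx + log(sum(exp(la - mx)))
}

# log-space backward recursion for the same total likelihood
bf_backward_loglik <- function(pi, A, E, x) {
  T_ <- nrow(x); K <- length(pi)
  le <- function(t) {
    vapply(seq_len(K), function(k)
      sum(log(ifelse(x[t, ] == 1, E[k, ], 1 - E[k, ]))), 0)
  }
  lb <- rep(0, K)
  for (t in rev(seq_len(T_ - 1))) {
    lem <- le(t + 1)
    lb <- vapply(seq_len(K), function(j) {
      v <- log(A[j, ]) + lem + lb
      mx <- max(v)
      mx + log(sum(exp(v - mx)))
    }, 0)
  }
  v <- log(pi) + le(1) + lb
  mx <- max(v)
  mx + log(sum(exp(v - mx)))
}

# minimum-cost assignment by full permutation enumeration (n <= 7)
bf_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  best <- Inf; arg <- NULL
  for (i in seq_len(nrow(perms))) {
    v <- sum(cost[cbind(seq_len(n), perms[i, ])])
    if (v < best) { best <- v; arg <- perms[i, ] }
  }
  list(assignment = arg, cost = best)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# per-anchor window extraction for meta profiles
bf_meta_profile <- function(track, anchors, flank) {
  bs <- track$bin_size
  nf <- flank %/% bs
  offs <- (-nf):nf
  rows <- matrix(NA_real_, nrow(anchors), length(offs))
  strand <- if ("strand" %in% names(anchors)) anchors$strand else
    rep("+", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    b0 <- ((anchors$pos[i] - 1) %/% bs) + 1
    o <- if (strand[i] == "-") -offs else offs
    idx <- b0 + o
    ok <- idx >= 1 & idx <= length(v)
    rows[i, ok] <- v[idx[ok]]
  }
  colMeans(rows, na.rm = TRUE)
}
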