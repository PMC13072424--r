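# Multivariate Bernoulli hidden Markov model for chromatin-state
# segmentation: Baum-Welch fitting, posterior / Viterbi decoding, and
# functional state labeling against a fixed prototype table.

#' Emission prototype table for the 15 functional chromatin states
#'
#' Each row gives, for one named state, the expected presence pattern of
#' the five marks (ATAC, H3K4me3, H3K27ac, H3K4me1, H3K27me3) on a 0/0.5/1
#' scale: strongly active promoters (TssA), weak promoters (TssAWk),
#' active TSS flanks without accessibility (TssAHet), transcribed regions
#' (TxFlnk, TxFlnkHet, TxFlnkWk), active enhancers (EnhA, EnhAHet,
#' EnhAMe, EnhAWk), poised enhancers (EnhPois), accessible islands
#' (ATAC_Is), bivalent promoters (TssBiv), polycomb-repressed (Repr) and
#' quiescent (Qui) chromatin. The table drives both EM initialization and
#' the nearest-prototype state labeling.
#'
#' @return A 15 x 5 numeric matrix with state rownames and mark colnames.
#' @export
state_prototypes <- function() {
  m <- rbind(
    TssA      = c(1,   1,   1,   0.5, 0),
    TssAWk    = c(0.5, 0.5, 0.5, 0.5, 0),
    TssAHet   = c(0,   1,   1,   0.5, 0),
    TxFlnk    = c(1,   0.5, 0.5, 1,   0),
    TxFlnkHet = c(0,   0.5, 0.5, 1,   0),
    TxFlnkWk  = c(0.5, 0.5, 0,   0.5, 0),
    EnhA      = c(1,   0,   1,   1,   0),
    EnhAHet   = c(0,   0,   1,   1,   0),
    EnhAMe    = c(1,   0,   0.5, 0.5, 0),
    EnhAWk    = c(0.5, 0,   0.5, 1,   0),
    EnhPois   = c(0,   0,   0,   1,   1),
    ATAC_Is   = c(1,   0,   0,   0,   0),
    TssBiv    = c(0.5, 1,   0,   0,   1),
    Repr      = c(0,   0,   0,   0,   1),
    Qui       = c(0,   0,   0,   0,   0)
  )
  colnames(m) <- mark_names()
  m
}

#' Names of the 15 chromatin states
#' @return Character vector in prototype-table order.
#' @export
state_labels <- function() rownames(state_prototypes())

# Flatten mark_matrix input (or a plain 0/1 matrix / list of matrices)
# into a list of T x M integer sequences.
as_sequences <- function(data) {
  if (inherits(data, "mark_matrix")) return(unname(data$bins))
  if (is.matrix(data)) return(list(data))
  out <- list()
  for (d in data) out <- c(out, as_sequences(d))
  out
}

# log emission matrix: T x K for one binary sequence under Bernoulli E
log_emission <- function(x, E) {
  Ec <- pmin(pmax(E, 1e-10), 1 - 1e-10)
  x %*% t(log(Ec)) + (1 - x) %*% t(log(1 - Ec))
}

#' Fit a multivariate Bernoulli HMM by Baum-Welch EM
#'
#' Each hidden state emits the five binary marks as independent
#' Bernoullis. The forward-backward recursions run scaled in compiled
#' code; the per-iteration log-likelihood is monotonically non-decreasing
#' and fitting stops when its absolute change falls below `tol` or after
#' `max_iter` iterations. With `K = 15` the emission matrix is
#' initialized from [state_prototypes()] perturbed by seed-controlled
#' uniform(+/-0.05) noise, which keeps the state identities stable while
#' leaving EM free to fit; other K use seeded uniform starts.
#'
#' @param data A `mark_matrix`, a list of them, or a list of `bins x 5`
#'   0/1 matrices; every chromosome of every sample is one independent
#'   observation sequence.
#' @param K Number of hidden states (`>= 2`).
#' @param seed Seed controlling initialization.
#' @param max_iter,tol EM stopping rule.
#' @param verbose Print the log-likelihood trace.
#' @return A `chromatin_state_model`: list with `K`, `pi`, `A` (K x K),
#'   `E` (K x 5), `loglik` (trace), `converged`, `iterations`,
#'   `labels` (`NULL` until [label_states()] is applied).
#' @export
hmm_fit <- function(data, K = 15, seed = 1, max_iter = 200, tol = 1e-4,
                    verbose = FALSE) {
  check_number(K, "K", min = 2)
  seqs <- as_sequences(data)
  if (!length(seqs)) stop2("no observation sequences supplied")
  M <- ncol(seqs[[1]])
  if (sum(vapply(seqs, function(s) sum(s), 0)) == 0)
    warning("all-zero data: model degenerates to a single effective state")
  proto <- state_prototypes()
  E <- with_stage_seed(seed, "hmm_init", {
    if (K == nrow(proto) && M == ncol(proto)) {
      proto + matrix(runif(K * M, -0.05, 0.05), K, M)
    } else {
      matrix(runif(K * M, 0.1, 0.9), K, M)
    }
  })
  E <- pmin(pmax(E, 0.02), 0.98)
  A <- matrix((1 - 0.96) / (K - 1), K, K); diag(A) <- 0.96
  pi <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    ll <- 0
    pi_new <- numeric(K)
    xisum <- matrix(0, K, K)
    Egam <- numeric(K)
    Ex <- matrix(0, K, M)
    for (x in seqs) {
      B <- exp(log_emission(x, E))
      fb <- fb_cpp(B, A, pi)
      ll <- ll + fb$loglik
      g <- fb$gamma
      pi_new <- pi_new + g[1, ]
      xisum <- xisum + fb$xisum
      Egam <- Egam + colSums(g)
      Ex <- Ex + t(g) %*% x
    }
    ll_trace <- c(ll_trace, ll)
    if (verbose) message(sprintf("iter %d: loglik %.4f", it, ll))
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) { converged <- TRUE; break }
    pi <- pi_new / sum(pi_new)
    rs <- rowSums(xisum)
    A <- xisum / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K
    E <- pmin(pmax(Ex / ifelse(Egam > 0, Egam, 1), 1e-4), 1 - 1e-4)
  }
  colnames(E) <- colnames(seqs[[1]]) %||% paste0("mark", seq_len(M))
  rownames(E) <- paste0("S", seq_len(K))
  dimnames(A) <- list(rownames(E), rownames(E))
  structure(list(K = as.integer(K), pi = pi, A = A, E = E,
                 loglik = ll_trace, converged = converged,
                 iterations = it, labels = NULL),
            class = "chromatin_state_model")
}

#' @export
print.chromatin_state_model <- function(x, ...) {
  cat(sprintf("chromatin_state_model: K = %d, %d EM iteration(s), %s\n",
              x$K, x$iterations,
              if (x$converged) "converged" else "not converged"))
  if (!is.null(x$labels)) cat("labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Posterior state marginals for one binary sequence
#'
#' @param model A fitted `chromatin_state_model`.
#' @param x A `bins x 5` 0/1 matrix.
#' @return A `bins x K` matrix of posterior probabilities (rows sum to 1).
#' @export
hmm_posterior <- function(model, x) {
  if (ncol(x) != ncol(model$E))
    stop2("data mark count does not match the model")
  B <- exp(log_emission(x, model$E))
  fb_cpp(B, model$A, model$pi)$gamma
}

#' Total log-likelihood of sequences under a model
#' @param model A `chromatin_state_model`.
#' @param data As in [hmm_fit()].
#' @return Scalar log-likelihood.
#' @export
hmm_loglik <- function(model, data) {
  sum(vapply(as_sequences(data), function(x) {
    B <- exp(log_emission(x, model$E))
    fb_cpp(B, model$A, model$pi)$loglik
  }, 0))
}

#' Decode a genome segmentation from a fitted model
#'
#' Assigns every bin its posterior-maximum state (default) or the Viterbi
#' path state, then run-length encodes consecutive equal-state bins into
#' segments that tile each chromosome.
#'
#' @param model A fitted (and optionally labeled) `chromatin_state_model`.
#' @param mm A `mark_matrix`.
#' @param method `"posterior"` (forward-backward marginal maximum) or
#'   `"viterbi"`.
#' @return A `GRanges` tiling each chromosome, with mcols `state`
#'   (integer) and `label` (state name when the model is labeled), and
#'   `metadata` fields `bin_size` and `sample_id`.
#' @export
hmm_decode <- function(model, mm, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  if (!inherits(mm, "mark_matrix")) stop2("`mm` must be a mark_matrix")
  bs <- mm$bin_size
  grl <- lapply(names(mm$bins), function(cc) {
    x <- mm$bins[[cc]]
    if (ncol(x) != ncol(model$E))
      stop2("data mark count does not match the model")
    states <- if (method == "posterior") {
      max.col(hmm_posterior(model, x), ties.method = "first")
    } else {
      Ec <- pmin(pmax(model$E, 1e-10), 1 - 1e-10)
      viterbi_cpp(log_emission(x, Ec), log(model$A), log(model$pi))
    }
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    GenomicRanges::GRanges(factor(cc, levels = names(mm$bins)),
      IRanges::IRanges(start = (starts - 1L) * bs + 1L, end = ends * bs),
      state = r$values)
  })
  seg <- do.call(c, grl)
  if (!is.null(model$labels)) seg$label <- model$labels[seg$state]
  S4Vectors::metadata(seg) <- list(bin_size = bs, sample_id = mm$sample_id)
  seg
}

#' Exact minimum-cost bijective assignment
#'
#' Solves the assignment problem for a square cost matrix by exact
#' dynamic programming over column subsets (O(n 2^n); n <= 20), used to
#' match fitted emission rows to prototype rows.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `p` with `p[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop2("cost matrix must be square")
  if (n > 20) stop2("assignment DP supports n <= 20")
  nS <- bitwShiftL(1L, n)
  f <- rep(Inf, nS)
  f[1] <- 0
  popcnt <- integer(nS)
  for (S in seq_len(nS - 1))
    popcnt[S + 1L] <- popcnt[bitwShiftR(S, 1L) + 1L] + bitwAnd(S, 1L)
  for (S in 0:(nS - 2L)) {
    fs <- f[S + 1L]
    if (!is.finite(fs)) next
    i <- popcnt[S + 1L] + 1L
    for (j in seq_len(n)) {
      b <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(S, b) == 0L) {
        S2 <- bitwOr(S, b) + 1L
        v <- fs + cost[i, j]
        if (v < f[S2]) f[S2] <- v
      }
    }
  }
  p <- integer(n)
  S <- nS - 1L
  for (i in rev(seq_len(n))) {
    for (j in seq_len(n)) {
      b <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(S, b) != 0L) {
        prev <- bitwXor(S, b)
        if (isTRUE(all.equal(f[S + 1L], f[prev + 1L] + cost[i, j]))) {
          p[i] <- j
          S <- prev
          break
        }
      }
    }
  }
  p
}

#' Assign functional labels to fitted states
#'
#' Matches each fitted emission row to one prototype row of
#' [state_prototypes()] by minimum total Euclidean distance (an exact
#' bijection via [solve_assignment()]), so every fitted state receives a
#' distinct functional name. Permuting model states permutes the labels
#' identically.
#'
#' @param model A fitted `chromatin_state_model` with `K` equal to the
#'   prototype count.
#' @param prototypes Prototype matrix (defaults to [state_prototypes()]).
#' @return The model with `labels` filled in.
#' @export
label_states <- function(model, prototypes = state_prototypes()) {
  if (model$K != nrow(prototypes))
    stop2("labeling requires K equal to the number of prototypes")
  cost <- as.matrix(stats::dist(rbind(model$E, prototypes)))
  cost <- cost[seq_len(model$K), model$K + seq_len(nrow(prototypes)), drop = FALSE]
  p <- solve_assignment(cost)
  model$labels <- rownames(prototypes)[p]
  rownames(model$E) <- model$labels
  dimnames(model$A) <- list(model$labels, model$labels)
  model
}
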