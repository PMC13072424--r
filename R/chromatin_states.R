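# Binarization of marks and per-state summaries: genome coverage,
# methylation, TSS positional enrichment, DEG-territory enrichment, and
# enhancer-signal/expression correlation.

bin_index <- function(pos, bin_size) ((pos - 1L) %/% bin_size) + 1L

#' Binarize peak calls onto a bin grid
#'
#' A bin scores 1 for a mark iff any peak of that mark overlaps it by at
#' least 1 bp.
#'
#' @param peaks Named list over [mark_names()] of `GRanges` peak sets.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 200).
#' @param sample_id Sample label.
#' @return A `mark_matrix`.
#' @export
binarize_peaks <- function(peaks, chrom_lengths, bin_size = 200,
                           sample_id = "sample") {
  marks <- mark_names()
  if (!all(marks %in% names(peaks)))
    stop2("`peaks` must contain all marks: ", paste(marks, collapse = ", "))
  bins <- lapply(names(chrom_lengths), function(cc) {
    nb <- ceiling(chrom_lengths[[cc]] / bin_size)
    m <- matrix(0L, nb, length(marks))
    for (k in seq_along(marks)) {
      p <- peaks[[marks[k]]]
      p <- p[as.character(GenomicRanges::seqnames(p)) == cc]
      if (!length(p)) next
      from <- bin_index(GenomicRanges::start(p), bin_size)
      to <- pmin(bin_index(GenomicRanges::end(p), bin_size), nb)
      for (i in seq_along(from)) m[from[i]:to[i], k] <- 1L
    }
    m
  })
  names(bins) <- names(chrom_lengths)
  mark_matrix(bins, bin_size, sample_id)
}

#' Binarize continuous signal by a Poisson upper-tail test
#'
#' A bin scores 1 for a mark iff the Poisson upper tail of its (rounded)
#' signal against the genome-wide mean rate of that track falls below
#' `p_threshold` — the standard signal-thresholding rule for
#' segmentation input. A track with no signal yields all zeros with a
#' warning.
#'
#' @param tracks Named list over [mark_names()] of `signal_track`s
#'   sharing one bin grid.
#' @param p_threshold Poisson tail threshold (default 1e-4).
#' @param sample_id Sample label.
#' @return A `mark_matrix`.
#' @export
binarize_signal <- function(tracks, p_threshold = 1e-4,
                            sample_id = "sample") {
  marks <- mark_names()
  if (!all(marks %in% names(tracks)))
    stop2("`tracks` must contain all marks: ", paste(marks, collapse = ", "))
  bs <- tracks[[marks[1]]]$bin_size
  chroms <- names(tracks[[marks[1]]]$values)
  bins <- lapply(chroms, function(cc) {
    m <- matrix(0L, length(tracks[[marks[1]]]$values[[cc]]), length(marks))
    m
  })
  names(bins) <- chroms
  for (k in seq_along(marks)) {
    tr <- tracks[[marks[k]]]
    lambda <- mean(unlist(tr$values, use.names = FALSE))
    if (lambda == 0) {
      warning(sprintf("track '%s' is empty; emitting all-zero calls", marks[k]))
      next
    }
    for (cc in chroms) {
      q <- round(tr$values[[cc]])
      pv <- ppois(q - 1, lambda, lower.tail = FALSE)
      bins[[cc]][, k] <- as.integer(pv < p_threshold)
    }
  }
  mark_matrix(bins, bs, sample_id)
}

seg_labels <- function(seg) {
  if (!is.null(seg$label)) as.character(seg$label) else as.character(seg$state)
}

#' Per-state segment counts, mean lengths and genome fractions
#'
#' @param seg A segmentation `GRanges` from [hmm_decode()].
#' @return A data.frame with one row per state (`state`, `n_segments`,
#'   `mean_length`, `genome_fraction`) plus an attribute
#'   `functional_fraction` — the genome fraction covered by all states
#'   except quiescent (`Qui`).
#' @export
state_summary <- function(seg) {
  lab <- seg_labels(seg)
  w <- GenomicRanges::width(seg)
  total <- sum(as.numeric(w))
  states <- sort(unique(lab))
  df <- data.frame(
    state = states,
    n_segments = as.integer(tapply(w, lab, length)[states]),
    mean_length = as.numeric(tapply(w, lab, mean)[states]),
    genome_fraction = as.numeric(tapply(as.numeric(w), lab, sum)[states]) / total,
    row.names = NULL
  )
  attr(df, "functional_fraction") <-
    sum(df$genome_fraction[df$state != "Qui"])
  df
}

#' Mean CpG methylation per chromatin state
#'
#' Unweighted mean of per-CpG methylation fractions over each state's
#' territory; states containing no CpG report `NA`.
#'
#' @param seg Segmentation `GRanges`.
#' @param methylation data.frame with columns `chrom`, `pos` (1-based CpG
#'   position) and `frac` in `[0, 1]`.
#' @return Named numeric vector, one mean per state present in `seg`.
#' @export
methylation_by_state <- function(seg, methylation) {
  if (any(methylation$frac < 0 | methylation$frac > 1))
    stop2("methylation fractions must lie in [0, 1]")
  cpg <- GenomicRanges::GRanges(methylation$chrom,
                                IRanges::IRanges(methylation$pos, width = 1L))
  hit <- GenomicRanges::findOverlaps(cpg, seg)
  lab <- seg_labels(seg)
  states <- sort(unique(lab))
  out <- setNames(rep(NA_real_, length(states)), states)
  if (length(hit)) {
    m <- tapply(methylation$frac[S4Vectors::queryHits(hit)],
                lab[S4Vectors::subjectHits(hit)], mean)
    out[names(m)] <- as.numeric(m)
  }
  out
}

# per-bin state label vectors reconstructed from a segmentation
seg_bin_vectors <- function(seg) {
  bs <- S4Vectors::metadata(seg)$bin_size
  if (is.null(bs)) stop2("segmentation lacks bin_size metadata")
  lab <- seg_labels(seg)
  chroms <- unique(as.character(GenomicRanges::seqnames(seg)))
  v <- lapply(chroms, function(cc) {
    i <- as.character(GenomicRanges::seqnames(seg)) == cc
    rep(lab[i], GenomicRanges::width(seg)[i] / bs)
  })
  names(v) <- chroms
  list(bins = v, bin_size = bs)
}

#' Positional state enrichment around transcription start sites
#'
#' For every state and offset bin in `+/- flank` around the TSS set,
#' reports the state frequency at that offset divided by its genome-wide
#' frequency (1 = no enrichment). Minus-strand TSSs are orientation-
#' flipped.
#'
#' @param seg Segmentation `GRanges` (with `bin_size` metadata).
#' @param tss data.frame with columns `chrom`, `pos`, `strand`.
#' @param flank Flank in bp; must be a multiple of the bin size.
#' @return Matrix `states x offsets`; column names are bp offsets.
#' @export
tss_state_enrichment <- function(seg, tss, flank = 2000) {
  sb <- seg_bin_vectors(seg)
  bs <- sb$bin_size
  if (flank %% bs != 0) stop2("`flank` must be a multiple of the bin size")
  nf <- flank %/% bs
  offsets <- (-nf):nf
  all_bins <- unlist(sb$bins, use.names = FALSE)
  states <- sort(unique(all_bins))
  genome_freq <- table(factor(all_bins, levels = states)) / length(all_bins)
  counts <- matrix(0, length(states), length(offsets),
                   dimnames = list(states, offsets * bs))
  totals <- numeric(length(offsets))
  for (i in seq_len(nrow(tss))) {
    v <- sb$bins[[tss$chrom[i]]]
    if (is.null(v)) next
    b0 <- bin_index(tss$pos[i], bs)
    off <- if (identical(tss$strand[i], "-")) -offsets else offsets
    idx <- b0 + off
    ok <- idx >= 1 & idx <= length(v)
    st <- v[idx[ok]]
    j <- which(ok)
    for (kk in seq_along(j)) {
      counts[st[kk], j[kk]] <- counts[st[kk], j[kk]] + 1
    }
    totals[j] <- totals[j] + 1
  }
  freq <- sweep(counts, 2, pmax(totals, 1), "/")
  sweep(freq, 1, as.numeric(genome_freq), "/")
}

state_bp_in <- function(seg, territory, states) {
  hit <- GenomicRanges::findOverlaps(seg, territory)
  out <- setNames(numeric(length(states)), states)
  if (!length(hit)) return(out)
  ov <- GenomicRanges::pintersect(
    seg[S4Vectors::queryHits(hit)], territory[S4Vectors::subjectHits(hit)])
  lab <- seg_labels(seg)[S4Vectors::queryHits(hit)]
  s <- tapply(as.numeric(GenomicRanges::width(ov)), lab, sum)
  out[names(s)] <- as.numeric(s)
  out
}

#' Chromatin-state enrichment in DEG territory
#'
#' Fold enrichment of each state inside a territory (differentially
#' expressed gene bodies plus flanks): the fraction of territory bp in
#' the state divided by the state's genome-wide bp fraction. An empirical
#' p-value comes from random placements of the territory segments,
#' length- and chromosome-matched.
#'
#' @param seg Segmentation `GRanges`.
#' @param deg_regions `GRanges` of DEG territory (e.g. gene bodies
#'   `+/- 2` kb); reduced internally.
#' @param n_perm Number of random placements.
#' @param seed Seed for the placements.
#' @return data.frame with `state`, `fold`, `p` (empirical upper-tail,
#'   `(1 + #{perm >= obs}) / (n_perm + 1)`).
#' @export
deg_state_enrichment <- function(seg, deg_regions, n_perm = 1000, seed = 1) {
  if (!length(deg_regions)) stop2("empty DEG region set")
  territory <- merge_intervals(deg_regions)
  lab <- seg_labels(seg)
  states <- sort(unique(lab))
  genome_bp <- tapply(as.numeric(GenomicRanges::width(seg)), lab, sum)[states]
  genome_total <- sum(as.numeric(GenomicRanges::width(seg)))
  terr_bp <- sum(as.numeric(GenomicRanges::width(territory)))
  fold_of <- function(terr) {
    inb <- state_bp_in(seg, terr, states)
    tb <- sum(as.numeric(GenomicRanges::width(terr)))
    (inb / tb) / (as.numeric(genome_bp) / genome_total)
  }
  obs <- fold_of(territory)
  chrom_len <- tapply(GenomicRanges::end(seg),
                      as.character(GenomicRanges::seqnames(seg)), max)
  tchr <- as.character(GenomicRanges::seqnames(territory))
  tw <- GenomicRanges::width(territory)
  exceed <- setNames(numeric(length(states)), states)
  with_stage_seed(seed, "deg_enrichment_perm", {
    for (b in seq_len(n_perm)) {
      ns <- vapply(seq_along(tw), function(i) {
        max_start <- chrom_len[[tchr[i]]] - tw[i] + 1L
        sample.int(max(max_start, 1L), 1L)
      }, 0L)
      placed <- GenomicRanges::GRanges(tchr, IRanges::IRanges(ns, width = tw))
      pf <- fold_of(placed)
      exceed <- exceed + as.numeric(pf >= obs)
    }
  })
  data.frame(state = states, fold = as.numeric(obs),
             p = (1 + exceed) / (n_perm + 1), row.names = NULL)
}

#' Mean signal of a track over a set of intervals
#'
#' @param track A `signal_track`.
#' @param gr Intervals.
#' @return Numeric vector, the mean per-bin signal over each interval.
#' @export
mean_signal_over <- function(track, gr) {
  bs <- track$bin_size
  vapply(seq_along(gr), function(i) {
    v <- track$values[[as.character(GenomicRanges::seqnames(gr[i]))]]
    if (is.null(v)) return(NA_real_)
    from <- bin_index(GenomicRanges::start(gr[i]), bs)
    to <- min(bin_index(GenomicRanges::end(gr[i]), bs), length(v))
    mean(v[from:to])
  }, 0)
}

#' Correlate enhancer signal with gene expression
#'
#' Pearson correlation (with least-squares line) between per-gene
#' enhancer H3K27ac signal and expression, both log2(x + 1) transformed
#' by default.
#'
#' @param signal Numeric vector of per-gene enhancer signal (RPKM-like).
#' @param expr Numeric vector of matching expression values (TPM).
#' @param log2p1 Apply `log2(x + 1)` to both vectors first.
#' @return List with `r`, `p`, `slope`, `intercept`, `n`; all `NA` if
#'   fewer than 4 complete pairs or a constant vector.
#' @export
enhancer_expression_correlation <- function(signal, expr, log2p1 = TRUE) {
  ok <- is.finite(signal) & is.finite(expr)
  x <- signal[ok]; y <- expr[ok]
  if (log2p1) { x <- log2(x + 1); y <- log2(y + 1) }
  if (length(x) < 4 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(x)))
  ct <- cor.test(x, y)
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}

#' @importFrom stats coef
NULL
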