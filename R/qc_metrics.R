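# ENCODE-style library quality metrics and cross-assay consistency.
# "Reads" are abstracted as single genomic coordinates (5' ends).

#' Library complexity metrics (NRF, PBC1, PBC2)
#'
#' NRF = distinct positions / total reads; PBC1 = positions seen exactly
#' once / distinct positions; PBC2 = positions seen exactly once /
#' positions seen exactly twice. When no position is seen twice, PBC2 is
#' `Inf` and flagged rather than raised as an error (the convention of
#' ENCODE QC tables). Invariant to input order.
#'
#' @param positions data.frame with columns `chrom` and `pos`.
#' @return List of class `library_qc`: `nrf`, `pbc1`, `pbc2`,
#'   `pbc2_finite` (flag), `n_reads`, `n_distinct`.
#' @export
complexity_metrics <- function(positions) {
  if (is.null(positions) || nrow(positions) == 0L)
    stop2("complexity metrics require a non-empty read set")
  counts <- table(paste(positions$chrom, positions$pos))
  n <- nrow(positions)
  d <- length(counts)
  one <- sum(counts == 1L)
  two <- sum(counts == 2L)
  structure(list(
    nrf = d / n,
    pbc1 = one / d,
    pbc2 = if (two == 0L) Inf else one / two,
    pbc2_finite = two > 0L,
    n_reads = n, n_distinct = d
  ), class = "library_qc")
}

#' @export
print.library_qc <- function(x, ...) {
  cat(sprintf("library_qc: NRF %.3f  PBC1 %.3f  PBC2 %s  (%d reads)\n",
              x$nrf, x$pbc1,
              if (is.finite(x$pbc2)) sprintf("%.2f", x$pbc2) else "Inf",
              x$n_reads))
  invisible(x)
}

#' Fraction of reads in peaks (FRiP)
#'
#' @param positions data.frame with columns `chrom` and `pos` (1-based).
#' @param peaks A `GRanges` of peak intervals.
#' @return Fraction in `[0, 1]` of positions inside any peak.
#' @export
frip <- function(positions, peaks) {
  if (nrow(positions) == 0L) return(NA_real_)
  pts <- GenomicRanges::GRanges(positions$chrom,
                                IRanges::IRanges(positions$pos, width = 1L))
  mean(GenomicRanges::countOverlaps(pts, peaks) > 0)
}

#' Pairwise Pearson correlation of signal tracks on a common bin grid
#'
#' Tracks are rebinned to `bin_size` by summing (their native bin size
#' must divide it), concatenated across chromosomes, and correlated.
#' Zero-variance tracks yield `NA` rows/columns, not zero.
#'
#' @param tracks Named list of `signal_track`s on the same genome.
#' @param bin_size Correlation bin width in bp (default 500).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
binned_correlation <- function(tracks, bin_size = 500) {
  if (length(tracks) < 2) stop2("need at least two tracks")
  rebin <- function(tr) {
    if (bin_size %% tr$bin_size != 0)
      stop2("track bin size must divide the correlation bin size")
    k <- bin_size %/% tr$bin_size
    unlist(lapply(tr$values, function(v) {
      n <- ceiling(length(v) / k)
      as.numeric(rowsum(v, rep(seq_len(n), each = k, length.out = length(v))))
    }), use.names = FALSE)
  }
  m <- vapply(tracks, rebin, numeric(length(rebin(tracks[[1]]))))
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  r
}

#' Average signal profile around a set of anchor positions
#'
#' Extracts the signal in `+/- flank` around each anchor (minus-strand
#' anchors orientation-flipped) and averages position-wise. Windows
#' truncated by chromosome ends contribute only their covered offsets
#' (coverage-weighted mean).
#'
#' @param track A `signal_track`.
#' @param anchors data.frame with columns `chrom`, `pos` and optionally
#'   `strand`.
#' @param flank Flank in bp; must be a multiple of the track bin size.
#' @return Numeric vector of length `2 * flank / bin_size + 1`, named by
#'   bp offset.
#' @export
meta_profile <- function(track, anchors, flank) {
  bs <- track$bin_size
  if (flank %% bs != 0) stop2("`flank` must be a multiple of the bin size")
  nf <- flank %/% bs
  offsets <- (-nf):nf
  acc <- numeric(length(offsets))
  cov <- numeric(length(offsets))
  strand <- if ("strand" %in% names(anchors)) anchors$strand else "+"
  strand <- rep_len(strand, nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    if (is.null(v)) next
    b0 <- bin_index(anchors$pos[i], bs)
    off <- if (identical(strand[i], "-")) -offsets else offsets
    idx <- b0 + off
    ok <- idx >= 1 & idx <= length(v)
    acc[ok] <- acc[ok] + v[idx[ok]]
    cov[ok] <- cov[ok] + 1
  }
  setNames(acc / pmax(cov, 1), offsets * bs)
}
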