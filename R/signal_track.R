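# Binned continuous signal (RPKM-like) per chromosome.

#' Construct a binned signal track
#'
#' A signal track stores one nonnegative value per fixed-width bin for
#' each chromosome, the in-memory stand-in for a bedGraph/bigwig coverage
#' track.
#'
#' @param values Named list, one numeric vector per chromosome.
#' @param bin_size Bin width in bp.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size) {
  check_number(bin_size, "bin_size", min = 1)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop2("`values` must be a named list (one vector per chromosome)")
  for (v in values) {
    if (any(!is.finite(v)) || any(v < 0))
      stop2("signal values must be finite and >= 0")
  }
  structure(list(values = lapply(values, as.numeric),
                 bin_size = as.integer(bin_size)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin %d bp, %d bins total\n",
              length(x$values), x$bin_size, sum(lengths(x$values))))
  invisible(x)
}

#' Chromosome lengths implied by a signal track
#' @param track A `signal_track`.
#' @return Named integer vector of lengths in bp.
#' @export
track_chrom_lengths <- function(track) {
  vapply(track$values, length, 0L) * track$bin_size
}

#' Read / write a signal track as bedGraph
#'
#' bedGraph lines are 0-based half-open; bins must align to the given
#' `bin_size` grid. Bins absent from the file are zero.
#'
#' @param path File path.
#' @param bin_size Bin width in bp of the track being read.
#' @param chrom_lengths Optional named vector fixing chromosome lengths
#'   (otherwise the last covered bin per chromosome defines the length).
#' @return `read_bedgraph`: a `signal_track`.
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths = NULL) {
  p <- read_tab_lines(path, 4L, "bedGraph")
  if (p$n == 0L) return(signal_track(list(), bin_size))
  ln <- seq_len(p$n)
  chrom <- vapply(p$fields, `[[`, "", 1L)
  start <- parse_coord(vapply(p$fields, `[[`, "", 2L), ln, "bedGraph")
  end <- parse_coord(vapply(p$fields, `[[`, "", 3L), ln, "bedGraph")
  val <- suppressWarnings(as.numeric(vapply(p$fields, `[[`, "", 4L)))
  if (anyNA(val))
    stop2(sprintf("bedGraph parse error at line %d: non-numeric value",
                  which(is.na(val))[1]))
  bad <- which(start %% bin_size != 0 | (end - start) != bin_size)
  if (length(bad))
    stop2(sprintf("bedGraph parse error at line %d: interval not on the %d-bp bin grid",
                  bad[1], bin_size))
  chroms <- unique(chrom)
  lens <- if (is.null(chrom_lengths))
    vapply(chroms, function(cc) max(end[chrom == cc]), 0) else
      chrom_lengths[chroms]
  vals <- lapply(chroms, function(cc) {
    v <- numeric(ceiling(lens[[cc]] / bin_size))
    i <- chrom == cc
    v[start[i] / bin_size + 1] <- val[i]
    v
  })
  names(vals) <- chroms
  signal_track(vals, bin_size)
}

#' @rdname read_bedgraph
#' @param track A `signal_track`.
#' @param keep_zero Write zero bins too (default drops them, the common
#'   bedGraph convention).
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (cc in names(track$values)) {
    v <- track$values[[cc]]
    idx <- if (keep_zero) seq_along(v) else which(v != 0)
    if (!length(idx)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", cc, (idx - 1L) * bs, idx * bs,
                       v[idx]), con)
  }
  invisible(path)
}

#' Binned binary mark matrix for one sample
#'
#' Per chromosome, a bins x 5 matrix of 0/1 presence calls for the five
#' marks in [mark_names()] order — the input representation for
#' chromatin-state segmentation.
#'
#' @param bins Named list, one `bins x 5` 0/1 matrix per chromosome.
#' @param bin_size Bin width in bp.
#' @param sample_id Sample label (breed + replicate).
#' @return An object of class `mark_matrix`.
#' @export
mark_matrix <- function(bins, bin_size, sample_id = "sample") {
  check_number(bin_size, "bin_size", min = 1)
  marks <- mark_names()
  bins <- lapply(bins, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != length(marks))
      stop2("each chromosome matrix must have 5 mark columns")
    if (!all(m %in% c(0, 1))) stop2("mark matrix entries must be 0/1")
    colnames(m) <- marks
    storage.mode(m) <- "integer"
    m
  })
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 marks = marks, sample_id = sample_id),
            class = "mark_matrix")
}

#' @export
print.mark_matrix <- function(x, ...) {
  cat(sprintf("mark_matrix '%s': %d chromosome(s), bin %d bp, %d bins\n",
              x$sample_id, length(x$bins), x$bin_size,
              sum(vapply(x$bins, nrow, 0L))))
  invisible(x)
}
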