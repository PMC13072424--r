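# Known-motif scanning over enhancer sequences: log-odds PWM scan
# against a 0-order background, with Fisher-exact enrichment of
# foreground vs background regions.

DNA <- c("A", "C", "G", "T")

#' Generate a random genome sequence
#'
#' I.i.d. uniform ACGT per chromosome, for motif analyses on synthetic
#' data.
#'
#' @param chrom_lengths Named vector of lengths in bp.
#' @param seed Seed.
#' @return Named character vector of sequences.
#' @export
simulate_genome_sequence <- function(chrom_lengths, seed = 1) {
  with_stage_seed(seed, "genome_sequence", {
    vapply(chrom_lengths, function(L)
      paste(sample(DNA, L, replace = TRUE), collapse = ""), "")
  })
}

#' Extract interval sequences from a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gr `GRanges` of intervals (must lie within the sequences).
#' @return Character vector of sequences.
#' @export
extract_sequences <- function(genome, gr) {
  cc <- as.character(GenomicRanges::seqnames(gr))
  bad <- which(!(cc %in% names(genome)) |
                 GenomicRanges::end(gr) > nchar(genome[cc]))
  if (length(bad))
    stop2(sprintf("interval %d outside the genome sequence", bad[1]))
  substring(genome[cc], GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Maximum log-odds PWM score over a sequence (both strands)
#'
#' Scores every window of a sequence with `sum log2(p_base / bg_base)`
#' under the PWM, on the forward and reverse-complement strands, and
#' returns the maximum.
#'
#' @param seq A DNA string.
#' @param pwm 4 x L probability matrix with rownames A, C, G, T.
#' @param bg Background base probabilities (0-order model).
#' @return Maximum window score (`-Inf` if the sequence is shorter than
#'   the motif).
#' @export
pwm_max_score <- function(seq, pwm, bg = rep(0.25, 4)) {
  if (any(colSums(pwm) <= 0)) stop2("PWM columns must have positive sums")
  w <- log2(pmax(pwm, 1e-6) / bg)
  L <- ncol(w)
  x <- match(strsplit(toupper(seq), "")[[1]], DNA)
  n <- length(x)
  if (n < L) return(-Inf)
  best <- -Inf
  xr <- rev(5L - x)  # reverse complement (A<->T, C<->G), NA-safe
  for (strand_x in list(x, xr)) {
    for (s in seq_len(n - L + 1)) {
      idx <- strand_x[s:(s + L - 1)]
      if (anyNA(idx)) next
      sc <- sum(w[cbind(idx, seq_len(L))])
      if (sc > best) best <- sc
    }
  }
  best
}

#' Best achievable score of a PWM
#' @param pwm 4 x L probability matrix.
#' @param bg Background base probabilities.
#' @return Sum over positions of the best per-position log-odds.
#' @export
pwm_top_score <- function(pwm, bg = rep(0.25, 4)) {
  sum(apply(log2(pmax(pwm, 1e-6) / bg), 2, max))
}

#' Motif hit calls over a set of sequences
#'
#' A sequence is a hit iff its best window score reaches `frac` of the
#' PWM's maximum achievable score.
#'
#' @param seqs Character vector of sequences.
#' @param pwm 4 x L probability matrix.
#' @param frac Score fraction threshold (default 0.8).
#' @param bg Background base probabilities.
#' @return Logical vector.
#' @export
motif_hits <- function(seqs, pwm, frac = 0.8, bg = rep(0.25, 4)) {
  cut <- frac * pwm_top_score(pwm, bg)
  vapply(seqs, function(s) pwm_max_score(s, pwm, bg) >= cut, TRUE,
         USE.NAMES = FALSE)
}

#' Shuffle intervals within chromosomes avoiding a region set
#'
#' Places each interval uniformly at random on its own chromosome,
#' rejecting positions overlapping `avoid` — the background generator
#' for motif enrichment.
#'
#' @param gr Intervals to re-place.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param avoid `GRanges` to avoid (default `gr` itself).
#' @param seed Seed.
#' @param max_tries Rejection-sampling cap per interval.
#' @return A `GRanges` of the same widths.
#' @export
shuffle_intervals <- function(gr, chrom_lengths, avoid = gr, seed = 1,
                              max_tries = 1000) {
  with_stage_seed(seed, "shuffle_intervals", {
    cc <- as.character(GenomicRanges::seqnames(gr))
    w <- GenomicRanges::width(gr)
    starts <- integer(length(gr))
    for (i in seq_along(gr)) {
      for (try in seq_len(max_tries)) {
        s <- sample.int(chrom_lengths[[cc[i]]] - w[i] + 1L, 1L)
        cand <- GenomicRanges::GRanges(cc[i], IRanges::IRanges(s, width = w[i]))
        if (!length(GenomicRanges::findOverlaps(cand, avoid))) break
      }
      starts[i] <- s
    }
    GenomicRanges::GRanges(cc, IRanges::IRanges(starts, width = w))
  })
}

#' Known-motif enrichment in foreground vs background regions
#'
#' For each PWM, counts foreground and background regions carrying at
#' least one hit and tests the 2 x 2 table by Fisher's exact test.
#'
#' @param foreground,background `GRanges` region sets.
#' @param genome Named character vector of chromosome sequences.
#' @param pwms Named list of 4 x L probability matrices.
#' @param frac Score fraction threshold for a hit.
#' @return data.frame with `motif_id`, `fg_hits`, `fg_n`, `bg_hits`,
#'   `bg_n`, `odds_ratio`, `p`.
#' @export
known_motif_enrichment <- function(foreground, background, genome, pwms,
                                   frac = 0.8) {
  fg_seq <- extract_sequences(genome, foreground)
  bg_seq <- extract_sequences(genome, background)
  rows <- lapply(names(pwms), function(id) {
    fh <- sum(motif_hits(fg_seq, pwms[[id]], frac))
    bh <- sum(motif_hits(bg_seq, pwms[[id]], frac))
    tab <- matrix(c(fh, length(fg_seq) - fh, bh, length(bg_seq) - bh), 2)
    ft <- fisher.test(tab)
    data.frame(motif_id = id, fg_hits = fh, fg_n = length(fg_seq),
               bg_hits = bh, bg_n = length(bg_seq),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  do.call(rbind, rows)
}

#' Read / write PWMs in a simple text format
#'
#' Each motif is a `>id` header line followed by four tab-separated rows
#' (A, C, G, T) of per-position probabilities.
#'
#' @param path File path.
#' @return `read_pwms`: named list of 4 x L matrices.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop2("no motifs found")
  out <- list()
  for (i in seq_along(heads)) {
    id <- sub("^>", "", lines[heads[i]])
    rows <- lines[(heads[i] + 1):(heads[i] + 4)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(r, "\t", fixed = TRUE)[[1]])))
    rownames(m) <- DNA
    out[[id]] <- m
  }
  out
}

#' @rdname read_pwms
#' @param pwms Named list of PWMs.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    writeLines(paste0(">", id), con)
    for (r in 1:4)
      writeLines(paste(pwms[[id]][r, ], collapse = "\t"), con)
  }
  invisible(path)
}
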