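# Breed-specific regulatory element (BSR) identification: consensus
# active-enhancer set, replicate binary scoring, breed classification,
# and signal profiles over the classified regions.

#' Extract merged EnhA segments from a segmentation
#'
#' @param seg Segmentation `GRanges` with a `label` column.
#' @param label State label to extract (default `"EnhA"`).
#' @return Merged `GRanges` of the state's territory.
#' @export
extract_state <- function(seg, label = "EnhA") {
  if (is.null(seg$label)) stop2("segmentation is unlabeled; run label_states()")
  merge_intervals(seg[seg$label == label])
}

#' Build the consensus enhancer set with replicate binary scores
#'
#' Unions the four replicate EnhA segment lists into a non-redundant
#' consensus; each consensus region is scored 1 against a replicate iff
#' that replicate's EnhA overlaps it by at least `min_bp` bp, and
#' classified from the score pattern: breed-specific requires score 1 in
#' both replicates of one breed and 0 in both of the other; `shared`
#' requires 1 in all four replicates (strict mode; `shared_relaxed =
#' TRUE` instead requires at least one replicate of each breed); any
#' other pattern is `other`.
#'
#' @param enh_by_rep Named list of four `GRanges` (replicate EnhA
#'   segments), names like `HU_1, HU_2, SH_1, SH_2`.
#' @param breeds Breed of each replicate (parsed from names by default).
#' @param min_bp Minimum overlap for a score of 1.
#' @param shared_relaxed Use the relaxed shared definition.
#' @return A `GRanges` of consensus regions with a `score_<rep>` column
#'   per replicate and a `class` column in
#'   `{HU_specific, SH_specific, shared, other}`.
#' @export
build_consensus <- function(enh_by_rep, breeds = NULL, min_bp = 1,
                            shared_relaxed = FALSE) {
  if (length(enh_by_rep) != 4)
    stop2("expected exactly 4 replicate EnhA lists (2 per breed)")
  if (is.null(breeds)) breeds <- sub("_.*", "", names(enh_by_rep))
  if (!setequal(unique(breeds), c("HU", "SH")) ||
      any(table(breeds) != 2))
    stop2("replicates must be two per breed (HU, SH)")
  consensus <- merge_intervals(do.call(c, unname(enh_by_rep)))
  scores <- vapply(enh_by_rep, function(gr)
    as.integer(GenomicRanges::countOverlaps(consensus, gr,
                                            minoverlap = min_bp) > 0),
    integer(length(consensus)))
  if (length(consensus) == 1L) scores <- matrix(scores, nrow = 1)
  hu <- scores[, breeds == "HU", drop = FALSE]
  sh <- scores[, breeds == "SH", drop = FALSE]
  hu_all <- rowSums(hu) == 2L; hu_none <- rowSums(hu) == 0L
  sh_all <- rowSums(sh) == 2L; sh_none <- rowSums(sh) == 0L
  cls <- rep("other", length(consensus))
  cls[hu_all & sh_none] <- "HU_specific"
  cls[sh_all & hu_none] <- "SH_specific"
  if (shared_relaxed) {
    cls[rowSums(hu) >= 1L & rowSums(sh) >= 1L] <- "shared"
  } else {
    cls[hu_all & sh_all] <- "shared"
  }
  for (j in seq_along(enh_by_rep))
    S4Vectors::mcols(consensus)[[paste0("score_", names(enh_by_rep)[j])]] <-
      scores[, j]
  consensus$class <- cls
  consensus
}

#' Partition a scored consensus set by breed class
#'
#' @param consensus Output of [build_consensus()].
#' @return List with `regions` (named list of `GRanges` per class) and
#'   `counts` (named integer vector over the four classes).
#' @export
classify_bsr <- function(consensus) {
  classes <- c("HU_specific", "SH_specific", "shared", "other")
  regions <- lapply(classes, function(cl) consensus[consensus$class == cl])
  names(regions) <- classes
  counts <- vapply(regions, length, 0L)
  list(regions = regions, counts = counts)
}

#' Jaccard similarity of two interval sets (bp scale)
#'
#' @param a,b `GRanges`.
#' @return `width(intersect) / width(union)`.
#' @export
interval_jaccard <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  inter <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE))))
  uni <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(a, b, ignore.strand = TRUE))))
  if (uni == 0) return(NA_real_)
  inter / uni
}

#' H3K27ac signal profile over classified enhancer regions
#'
#' Rescales each region to a fixed number of interior bins, adds
#' `+/- flank` flanking bins, and averages the per-breed signal across
#' regions.
#'
#' @param regions `GRanges` of one enhancer class.
#' @param tracks_by_breed Named list (`HU`, `SH`) of H3K27ac
#'   `signal_track`s.
#' @param flank Flank in bp (default 3000).
#' @param n_interior Interior bins after rescaling (default 20).
#' @return List with `curves` (breed x position matrix of mean signal)
#'   and `heat` (per-breed list of region x position matrices).
#' @export
bsr_signal_profile <- function(regions, tracks_by_breed, flank = 3000,
                               n_interior = 20) {
  if (!length(regions)) stop2("no regions to profile")
  profiles <- lapply(tracks_by_breed, function(track) {
    bs <- track$bin_size
    nf <- flank %/% bs
    t(vapply(seq_along(regions), function(i) {
      cc <- as.character(GenomicRanges::seqnames(regions[i]))
      v <- track$values[[cc]]
      from <- bin_index(GenomicRanges::start(regions[i]), bs)
      to <- min(bin_index(GenomicRanges::end(regions[i]), bs), length(v))
      interior <- v[from:to]
      scaled <- interior[pmin(pmax(round(seq(1, length(interior),
                                             length.out = n_interior)), 1),
                              length(interior))]
      left <- v[pmax(from - nf, 1):max(from - 1, 1)]
      left <- c(rep(NA_real_, nf - length(left)), left)
      if (from == 1) left <- rep(NA_real_, nf)
      right_idx <- (to + 1):(to + nf)
      right <- ifelse(right_idx <= length(v), v[pmin(right_idx, length(v))],
                      NA_real_)
      c(left, scaled, right)
    }, numeric(2 * (flank %/% tracks_by_breed[[1]]$bin_size) + n_interior)))
  })
  curves <- t(vapply(profiles, function(m) colMeans(m, na.rm = TRUE),
                     numeric(ncol(profiles[[1]]))))
  rownames(curves) <- names(tracks_by_breed)
  list(curves = curves, heat = profiles)
}
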