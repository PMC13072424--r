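# Interval construction, interval algebra, and plain-text genomic formats.
#
# Internally every interval lives in a GRanges (1-based, closed — the
# Bioconductor convention). BED-family files (0-based, half-open) are
# converted at the boundary; GFF shares the internal convention.

#' Build a GRanges from BED-style (0-based half-open) coordinates
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start 0-based inclusive start positions (`>= 0`).
#' @param end Exclusive end positions (`> start`).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled). `"."` maps
#'   to the unstranded `"*"`.
#' @param score Optional numeric score vector.
#' @param name Optional feature names.
#' @return A `GRanges` with the same genomic extent in 1-based closed
#'   coordinates.
#' @examples
#' bed_ranges("chr1", 0, 100)   # spans bases 1..100 internally
#' @export
bed_ranges <- function(chrom, start, end, strand = ".", score = NULL,
                       name = NULL) {
  if (length(chrom) == 0L)
    return(GenomicRanges::GRanges())
  if (any(!nzchar(chrom))) stop2("chromosome names must be non-empty")
  if (any(start < 0)) stop2("start coordinates must be >= 0")
  if (any(end <= start)) stop2("intervals must satisfy end > start")
  strand <- rep_len(ifelse(strand == ".", "*", strand), length(chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  if (!is.null(score)) gr$score <- score
  if (!is.null(name)) gr$name <- name
  gr
}

#' Merge overlapping or near-adjacent intervals
#'
#' Unions all intervals that overlap or lie within `gap` bp of each other.
#' With the default `gap = 0`, book-ended intervals (touching in BED
#' coordinates) are merged. Strand is ignored.
#'
#' @param gr A `GRanges` (may be unsorted).
#' @param gap Maximum separation in bp for two intervals to be unioned.
#' @return A sorted, pairwise non-overlapping `GRanges`.
#' @export
merge_intervals <- function(gr, gap = 0) {
  check_number(gap, "gap", min = 0)
  GenomicRanges::reduce(gr, min.gapwidth = gap + 1L, ignore.strand = TRUE)
}

#' Pairwise interval overlap test
#'
#' Tests element-wise whether intervals of `a` and `b` share at least
#' `min_bp` bases on the same chromosome. `a` and `b` are recycled to a
#' common length, so a single interval can be tested against many.
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @param min_bp Minimum overlap in bp (`>= 1`).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b, min_bp = 1) {
  check_number(min_bp, "min_bp", min = 1)
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  same & ov >= min_bp
}

# ---- line-oriented parsing helpers -----------------------------------------

read_tab_lines <- function(path, min_fields, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(list(fields = list(), n = 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad))
    stop2(sprintf("%s parse error at line %d: expected >= %d tab-separated fields, found %d",
                  what, bad[1], min_fields, nf[bad[1]]))
  list(fields = fields, n = length(lines))
}

parse_coord <- function(x, line, what, allow_zero = TRUE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v < if (allow_zero) 0 else 1)
  if (length(bad))
    stop2(sprintf("%s parse error at line %d: invalid or negative coordinate '%s'",
                  what, line[bad[1]], x[bad[1]]))
  v
}

# ---- BED --------------------------------------------------------------------

#' Read a BED (3/5/6 column) file
#'
#' Coordinates are 0-based half-open on disk and converted to the internal
#' 1-based closed representation. Malformed lines and negative coordinates
#' raise an error naming the offending line.
#'
#' @param path File path.
#' @return A `GRanges`; columns 4-6, when present, populate `name`,
#'   `score` and strand.
#' @export
read_bed <- function(path) {
  p <- read_tab_lines(path, 3L, "BED")
  if (p$n == 0L) return(GenomicRanges::GRanges())
  ln <- seq_len(p$n)
  chrom <- vapply(p$fields, `[[`, "", 1L)
  start <- parse_coord(vapply(p$fields, `[[`, "", 2L), ln, "BED")
  end <- parse_coord(vapply(p$fields, `[[`, "", 3L), ln, "BED")
  bad <- which(end <= start)
  if (length(bad))
    stop2(sprintf("BED parse error at line %d: end <= start", bad[1]))
  nf <- lengths(p$fields)
  nm <- if (all(nf >= 4L)) vapply(p$fields, `[[`, "", 4L) else NULL
  sc <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(vapply(p$fields, `[[`, "", 5L))) else NULL
  if (!is.null(sc) && anyNA(sc))
    stop2(sprintf("BED parse error at line %d: non-numeric score",
                  which(is.na(sc))[1]))
  st <- if (all(nf >= 6L)) vapply(p$fields, `[[`, "", 6L) else "."
  bed_ranges(chrom, start, end, strand = st, score = sc, name = nm)
}

#' Write a GRanges as BED
#'
#' Emits 3, 5 or 6 tab-separated columns (no header), 0-based half-open,
#' newline-terminated. Name/score/strand columns are written when present
#' (6-column output requires both).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param extra Optional character vector of mcols to append after the
#'   sixth column (e.g. a state label).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, extra = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  has_name <- "name" %in% names(S4Vectors::mcols(gr))
  has_score <- "score" %in% names(S4Vectors::mcols(gr))
  if (has_name || has_score || !is.null(extra)) {
    df$name <- if (has_name) gr$name else "."
    df$score <- if (has_score) gr$score else 0
    st <- as.character(GenomicRanges::strand(gr))
    df$strand <- ifelse(st == "*", ".", st)
  }
  for (e in extra) df[[e]] <- S4Vectors::mcols(gr)[[e]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- BEDPE (chromatin loops) -----------------------------------------------

#' Read chromatin loops from a BEDPE file
#'
#' Each line gives two anchors (six coordinate columns, 0-based
#' half-open). Anchors of one loop must lie on the same chromosome, be
#' ordered (first anchor before second), and not overlap.
#'
#' @param path File path.
#' @return A `S4Vectors::Pairs` of two `GRanges` (anchor A, anchor B).
#' @export
read_bedpe <- function(path) {
  p <- read_tab_lines(path, 6L, "BEDPE")
  if (p$n == 0L)
    return(S4Vectors::Pairs(GenomicRanges::GRanges(), GenomicRanges::GRanges()))
  ln <- seq_len(p$n)
  f <- function(i) vapply(p$fields, `[[`, "", i)
  a <- bed_ranges(f(1), parse_coord(f(2), ln, "BEDPE"),
                  parse_coord(f(3), ln, "BEDPE"))
  b <- bed_ranges(f(4), parse_coord(f(5), ln, "BEDPE"),
                  parse_coord(f(6), ln, "BEDPE"))
  loops <- S4Vectors::Pairs(a, b)
  validate_loops(loops)
  loops
}

#' Validate loop anchors
#'
#' Checks the loop invariants: anchors on the same chromosome, first
#' anchor strictly before the second, anchors non-overlapping.
#'
#' @param loops A `Pairs` of `GRanges`.
#' @return `loops`, invisibly; errors name the first offending loop.
#' @export
validate_loops <- function(loops) {
  a <- S4Vectors::first(loops); b <- S4Vectors::second(loops)
  bad <- which(as.character(GenomicRanges::seqnames(a)) !=
                 as.character(GenomicRanges::seqnames(b)))
  if (length(bad))
    stop2(sprintf("loop %d: anchors on different chromosomes", bad[1]))
  bad <- which(GenomicRanges::end(a) >= GenomicRanges::start(b))
  if (length(bad))
    stop2(sprintf("loop %d: anchors must be ordered and non-overlapping", bad[1]))
  invisible(loops)
}

#' Write loops as BEDPE
#' @param loops A `Pairs` of `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  a <- S4Vectors::first(loops); b <- S4Vectors::second(loops)
  df <- data.frame(
    as.character(GenomicRanges::seqnames(a)),
    GenomicRanges::start(a) - 1L, GenomicRanges::end(a),
    as.character(GenomicRanges::seqnames(b)),
    GenomicRanges::start(b) - 1L, GenomicRanges::end(b)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- gene annotation --------------------------------------------------------

#' Build a gene annotation GRanges
#'
#' @param chrom,start,end BED-style (0-based half-open) gene body
#'   coordinates.
#' @param strand `"+"` or `"-"`; determines the TSS end.
#' @param gene_id,gene_name Identifiers.
#' @param exon_length Exonic bp used for TPM length normalization
#'   (defaults to the gene body width).
#' @return A `GRanges` with mcols `gene_id`, `gene_name`, `tss` (1-based
#'   genomic position of the transcription start site) and `exon_length`.
#' @export
gene_annotation <- function(chrom, start, end, strand, gene_id,
                            gene_name = gene_id, exon_length = NULL) {
  gr <- bed_ranges(chrom, start, end, strand = strand)
  gr$gene_id <- gene_id
  gr$gene_name <- gene_name
  gr$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                   GenomicRanges::end(gr), GenomicRanges::start(gr))
  gr$exon_length <- exon_length %||% GenomicRanges::width(gr)
  if (any(gr$exon_length <= 0)) stop2("exon_length must be > 0")
  gr
}

#' Read the gene subset of a GFF3 file
#'
#' Keeps `gene` features. GFF coordinates are 1-based inclusive — the
#' internal convention — so no shift is applied. `ID` and `Name`
#' attributes populate `gene_id`/`gene_name`; an optional `exon_length`
#' attribute overrides the length used for TPM.
#'
#' @param path File path.
#' @return A gene annotation `GRanges` (see [gene_annotation()]).
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  ln_all <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(fields)) {
    bad <- which(nf < 9L)
    if (length(bad))
      stop2(sprintf("GFF parse error at line %d: expected 9 fields", ln_all[bad[1]]))
  }
  is_gene <- vapply(fields, function(f) f[[3]] == "gene", logical(1))
  fields <- fields[is_gene]; ln <- ln_all[is_gene]
  if (!length(fields))
    return(gene_annotation(character(), numeric(), numeric(),
                           character(), character()))
  f <- function(i) vapply(fields, `[[`, "", i)
  start1 <- parse_coord(f(4), ln, "GFF", allow_zero = FALSE)
  end1 <- parse_coord(f(5), ln, "GFF", allow_zero = FALSE)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    ifelse(lengths(m) > 0 | nzchar(m), sub(paste0(".*", key, "="), "", m), NA)
  }
  attrs <- f(9)
  ids <- vapply(attrs, function(a) {
    v <- attr_get(a, "ID"); if (length(v) && !is.na(v)) v else NA_character_
  }, "", USE.NAMES = FALSE)
  nms <- vapply(attrs, function(a) {
    v <- attr_get(a, "Name"); if (length(v) && !is.na(v)) v else NA_character_
  }, "", USE.NAMES = FALSE)
  exl <- vapply(attrs, function(a) {
    v <- attr_get(a, "exon_length")
    if (length(v) && !is.na(v)) as.numeric(v) else NA_real_
  }, 0, USE.NAMES = FALSE)
  nms[is.na(nms)] <- ids[is.na(nms)]
  gene_annotation(f(1), start1 - 1, end1, f(7), ids, nms,
                  exon_length = ifelse(is.na(exl), end1 - start1 + 1, exl))
}

#' Write a gene annotation as GFF3
#' @param genes Gene annotation `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  st <- as.character(GenomicRanges::strand(genes))
  lines <- sprintf(
    "%s\tchrombsr\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;exon_length=%d",
    as.character(GenomicRanges::seqnames(genes)),
    GenomicRanges::start(genes), GenomicRanges::end(genes),
    ifelse(st == "*", ".", st),
    genes$gene_id, genes$gene_name, as.integer(genes$exon_length)
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# ---- TSV matrices -----------------------------------------------------------

#' Read / write a numeric matrix as TSV (header row + rowname column)
#' @param path File path.
#' @return `read_tsv_matrix`: a numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_tsv_matrix
#' @param m Numeric matrix with dimnames.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
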