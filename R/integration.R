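# Enhancer-to-gene assignment (proximal priority rule and chromatin
# loops), intersection with DEGs including the coverage statistic, and
# the thresholded co-expression hub network.

#' Assign enhancers to proximal target genes
#'
#' Priority rule per enhancer: (1) overlap of a promoter window
#' (TSS -2000..+500, strand-aware) assigns that gene, category
#' `promoter`; (2) otherwise overlap of a gene body assigns that gene,
#' category `gene_body`; (3) otherwise the nearest TSS within `window`
#' bp, category `intergenic`. Ties (equidistant TSS, multiple
#' overlapping genes) break toward the lexicographically smaller
#' `gene_id`. Enhancers with no gene in reach yield an unassigned row.
#'
#' @param enhancers `GRanges`.
#' @param genes Gene annotation `GRanges` (see [gene_annotation()]).
#' @param window Maximum enhancer-TSS distance in bp (default 1e5).
#' @param promoter_up,promoter_down Promoter window extent upstream /
#'   downstream of the TSS in bp.
#' @return data.frame with `enh_idx`, `chrom`, `start`, `end` (BED
#'   coordinates), `gene_id` (`NA` if unassigned), `mode` = "proximal",
#'   `category`, `distance` (bp to the assigned TSS).
#' @export
proximal_targets <- function(enhancers, genes, window = 1e5,
                             promoter_up = 2000, promoter_down = 500) {
  st <- as.character(GenomicRanges::strand(genes))
  prom_start <- ifelse(st == "-", genes$tss - promoter_down,
                       genes$tss - promoter_up)
  prom_end <- ifelse(st == "-", genes$tss + promoter_up,
                     genes$tss + promoter_down)
  promoters <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(prom_start, 1), prom_end))
  pick <- function(cand_ids) cand_ids[order(cand_ids)][1]
  # enhancers on chromosomes without genes are legitimate input; silence
  # the benign disjoint-seqlevel warning
  ov <- function(...) suppressWarnings(GenomicRanges::findOverlaps(...))
  rows <- lapply(seq_along(enhancers), function(i) {
    e <- enhancers[i]
    gene_id <- NA_character_; category <- "intergenic"; dist <- NA_real_
    hit <- S4Vectors::subjectHits(ov(e, promoters))
    if (length(hit)) {
      gene_id <- pick(genes$gene_id[hit])
      category <- "promoter"
    } else {
      hit <- S4Vectors::subjectHits(ov(e, genes, ignore.strand = TRUE))
      if (length(hit)) {
        gene_id <- pick(genes$gene_id[hit])
        category <- "gene_body"
      } else {
        same <- which(as.character(GenomicRanges::seqnames(genes)) ==
                        as.character(GenomicRanges::seqnames(e)))
        if (length(same)) {
          d <- pmax(GenomicRanges::start(e) - genes$tss[same],
                    genes$tss[same] - GenomicRanges::end(e), 0)
          ok <- d <= window
          if (any(ok)) {
            dmin <- min(d[ok])
            gene_id <- pick(genes$gene_id[same[ok][d[ok] == dmin]])
            dist <- dmin
          }
        }
      }
    }
    if (category != "intergenic" || !is.na(gene_id)) {
      if (is.na(dist)) {
        g <- genes[match(gene_id, genes$gene_id)]
        dist <- max(GenomicRanges::start(e) - g$tss,
                    g$tss - GenomicRanges::end(e), 0)
      }
    }
    data.frame(enh_idx = i,
               chrom = as.character(GenomicRanges::seqnames(e)),
               start = GenomicRanges::start(e) - 1L,
               end = GenomicRanges::end(e),
               gene_id = gene_id, mode = "proximal", category = category,
               distance = dist, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign enhancers to loop-mediated target genes
#'
#' For each loop, an enhancer overlapping one anchor (>= 1 bp) is
#' assigned every gene whose TSS lies in the partner anchor (and vice
#' versa). An enhancer overlapping both anchors of a loop gains no
#' assignment from it (self-loops excluded). One enhancer may collect
#' multiple loop targets.
#'
#' @param enhancers `GRanges`.
#' @param loops `Pairs` of anchor `GRanges` (validated).
#' @param genes Gene annotation `GRanges`.
#' @return data.frame with `enh_idx`, coordinates, `gene_id`,
#'   `mode` = "loop", `loop_id`.
#' @export
loop_targets <- function(enhancers, loops, genes) {
  validate_loops(loops)
  a <- S4Vectors::first(loops); b <- S4Vectors::second(loops)
  tss <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(genes$tss, width = 1L))
  ov_ea <- GenomicRanges::findOverlaps(enhancers, a)
  ov_eb <- GenomicRanges::findOverlaps(enhancers, b)
  ov_ta <- GenomicRanges::findOverlaps(tss, a)
  ov_tb <- GenomicRanges::findOverlaps(tss, b)
  both <- intersect(
    paste(S4Vectors::queryHits(ov_ea), S4Vectors::subjectHits(ov_ea)),
    paste(S4Vectors::queryHits(ov_eb), S4Vectors::subjectHits(ov_eb)))
  collect <- function(ov_e, ov_t) {
    if (!length(ov_e) || !length(ov_t)) return(NULL)
    eh <- S4Vectors::queryHits(ov_e); el <- S4Vectors::subjectHits(ov_e)
    keep <- !(paste(eh, el) %in% both)
    eh <- eh[keep]; el <- el[keep]
    th <- S4Vectors::queryHits(ov_t); tl <- S4Vectors::subjectHits(ov_t)
    m <- merge(data.frame(enh_idx = eh, loop_id = el),
               data.frame(gene = th, loop_id = tl))
    if (!nrow(m)) return(NULL)
    m
  }
  m <- rbind(collect(ov_ea, ov_tb), collect(ov_eb, ov_ta))
  if (is.null(m) || !nrow(m))
    return(data.frame(enh_idx = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      gene_id = character(0), mode = character(0),
                      loop_id = integer(0), stringsAsFactors = FALSE))
  m <- unique(m)
  data.frame(
    enh_idx = m$enh_idx,
    chrom = as.character(GenomicRanges::seqnames(enhancers))[m$enh_idx],
    start = GenomicRanges::start(enhancers)[m$enh_idx] - 1L,
    end = GenomicRanges::end(enhancers)[m$enh_idx],
    gene_id = genes$gene_id[m$gene], mode = "loop", loop_id = m$loop_id,
    stringsAsFactors = FALSE)
}

#' Intersect enhancer target genes with upregulated DEGs
#'
#' Computes the proximal-overlap and loop-overlap gene sets, their
#' union, and the coverage statistic
#' `100 * |union & up| / |up considered|` (two decimals). Gene
#' identifiers beginning `LOC` can be excluded from the considered
#' denominator (`drop_loc`); both denominators are always reported.
#'
#' @param assignments data.frame combining [proximal_targets()] and
#'   [loop_targets()] rows.
#' @param deg A `deg_table` from [differential_expression()].
#' @param status DEG status defining "upregulated" (default `SH_up`).
#' @param drop_loc Exclude `LOC*` genes from the headline coverage.
#' @return List with `proximal_genes`, `loop_genes`, `union_genes`
#'   (each intersected with the up set), `n_up`, `n_up_non_loc`,
#'   `coverage_pct` (headline, per `drop_loc`), `coverage_pct_all`,
#'   `coverage_pct_non_loc`.
#' @export
integrate_with_degs <- function(assignments, deg, status = "SH_up",
                                drop_loc = FALSE) {
  if (!nrow(deg)) stop2("empty DEG table")
  up <- deg$gene_id[deg$status == status]
  if (!length(up)) stop2("no genes with status ", status)
  tgt <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  prox <- sort(unique(tgt$gene_id[tgt$mode == "proximal"]))
  loop <- sort(unique(tgt$gene_id[tgt$mode == "loop"]))
  uni <- sort(unique(c(prox, loop)))
  non_loc <- up[!startsWith(up, "LOC")]
  cov_all <- round(100 * length(intersect(uni, up)) / length(up), 2)
  cov_nl <- if (length(non_loc))
    round(100 * length(intersect(uni, non_loc)) / length(non_loc), 2)
  else NA_real_
  list(proximal_genes = intersect(prox, up),
       loop_genes = intersect(loop, up),
       union_genes = intersect(uni, up),
       n_up = length(up), n_up_non_loc = length(non_loc),
       coverage_pct = if (drop_loc) cov_nl else cov_all,
       coverage_pct_all = cov_all, coverage_pct_non_loc = cov_nl)
}

#' Correlate enhancer signal with target expression, split by mode
#'
#' For each assignment mode, Pearson correlation between per-pair
#' enhancer signal and target-gene expression (both log2(x + 1));
#' reports both so the proximal-vs-loop ordering can be compared.
#' Fewer than 4 pairs in a mode gives `NA`.
#'
#' @param assignments Combined assignment data.frame (with `mode`).
#' @param enh_signal Numeric vector of per-enhancer signal, indexed by
#'   `enh_idx`.
#' @param expr Named numeric vector of per-gene expression (TPM).
#' @return List of per-mode results (`r`, `p`, `n`).
#' @export
assignment_expression_correlation <- function(assignments, enh_signal, expr) {
  out <- list()
  for (mode in c("proximal", "loop")) {
    rows <- assignments[assignments$mode == mode &
                          !is.na(assignments$gene_id), , drop = FALSE]
    rows <- rows[rows$gene_id %in% names(expr), , drop = FALSE]
    if (nrow(rows) < 4) {
      out[[mode]] <- list(r = NA_real_, p = NA_real_, n = nrow(rows))
    } else {
      res <- enhancer_expression_correlation(
        enh_signal[rows$enh_idx], expr[rows$gene_id])
      out[[mode]] <- list(r = res$r, p = res$p, n = nrow(rows))
    }
  }
  out
}

#' Thresholded co-expression network over candidate genes
#'
#' All-pairs Pearson correlation on `log2(TPM + 1)` profiles; an
#' undirected edge is retained iff `r > r_min` and the two-sided p-value
#' is below `alpha`. Hubs are the top-`k_hubs` genes by degree.
#' Constant-profile genes are excluded with a warning.
#'
#' @param tpm_rows Genes x samples TPM matrix (rownames = gene ids).
#' @param r_min Correlation threshold (default 0.8; strict `>`).
#' @param alpha Significance threshold (default 0.05).
#' @param k_hubs Number of hub genes to report.
#' @param log2p1 Log-transform the profiles first.
#' @return List of class `regulatory_network`: `edges` (data.frame
#'   `gene_a`, `gene_b`, `r`, `p`), `degree` (named vector over retained
#'   genes), `hubs`.
#' @export
coexpression_network <- function(tpm_rows, r_min = 0.8, alpha = 0.05,
                                 k_hubs = 3, log2p1 = TRUE) {
  if (nrow(tpm_rows) < 3) stop2("need >= 3 genes")
  if (ncol(tpm_rows) < 4) stop2("need >= 4 samples")
  m <- if (log2p1) log2(tpm_rows + 1) else tpm_rows
  const <- apply(m, 1, sd) == 0
  if (any(const)) {
    warning(sum(const), " constant gene profile(s) excluded")
    m <- m[!const, , drop = FALSE]
  }
  ids <- rownames(m)
  edges <- list()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    ct <- cor.test(m[i, ], m[j, ])
    if (!is.na(ct$estimate) && ct$estimate > r_min && ct$p.value < alpha)
      edges[[length(edges) + 1]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j],
        r = unname(ct$estimate), p = ct$p.value)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(gene_a = character(0), gene_b = character(0),
                    r = numeric(0), p = numeric(0))
  degree <- setNames(numeric(length(ids)), ids)
  for (g in c(edges$gene_a, edges$gene_b)) degree[g] <- degree[g] + 1
  hubs <- names(sort(degree, decreasing = TRUE))[seq_len(min(k_hubs, length(ids)))]
  structure(list(edges = edges, degree = degree, hubs = hubs),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d gene(s), %d edge(s); hubs: %s\n",
              length(x$degree), nrow(x$edges), paste(x$hubs, collapse = ", ")))
  invisible(x)
}
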