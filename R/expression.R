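# Expression quantification and differential testing: TPM, a minimal
# negative-binomial Wald pipeline (median-of-ratios normalization +
# method-of-moments dispersion), qPCR fold change, and the phenotype
# statistics.

#' Transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / l_g) / sum_j (c_j / l_j)` per sample; columns
#' sum to 1e6.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param lengths Exonic lengths in bp, one per gene (`> 0`).
#' @return Numeric TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop2("gene lengths must be > 0")
  if (length(lengths) != nrow(counts))
    stop2("`lengths` must have one entry per gene")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop2("sample with all-zero counts")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' The per-sample median of count ratios to the per-gene geometric mean,
#' over genes with nonzero counts in every sample.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) stop2("no gene has nonzero counts in every sample")
  apply(counts, 2, function(cj) exp(median(log(cj[ok]) - lg[ok])))
}

#' Negative-binomial differential expression between two breeds
#'
#' Counts are normalized by median-of-ratios size factors; per-gene
#' dispersion is estimated by the method of moments from the pooled
#' within-group variance (floored at 1e-8); the Wald statistic on the
#' log2 fold change of normalized group means is referred to a t
#' distribution with `n1 + n2 - 2` degrees of freedom (small-sample
#' reference). A gene is *expressed* iff its breed-mean TPM exceeds
#' `tpm_threshold` in at least one breed; DEG status applies the
#' thresholds `|FC| > fc_threshold` and `p < alpha` to expressed genes.
#' No multiple-testing correction is applied by default (nominal
#' p-values); `adjust = TRUE` adds a BH-adjusted column and uses it for
#' status calls.
#'
#' @param counts Genes x samples count matrix (rownames = gene ids).
#' @param breed Character/factor vector per sample, two levels.
#' @param tpm_mat Optional TPM matrix (computed from `lengths` if absent).
#' @param lengths Gene lengths, used when `tpm_mat` is missing.
#' @param numerator,denominator Breed labels; `log2fc` is
#'   numerator over denominator.
#' @param fc_threshold,alpha,tpm_threshold DEG thresholds (fold change
#'   scale, nominal significance, expression filter).
#' @param adjust Apply Benjamini-Hochberg correction (off by default).
#' @return data.frame of class `deg_table`: `gene_id`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `p_value` (and `padj` when `adjust`),
#'   per-breed mean TPM, and `status` in
#'   `{<num>_up, <den>_up, not_DE, not_expressed}`.
#' @export
differential_expression <- function(counts, breed, tpm_mat = NULL,
                                    lengths = NULL,
                                    numerator = "SH", denominator = "HU",
                                    fc_threshold = 2, alpha = 0.05,
                                    tpm_threshold = 1, adjust = FALSE) {
  breed <- as.character(breed)
  if (!all(c(numerator, denominator) %in% breed))
    stop2("both breed labels must occur in `breed`")
  g1 <- breed == numerator
  g0 <- breed == denominator
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 2 || n0 < 2) stop2("need >= 2 replicates per breed")
  if (is.null(tpm_mat)) {
    if (is.null(lengths)) stop2("supply `tpm_mat` or `lengths`")
    tpm_mat <- tpm(counts, lengths)
  }
  sf <- size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  m1 <- rowMeans(nc[, g1, drop = FALSE])
  m0 <- rowMeans(nc[, g0, drop = FALSE])
  v1 <- apply(nc[, g1, drop = FALSE], 1, var)
  v0 <- apply(nc[, g0, drop = FALSE], 1, var)
  s2p <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  mbar <- (m1 + m0) / 2
  disp <- pmax((s2p - mbar) / pmax(mbar, 1e-12)^2, 1e-8)
  eps <- 0.5
  log2fc <- log2(m1 + eps) - log2(m0 + eps)
  se <- sqrt((m1 + disp * m1^2) / (n1 * (m1 + eps)^2) +
             (m0 + disp * m0^2) / (n0 * (m0 + eps)^2)) / log(2)
  stat <- log2fc / se
  p <- 2 * pt(-abs(stat), df = n1 + n0 - 2)
  mt1 <- rowMeans(tpm_mat[, g1, drop = FALSE])
  mt0 <- rowMeans(tpm_mat[, g0, drop = FALSE])
  expressed <- mt1 > tpm_threshold | mt0 > tpm_threshold
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- NA_real_
  stat[all_zero] <- NA_real_
  p_call <- if (adjust) p.adjust(p, "BH") else p
  lfc_cut <- log2(fc_threshold)
  status <- rep("not_DE", nrow(counts))
  status[expressed & !is.na(p_call) & p_call < alpha & log2fc > lfc_cut] <-
    paste0(numerator, "_up")
  status[expressed & !is.na(p_call) & p_call < alpha & log2fc < -lfc_cut] <-
    paste0(denominator, "_up")
  status[!expressed | all_zero] <- "not_expressed"
  out <- data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = (m1 + m0) / 2,
    log2fc = log2fc, se = se, stat = stat, p_value = p,
    status = status, row.names = NULL
  )
  if (adjust) out$padj <- p.adjust(p, "BH")
  out[[paste0("mean_tpm_", numerator)]] <- mt1
  out[[paste0("mean_tpm_", denominator)]] <- mt0
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_case,ct_ref_case Target and reference-gene Ct in the
#'   case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control condition.
#' @return Relative expression (1 = no change).
#' @export
delta_delta_ct <- function(ct_target_case, ct_ref_case,
                           ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Wilcoxon rank-sum comparison of a phenotype between two groups
#'
#' Exact two-sided p for small tie-free samples (both n <= 10), normal
#' approximation with midranks otherwise; identical groups give p = 1.
#'
#' @param x,y Numeric vectors (each `n >= 2`).
#' @return List with `statistic` (rank-sum W) and `p`.
#' @export
phenotype_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop2("each group needs n >= 2")
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(wilcox.test(
    x, y, exact = !ties && length(x) <= 10 && length(y) <= 10,
    correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # degenerate all-equal data: no evidence
  list(statistic = unname(wt$statistic), p = p)
}

#' Spearman correlation of gene expression with phenotypes
#'
#' Per gene x trait pair: Spearman rho, two-sided p, and significance
#' stars (`*` p < 0.05, `**` p < 0.01). Constant vectors give `NA`.
#'
#' @param tpm_rows Genes x samples TPM matrix.
#' @param phenotypes Samples x traits data.frame/matrix (same sample
#'   order).
#' @return List of matrices `rho`, `p`, `stars` (genes x traits).
#' @export
gene_phenotype_correlation <- function(tpm_rows, phenotypes) {
  phenotypes <- as.matrix(phenotypes)
  if (ncol(tpm_rows) != nrow(phenotypes))
    stop2("sample count mismatch between expression and phenotypes")
  if (nrow(phenotypes) < 4) stop2("need >= 4 paired observations")
  ng <- nrow(tpm_rows); nt <- ncol(phenotypes)
  rho <- p <- matrix(NA_real_, ng, nt,
                     dimnames = list(rownames(tpm_rows), colnames(phenotypes)))
  for (i in seq_len(ng)) for (j in seq_len(nt)) {
    x <- tpm_rows[i, ]; y <- phenotypes[, j]
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  stars <- matrix("", ng, nt, dimnames = dimnames(rho))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  list(rho = rho, p = p, stars = stars)
}
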