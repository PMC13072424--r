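toy_genes <- function() {
  gene_annotation(
    chrom = rep("chr1", 3),
    start = c(10000, 40000, 41000),
    end = c(15000, 40800, 46000),
    strand = c("+", "+", "-"),
    gene_id = c("geneB", "geneA", "geneC"))
}

test_that("proximal assignment follows the promoter > body > nearest-TSS priority", {
  genes <- toy_genes()
  # inside geneB's promoter window (TSS 10001, window -2000..+500)
  p1 <- proximal_targets(bed_ranges("chr1", 9000, 9400), genes)
  expect_identical(p1$gene_id, "geneB")
  expect_identical(p1$category, "promoter")
  # inside geneB's body, outside any promoter window
  p2 <- proximal_targets(bed_ranges("chr1", 13000, 13500), genes)
  expect_identical(p2$gene_id, "geneB")
  expect_identical(p2$category, "gene_body")
  # intergenic, nearest TSS within the window
  p3 <- proximal_targets(bed_ranges("chr1", 20000, 20400), genes)
  expect_identical(p3$gene_id, "geneB")
  expect_identical(p3$category, "intergenic")
  expect_equal(p3$distance, 20001 - 10001)
  # beyond the window: unassigned
  p4 <- proximal_targets(bed_ranges("chr2", 0, 400), genes)
  expect_true(is.na(p4$gene_id))
  far <- proximal_targets(bed_ranges("chr1", 500000, 500400), genes,
                          window = 1e4)
  expect_true(is.na(far$gene_id))
})

test_that("equidistant ties break toward the smaller gene identifier", {
  genes <- gene_annotation(rep("chr1", 2), c(1000, 9000), c(2000, 10000),
                           c("+", "+"), c("geneZ", "geneM"))
  # enhancer midway: TSS at 1001 and 9001, enhancer 4801..5200
  tie <- proximal_targets(bed_ranges("chr1", 4800, 5201), genes,
                          promoter_up = 0, promoter_down = 0)
  d1 <- 4801 - 1001; d2 <- 9001 - 5201
  expect_equal(d1, d2)
  expect_identical(tie$gene_id, "geneM")
})

test_that("intergenic assignment matches a brute-force nearest-TSS scan", {
  set.seed(701)
  starts <- sort(sample(seq(0, 4e5, by = 1e4), 20)) + 1000
  genes <- gene_annotation(
    chrom = rep("chr1", 20),
    start = starts,
    end = starts + sample(2000:8000, 20),
    strand = sample(c("+", "-"), 20, replace = TRUE),
    gene_id = sprintf("g%02d", sample(20)))
  enh <- random_intervals(40, max_coord = 5e5, chroms = "chr1")
  got <- proximal_targets(enh, genes, window = 1e5)
  promoters_body <- got$category %in% c("promoter", "gene_body")
  for (i in which(!promoters_body)) {
    d <- pmax(GenomicRanges::start(enh)[i] - genes$tss,
              genes$tss - GenomicRanges::end(enh)[i], 0)
    if (all(d > 1e5)) {
      expect_true(is.na(got$gene_id[i]))
    } else {
      cand <- genes$gene_id[d == min(d)]
      expect_identical(got$gene_id[i], sort(cand)[1])
      expect_equal(got$distance[i], min(d))
    }
  }
})

test_that("loop assignment requires enhancer and TSS in partner anchors", {
  genes <- toy_genes()
  loops <- S4Vectors::Pairs(
    bed_ranges("chr1", c(20000, 100000), c(24000, 104000)),
    bed_ranges("chr1", c(39000, 200000), c(43000, 204000)))
  # enhancer in anchor A of loop 1; geneA TSS (40001) and geneC TSS (46000)
  enh <- bed_ranges("chr1", 21000, 22000)
  hits <- loop_targets(enh, loops, genes)
  expect_setequal(hits$gene_id, "geneA")  # geneC TSS 46000 outside anchor B
  expect_identical(hits$mode, "loop")
  # enhancer outside every anchor
  expect_equal(nrow(loop_targets(bed_ranges("chr1", 60000, 61000),
                                 loops, genes)), 0)
  # enhancer spanning both anchors of one loop gains nothing from it
  straddle <- bed_ranges("chr1", 20000, 43000)
  expect_equal(nrow(loop_targets(straddle, loops, genes)), 0)
  # symmetric orientation: enhancer in anchor B, TSS in anchor A
  genes_rev <- gene_annotation("chr1", 21000, 23000, "+", "geneR")
  hits_rev <- loop_targets(bed_ranges("chr1", 40000, 40500), loops, genes_rev)
  expect_identical(hits_rev$gene_id, "geneR")
})

test_that("DEG integration reproduces the printed coverage arithmetic", {
  deg <- data.frame(gene_id = sprintf("sh%03d", 1:145),
                    status = "SH_up", stringsAsFactors = FALSE)
  class(deg) <- c("deg_table", "data.frame")
  prox_genes <- sprintf("sh%03d", 1:15)
  loop_genes <- sprintf("sh%03d", 11:25)   # union with proximal is 25
  asg <- data.frame(
    enh_idx = seq_len(30), chrom = "chr1", start = 0, end = 1,
    gene_id = c(prox_genes, loop_genes),
    mode = rep(c("proximal", "loop"), each = 15), stringsAsFactors = FALSE)
  res <- integrate_with_degs(asg, deg)
  expect_equal(length(res$union_genes), 25)
  expect_equal(res$n_up, 145)
  expect_equal(res$coverage_pct_all, 17.24)
  # duplicate assignments do not change the set-based statistic
  res_dup <- integrate_with_degs(rbind(asg, asg, asg), deg)
  expect_equal(res_dup$coverage_pct_all, 17.24)
  # disjoint sets give zero coverage
  none <- asg; none$gene_id <- paste0("x", none$gene_id)
  expect_equal(integrate_with_degs(none, deg)$coverage_pct_all, 0)
  expect_error(integrate_with_degs(asg, deg[0, ]), "empty")
})

test_that("coverage respects set semantics and LOC exclusion", {
  set.seed(702)
  for (case in 1:10) {
    up <- unique(c(sprintf("g%03d", sample(200, 40)),
                   sprintf("LOC%03d", sample(50, 5))))
    tg <- unique(sample(c(up, sprintf("h%03d", 1:50)), 30))
    deg <- data.frame(gene_id = up, status = "SH_up")
    asg <- data.frame(enh_idx = seq_along(tg), chrom = "chr1", start = 0,
                      end = 1, gene_id = tg,
                      mode = sample(c("proximal", "loop"), length(tg),
                                    replace = TRUE))
    res <- integrate_with_degs(asg, deg)
    expect_setequal(res$union_genes, intersect(tg, up))
    expect_equal(res$coverage_pct_all,
                 round(100 * length(intersect(tg, up)) / length(up), 2))
    non_loc <- up[!startsWith(up, "LOC")]
    expect_equal(res$coverage_pct_non_loc,
                 round(100 * length(intersect(tg, non_loc)) / length(non_loc), 2))
    # referential integrity: reported genes exist on both sides
    expect_true(all(res$union_genes %in% deg$gene_id))
    expect_true(all(res$union_genes %in% asg$gene_id))
  }
})

test_that("network thresholding applies both the correlation and p-value cuts", {
  # profiles engineered to an exact empirical correlation r against x
  x <- scale(c(1, 2, 3, 4, 5, 6))[, 1]
  e <- scale(resid(lm(c(2, 1, 4, 3, 6, 5) ~ x)))[, 1]
  make_r <- function(r) 10 + r * x + sqrt(1 - r^2) * e
  m <- rbind(a = 2^(10 + x) - 1,          # r = 1 against itself family
             b = 2^make_r(0.805) - 1,
             c = 2^make_r(0.9) - 1)
  net <- coexpression_network(m, r_min = 0.8, alpha = 0.05)
  pairs <- paste(net$edges$gene_a, net$edges$gene_b)
  # r = 0.805 at n = 6: p above 0.05 (critical r ~ 0.811), edge rejected
  expect_false("a b" %in% pairs)
  # r = 0.9 at n = 6: retained
  expect_true("a c" %in% pairs)
  expect_equal(sum(net$degree), 2 * nrow(net$edges))

  ident <- rbind(p = c(1, 5, 2, 8, 3, 9), q = c(1, 5, 2, 8, 3, 9),
                 r = c(9, 1, 8, 2, 7, 3))
  net2 <- coexpression_network(ident)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$r, 1)
  expect_warning(
    coexpression_network(rbind(ident, z = rep(3, 6))), "constant")
  expect_error(coexpression_network(ident[, 1:3]), "samples")
})

test_that("hub selection equals the brute-force maximum degree", {
  set.seed(703)
  for (case in 1:5) {
    m <- matrix(rnorm(8 * 10), 8, 10,
                dimnames = list(paste0("g", 1:8), NULL))
    # plant a correlated block so some edges exist
    m[2, ] <- m[1, ] + rnorm(10, 0, 0.1)
    m[3, ] <- m[1, ] + rnorm(10, 0, 0.1)
    net <- coexpression_network(2^m - min(2^m) + 0.01, r_min = 0.6)
    if (nrow(net$edges) == 0) next
    deg <- net$degree
    expect_equal(unname(deg[net$hubs[1]]), max(deg))
    expect_setequal(net$hubs,
                    names(sort(deg, decreasing = TRUE))[seq_along(net$hubs)])
  }
})

test_that("planted enhancer-gene links are recovered with the loop split", {
  sim <- default_sim()
  cls <- classify_bsr(default_consensus())
  sh <- cls$regions$SH_specific
  prox <- proximal_targets(sh, sim$genes)
  loops <- loop_targets(sh, sim$loops, sim$genes)
  cols <- c("enh_idx", "chrom", "start", "end", "gene_id", "mode")
  asg <- rbind(prox[, cols], loops[, cols])
  truth <- sim$truth$planted_links
  rec <- unique(asg$gene_id[!is.na(asg$gene_id)])
  expect_gte(mean(truth$gene_id %in% rec), 0.7)          # recall
  expect_gte(mean(rec %in% truth$gene_id), 0.8)          # precision
  # loop-mediated targets are invisible to proximal assignment alone
  loop_only <- truth$gene_id[truth$mode == "loop"]
  expect_lte(mean(loop_only %in% prox$gene_id), 0.1)
  expect_gte(mean(loop_only %in% loops$gene_id), 0.7)
})
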