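seg_from_states <- function(states, bin_size = 200, chrom = "chr1",
                            labels = NULL) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    (starts - 1L) * bin_size + 1L, ends * bin_size), state = r$values)
  gr$label <- if (is.null(labels)) as.character(r$values) else labels[r$values]
  S4Vectors::metadata(gr) <- list(bin_size = bin_size)
  gr
}

test_that("peak binarization sets exactly the overlapped bins", {
  peaks <- list(ATAC = bed_ranges("chr1", 0, 400),
                H3K4me3 = bed_ranges("chr1", 399, 401),
                H3K27ac = GenomicRanges::GRanges(),
                H3K4me1 = bed_ranges("chr1", 950, 960),
                H3K27me3 = bed_ranges("chr2", 0, 100))
  mm <- binarize_peaks(peaks, c(chr1 = 1000, chr2 = 400), bin_size = 200)
  expect_equal(mm$bins$chr1[, "ATAC"], c(1L, 1L, 0L, 0L, 0L))
  expect_equal(mm$bins$chr1[, "H3K4me3"], c(0L, 1L, 1L, 0L, 0L))
  expect_equal(sum(mm$bins$chr1[, "H3K27ac"]), 0L)
  expect_equal(mm$bins$chr1[, "H3K4me1"], c(0L, 0L, 0L, 0L, 1L))
  expect_equal(mm$bins$chr2[, "H3K27me3"], c(1L, 0L))
})

test_that("signal binarization applies the Poisson tail rule exactly", {
  set.seed(501)
  vals <- rpois(2000, 5) + ifelse(runif(2000) < 0.02, 40, 0)
  tracks <- setNames(rep(list(signal_track(list(chr1 = vals), 200)), 5),
                     mark_names())
  mm <- binarize_signal(tracks, p_threshold = 1e-4)
  lambda <- mean(vals)
  want <- as.integer(ppois(round(vals) - 1, lambda, lower.tail = FALSE) < 1e-4)
  for (mk in mark_names()) expect_equal(mm$bins$chr1[, mk], want)
  # flat signal at the global mean rate stays silent
  flat <- setNames(rep(list(signal_track(list(chr1 = rep(5, 100)), 200)), 5),
                   mark_names())
  expect_equal(sum(binarize_signal(flat)$bins$chr1), 0L)
  one_empty <- flat
  one_empty$ATAC <- signal_track(list(chr1 = rep(0, 100)), 200)
  expect_warning(mz <- binarize_signal(one_empty), "empty")
  expect_equal(sum(mz$bins$chr1[, "ATAC"]), 0L)
})

test_that("state summaries conserve the genome and count runs exactly", {
  single <- seg_from_states(rep(3L, 50), labels = c("a", "b", "c"))
  s1 <- state_summary(single)
  expect_equal(s1$genome_fraction, 1)
  expect_equal(s1$n_segments, 1L)

  set.seed(502)
  for (case in 1:5) {
    states <- sample.int(5, 400, replace = TRUE)
    seg <- seg_from_states(states, labels = paste0("S", 1:5))
    sm <- state_summary(seg)
    expect_equal(sum(sm$genome_fraction), 1, tolerance = 1e-12)
    runs <- rle(states)
    want_counts <- table(paste0("S", runs$values))
    expect_equal(setNames(sm$n_segments, sm$state),
                 c(unclass(want_counts))[sm$state])
    expect_equal(setNames(sm$genome_fraction, sm$state)[paste0("S", 1:5)],
                 c(prop.table(table(paste0("S", states))))[paste0("S", 1:5)],
                 tolerance = 1e-12)
  }
  lab <- seg_from_states(c(rep(1L, 30), rep(2L, 70)),
                         labels = c("EnhA", "Qui"))
  expect_equal(attr(state_summary(lab), "functional_fraction"), 0.3)
})

test_that("methylation means per state match direct lookup and flag bad input", {
  labels <- c("TssA", "Repr", "Qui")
  seg <- seg_from_states(rep(1:3, each = 20), labels = labels)
  flat <- data.frame(chrom = "chr1", pos = seq(100, 11900, by = 250),
                     frac = 0.5)
  m <- methylation_by_state(seg, flat)
  expect_equal(unname(m[labels]), rep(0.5, 3))

  only_repr <- data.frame(chrom = "chr1", pos = c(4500, 5500, 7000),
                          frac = 0.9)
  m2 <- methylation_by_state(seg, only_repr)
  expect_equal(unname(m2["Repr"]), 0.9)
  expect_true(is.na(m2["TssA"]) && is.na(m2["Qui"]))

  set.seed(503)
  cpg <- data.frame(chrom = "chr1", pos = sample.int(12000, 300),
                    frac = runif(300))
  m3 <- methylation_by_state(seg, cpg)
  states_at <- labels[findInterval(cpg$pos - 1, c(0, 4000, 8000))]
  expect_equal(unname(m3[labels]),
               as.numeric(tapply(cpg$frac, states_at, mean)[labels]),
               tolerance = 1e-12)
  bad <- data.frame(chrom = "chr1", pos = 10, frac = 1.2)
  expect_error(methylation_by_state(seg, bad), "\\[0, 1\\]")
})

test_that("TSS state enrichment is flat for uniform states and peaks for planted ones", {
  set.seed(504)
  states <- sample.int(4, 10000, replace = TRUE)
  seg <- seg_from_states(states, labels = paste0("S", 1:4))
  tss <- data.frame(chrom = "chr1",
                    pos = sample(seq(5000, 1995000, by = 200), 1000),
                    strand = "+")
  enr <- tss_state_enrichment(seg, tss, flank = 2000)
  expect_lt(max(abs(enr - 1)), 0.35)  # flat within sampling noise at 1000 TSS
  expect_lt(mean(abs(enr - 1)), 0.1)

  # a state placed only at TSS bins peaks at offset 0 at 1/genome frequency
  states2 <- rep(1L, 5000)
  tss_bins <- seq(100, 4900, by = 100)
  states2[tss_bins] <- 2L
  seg2 <- seg_from_states(states2, labels = c("bg", "tssonly"))
  tss2 <- data.frame(chrom = "chr1", pos = (tss_bins - 1) * 200 + 50,
                     strand = "+")
  enr2 <- tss_state_enrichment(seg2, tss2, flank = 1000)
  gf <- mean(states2 == 2L)
  expect_equal(enr2["tssonly", "0"], 1 / gf, tolerance = 1e-9)
  # symmetric construction gives a symmetric curve
  expect_equal(enr2["tssonly", ], rev(enr2["tssonly", ]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("DEG-territory enrichment folds follow the coverage ratio formula", {
  # one state tiling the whole genome has fold exactly 1
  seg <- seg_from_states(rep(1L, 1000), labels = "only")
  terr <- bed_ranges("chr1", c(10000, 50000), c(20000, 60000))
  res <- deg_state_enrichment(seg, terr, n_perm = 10, seed = 1)
  expect_equal(res$fold, 1)

  # state covering 10% genome-wide but 30% of the territory: fold 3
  states <- rep(1L, 1000)
  states[1:30] <- 2L                      # 30 bins inside the territory
  states[200 + 1:70] <- 2L                # 70 bins elsewhere
  seg2 <- seg_from_states(states, labels = c("bg", "hot"))
  terr2 <- bed_ranges("chr1", 0, 100 * 200)  # first 100 bins
  res2 <- deg_state_enrichment(seg2, terr2, n_perm = 10, seed = 1)
  expect_equal(res2$fold[res2$state == "hot"], 3)
  expect_error(deg_state_enrichment(seg2, GenomicRanges::GRanges()), "empty")
})

test_that("permutation p-values are consistent with exhaustive placement", {
  # single territory segment on a small genome: every placement can be
  # enumerated, giving the exact null exceedance probability
  states <- rep(1L, 500)
  states[101:150] <- 2L
  seg <- seg_from_states(states, bin_size = 10, labels = c("bg", "hot"))
  terr <- bed_ranges("chr1", 980, 1580)  # 60 bp window, overlaps the hot block
  res <- deg_state_enrichment(seg, terr, n_perm = 400, seed = 11)
  obs <- res$fold[res$state == "hot"]
  w <- 600
  L <- 5000
  folds <- vapply(seq_len(L - w + 1), function(s) {
    bp_hot <- length(intersect(s:(s + w - 1), 1001:1500))
    (bp_hot / w) / (500 / 5000)
  }, 0)
  p_exact <- mean(folds >= obs)
  p_got <- res$p[res$state == "hot"]
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(p_got - p_exact), 3 * se + 2 / 400)
})

test_that("enhancer-expression correlation returns exact Pearson geometry", {
  x <- c(1, 2, 3, 4, 5)
  res <- enhancer_expression_correlation(x, 2 * x, log2p1 = FALSE)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 0)
  sig <- c(2, 9, 4, 1, 7)
  expr <- c(5, 30, 11, 2, 26)
  res2 <- enhancer_expression_correlation(sig, expr)
  lx <- log2(sig + 1); ly <- log2(expr + 1)
  r_hand <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(res2$r, r_hand, tolerance = 1e-12)
  expect_true(is.na(enhancer_expression_correlation(rep(1, 5), 1:5)$r))
  expect_true(is.na(enhancer_expression_correlation(1:3, 1:3)$r))
})
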