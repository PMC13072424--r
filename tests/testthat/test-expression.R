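sim_null_counts <- function(n_genes, n_per_group, mu_sdlog = 1,
                            mean_depth = 500, disp = 0.1) {
  mu <- rlnorm(n_genes, log(mean_depth), mu_sdlog)
  m <- matrix(rnbinom(n_genes * 2 * n_per_group, mu = rep(mu, 2 * n_per_group),
                      size = 1 / disp), n_genes)
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- paste0(rep(c("HU", "SH"), each = n_per_group), "_",
                        seq_len(n_per_group))
  list(counts = m, mu = mu)
}

test_that("tpm follows the closed formula and columns sum to one million", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  out <- tpm(counts, c(1000, 2000))
  expect_equal(unname(out[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-8)
  expect_equal(unname(tpm(matrix(7, 1, 1), 500)[1, 1]), 1e6)
  set.seed(301)
  m <- matrix(rpois(200, 50), 20, 10)
  lens <- sample(200:3000, 20)
  expect_equal(unname(colSums(tpm(m, lens))), rep(1e6, 10), tolerance = 1e-6)
  expect_error(tpm(m, c(lens[-1], 0)), "lengths")
  m[, 3] <- 0
  expect_error(tpm(m, lens), "all-zero")
})

test_that("size factors track relative depth and DE calls are depth-invariant", {
  set.seed(302)
  sim <- sim_null_counts(500, 3)
  sf <- size_factors(sim$counts)
  # a whole-matrix rescaling cancels out of the ratio-to-geomean entirely
  expect_equal(size_factors(sim$counts * 2), sf, tolerance = 1e-12)
  # per-sample depth enters the size-factor ratios exactly
  scaled <- sim$counts
  scaled[, 1] <- scaled[, 1] * 4
  sf2 <- size_factors(scaled)
  expect_equal(sf2[1] / sf2[2], 4 * sf[1] / sf[2], tolerance = 1e-12)
  breed <- rep(c("HU", "SH"), each = 3)
  lens <- rep(1000, 500)
  d1 <- differential_expression(sim$counts, breed, lengths = lens)
  d2 <- differential_expression(sweep(sim$counts, 2, c(1, 2, 4, 1, 3, 5), "*"),
                                breed, lengths = lens)
  expect_identical(d1$status, d2$status)
  expect_equal(d1$log2fc, d2$log2fc, tolerance = 0.02)
})

test_that("swapping breed labels mirrors every call exactly", {
  set.seed(303)
  sim <- sim_null_counts(300, 3)
  idx <- 1:30
  sim$counts[idx, 4:6] <- matrix(
    rnbinom(30 * 3, mu = rep(sim$mu[idx] * 6, 3), size = 10), 30)
  breed <- rep(c("HU", "SH"), each = 3)
  lens <- rep(1000, 300)
  fwd <- differential_expression(sim$counts, breed, lengths = lens)
  # reversing the contrast direction negates fold changes, keeps calls
  rev <- differential_expression(sim$counts, breed, lengths = lens,
                                 numerator = "HU", denominator = "SH")
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-10)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-10)
  expect_identical(fwd$status, rev$status)
  # relabeling the samples themselves maps SH_up <-> HU_up one-to-one
  swapped_breed <- ifelse(breed == "SH", "HU", "SH")
  swp <- differential_expression(sim$counts, swapped_breed, lengths = lens)
  expect_equal(fwd$log2fc, -swp$log2fc, tolerance = 1e-10)
  map <- c(SH_up = "HU_up", HU_up = "SH_up", not_DE = "not_DE",
           not_expressed = "not_expressed")
  expect_identical(unname(map[fwd$status]), swp$status)
})

test_that("identical groups give zero fold change and no calls", {
  set.seed(304)
  half <- matrix(rnbinom(100 * 3, mu = 200, size = 10), 100)
  counts <- cbind(half, half)
  rownames(counts) <- paste0("g", 1:100)
  colnames(counts) <- paste0("s", 1:6)
  deg <- differential_expression(counts, rep(c("HU", "SH"), each = 3),
                                 lengths = rep(1000, 100))
  expect_equal(deg$log2fc, rep(0, 100))
  expect_false(any(deg$status %in% c("SH_up", "HU_up")))
})

test_that("all-zero genes are reported as not expressed without a test", {
  set.seed(305)
  sim <- sim_null_counts(50, 3)
  sim$counts[7, ] <- 0
  deg <- differential_expression(sim$counts, rep(c("HU", "SH"), each = 3),
                                 lengths = rep(1000, 50))
  expect_identical(deg$status[7], "not_expressed")
  expect_true(is.na(deg$p_value[7]))
})

test_that("NB Wald calls agree with a glm.nb likelihood-ratio oracle", {
  set.seed(306)
  sim <- sim_null_counts(400, 3)
  idx <- 1:80
  sim$counts[idx, 4:6] <- matrix(
    rnbinom(80 * 3, mu = rep(sim$mu[idx] * 2^2.5, 3), size = 10), 80)
  breed <- rep(c("HU", "SH"), each = 3)
  deg <- differential_expression(sim$counts, breed, lengths = rep(1000, 400))
  sf <- size_factors(sim$counts)
  grp <- factor(breed, levels = c("HU", "SH"))
  oracle_call <- vapply(seq_len(nrow(sim$counts)), function(g) {
    y <- sim$counts[g, ]
    fit <- tryCatch(
      MASS::glm.nb(y ~ grp + offset(log(sf))),
      error = function(e) NULL, warning = function(w) suppressWarnings(
        MASS::glm.nb(y ~ grp + offset(log(sf)))))
    if (is.null(fit)) return(NA)
    null <- suppressWarnings(MASS::glm.nb(y ~ 1 + offset(log(sf))))
    lrt_p <- pchisq(2 * (logLik(fit) - logLik(null)), 1, lower.tail = FALSE)
    lfc <- coef(fit)[["grpSH"]] / log(2)
    lrt_p < 0.05 && abs(lfc) > 1
  }, NA)
  ours <- deg$status %in% c("SH_up", "HU_up")
  ok <- !is.na(oracle_call)
  expect_gte(mean(ours[ok] == oracle_call[ok]), 0.95)
  expect_gte(mean(deg$status[idx] == "SH_up"), 0.9)  # sensitivity at lfc 2.5
})

test_that("planted DEGs are recovered on simulated data across seeds", {
  sens <- fdp <- numeric(5)
  for (i in 1:5) {
    sim <- simulate_epigenome(small_config(seed = 100 + i))
    deg <- differential_expression(sim$counts, sim$sample_breed,
                                   tpm_mat = sim$tpm)
    truth <- sim$truth$planted_deg
    called_up <- deg$gene_id[deg$status %in% c("SH_up", "HU_up")]
    hit <- paste(deg$gene_id, deg$status) %in%
      paste(truth$gene_id, truth$direction)
    sens[i] <- sum(hit) / nrow(truth)
    fdp[i] <- 1 - sum(hit) / length(called_up)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdp), 0.1)
})

test_that("delta-delta-Ct reproduces the worked relative-expression cases", {
  expect_equal(delta_delta_ct(20, 15, 20, 15), 1)
  expect_equal(delta_delta_ct(20, 15, 22, 15), 4)
  expect_equal(delta_delta_ct(21, 15, 20, 15), 0.5)
})

test_that("rank-sum phenotype test matches exact enumeration", {
  expect_equal(phenotype_test(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(phenotype_test(c(5, 5, 5), c(5, 5, 5))$p, 1)
  set.seed(307)
  for (case in 1:10) {
    x <- sample(seq(1, 100, 0.5), sample(3:6, 1))
    y <- sample(setdiff(seq(1, 100, 0.5), x), sample(3:6, 1))
    expect_equal(phenotype_test(x, y)$p, bf_wilcox_p(x, y), tolerance = 1e-10)
  }
  expect_error(phenotype_test(1, c(2, 3)), "n >= 2")
})

test_that("gene-phenotype Spearman matches the rank-then-Pearson oracle", {
  tpm_rows <- rbind(inc = c(1, 3, 7, 20, 55, 90),
                    dec = c(90, 55, 20, 7, 3, 1))
  ph <- data.frame(trait = c(2, 4, 8, 16, 32, 64))
  res <- gene_phenotype_correlation(tpm_rows, ph)
  expect_equal(unname(res$rho[, 1]), c(1, -1))
  set.seed(308)
  m <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("g", 1:5), NULL))
  ph2 <- data.frame(a = rnorm(8), b = rnorm(8))
  res2 <- gene_phenotype_correlation(m, ph2)
  for (i in 1:5) for (j in 1:2)
    expect_equal(res2$rho[i, j], cor(rank(m[i, ]), rank(ph2[[j]])),
                 tolerance = 1e-10)
  # stars mirror the significance conventions; constants go missing
  strong <- rbind(g = ph2$a)
  rs <- gene_phenotype_correlation(strong, data.frame(a = ph2$a))
  expect_identical(rs$stars[1, 1], "**")
  cst <- gene_phenotype_correlation(rbind(k = rep(1, 8)), ph2)
  expect_true(all(is.na(cst$rho)))
})
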