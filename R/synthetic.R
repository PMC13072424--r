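# Synthetic two-breed epigenome with planted ground truth: a 15-state
# Markov chain per chromosome, Bernoulli mark emissions per replicate,
# Gamma-noised continuous signal, planted breed-specific enhancers
# causally linked (proximally or through chromatin loops) to planted
# upregulated genes, negative-binomial expression, per-state CpG
# methylation, phenotypes, and abstracted read positions for QC.

#' Default per-state emission matrix for the simulator
#'
#' The [state_prototypes()] pattern mapped onto realistic Bernoulli
#' success probabilities: absent 0.05, weak 0.5, strong 0.95.
#'
#' @return A 15 x 5 probability matrix.
#' @export
default_emission <- function() {
  0.05 + 0.9 * state_prototypes()
}

#' Default mean CpG methylation per chromatin state
#'
#' Active promoters lowest, repressed and quiescent chromatin highest,
#' enhancers intermediate — the canonical ordering for muscle WGBS.
#'
#' @return Named numeric vector over [state_labels()].
#' @export
default_methylation_means <- function() {
  c(TssA = 0.10, TssAWk = 0.20, TssAHet = 0.15, TxFlnk = 0.60,
    TxFlnkHet = 0.60, TxFlnkWk = 0.55, EnhA = 0.35, EnhAHet = 0.40,
    EnhAMe = 0.45, EnhAWk = 0.45, EnhPois = 0.60, ATAC_Is = 0.30,
    TssBiv = 0.25, Repr = 0.85, Qui = 0.80)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic epigenome. Defaults define the
#' study conditions the package is exercised under: two breeds (HU
#' purebred, SH crossbred), two 5-Mb chromosomes in 200-bp bins, 400
#' genes, a 15-state chain with self-transition 0.96, 40 SH-specific and
#' 15 HU-specific planted enhancers, 60 planted upregulated genes per
#' breed at log2 fold change 2.5, NB dispersion 0.1 at mean depth 500,
#' 3 RNA and 2 mark replicates per breed, 50 loops with half of the
#' enhancer-gene links loop-mediated.
#'
#' @param seed Master seed; all stage streams derive from it.
#' @param n_chroms,chrom_length,bin_size Genome geometry.
#' @param n_genes Gene count (spread evenly over chromosomes).
#' @param self_prob Markov-chain self-transition probability.
#' @param emission 15 x 5 Bernoulli emission matrix.
#' @param n_bsr_sh,n_bsr_hu Planted breed-specific enhancers per breed.
#' @param n_planted_deg Planted upregulated genes per breed.
#' @param deg_log2fc Planted log2 fold change.
#' @param nb_dispersion NB dispersion (variance = mu + disp * mu^2).
#' @param mean_depth Mean counts per gene.
#' @param n_loops Total loops (planted links + decoys).
#' @param frac_distal Fraction of SH enhancer-gene links that are
#'   loop-mediated only (`round(frac_distal * n_bsr_sh)` loops,
#'   deterministic rounding).
#' @param meth_means Per-state mean methylation.
#' @param rna_reps,mark_reps Replicates per breed.
#' @param enh_len_bins Planted enhancer length in bins.
#' @param loop_anchor_bp Loop anchor width in bp.
#' @param signal_scale Continuous signal units per emission probability.
#' @param strength_sdlog Lognormal sd of strength for enhancers without
#'   a planted target.
#' @param coupling_noise_sd Log2-scale noise between a proximal target's
#'   expression level and its enhancer's signal strength.
#' @param loop_noise_sd Same for loop-mediated links (larger: distal
#'   regulation couples more loosely than proximal regulation).
#' @param n_reads Read positions per simulated mark library.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length = 5e6,
                       bin_size = 200, n_genes = 400, self_prob = 0.96,
                       emission = default_emission(),
                       n_bsr_sh = 40, n_bsr_hu = 15, n_planted_deg = 60,
                       deg_log2fc = 2.5, nb_dispersion = 0.1,
                       mean_depth = 500, n_loops = 50, frac_distal = 0.5,
                       meth_means = default_methylation_means(),
                       rna_reps = 3, mark_reps = 2, enh_len_bins = 5,
                       loop_anchor_bp = 4000, signal_scale = 10,
                       strength_sdlog = 0.4, coupling_noise_sd = 0.25,
                       loop_noise_sd = 1.75, n_reads = 1e5) {
  cfg <- list(seed = seed, n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, bin_size = as.integer(bin_size),
              n_genes = as.integer(n_genes), n_states = nrow(emission),
              self_prob = self_prob, emission = emission,
              n_bsr_sh = as.integer(n_bsr_sh), n_bsr_hu = as.integer(n_bsr_hu),
              n_planted_deg = as.integer(n_planted_deg),
              deg_log2fc = deg_log2fc, nb_dispersion = nb_dispersion,
              mean_depth = mean_depth, n_loops = as.integer(n_loops),
              frac_distal = frac_distal, meth_means = meth_means,
              rna_reps = as.integer(rna_reps), mark_reps = as.integer(mark_reps),
              enh_len_bins = as.integer(enh_len_bins),
              loop_anchor_bp = as.integer(loop_anchor_bp),
              signal_scale = signal_scale, strength_sdlog = strength_sdlog,
              coupling_noise_sd = coupling_noise_sd,
              loop_noise_sd = loop_noise_sd, n_reads = as.integer(n_reads))
  if (any(emission < 0 | emission > 1))
    stop2("emission probabilities must lie in [0, 1]")
  if (frac_distal < 0 || frac_distal > 1)
    stop2("frac_distal must lie in [0, 1]")
  if (self_prob <= 0 || self_prob >= 1)
    stop2("self_prob must lie in (0, 1)")
  structure(cfg, class = "sim_config")
}

#' Split enhancer-gene links into proximal and loop-mediated arms
#'
#' Assigns each planted enhancer exactly one target gene; the first
#' `round(frac_distal * n)` links (deterministic rounding) are
#' loop-mediated, the remainder proximal.
#'
#' @param enh_ids Enhancer identifiers.
#' @param gene_ids Target gene identifiers (same length; each enhancer
#'   gets exactly one gene).
#' @param frac_distal Fraction of loop-mediated links.
#' @return data.frame with `enh_id`, `gene_id`, `mode`.
#' @export
plan_regulatory_links <- function(enh_ids, gene_ids, frac_distal) {
  n <- length(enh_ids)
  if (length(gene_ids) < n) stop2("not enough target genes for planted enhancers")
  n_loop <- round(frac_distal * n)
  data.frame(enh_id = enh_ids, gene_id = gene_ids[seq_len(n)],
             mode = rep(c("loop", "proximal"), c(n_loop, n - n_loop)),
             stringsAsFactors = FALSE)
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

# Markov-chain state track for one chromosome.
sim_state_chain <- function(n_bins, K, self_prob) {
  s <- integer(n_bins)
  s[1] <- sample.int(K, 1)
  jumps <- runif(n_bins - 1) >= self_prob
  targets <- sample.int(K - 1, n_bins - 1, replace = TRUE)
  for (t in 2:n_bins) {
    if (jumps[t - 1]) {
      k <- targets[t - 1]
      s[t] <- if (k >= s[t - 1]) k + 1L else k
    } else s[t] <- s[t - 1]
  }
  s
}

place_genes <- function(cfg) {
  chroms <- sim_chrom_names(cfg)
  per <- ceiling(cfg$n_genes / cfg$n_chroms)
  region_end <- 0.68 * cfg$chrom_length
  # leave room upstream of the first gene for planted proximal enhancers
  region_start <- 8000
  spacing <- floor((region_end - region_start - 6000) / per)
  if (spacing < 9000)
    stop2("gene region too small for the requested gene count")
  chrom <- character(0); start <- numeric(0); width <- numeric(0)
  for (cc in chroms) {
    n_here <- min(per, cfg$n_genes - length(chrom))
    if (n_here <= 0) break
    s0 <- region_start + (seq_len(n_here) - 1) * spacing
    chrom <- c(chrom, rep(cc, n_here))
    start <- c(start, s0)
    width <- c(width, sample(seq(2000, 6000, by = 200), n_here, replace = TRUE))
  }
  strand <- sample(c("+", "-"), length(chrom), replace = TRUE)
  ids <- sprintf("gene%04d", seq_along(chrom))
  # a realistic minority of genes carry uncurated LOC identifiers
  is_loc <- runif(length(ids)) < 0.15
  ids[is_loc] <- sprintf("LOC1%05d", which(is_loc))
  gene_annotation(chrom, start, start + width, strand, ids,
                  exon_length = pmax(round(width * 0.5), 200))
}

#' Simulate the full two-breed synthetic dataset
#'
#' Runs every generator stage under seeds derived from `config$seed`
#' (identical seed, identical output) and returns the dataset bundle
#' together with the planted truth needed for recovery tests.
#'
#' @param config A [sim_config()].
#' @param emit_reads Also simulate per-library read positions for QC
#'   (adds memory; on by default).
#' @return List with elements `config`, `chrom_lengths`, `genes`,
#'   `marks` (binarized `mark_matrix` per breed x replicate), `signal`
#'   (per breed, per mark `signal_track`), `peaks` (per breed x
#'   replicate, per mark `GRanges`), `counts`, `tpm`, `sample_breed`,
#'   `loops`, `methylation`, `phenotypes`, `reads`, and `truth` (state
#'   tracks per breed, `planted_bsr`, `planted_deg`, `planted_links`,
#'   the generating `emission` and `meth_means`).
#' @export
simulate_epigenome <- function(config = sim_config(), emit_reads = TRUE) {
  cfg <- config
  chroms <- sim_chrom_names(cfg)
  bs <- cfg$bin_size
  n_bins <- as.integer(ceiling(cfg$chrom_length / bs))
  K <- cfg$n_states
  labels <- rownames(cfg$emission) %||% state_labels()
  enha_state <- match("EnhA", labels)
  qui_state <- match("Qui", labels)
  chrom_lengths <- setNames(rep(n_bins * bs, cfg$n_chroms), chroms)

  genes <- with_stage_seed(cfg$seed, "genes", place_genes(cfg))

  # ---- planted DEGs and enhancer placement ---------------------------------
  plan <- with_stage_seed(cfg$seed, "planting", {
    idx <- sample.int(length(genes))
    sh_up <- idx[seq_len(cfg$n_planted_deg)]
    hu_up <- idx[cfg$n_planted_deg + seq_len(cfg$n_planted_deg)]
    if (cfg$n_planted_deg > 0 && cfg$n_bsr_sh > cfg$n_planted_deg)
      stop2("not enough planted upregulated genes to link every SH enhancer")
    link_targets <- if (cfg$n_planted_deg > 0) sample(sh_up, cfg$n_bsr_sh)
      else integer(0)
    links <- if (length(link_targets))
      plan_regulatory_links(sprintf("SH_enh%03d", seq_len(cfg$n_bsr_sh)),
                            genes$gene_id[link_targets], cfg$frac_distal)
    else data.frame(enh_id = character(0), gene_id = character(0),
                    mode = character(0))
    base <- rlnorm(length(genes), log(cfg$mean_depth), 1)
    # a linked enhancer's H3K27ac strength tracks its target's
    # expression level, with looser coupling for loop-mediated links
    strengths <- rlnorm(cfg$n_bsr_sh, 0, cfg$strength_sdlog)
    if (nrow(links)) {
      gi <- match(links$gene_id, genes$gene_id)
      noise_sd <- ifelse(links$mode == "loop", cfg$loop_noise_sd,
                         cfg$coupling_noise_sd)
      strengths[seq_len(nrow(links))] <- (base[gi] / cfg$mean_depth) *
        2^rnorm(nrow(links), 0, noise_sd)
    }
    # desert slots for loop-mediated and HU enhancers, >100 kb from genes
    d0 <- ceiling(0.72 * cfg$chrom_length); d1 <- floor(0.98 * cfg$chrom_length)
    slot_w <- 20000
    slots_per <- floor((d1 - d0) / slot_w)
    n_desert <- sum(links$mode == "loop") +
      (cfg$n_bsr_sh - nrow(links)) + cfg$n_bsr_hu
    if (n_desert > slots_per * cfg$n_chroms)
      stop2("more planted enhancers than available enhancer positions")
    list(sh_up = sh_up, hu_up = hu_up, links = links, base = base,
         strengths = strengths, d0 = d0, slot_w = slot_w,
         prox_dist = sample(seq(2500, 4500, by = 100),
                            max(cfg$n_bsr_sh, 1), replace = TRUE))
  })

  enh_len <- cfg$enh_len_bins * bs
  desert_used <- setNames(integer(cfg$n_chroms), chroms)
  take_desert_slot <- function(cc) {
    desert_used[[cc]] <<- desert_used[[cc]] + 1L
    s <- plan$d0 + (desert_used[[cc]] - 1L) * plan$slot_w
    floor(s / bs) * bs
  }
  enh_chrom <- character(0); enh_start <- numeric(0)
  enh_breed <- character(0); enh_id <- character(0)
  gene_of <- setNames(seq_along(genes), genes$gene_id)
  for (i in seq_len(cfg$n_bsr_sh)) {
    id <- sprintf("SH_enh%03d", i)
    row <- match(id, plan$links$enh_id)
    if (!is.na(row) && plan$links$mode[row] == "proximal") {
      g <- genes[gene_of[[plan$links$gene_id[row]]]]
      d <- plan$prox_dist[i]
      if (as.character(GenomicRanges::strand(g)) == "+") {
        s <- GenomicRanges::start(g) - 1 - d - enh_len
      } else {
        s <- GenomicRanges::end(g) + d
      }
      cc <- as.character(GenomicRanges::seqnames(g))
      enh_start <- c(enh_start, floor(s / bs) * bs)
    } else {
      cc <- if (!is.na(row)) {
        as.character(GenomicRanges::seqnames(
          genes[gene_of[[plan$links$gene_id[row]]]]))
      } else chroms[(i %% cfg$n_chroms) + 1L]
      enh_start <- c(enh_start, take_desert_slot(cc))
    }
    enh_chrom <- c(enh_chrom, cc)
    enh_breed <- c(enh_breed, "SH")
    enh_id <- c(enh_id, id)
  }
  for (i in seq_len(cfg$n_bsr_hu)) {
    cc <- chroms[(i %% cfg$n_chroms) + 1L]
    enh_chrom <- c(enh_chrom, cc)
    enh_start <- c(enh_start, take_desert_slot(cc))
    enh_breed <- c(enh_breed, "HU")
    enh_id <- c(enh_id, sprintf("HU_enh%03d", i))
  }
  planted_bsr <- bed_ranges(enh_chrom, enh_start, enh_start + enh_len)
  planted_bsr$breed <- enh_breed
  planted_bsr$enh_id <- enh_id
  planted_bsr$strength <- c(plan$strengths[seq_len(cfg$n_bsr_sh)],
                            rep(1, cfg$n_bsr_hu))

  # ---- state tracks per breed ----------------------------------------------
  base_states <- lapply(seq_along(chroms), function(ci)
    with_stage_seed(cfg$seed, paste0("chain_", chroms[ci]),
                    sim_state_chain(n_bins, K, cfg$self_prob)))
  names(base_states) <- chroms
  tracks <- list(HU = base_states, SH = base_states)
  # core bins carry the enhancer; 2 buffer bins each side are forced
  # quiescent in both breeds so planted breed specificity is unambiguous
  enh_core <- lapply(seq_along(planted_bsr), function(i) {
    b <- bin_index(GenomicRanges::start(planted_bsr[i]), bs):
      bin_index(GenomicRanges::end(planted_bsr[i]), bs)
    b[b >= 1 & b <= n_bins]
  })
  enh_buffer <- lapply(seq_along(planted_bsr), function(i) {
    b <- enh_core[[i]]
    bb <- c(min(b) - (2:1), max(b) + (1:2))
    bb[bb >= 1 & bb <= n_bins]
  })
  for (i in seq_along(planted_bsr)) {
    cc <- as.character(GenomicRanges::seqnames(planted_bsr[i]))
    own <- planted_bsr$breed[i]
    other <- setdiff(c("HU", "SH"), own)
    tracks[[own]][[cc]][enh_core[[i]]] <- enha_state
    tracks[[other]][[cc]][enh_core[[i]]] <- qui_state
    tracks$HU[[cc]][enh_buffer[[i]]] <- qui_state
    tracks$SH[[cc]][enh_buffer[[i]]] <- qui_state
  }

  # ---- binarized marks per breed x replicate -------------------------------
  enha_pattern <- as.integer(state_prototypes()["EnhA", ] == 1)
  marks <- list()
  for (breed in c("HU", "SH")) {
    for (r in seq_len(cfg$mark_reps)) {
      sid <- sprintf("%s_%d", breed, r)
      bins <- with_stage_seed(cfg$seed, paste0("marks_", sid), {
        lapply(chroms, function(cc) {
          st <- tracks[[breed]][[cc]]
          pr <- cfg$emission[st, , drop = FALSE]
          matrix(as.integer(runif(length(pr)) < pr), nrow = n_bins)
        })
      })
      names(bins) <- chroms
      k27 <- match("H3K27ac", mark_names())
      for (i in seq_along(planted_bsr)) {
        cc <- as.character(GenomicRanges::seqnames(planted_bsr[i]))
        b <- enh_core[[i]]
        if (planted_bsr$breed[i] == breed) {
          bins[[cc]][b, ] <- matrix(enha_pattern, length(b), 5, byrow = TRUE)
        } else {
          bins[[cc]][b, k27] <- 0L
        }
        bins[[cc]][enh_buffer[[i]], k27] <- 0L
      }
      marks[[sid]] <- mark_matrix(bins, bs, sid)
    }
  }

  # ---- continuous signal tracks per breed x mark ---------------------------
  signal <- list()
  for (breed in c("HU", "SH")) {
    per_mark <- list()
    for (k in seq_along(mark_names())) {
      mk <- mark_names()[k]
      vals <- with_stage_seed(cfg$seed, paste0("signal_", breed, "_", mk), {
        lapply(chroms, function(cc) {
          st <- tracks[[breed]][[cc]]
          inten <- cfg$signal_scale * cfg$emission[st, k]
          (inten + 0.1) * rgamma(n_bins, shape = 4, rate = 4)
        })
      })
      names(vals) <- chroms
      per_mark[[mk]] <- signal_track(vals, bs)
    }
    signal[[breed]] <- per_mark
  }
  # planted enhancer strength modulates the active-mark signal
  for (i in seq_along(planted_bsr)) {
    cc <- as.character(GenomicRanges::seqnames(planted_bsr[i]))
    b <- enh_core[[i]]
    own <- planted_bsr$breed[i]
    other <- setdiff(c("HU", "SH"), own)
    for (mk in c("ATAC", "H3K27ac", "H3K4me1")) {
      signal[[own]][[mk]]$values[[cc]][b] <-
        signal[[own]][[mk]]$values[[cc]][b] * planted_bsr$strength[i] *
        (0.95 / mean(cfg$emission[tracks[[own]][[cc]][b], mk]))
      signal[[other]][[mk]]$values[[cc]][b] <-
        pmin(signal[[other]][[mk]]$values[[cc]][b], 0.1 * cfg$signal_scale * 0.05)
    }
  }

  # ---- peak calls: maximal runs of positive bins ---------------------------
  peaks <- lapply(marks, function(mm) {
    out <- list()
    for (k in seq_along(mark_names())) {
      grl <- lapply(names(mm$bins), function(cc) {
        v <- mm$bins[[cc]][, k]
        r <- rle(v)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        keep <- r$values == 1L
        GenomicRanges::GRanges(factor(cc, levels = chroms), IRanges::IRanges(
          (starts[keep] - 1L) * bs + 1L, ends[keep] * bs))
      })
      out[[mark_names()[k]]] <- do.call(c, grl)
    }
    out
  })

  # ---- expression ----------------------------------------------------------
  ng <- length(genes)
  lfc <- numeric(ng)
  if (cfg$n_planted_deg > 0) {
    lfc[plan$sh_up] <- cfg$deg_log2fc
    lfc[plan$hu_up] <- -cfg$deg_log2fc
  }
  expr <- with_stage_seed(cfg$seed, "expression", {
    base <- plan$base
    n_samp <- 2L * cfg$rna_reps
    breed_of <- rep(c("HU", "SH"), each = cfg$rna_reps)
    mu <- outer(base, rep(1, n_samp))
    mu[, breed_of == "SH"] <- mu[, breed_of == "SH"] * 2^lfc
    counts <- matrix(rnbinom(ng * n_samp, mu = mu, size = 1 / cfg$nb_dispersion),
                     ng, n_samp)
    rownames(counts) <- genes$gene_id
    colnames(counts) <- paste0(breed_of, "_", rep(seq_len(cfg$rna_reps), 2))
    list(counts = counts, breed_of = breed_of, lfc = lfc)
  })
  tpm_mat <- tpm(expr$counts, genes$exon_length)

  # ---- loops ---------------------------------------------------------------
  loops <- with_stage_seed(cfg$seed, "loops", {
    aw <- cfg$loop_anchor_bp
    ac <- character(0); as1 <- numeric(0); ae1 <- numeric(0)
    as2 <- numeric(0); ae2 <- numeric(0)
    loop_links <- plan$links[plan$links$mode == "loop", , drop = FALSE]
    for (i in seq_len(nrow(loop_links))) {
      e <- planted_bsr[match(loop_links$enh_id[i], planted_bsr$enh_id)]
      g <- genes[gene_of[[loop_links$gene_id[i]]]]
      ea <- c(GenomicRanges::start(e) - 1 - (aw - enh_len) / 2,
              GenomicRanges::end(e) + (aw - enh_len) / 2)
      ga <- c(g$tss - aw / 2, g$tss + aw / 2)
      first <- if (ea[1] < ga[1]) ea else ga
      second <- if (ea[1] < ga[1]) ga else ea
      ac <- c(ac, as.character(GenomicRanges::seqnames(e)))
      as1 <- c(as1, first[1]); ae1 <- c(ae1, first[2])
      as2 <- c(as2, second[1]); ae2 <- c(ae2, second[2])
    }
    n_decoy <- max(cfg$n_loops - nrow(loop_links), 0L)
    for (i in seq_len(n_decoy)) {
      cc <- sample(chroms, 1)
      s1 <- sample.int(floor(0.3 * cfg$chrom_length), 1)
      s2 <- s1 + sample(seq(50000, 300000, by = 1000), 1)
      ac <- c(ac, cc); as1 <- c(as1, s1); ae1 <- c(ae1, s1 + aw)
      as2 <- c(as2, s2); ae2 <- c(ae2, s2 + aw)
    }
    S4Vectors::Pairs(bed_ranges(ac, as1, ae1), bed_ranges(ac, as2, ae2))
  })
  validate_loops(loops)

  # ---- methylation ---------------------------------------------------------
  methylation <- with_stage_seed(cfg$seed, "methylation", {
    mm <- cfg$meth_means[labels]
    out <- lapply(chroms, function(cc) {
      pos <- seq(50L, chrom_lengths[[cc]], by = 100L)
      mu <- mm[tracks$HU[[cc]][bin_index(pos, bs)]]
      conc <- 20
      data.frame(chrom = cc, pos = pos,
                 frac = rbeta(length(pos), mu * conc, (1 - mu) * conc))
    })
    do.call(rbind, out)
  })

  # ---- phenotypes ----------------------------------------------------------
  phenotypes <- with_stage_seed(cfg$seed, "phenotypes", {
    n_animals <- 2L * cfg$rna_reps
    pheno_genes <- if (nrow(plan$links) >= 3) plan$links$gene_id[1:3]
      else genes$gene_id[seq_len(min(3, ng))]
    z <- colMeans(scale(t(log2(tpm_mat[pheno_genes, , drop = FALSE] + 1))))
    data.frame(
      animal = colnames(expr$counts),
      breed = expr$breed_of,
      body_weight_100d = 28 + 2.5 * z + rnorm(n_animals, 0, 0.5),
      body_weight_120d = 36 + 3.0 * z + rnorm(n_animals, 0, 0.5),
      eye_muscle_area = 14 + 2.0 * z + rnorm(n_animals, 0, 0.5),
      row.names = NULL
    )
  })

  # ---- abstracted read positions per mark library --------------------------
  reads <- NULL
  if (emit_reads) {
    reads <- list()
    for (sid in names(marks)) {
      breed <- sub("_.*", "", sid)
      for (mk in mark_names()) {
        lib <- paste0(sid, "_", mk)
        reads[[lib]] <- with_stage_seed(cfg$seed, paste0("reads_", lib), {
          w <- unlist(lapply(signal[[breed]][[mk]]$values, identity),
                      use.names = FALSE)
          idx <- sample.int(length(w), cfg$n_reads, replace = TRUE,
                            prob = w + 0.01)
          cl <- rep(chroms, each = n_bins)
          data.frame(chrom = cl[idx],
                     pos = ((idx - 1L) %% n_bins) * bs +
                       sample.int(bs, cfg$n_reads, replace = TRUE))
        })
      }
    }
  }

  planted_deg <- data.frame(
    gene_id = genes$gene_id[c(plan$sh_up, plan$hu_up)],
    direction = rep(c("SH_up", "HU_up"),
                    c(length(plan$sh_up), length(plan$hu_up))),
    true_log2fc = expr$lfc[c(plan$sh_up, plan$hu_up)],
    stringsAsFactors = FALSE
  )

  list(config = cfg, chrom_lengths = chrom_lengths, genes = genes,
       marks = marks, signal = signal, peaks = peaks,
       counts = expr$counts, tpm = tpm_mat, sample_breed = expr$breed_of,
       loops = loops, methylation = methylation, phenotypes = phenotypes,
       reads = reads,
       truth = list(state_tracks = tracks, planted_bsr = planted_bsr,
                    planted_deg = planted_deg, planted_links = plan$links,
                    emission = cfg$emission, meth_means = cfg$meth_means))
}
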