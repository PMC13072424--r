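# End-to-end orchestration on the synthetic dataset: simulate -> QC ->
# segmentation -> differential expression -> state summaries -> BSR ->
# integration -> network, with files, a manifest and a JSON report.

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop2(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  list(result = res, seconds = as.numeric(Sys.time() - t0, units = "secs"))
}

# union of replicate binary calls -> one pooled per-breed mark matrix
pool_replicates <- function(marks, breed) {
  reps <- marks[startsWith(names(marks), paste0(breed, "_"))]
  bins <- reps[[1]]$bins
  for (r in reps[-1]) {
    for (cc in names(bins)) bins[[cc]] <- pmax(bins[[cc]], r$bins[[cc]])
  }
  mark_matrix(bins, reps[[1]]$bin_size, breed)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes every stage in dependency order under one master seed,
#' writes per-stage output files plus a run manifest (file, stage, md5)
#' and a JSON report, and returns the aggregated report. Identical seed
#' and configuration give an identical report.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_perm Permutations for the DEG state-enrichment p-values.
#' @param hmm_max_iter EM iteration cap for the segmentation model.
#' @return Invisibly, a list with `report`, `manifest`, and the main
#'   intermediate objects (`sim`, `model`, `segmentations`, `deg`,
#'   `consensus`, `integration`, `network`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("chrombsr_"),
                         n_perm = 200, hmm_max_iter = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); stages <- character(0); timings <- numeric(0)
  emit <- function(path, stage_name) {
    files <<- c(files, path); stages <<- c(stages, stage_name)
    path
  }
  note <- function(name, secs) timings[name] <<- secs

  s <- stage("simulate", simulate_epigenome(config))
  sim <- s$result; note("simulate", s$seconds)

  s <- stage("qc", {
    qc_rows <- lapply(names(sim$reads), function(lib) {
      cm <- complexity_metrics(sim$reads[[lib]])
      sid <- sub("_[^_]+$", "", lib)
      mk <- sub(".*_", "", lib)
      data.frame(library = lib, nrf = cm$nrf, pbc1 = cm$pbc1,
                 pbc2 = cm$pbc2,
                 frip = frip(sim$reads[[lib]], sim$peaks[[sid]][[mk]]))
    })
    qc_tab <- do.call(rbind, qc_rows)
    k27 <- list(HU_H3K27ac = sim$signal$HU$H3K27ac,
                SH_H3K27ac = sim$signal$SH$H3K27ac,
                HU_ATAC = sim$signal$HU$ATAC, SH_ATAC = sim$signal$SH$ATAC)
    # correlation grid must be a multiple of the native bin size
    corr_bin <- ceiling(500 / config$bin_size) * config$bin_size
    list(table = qc_tab, correlation = binned_correlation(k27, corr_bin))
  })
  qc <- s$result; note("qc", s$seconds)
  write.table(qc$table, emit(file.path(out_dir, "qc_libraries.tsv"), "qc"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_matrix(qc$correlation,
                   emit(file.path(out_dir, "qc_correlation.tsv"), "qc"))

  s <- stage("segmentation", {
    model <- hmm_fit(sim$marks, K = config$n_states, seed = config$seed,
                     max_iter = hmm_max_iter)
    model <- label_states(model)
    seg_rep <- lapply(sim$marks, function(mm) hmm_decode(model, mm))
    seg_breed <- lapply(c(HU = "HU", SH = "SH"), function(b)
      hmm_decode(model, pool_replicates(sim$marks, b)))
    list(model = model, seg_rep = seg_rep, seg_breed = seg_breed)
  })
  segres <- s$result; note("segmentation", s$seconds)
  write_tsv_matrix(segres$model$E,
                   emit(file.path(out_dir, "model_emission.tsv"), "segmentation"))
  write_tsv_matrix(segres$model$A,
                   emit(file.path(out_dir, "model_transition.tsv"), "segmentation"))
  for (b in names(segres$seg_breed)) {
    seg <- segres$seg_breed[[b]]
    seg$name <- seg$label
    write_bed(seg, emit(file.path(out_dir, paste0("segmentation_", b, ".bed")),
                        "segmentation"))
  }
  state_sum <- lapply(segres$seg_breed, state_summary)
  for (b in names(state_sum))
    write.table(state_sum[[b]],
                emit(file.path(out_dir, paste0("state_summary_", b, ".tsv")),
                     "segmentation"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  s <- stage("expression", {
    differential_expression(sim$counts, sim$sample_breed, tpm_mat = sim$tpm)
  })
  deg <- s$result; note("expression", s$seconds)
  write.table(deg, emit(file.path(out_dir, "deg_table.tsv"), "expression"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  s <- stage("state_enrichment", {
    meth <- lapply(segres$seg_breed, methylation_by_state,
                   methylation = sim$methylation)
    up <- deg$gene_id[deg$status == "SH_up"]
    enr <- if (length(up)) {
      g <- sim$genes[sim$genes$gene_id %in% up]
      terr <- GenomicRanges::resize(g, GenomicRanges::width(g) + 4000,
                                    fix = "center")
      deg_state_enrichment(segres$seg_breed$SH, terr, n_perm = n_perm,
                           seed = config$seed)
    } else NULL
    list(methylation = meth, deg_enrichment = enr)
  })
  stenr <- s$result; note("state_enrichment", s$seconds)
  if (!is.null(stenr$deg_enrichment))
    write.table(stenr$deg_enrichment,
                emit(file.path(out_dir, "deg_state_enrichment.tsv"),
                     "state_enrichment"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  s <- stage("bsr", {
    enh_rep <- lapply(segres$seg_rep, extract_state)
    consensus <- build_consensus(enh_rep)
    cls <- classify_bsr(consensus)
    prof <- if (length(cls$regions$SH_specific))
      bsr_signal_profile(cls$regions$SH_specific,
                         list(HU = sim$signal$HU$H3K27ac,
                              SH = sim$signal$SH$H3K27ac))
    else NULL
    list(consensus = consensus, classes = cls, profile = prof)
  })
  bsr <- s$result; note("bsr", s$seconds)
  cons <- bsr$consensus
  cons$name <- cons$class
  write_bed(cons, emit(file.path(out_dir, "consensus_enhancers.bed"), "bsr"))

  s <- stage("integration", {
    sh_enh <- bsr$classes$regions$SH_specific
    prox <- proximal_targets(sh_enh, sim$genes)
    loop <- loop_targets(sh_enh, sim$loops, sim$genes)
    assignments <- rbind(prox[, c("enh_idx", "chrom", "start", "end",
                                  "gene_id", "mode")],
                         loop[, c("enh_idx", "chrom", "start", "end",
                                  "gene_id", "mode")])
    cov <- integrate_with_degs(assignments, deg)
    enh_sig <- mean_signal_over(sim$signal$SH$H3K27ac, sh_enh)
    expr <- rowMeans(sim$tpm[, sim$sample_breed == "SH", drop = FALSE])
    corr <- assignment_expression_correlation(assignments, enh_sig, expr)
    list(assignments = assignments, coverage = cov, correlation = corr)
  })
  integ <- s$result; note("integration", s$seconds)
  write.table(integ$assignments,
              emit(file.path(out_dir, "target_assignments.tsv"), "integration"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  s <- stage("network", {
    cand <- integ$coverage$union_genes
    if (length(cand) >= 3)
      coexpression_network(sim$tpm[cand, , drop = FALSE])
    else NULL
  })
  net <- s$result; note("network", s$seconds)
  if (!is.null(net))
    write.table(net$edges,
                emit(file.path(out_dir, "network_edges.tsv"), "network"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    seed = config$seed,
    qc = list(mean_nrf = mean(qc$table$nrf), mean_pbc1 = mean(qc$table$pbc1),
              mean_frip = mean(qc$table$frip)),
    deg_counts = as.list(table(deg$status)),
    n_states = segres$model$K,
    state_labels = segres$model$labels,
    functional_fraction = lapply(state_sum, attr, "functional_fraction"),
    bsr_counts = as.list(bsr$classes$counts),
    coverage = integ$coverage[c("n_up", "n_up_non_loc", "coverage_pct_all",
                                "coverage_pct_non_loc")],
    n_union_genes = length(integ$coverage$union_genes),
    correlation = integ$correlation,
    hubs = if (!is.null(net)) net$hubs else character(0),
    n_network_edges = if (!is.null(net)) nrow(net$edges) else 0L,
    timings = as.list(timings)
  )
  report_path <- emit(file.path(out_dir, "report.json"), "report")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  manifest <- data.frame(file = basename(files), stage = stages,
                         md5 = unname(tools::md5sum(files)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(report = report, manifest = manifest, out_dir = out_dir,
                 sim = sim, model = segres$model,
                 segmentations = segres$seg_breed,
                 seg_replicates = segres$seg_rep,
                 deg = deg, state_summary = state_sum,
                 state_enrichment = stenr,
                 consensus = bsr$consensus, bsr_counts = bsr$classes$counts,
                 bsr_classes = bsr$classes,
                 integration = integ, network = net))
}
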