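# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# full-scale dataset at simulator defaults (the study conditions)
default_sim <- function() fixture("sim", simulate_epigenome(sim_config(seed = 42)))

# shared segmentation model fitted on the default dataset
default_model <- function() fixture("model", {
  label_states(hmm_fit(default_sim()$marks, K = 15, seed = 42, max_iter = 100))
})

# per-replicate decoded EnhA segments of the default dataset
default_enh_reps <- function() fixture("enh_reps", {
  lapply(default_sim()$marks, function(m)
    extract_state(hmm_decode(default_model(), m)))
})

default_consensus <- function() fixture("consensus", {
  build_consensus(default_enh_reps())
})

# small, fast dataset for structural checks; ... overrides any default
small_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_chroms = 1, chrom_length = 1e6, n_genes = 40,
               n_bsr_sh = 8, n_bsr_hu = 4, n_planted_deg = 12, n_loops = 12,
               n_reads = 5000)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_sim <- function() fixture("small_sim", simulate_epigenome(small_config()))

random_intervals <- function(n, max_coord = 1000, chroms = c("chr1", "chr2")) {
  start <- sample.int(max_coord, n, replace = TRUE) - 1L
  width <- sample.int(50, n, replace = TRUE)
  bed_ranges(sample(chroms, n, replace = TRUE), start, start + width)
}
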