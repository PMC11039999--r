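# Shared simulated dataset at the documented default configuration; built
# once per test session and reused across files (the genome build dominates
# the cost).

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_genome(sim_config())
  }
  .fixture_env$sim
}

sim_assay <- function(what) {
  if (is.null(.fixture_env[[what]])) {
    sim <- default_sim()
    .fixture_env[[what]] <- switch(what,
      mnase_control = simulate_mnase_fragments(sim, "control"),
      mnase_kd = simulate_mnase_fragments(sim, "kd"),
      atac_pre = simulate_atac_fragments(sim, "pre"),
      atac_post = simulate_atac_fragments(sim, "post")
    )
  }
  .fixture_env[[what]]
}

# dyads of a mono-nucleosomal MNase library under the capture policy
sim_dyads <- function(condition) {
  fr <- sim_assay(paste0("mnase_", condition))
  fragment_midpoints(apply_assay_policy(fr, assay_policy("capture_mnase")))
}

# small configuration for fast pipeline-level tests
small_config <- function(seed = 42) {
  sim_config(genome_length = 6e4, n_sites_per_class = 5,
             mnase_depth = 5000, chip_depth = 5000,
             chip_background_weight = 15, seed = seed)
}

intervals <- function(chrom, start, end, name = NA_character_,
                      strand = NA_character_) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = name, strand = strand)
}

events_at <- function(pos, chrom = "chr1") tibble::tibble(chrom = chrom, pos = pos)
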