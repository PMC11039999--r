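#' Checksum manifest of an output directory
#'
#' @param dir Directory whose files are listed.
#' @param files Relative file names; default all files in `dir`.
#' @return Tibble `file`, `bytes`, `md5`, written to `manifest.tsv` in
#'   `dir` as a side effect.
#' @export
write_manifest <- function(dir, files = NULL) {
  if (is.null(files)) {
    files <- setdiff(list.files(dir, recursive = TRUE), "manifest.tsv")
  }
  files <- sort(files)
  paths <- file.path(dir, files)
  man <- tibble(
    file = files,
    bytes = file.size(paths),
    md5 = unname(tools::md5sum(paths))
  )
  readr::write_tsv(man, file.path(dir, "manifest.tsv"))
  man
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the full generator: genome FASTA, chromosome sizes, planted-site
#' BED (class in the name column), truth table, the per-assay BEDPE files
#' (MNase control/kd, accessibility pre/post, ChIP) and a JSON echo of the
#' configuration, then writes a checksum manifest. Everything derives from
#' `config$seed`, so two runs with one seed are byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the `sim_genome` and the manifest tibble.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  readr::write_tsv(sim$chrom_sizes, file.path(out_dir, "chrom.sizes"),
                   col_names = FALSE)
  write_bed(sim$sites, file.path(out_dir, "sites.bed"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_bedpe(simulate_mnase_fragments(sim, "control"),
              file.path(out_dir, "mnase_control.bedpe"))
  write_bedpe(simulate_mnase_fragments(sim, "kd"),
              file.path(out_dir, "mnase_kd.bedpe"))
  write_bedpe(simulate_atac_fragments(sim, "pre"),
              file.path(out_dir, "atac_pre.bedpe"))
  write_bedpe(simulate_atac_fragments(sim, "post"),
              file.path(out_dir, "atac_post.bedpe"))
  write_bedpe(simulate_chip_fragments(sim),
              file.path(out_dir, "chip.bedpe"))
  man <- write_manifest(out_dir)
  invisible(list(sim = sim, manifest = man))
}

load_table <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

#' Classify peaks from fragment files and write results
#'
#' Thin orchestration over [classify_peaks()]: reads peaks and the two
#' condition fragment files (BEDPE), applies the accessibility assay policy
#' (deduplication), classifies, and writes a class BED (label in the name
#' column) and a per-class summary TSV.
#'
#' @param peaks Peak BED path or interval tibble.
#' @param pre,post BEDPE paths or fragment tibbles for time 0 and
#'   post-induction.
#' @param out_dir Output directory.
#' @param ... Passed to [classify_peaks()] (thresholds, `target`, ...).
#' @return The classified tibble, invisibly.
#' @export
run_classification <- function(peaks, pre, post, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  peaks <- load_table(peaks, read_bed)
  pre <- deduplicate_fragments(load_table(pre, function(f) read_fragments(f, "bedpe")))
  post <- deduplicate_fragments(load_table(post, function(f) read_fragments(f, "bedpe")))
  res <- classify_peaks(peaks, pre, post, ...)
  if (nrow(res) > 0L) {
    write_bed(mutate(res, name = .data$label), file.path(out_dir, "classes.bed"))
  } else {
    warn("empty peak set; writing empty outputs")
    readr::write_lines(character(), file.path(out_dir, "classes.bed"))
  }
  readr::write_tsv(classify_summary(res), file.path(out_dir, "class_summary.tsv"))
  write_manifest(out_dir)
  invisible(res)
}

#' Dyad-frequency maps across timepoints, normalized to the first
#'
#' For each timepoint: read fragments, apply the capture MNase policy
#' (mono-nucleosomal 120-170 bp filter, duplicates retained), take
#' midpoints as dyads, build the anchor-centred matrix depth-scaled to
#' `target`, and normalize to the first (time 0) timepoint as a log2
#' ratio. Matrices and metaplot profiles are written as TSV.
#'
#' @param fragments Named list of BEDPE paths or fragment tibbles; the
#'   first element is the reference (time 0).
#' @param anchors Anchor BED path or interval tibble.
#' @param out_dir Output directory.
#' @param flank,bin Matrix geometry in bp.
#' @param target Depth-normalization target.
#' @param pseudocount For the log2 ratio.
#' @return Invisibly, a list with `matrices` (raw, depth-scaled),
#'   `ratios` (log2 vs the first) and `profiles` (metaplot tibbles).
#' @export
run_dyad_map <- function(fragments, anchors, out_dir, flank = 2000, bin = 10,
                         target = 1e5, pseudocount = 1) {
  stopifnot(length(fragments) >= 1L, !is.null(names(fragments)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anchors <- load_table(anchors, read_bed)
  if (nrow(anchors) == 0L) abort("no anchors supplied")
  policy <- assay_policy("capture_mnase")
  mats <- purrr::imap(fragments, function(fr, nm) {
    fr <- apply_assay_policy(load_table(fr, function(f) read_fragments(f, "bedpe")),
                             policy)
    dyads <- fragment_midpoints(fr)
    build_signal_matrix(dyads, anchors, flank = flank, bin = bin,
                        scale_factor = scale_factor(max(nrow(fr), 1), target))
  })
  ratios <- purrr::map(mats[-1], normalize_to_reference, reference = mats[[1]],
                       pseudocount = pseudocount)
  profiles <- purrr::map(mats, metaplot)
  for (nm in names(mats)) {
    write_matrix_tsv(mats[[nm]], file.path(out_dir, sprintf("dyad_%s.tsv", nm)))
    readr::write_tsv(profiles[[nm]],
                     file.path(out_dir, sprintf("metaplot_%s.tsv", nm)))
  }
  for (nm in names(ratios)) {
    write_matrix_tsv(ratios[[nm]],
                     file.path(out_dir, sprintf("log2ratio_%s_vs_%s.tsv",
                                                nm, names(mats)[1])))
  }
  write_manifest(out_dir)
  invisible(list(matrices = mats, ratios = ratios, profiles = profiles))
}

#' Write a signal matrix as TSV (anchors x bin offsets)
#'
#' @param x A `signal_matrix`.
#' @param file Output path.
#' @return `x`, invisibly.
#' @export
write_matrix_tsv <- function(x, file) {
  df <- as_tibble(x$values, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(anchor = rownames(x$values)), df)
  readr::write_tsv(df, file)
  invisible(x)
}

#' Motif scan plus sampling-enrichment workflow
#'
#' Scans the genome for the consensus, builds peak-excluded sampling loci,
#' draws an equal number of width-matched random background regions, and
#' compares ChIP fragment counts between the two sets. Writes the site,
#' locus and background BEDs, the per-locus counts, and a JSON report.
#'
#' @param genome FASTA path or named character vector.
#' @param pattern IUPAC consensus.
#' @param chip_peaks Peak BED path or interval tibble (may be empty).
#' @param events BEDPE path or fragment/event tibble.
#' @param out_dir Output directory.
#' @param width Sampling-locus width in bp.
#' @param seed Seed for the background draw.
#' @param scale Depth scale factor for counts.
#' @return Invisibly, the `motif_enrichment` object.
#' @export
run_motif_enrichment <- function(genome, pattern, chip_peaks, events, out_dir,
                                 width = 200, seed = 1, scale = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    read_fasta(genome) else as_genome(genome)
  chip_peaks <- load_table(chip_peaks, read_bed)
  events <- load_table(events, function(f) read_fragments(f, "bedpe"))
  sizes <- tibble(chrom = names(genome), size = nchar(genome))
  sites <- scan_motif(genome, pattern)
  write_bed(sites, file.path(out_dir, "motif_sites.bed"))
  loci <- build_sampling_loci(sites, chip_peaks, width = width,
                              chrom_sizes = sizes)
  write_bed(loci, file.path(out_dir, "sampling_loci.bed"))
  if (nrow(loci) == 0L) abort("no sampling loci retained")
  bg <- sample_random_regions(sizes, nrow(loci), width, seed = seed)
  write_bed(bg, file.path(out_dir, "background.bed"))
  enr <- sampling_enrichment(events, loci, bg, scale = scale)
  readr::write_tsv(tidy(enr), file.path(out_dir, "locus_counts.tsv"))
  jsonlite::write_json(as.list(glance(enr)), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir)
  invisible(enr)
}
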