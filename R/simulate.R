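#' Simulation configuration
#'
#' Defines the generative model used to validate the analysis end to end:
#' one synthetic chromosome with planted TF motif instances, each assigned
#' to one of the three accessibility classes; a nucleosome dyad mixture per
#' site (a motif-covering nucleosome plus a phased array at
#' `+/- k * nucleosome_spacing`); condition-dependent occupancy and
#' flanking-array amplitude (control vs remodeler-depleted `kd`);
#' accessibility (transposition) rates per class before (`pre`) and after
#' (`post`) factor induction; and occupancy-weighted ChIP fragments.
#'
#' Default effect directions encode the studied phenomenology: upon
#' remodeler depletion the motif-covering nucleosome loses occupancy while
#' the flanking phased array gains amplitude (most strongly visible at
#' constitutively inaccessible sites), and newly accessible sites gain
#' transposition after induction. Magnitudes are free model parameters with
#' documented defaults.
#'
#' @param genome_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param n_sites_per_class Planted sites per accessibility class.
#' @param motif IUPAC consensus planted at site centres.
#' @param nucleosome_spacing Phased-array repeat length in bp (> 147).
#' @param dyad_jitter_sd Gaussian jitter of dyads around theoretical
#'   centres, bp.
#' @param n_phased_nucleosomes Phased nucleosomes per side of the motif.
#' @param occupancy_over_motif Named list per class of `c(control, kd)`
#'   mixture weights of the motif-covering nucleosome component.
#' @param phase_amplitude Named vector per class: weight of each flanking
#'   nucleosome component (before the condition shift).
#' @param eviction_shift Named vector `c(control, kd)` multiplying the
#'   flanking-array amplitude.
#' @param mnase_depth Total MNase fragments per condition.
#' @param mnase_background_frac Fraction of MNase fragments from uniform
#'   background.
#' @param frag_len_mean,frag_len_sd,frag_len_clip Nucleosomal fragment
#'   length model: normal, clipped to `frag_len_clip`.
#' @param atac_background_rate Transposition events per bp genome-wide.
#' @param accessibility_rate Named list per class of `c(pre, post)` extra
#'   events per bp within +/- 200 bp of the site centre.
#' @param atac_frag_len Length-2 range of accessibility fragment lengths
#'   (uniform).
#' @param chip_depth Total ChIP fragments.
#' @param chip_background_weight Background weight in occupancy units: a
#'   fragment is background with probability
#'   `B / (B + sum(occupancy))`, so site-derived signal scales (near)
#'   linearly with occupancy while background absorbs the rest.
#' @param chip_sd SD (bp) of ChIP fragment centres around bound motifs.
#' @param chip_occupancy Named vector per class: relative ChIP occupancy.
#' @param norm_target Library-size normalization target matched to the
#'   simulated depth (see the methods vignette).
#' @param seed Master seed; every emitted dataset derives its own stream
#'   from `(seed, file tag)` so assays never perturb each other.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 3e6,
                       chrom = "chrSim",
                       n_sites_per_class = 300,
                       motif = "WGATAR",
                       nucleosome_spacing = 190,
                       dyad_jitter_sd = 20,
                       n_phased_nucleosomes = 3,
                       occupancy_over_motif = list(
                         newly_accessible = c(control = 0.10, kd = 0.05),
                         constitutively_accessible = c(control = 0.10, kd = 0.10),
                         constitutively_inaccessible = c(control = 0.45, kd = 0.15)
                       ),
                       phase_amplitude = c(
                         newly_accessible = 0.12,
                         constitutively_accessible = 0.10,
                         constitutively_inaccessible = 0.06
                       ),
                       eviction_shift = c(control = 1, kd = 1.8),
                       mnase_depth = 1e5,
                       mnase_background_frac = 0.2,
                       frag_len_mean = 150, frag_len_sd = 12,
                       frag_len_clip = c(100, 200),
                       atac_background_rate = 2e-4,
                       accessibility_rate = list(
                         newly_accessible = c(pre = 0.015, post = 0.15),
                         constitutively_accessible = c(pre = 0.10, post = 0.10),
                         constitutively_inaccessible = c(pre = 0.001, post = 0.001)
                       ),
                       atac_frag_len = c(60, 120),
                       chip_depth = 2e5,
                       chip_background_weight = 900,
                       chip_sd = 60,
                       chip_occupancy = c(
                         newly_accessible = 1,
                         constitutively_accessible = 1,
                         constitutively_inaccessible = 0.6
                       ),
                       norm_target = 1e5,
                       seed = 1) {
  cfg <- as.list(environment())
  check_iupac(cfg$motif)
  if (cfg$nucleosome_spacing <= 147) abort("nucleosome_spacing must exceed 147 bp")
  occ <- unlist(cfg$occupancy_over_motif)
  if (any(occ < 0 | occ > 1)) abort("occupancy_over_motif values must be in [0, 1]")
  rates <- c(unlist(cfg$accessibility_rate), cfg$atac_background_rate)
  if (any(rates < 0)) abort("accessibility rates must be >= 0")
  if (any(cfg$phase_amplitude < 0) || any(cfg$eviction_shift < 0))
    abort("amplitudes must be >= 0")
  if (cfg$n_sites_per_class > 0) site_slots(cfg)  # errors when packing infeasible
  structure(cfg, class = "sim_config")
}

SIM_CLASSES <- c("newly_accessible", "constitutively_accessible",
                 "constitutively_inaccessible")

# deterministic sub-seed (< 2^31) from the master seed and a file tag
derive_seed <- function(seed, tag) {
  m <- 2147483647
  h <- seed %% m
  for (k in utf8ToInt(tag)) h <- (h * 69069 + k) %% m
  as.integer(h)
}

# jittered-grid site placement honouring the minimum inter-site distance
site_slots <- function(cfg) {
  n <- 3L * cfg$n_sites_per_class
  min_dist <- 2 * cfg$n_phased_nucleosomes * cfg$nucleosome_spacing
  margin <- cfg$n_phased_nucleosomes * cfg$nucleosome_spacing + 600
  slot <- (cfg$genome_length - 2 * margin) / n
  if (slot < min_dist)
    abort("infeasible packing: genome too short for the requested sites")
  list(n = n, min_dist = min_dist, margin = margin, slot = slot)
}

#' Generate a synthetic genome with planted motif sites
#'
#' Draws a uniform random sequence, removes every spurious occurrence of the
#' consensus motif (single-base substitutions, iterated until the scanner
#' finds none), then plants one concrete motif instance per site on a random
#' strand. Site centres sit on a jittered grid that enforces the minimum
#' inter-site distance of twice the phased-array extent, and classes are
#' shuffled over sites. The emitted scanner truth is therefore exact: a
#' motif scan of the genome returns precisely the planted sites.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome` list: `genome` (named character), `chrom_sizes`,
#'   `sites` (interval tibble, class in `name`), `truth` (per-site tibble
#'   with class, strand, centre and the per-condition parameters used) and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "genome"), {
    L <- config$genome_length
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    plen <- nchar(config$motif)
    if (config$n_sites_per_class > 0) {
      sl <- site_slots(config)
      jitter <- runif(sl$n, -(sl$slot - sl$min_dist) / 2, (sl$slot - sl$min_dist) / 2)
      centers <- round(sl$margin + (seq_len(sl$n) - 0.5) * sl$slot + jitter)
      classes <- sample(rep(SIM_CLASSES, each = config$n_sites_per_class))
      strands <- sample(c("+", "-"), sl$n, replace = TRUE)
      starts <- centers - plen %/% 2
    } else {
      centers <- numeric(0); classes <- character(0)
      strands <- character(0); starts <- numeric(0)
    }
    # plant concrete instances, then scrub all non-planted matches
    inst <- vapply(seq_along(starts), function(i) {
      codes <- strsplit(config$motif, "")[[1]]
      s <- paste(vapply(codes, function(cc) sample(IUPAC_SETS[[cc]], 1L), ""),
                 collapse = "")
      if (strands[i] == "-") rc_pattern(s) else s
    }, "")
    for (i in seq_along(starts)) {
      chars[(starts[i] + 1):(starts[i] + plen)] <- strsplit(inst[i], "")[[1]]
    }
    protected <- unlist(lapply(starts, function(s) (s + 1):(s + plen)))
    seq <- paste(chars, collapse = "")
    for (iter in seq_len(25L)) {
      hits <- scan_motif(setNames(seq, config$chrom), config$motif)
      spurious <- hits[!hits$start %in% starts, ]
      if (nrow(spurious) == 0L) break
      for (s in spurious$start) {
        cand <- setdiff((s + 1):(s + plen), protected)
        if (length(cand) == 0L) next  # overlaps a planted span entirely
        p <- cand[ceiling(length(cand) / 2)]
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      seq <- paste(chars, collapse = "")
    }
    sites <- tibble(chrom = config$chrom, start = starts,
                    end = starts + plen, name = classes, strand = strands)
    truth <- tibble(
      site_id = sprintf("site_%d", seq_along(centers)),
      chrom = config$chrom, center = centers,
      start = starts, end = starts + plen,
      class = classes, strand = strands,
      occ_motif_control = vapply(classes, function(k) config$occupancy_over_motif[[k]][["control"]], 0),
      occ_motif_kd = vapply(classes, function(k) config$occupancy_over_motif[[k]][["kd"]], 0),
      atac_rate_pre = vapply(classes, function(k) config$accessibility_rate[[k]][["pre"]], 0),
      atac_rate_post = vapply(classes, function(k) config$accessibility_rate[[k]][["post"]], 0)
    )
    structure(
      list(genome = setNames(seq, config$chrom),
           chrom_sizes = tibble(chrom = config$chrom, size = L),
           sites = sites, truth = truth, config = config),
      class = "sim_genome"
    )
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %s (%d bp), %d planted %s sites\n",
              names(x$genome), nchar(x$genome), nrow(x$sites),
              x$config$motif))
  invisible(x)
}

clip_fragments <- function(start, end, L) {
  tibble(start = pmax(start, 0), end = pmin(end, L)) |>
    mutate(length = .data$end - .data$start)
}

rlen_nucleosomal <- function(n, cfg) {
  pmin(pmax(round(rnorm(n, cfg$frag_len_mean, cfg$frag_len_sd)),
            cfg$frag_len_clip[1]), cfg$frag_len_clip[2])
}

#' Simulate MNase mono-nucleosome-scale fragments
#'
#' Dyads are drawn from the per-site mixture (motif-covering component with
#' weight `occupancy_over_motif[class, condition]`; flanking components at
#' `+/- k * spacing`, `k = 1..n_phased_nucleosomes`, with amplitude
#' `phase_amplitude[class] * eviction_shift[condition]`; Gaussian jitter)
#' plus a uniform genome-wide background; fragment lengths follow the
#' clipped-normal nucleosomal model and fragments are centred on their dyad.
#'
#' @param sim A `sim_genome`.
#' @param condition `"control"` or `"kd"` (remodeler depleted).
#' @param depth Total fragments; defaults to the configured `mnase_depth`.
#' @return Fragment tibble (`chrom`, `start`, `end`, `length`).
#' @export
simulate_mnase_fragments <- function(sim, condition = c("control", "kd"),
                                     depth = NULL) {
  condition <- match.arg(condition)
  cfg <- sim$config
  if (is.null(depth)) depth <- cfg$mnase_depth
  withr::with_seed(derive_seed(cfg$seed, paste0("mnase_", condition)), {
    L <- cfg$genome_length
    n_bg <- rbinom(1L, depth, cfg$mnase_background_frac)
    n_site <- depth - n_bg
    dyads <- floor(runif(n_bg, 0, L))
    tr <- sim$truth
    if (nrow(tr) > 0L && n_site > 0L) {
      occ <- if (condition == "control") tr$occ_motif_control else tr$occ_motif_kd
      amp <- unname(cfg$phase_amplitude[tr$class]) *
        cfg$eviction_shift[[condition]]
      w_site <- occ + 2 * cfg$n_phased_nucleosomes * amp
      si <- sample.int(nrow(tr), n_site, replace = TRUE, prob = w_site)
      # component: 0 = motif nucleosome, otherwise signed phased index;
      # mixture weights depend only on (class, condition), so draw per class
      ks <- c(0, c(-seq_len(cfg$n_phased_nucleosomes),
                   seq_len(cfg$n_phased_nucleosomes)))
      comp <- numeric(n_site)
      for (cl in unique(tr$class[si])) {
        idx <- which(tr$class[si] == cl)
        i1 <- match(cl, tr$class)
        comp[idx] <- sample(ks, length(idx), replace = TRUE,
                            prob = c(occ[i1], rep(amp[i1], 2 * cfg$n_phased_nucleosomes)))
      }
      mu <- tr$center[si] + comp * cfg$nucleosome_spacing
      jit <- if (cfg$dyad_jitter_sd > 0) round(rnorm(n_site, 0, cfg$dyad_jitter_sd)) else 0
      dyads <- c(dyads, mu + jit)
    } else if (n_site > 0L) {
      dyads <- c(dyads, floor(runif(n_site, 0, L)))
    }
    len <- rlen_nucleosomal(length(dyads), cfg)
    out <- clip_fragments(dyads - len %/% 2, dyads - len %/% 2 + len, L)
    tibble(chrom = cfg$chrom, start = out$start, end = out$end,
           length = out$length)
  })
}

#' Simulate transposase-accessibility fragments
#'
#' Event centres are Poisson: a genome-wide background at
#' `atac_background_rate` plus `accessibility_rate[class, condition]` extra
#' events per bp within +/- 200 bp of each site centre. Fragment lengths are
#' uniform over `atac_frag_len` (sub-nucleosomal).
#'
#' @param sim A `sim_genome`.
#' @param condition `"pre"` (time 0) or `"post"` (after factor induction).
#' @return Fragment tibble.
#' @export
simulate_atac_fragments <- function(sim, condition = c("pre", "post")) {
  condition <- match.arg(condition)
  cfg <- sim$config
  withr::with_seed(derive_seed(cfg$seed, paste0("atac_", condition)), {
    L <- cfg$genome_length
    n_bg <- rpois(1L, cfg$atac_background_rate * L)
    centers <- floor(runif(n_bg, 0, L))
    tr <- sim$truth
    if (nrow(tr) > 0L) {
      rate <- if (condition == "pre") tr$atac_rate_pre else tr$atac_rate_post
      n_i <- rpois(nrow(tr), rate * 400)
      if (sum(n_i) > 0L) {
        si <- rep.int(seq_len(nrow(tr)), n_i)
        centers <- c(centers, floor(runif(sum(n_i), tr$center[si] - 200,
                                          tr$center[si] + 200)))
      }
    }
    len <- floor(runif(length(centers), cfg$atac_frag_len[1],
                       cfg$atac_frag_len[2] + 1))
    out <- clip_fragments(centers - len %/% 2, centers - len %/% 2 + len, L)
    tibble(chrom = cfg$chrom, start = out$start, end = out$end,
           length = out$length)
  })
}

#' Simulate occupancy-dependent ChIP fragments
#'
#' Fragment centres are normal around bound motif centres (sd `chip_sd`)
#' with per-site weight proportional to occupancy, plus a uniform
#' background whose constant weight `chip_background_weight` competes with
#' the summed occupancies -- so expected site-derived counts scale (near)
#' linearly with occupancy when background dominates. Supplying a small
#' uniform `occupancy` for all sites emulates sub-peak-threshold motif
#' sampling.
#'
#' @param sim A `sim_genome`.
#' @param occupancy Either a named per-class vector (default
#'   `config$chip_occupancy`) or a numeric vector with one weight per site.
#' @param depth Total fragments; defaults to the configured `chip_depth`.
#' @param tag Extra string mixed into the RNG stream so several ChIP
#'   datasets can be drawn independently.
#' @return Fragment tibble.
#' @export
simulate_chip_fragments <- function(sim, occupancy = NULL, depth = NULL,
                                    tag = "chip") {
  cfg <- sim$config
  if (is.null(depth)) depth <- cfg$chip_depth
  tr <- sim$truth
  if (is.null(occupancy)) occupancy <- cfg$chip_occupancy
  w <- if (!is.null(names(occupancy))) unname(occupancy[tr$class]) else
    rep_len(occupancy, nrow(tr))
  withr::with_seed(derive_seed(cfg$seed, tag), {
    L <- cfg$genome_length
    all_zero <- nrow(tr) == 0L || sum(w) == 0
    p_site <- if (all_zero) 0 else sum(w) / (sum(w) + cfg$chip_background_weight)
    n_site <- rbinom(1L, depth, p_site)
    n_bg <- depth - n_site
    centers <- floor(runif(n_bg, 0, L))
    if (!all_zero && n_site > 0L) {
      si <- sample.int(nrow(tr), n_site, replace = TRUE, prob = w)
      centers <- c(centers, round(tr$center[si] + rnorm(n_site, 0, cfg$chip_sd)))
    }
    len <- pmin(pmax(round(rnorm(length(centers), 200, 30)), 120), 300)
    out <- clip_fragments(centers - len %/% 2, centers - len %/% 2 + len, L)
    tibble(chrom = cfg$chrom, start = out$start, end = out$end,
           length = out$length)
  })
}

#' Write fragments as BEDPE mate pairs
#'
#' Each fragment is split into two `read_length` bp mates at its ends (the
#' whole fragment when shorter), so [read_fragments()] reconstructs the
#' original span exactly.
#'
#' @param fragments Fragment tibble.
#' @param file Output path.
#' @param read_length Mate length in bp.
#' @return `fragments`, invisibly.
#' @export
write_bedpe <- function(fragments, file, read_length = 50) {
  rl <- pmin(read_length, fragments$end - fragments$start)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\tfrag_%d\t0\t+\t-",
    fragments$chrom, as.integer(fragments$start),
    as.integer(fragments$start + rl),
    fragments$chrom, as.integer(fragments$end - rl),
    as.integer(fragments$end), seq_len(nrow(fragments))
  )
  readr::write_lines(lines, file)
  invisible(fragments)
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param file Output path.
#' @param width Line wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, file, width = 70) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, file, width = width)
  invisible(file)
}

#' Read a (multi-record, wrapped) FASTA file
#'
#' @param file Path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readDNAStringSet(file)
  setNames(as.character(set), names(set))
}
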