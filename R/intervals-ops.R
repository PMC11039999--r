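#' Re-centre intervals to fixed-width windows
#'
#' Replaces each interval by `[c - half_width, c + half_width)` where
#' `c = floor((start + end) / 2)` is the interval centre. Windows are clamped
#' to `[0, chrom length)` when a sizes table is supplied, so counts of
#' intervals are preserved at chromosome edges.
#'
#' @param x Interval tibble.
#' @param half_width Half window width in bp (> 0); e.g. 200 for the
#'   +/- 200 bp peak-centre windows, 1000 for +/- 1 kb flanks.
#' @param chrom_sizes Optional sizes tibble/named vector for clamping.
#' @return Interval tibble with the same rows, re-centred.
#' @export
center_window <- function(x, half_width, chrom_sizes = NULL) {
  stopifnot(half_width > 0)
  x <- validate_intervals(x)
  ctr <- interval_center(x)
  out <- mutate(x, start = pmax(ctr - half_width, 0), end = ctr + half_width)
  if (!is.null(chrom_sizes)) {
    sizes <- validate_chrom_sizes(chrom_sizes)
    sz <- sizes$size[match(out$chrom, sizes$chrom)]
    out$end <- ifelse(is.na(sz), out$end, pmin(out$end, sz))
  }
  out
}

#' Drop loci that overlap exclusion regions (and, optionally, each other)
#'
#' Overlap means >= 1 shared bp on the same chromosome under half-open
#' arithmetic. With `remove_mutual = TRUE` every locus overlapping another
#' locus is also dropped -- both members of a mutually overlapping pair go,
#' which avoids counting the same signal twice when windows around nearby
#' motif instances collide.
#'
#' @param x Loci (interval tibble).
#' @param exclude Exclusion intervals (e.g. called ChIP-seq peaks); may be
#'   empty or `NULL`.
#' @param remove_mutual Also drop loci that overlap another locus in `x`.
#' @return The retained loci, original order preserved.
#' @export
remove_overlapping <- function(x, exclude = NULL, remove_mutual = FALSE) {
  x <- validate_intervals(x)
  drop <- rep(FALSE, nrow(x))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    drop <- overlaps_any(x, validate_intervals(exclude))
  }
  if (remove_mutual && nrow(x) > 1L) {
    for (ch in unique(x$chrom)) {
      xi <- which(x$chrom == ch)
      ir <- as_iranges(x[xi, ])
      # self-hit contributes 1 to every count; > 1 means a genuine partner
      cnt <- IRanges::countOverlaps(ir, ir)
      drop[xi] <- drop[xi] | cnt > 1L
    }
  }
  x[!drop, ]
}

#' Sample random background regions
#'
#' Draws `n` intervals of exactly `width` bp: the chromosome is chosen with
#' probability proportional to its length and the start uniformly over the
#' valid range. Used as the random genomic background against which
#' motif-locus enrichment is compared.
#'
#' @param chrom_sizes Sizes tibble or named vector.
#' @param n Number of regions (>= 0).
#' @param width Region width in bp.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the session RNG state is left untouched.
#' @return Interval tibble with `n` rows.
#' @export
sample_random_regions <- function(chrom_sizes, n, width, seed = NULL) {
  sizes <- validate_chrom_sizes(chrom_sizes)
  eligible <- sizes[sizes$size >= width, ]
  if (nrow(eligible) == 0L) abort("width exceeds every chromosome length")
  if (n == 0L) return(empty_intervals())
  draw <- function() {
    ci <- sample.int(nrow(eligible), n, replace = TRUE, prob = eligible$size)
    start <- floor(runif(n, 0, eligible$size[ci] - width + 1))
    tibble(chrom = eligible$chrom[ci], start = start, end = start + width,
           name = sprintf("random_%d", seq_len(n)), strand = NA_character_)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Label peaks as TSS-proximal or distal
#'
#' A peak is `TSS` when the distance from its centre to the nearest annotated
#' transcription start site is at most `threshold` (default 1 kb, the
#' conventional promoter-proximal cutoff), `non-TSS` otherwise.
#'
#' @param peaks Interval tibble.
#' @param tss TSS tibble (`chrom`, `pos`, `gene`, `strand`), e.g. from
#'   [read_tss_bed()].
#' @param threshold Distance cutoff in bp (> 0).
#' @return `peaks` with added columns `tss_dist` (bp, `Inf` when no TSS on
#'   the chromosome) and `tss_class` (`"TSS"` / `"non-TSS"`).
#' @export
classify_tss_proximity <- function(peaks, tss, threshold = 1000) {
  stopifnot(threshold > 0)
  peaks <- validate_intervals(peaks)
  if (is.null(tss) || nrow(tss) == 0L) {
    warn("no TSS records supplied; all peaks labelled non-TSS")
    return(mutate(peaks, tss_dist = Inf, tss_class = "non-TSS"))
  }
  ctr <- interval_center(peaks)
  dist <- rep(Inf, nrow(peaks))
  for (ch in intersect(unique(peaks$chrom), unique(tss$chrom))) {
    pi <- which(peaks$chrom == ch)
    pos <- sort(tss$pos[tss$chrom == ch])
    idx <- findInterval(ctr[pi], pos)
    left <- ifelse(idx >= 1L, abs(ctr[pi] - pos[pmax(idx, 1L)]), Inf)
    right <- ifelse(idx < length(pos), abs(pos[pmin(idx + 1L, length(pos))] - ctr[pi]), Inf)
    dist[pi] <- pmin(left, right)
  }
  mutate(peaks, tss_dist = dist,
         tss_class = ifelse(dist <= threshold, "TSS", "non-TSS"))
}

#' Assign each peak to its nearest gene within a distance limit
#'
#' Each peak is mapped to the gene whose TSS lies nearest to the peak centre
#' and within `max_dist` (default 100 kb); peaks with no TSS in range get
#' `NA`. Equidistant candidates are resolved deterministically: smaller TSS
#' coordinate first, then lexicographic gene name.
#'
#' @inheritParams classify_tss_proximity
#' @param max_dist Maximum centre-to-TSS distance in bp (> 0).
#' @return `peaks` with added columns `gene` and `gene_dist`.
#' @export
assign_peaks_to_genes <- function(peaks, tss, max_dist = 100000) {
  stopifnot(max_dist > 0)
  peaks <- validate_intervals(peaks)
  pk <- mutate(peaks, .peak = row_number(), .center = interval_center(peaks))
  cand <- dplyr::inner_join(
    select(pk, ".peak", "chrom", ".center"),
    select(as_tibble(tss), "chrom", "pos", "gene"),
    by = "chrom", relationship = "many-to-many"
  )
  cand <- filter(mutate(cand, dist = abs(.data$.center - .data$pos)),
                 .data$dist <= max_dist)
  best <- cand |>
    arrange(.data$dist, .data$pos, .data$gene) |>
    distinct(.data$.peak, .keep_all = TRUE) |>
    select(".peak", "gene", gene_dist = "dist")
  out <- left_join(pk, best, by = ".peak")
  select(out, -".peak", -".center")
}

#' Compare two peak sets by overlap
#'
#' A peak is *shared* when it overlaps (>= 1 bp) at least one peak of the
#' other set; a peak overlapping several partners is still counted once. The
#' four categories partition each input, the basis of gained/lost peak calls
#' and overlap Venn counts.
#'
#' @param a,b Interval tibbles.
#' @return A `peak_overlap` object: list with tibbles `shared_a`, `a_only`,
#'   `shared_b`, `b_only` and a `counts` tibble. `tidy()` returns the counts.
#' @export
compare_peak_sets <- function(a, b) {
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  in_b <- overlaps_any(a, b)
  in_a <- overlaps_any(b, a)
  out <- list(
    shared_a = a[in_b, ], a_only = a[!in_b, ],
    shared_b = b[in_a, ], b_only = b[!in_a, ],
    counts = tibble(
      category = c("shared_a", "a_only", "shared_b", "b_only"),
      n = c(sum(in_b), sum(!in_b), sum(in_a), sum(!in_a))
    )
  )
  structure(out, class = "peak_overlap")
}

#' @export
print.peak_overlap <- function(x, ...) {
  cat("Peak-set overlap\n")
  cat(sprintf("  set A: %d peaks (%d shared, %d A-only)\n",
              nrow(x$shared_a) + nrow(x$a_only), nrow(x$shared_a), nrow(x$a_only)))
  cat(sprintf("  set B: %d peaks (%d shared, %d B-only)\n",
              nrow(x$shared_b) + nrow(x$b_only), nrow(x$shared_b), nrow(x$b_only)))
  invisible(x)
}

#' @export
tidy.peak_overlap <- function(x, ...) x$counts
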