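IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

check_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    abort("pattern must be a non-empty string")
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0L)
    abort(sprintf("invalid IUPAC code(s): %s", paste(unique(bad), collapse = ", ")))
  pattern
}

rc_pattern <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

#' Scan sequence for an IUPAC consensus motif
#'
#' Reports every position where the degenerate pattern matches the forward
#' strand, plus (with `both_strands = TRUE`) positions where its reverse
#' complement matches, reported on `-`. Genome `N`s never satisfy a non-`N`
#' pattern code. A position matching on both strands (a palindromic
#' consensus such as `TGASTCA`) is reported once on `+` when
#' `collapse_palindromes = TRUE`, preventing double counting of one
#' physical site.
#'
#' @param genome Named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a single string (then named `seq`).
#' @param pattern IUPAC consensus, e.g. `"WGATAR"` (GATA) or `"TGASTCA"`
#'   (AP-1).
#' @param both_strands Scan the reverse strand too.
#' @param collapse_palindromes Collapse double-strand matches at one
#'   position to a single `+` site.
#' @return Interval tibble of motif sites: `chrom`, `start` (0-based),
#'   `end`, `name` (matched sequence on the reported strand), `strand`.
#' @export
scan_motif <- function(genome, pattern, both_strands = TRUE,
                       collapse_palindromes = TRUE) {
  pattern <- check_iupac(pattern)
  genome <- as_genome(genome)
  plen <- nchar(pattern)
  res <- purrr::imap(genome, function(seq, chrom) {
    subj <- Biostrings::DNAString(seq)
    fwd <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(pattern), subj, fixed = "subject")) - 1L
    rev <- integer(0)
    if (both_strands) {
      rev <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(rc_pattern(pattern)), subj, fixed = "subject")) - 1L
      if (collapse_palindromes) rev <- setdiff(rev, fwd)
    }
    starts <- c(fwd, rev)
    strands <- c(rep("+", length(fwd)), rep("-", length(rev)))
    if (length(starts) == 0L) return(empty_intervals())
    ord <- order(starts, strands)
    starts <- starts[ord]; strands <- strands[ord]
    seqs <- substring(seq, starts + 1L, starts + plen)
    if (any(strands == "-")) {
      seqs[strands == "-"] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[strands == "-"])))
    }
    tibble(chrom = chrom, start = as.numeric(starts),
           end = as.numeric(starts + plen), name = unname(seqs),
           strand = strands)
  })
  bind_rows(res)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    if (is.null(names(out))) names(out) <- sprintf("seq%d", seq_along(out))
    return(out)
  }
  if (inherits(genome, "DNAString")) genome <- as.character(genome)
  stopifnot(is.character(genome))
  if (is.null(names(genome))) {
    names(genome) <- if (length(genome) == 1L) "seq" else
      sprintf("seq%d", seq_along(genome))
  }
  toupper(genome)
}

#' Build peak-excluded motif-sampling loci
#'
#' The workflow behind motif-sampling detection: each consensus motif site
#' is extended to a `width` bp window around its centre, then every window
#' overlapping a called ChIP-seq peak is removed (sampling is by definition
#' outside called peaks), and mutually overlapping windows are removed
#' (both members), so no fragment can be counted twice.
#'
#' @param motif_sites Interval tibble from [scan_motif()].
#' @param chip_peaks Interval tibble of called peaks to exclude.
#' @param width Window width in bp (default 200).
#' @param chrom_sizes Optional sizes for clamping at chromosome edges.
#' @return Interval tibble of retained sampling loci.
#' @export
build_sampling_loci <- function(motif_sites, chip_peaks, width = 200,
                                chrom_sizes = NULL) {
  loci <- center_window(motif_sites, width / 2, chrom_sizes)
  remove_overlapping(loci, exclude = chip_peaks, remove_mutual = TRUE)
}

#' Mann-Whitney U from midranks
#'
#' U for the first sample (equivalently the rank-sum form), with tied
#' observations assigned midranks. The p-value is exact (distribution-free
#' enumeration via [stats::wilcox.test()]) when `n1 * n2 <= exact_max` and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction. When every observation in both groups is
#' identical the comparison is degenerate: `U = n1 n2 / 2`, `p = 1`.
#'
#' @param x,y Numeric samples.
#' @param exact_max Use the exact distribution when `n1 * n2` is at most
#'   this and there are no ties.
#' @return List with `U`, `p`, `n1`, `n2`, `degenerate`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 10000) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = U, p = 1, n1 = n1, n2 = n2, degenerate = TRUE))
  }
  exact <- !ties && n1 * n2 <= exact_max
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  list(U = U, p = p, n1 = n1, n2 = n2, degenerate = FALSE)
}

#' Enrichment of signal at motif loci over random background
#'
#' Counts events (fragment midpoints) per locus in both sets, scales to a
#' common depth, and compares the two count distributions with the
#' two-sided Mann-Whitney test -- aggregate enrichment over background is
#' the signature of motif sampling by a transcription factor outside its
#' called peaks.
#'
#' @param events Event tibble (`chrom`, `pos`) or fragment tibble.
#' @param loci Motif-sampling loci (e.g. from [build_sampling_loci()]).
#' @param background Random background loci (e.g. from
#'   [sample_random_regions()]).
#' @param scale Depth scale factor applied to all counts.
#' @return A `motif_enrichment` object. `tidy()` gives per-locus counts
#'   (`group`, `count`); `glance()` a one-row summary with `U`, `p.value`,
#'   `median_loci`, `median_background`, `median_ratio`, `n_loci`,
#'   `n_background`, `degenerate`.
#' @export
sampling_enrichment <- function(events, loci, background, scale = 1) {
  stopifnot(nrow(loci) >= 1L, nrow(background) >= 1L)
  ev <- as_events(events)
  cl <- count_in_window(ev, loci) * scale
  cb <- count_in_window(ev, background) * scale
  mw <- mann_whitney_u(cl, cb)
  if (mw$degenerate) warn("all locus and background counts identical; p = 1")
  structure(
    list(
      counts = bind_rows(
        tibble(group = "motif_loci", count = cl),
        tibble(group = "background", count = cb)
      ),
      U = mw$U, p.value = mw$p,
      median_loci = median(cl), median_background = median(cb),
      n_loci = mw$n1, n_background = mw$n2, degenerate = mw$degenerate
    ),
    class = "motif_enrichment"
  )
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf(
    "Motif-sampling enrichment: %d motif loci vs %d background regions\n",
    x$n_loci, x$n_background))
  cat(sprintf("  medians %.3g vs %.3g; U = %.0f, two-sided p = %.3g%s\n",
              x$median_loci, x$median_background, x$U, x$p.value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
tidy.motif_enrichment <- function(x, ...) x$counts

#' @export
glance.motif_enrichment <- function(x, ...) {
  tibble(U = x$U, p.value = x$p.value,
         median_loci = x$median_loci, median_background = x$median_background,
         median_ratio = x$median_loci / x$median_background,
         n_loci = x$n_loci, n_background = x$n_background,
         degenerate = x$degenerate)
}

#' Expected spacing between consensus motif occurrences
#'
#' Analytic expectation of the distance between successive matches of a
#' degenerate consensus along i.i.d. random sequence: the reciprocal of the
#' per-position match probability. With `both_strands = TRUE` the forward
#' and reverse-complement match probabilities are summed; when a position
#' can satisfy both strands at once (palindromic consensus) the overlap is
#' subtracted under the default collapsing, mirroring [scan_motif()]'s
#' counting. For `WGATAR` under uniform base composition this gives
#' `4096 / 8 = 512` bp.
#'
#' @param pattern IUPAC consensus.
#' @param base_freq Named base frequencies (`A`, `C`, `G`, `T`), summing
#'   to 1; default uniform.
#' @param both_strands Count matches on either strand.
#' @param collapse_palindromes Count a position matching both strands once.
#' @return Expected spacing in bp.
#' @export
expected_motif_spacing <- function(pattern,
                                   base_freq = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                                   both_strands = TRUE,
                                   collapse_palindromes = TRUE) {
  pattern <- check_iupac(pattern)
  stopifnot(all(c("A", "C", "G", "T") %in% names(base_freq)),
            abs(sum(base_freq) - 1) < 1e-8)
  prob <- function(pat) {
    chars <- strsplit(pat, "")[[1]]
    prod(vapply(chars, function(cc) sum(base_freq[IUPAC_SETS[[cc]]]), 0))
  }
  both_prob <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    prod(vapply(seq_along(ca), function(i) {
      sum(base_freq[intersect(IUPAC_SETS[[ca[i]]], IUPAC_SETS[[cb[i]]])])
    }, 0))
  }
  p <- prob(pattern)
  if (both_strands) {
    rc <- rc_pattern(pattern)
    p <- p + prob(rc) - if (collapse_palindromes) both_prob(pattern, rc) else 0
  }
  if (p <= 0) abort("pattern has zero match probability under base_freq")
  1 / p
}
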