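#' Read sequenced fragments from BEDPE or fragment BED
#'
#' BEDPE mate pairs (both mates on one line, first six columns used) are
#' collapsed to a single fragment spanning `min(starts)..max(ends)` of the
#' two mates -- the standard "convert read pairs to one fragment" step.
#' Inter-chromosomal pairs are dropped and their count reported as an
#' attribute. `fragment_bed` reads BED3+ of already-merged fragments.
#'
#' @param file Path (gzip transparent) or literal lines with `text = TRUE`.
#' @param format `"bedpe"` or `"fragment_bed"`.
#' @param text Treat `file` as the lines themselves.
#' @return A tibble with columns `chrom`, `start`, `end`, `length`, plus an
#'   attribute `dropped_interchrom` (BEDPE only).
#' @export
read_fragments <- function(file, format = c("bedpe", "fragment_bed"),
                           text = FALSE) {
  format <- match.arg(format)
  if (format == "fragment_bed") {
    x <- read_bed(file, text = text)
    return(mutate(select(x, "chrom", "start", "end"), length = .data$end - .data$start))
  }
  lines <- if (text) file else readr::read_lines(file)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  length = numeric())
    attr(out, "dropped_interchrom") <- 0L
    return(out)
  }
  tab <- suppressWarnings(readr::read_tsv(
    I(lines), col_names = FALSE, col_types = readr::cols(.default = "c"),
    progress = FALSE
  ))
  if (ncol(tab) < 6L) {
    abort(sprintf("fewer than 6 BEDPE columns at line %d", lineno[1]))
  }
  short <- !stats::complete.cases(tab[, 1:6])
  if (any(short)) {
    abort(sprintf("fewer than 6 BEDPE columns at line %d",
                  lineno[which(short)[1]]))
  }
  num <- function(i) {
    v <- suppressWarnings(as.numeric(tab[[i]]))
    if (anyNA(v)) abort(sprintf("non-numeric coordinate at line %d",
                                lineno[which(is.na(v))[1]]))
    v
  }
  c1 <- tab[[1L]]; c2 <- tab[[4L]]
  s1 <- num(2L); e1 <- num(3L); s2 <- num(5L); e2 <- num(6L)
  same <- c1 == c2
  out <- tibble(
    chrom = c1[same],
    start = pmin(s1, s2)[same],
    end = pmax(e1, e2)[same]
  )
  if (any(out$start >= out$end)) {
    abort("mate pair with non-positive span")
  }
  out <- mutate(out, length = .data$end - .data$start)
  attr(out, "dropped_interchrom") <- sum(!same)
  out
}

#' Keep mono-nucleosomal fragments
#'
#' Retains fragments whose length lies in the closed interval
#' `[lo, hi]` -- by default 120-170 bp, the size protected by a single
#' nucleosome after MNase digestion. Only these fragments contribute dyads.
#'
#' @param fragments Fragment tibble.
#' @param lo,hi Inclusive length bounds in bp.
#' @return The filtered fragment tibble.
#' @export
filter_mononucleosomal <- function(fragments, lo = 120, hi = 170) {
  stopifnot(lo <= hi)
  len <- fragments$end - fragments$start
  fragments[len >= lo & len <= hi, ]
}

#' Per-assay fragment handling policy
#'
#' Encodes the processing conventions of each assay: ATAC-seq and ChIP-seq
#' use non-duplicate fragments; capture MNase-seq retains duplicates (deep
#' targeted coverage makes genuine re-observation of the same fragment
#' likely); MNase dyad analysis additionally restricts to mono-nucleosomal
#' lengths.
#'
#' @param assay One of `"atac"`, `"chip"`, `"mnase"`, `"capture_mnase"`.
#' @return A list with fields `assay`, `dedup`, `length_min`, `length_max`.
#' @export
assay_policy <- function(assay = c("atac", "chip", "mnase", "capture_mnase")) {
  assay <- match.arg(assay)
  switch(assay,
    atac = list(assay = assay, dedup = TRUE, length_min = NULL, length_max = NULL),
    chip = list(assay = assay, dedup = TRUE, length_min = NULL, length_max = NULL),
    mnase = list(assay = assay, dedup = TRUE, length_min = 120, length_max = 170),
    capture_mnase = list(assay = assay, dedup = FALSE, length_min = 120, length_max = 170)
  )
}

#' Deduplicate fragments by identical coordinates
#'
#' With `dedup = TRUE` (or a policy with `dedup = TRUE`) one fragment is kept
#' per identical `(chrom, start, end)` key; with `FALSE` the input is
#' returned unchanged (duplicates retained, the capture MNase-seq
#' convention).
#'
#' @param fragments Fragment tibble.
#' @param policy Either a logical or a list from [assay_policy()].
#' @return Fragment tibble.
#' @export
deduplicate_fragments <- function(fragments, policy = TRUE) {
  dedup <- if (is.list(policy)) isTRUE(policy$dedup) else isTRUE(policy)
  if (!dedup) return(fragments)
  distinct(fragments, .data$chrom, .data$start, .data$end, .keep_all = TRUE)
}

#' Apply a full assay policy (length filter + deduplication)
#'
#' @param fragments Fragment tibble.
#' @param policy List from [assay_policy()].
#' @return Processed fragment tibble.
#' @export
apply_assay_policy <- function(fragments, policy) {
  if (!is.null(policy$length_min)) {
    fragments <- filter_mononucleosomal(fragments, policy$length_min, policy$length_max)
  }
  deduplicate_fragments(fragments, policy)
}

#' Fragment midpoints as dyad positions
#'
#' The midpoint of a mono-nucleosomal fragment estimates the nucleosome dyad
#' (the centre of the wrapped DNA). Midpoints use `floor((start + end) / 2)`
#' so odd spans resolve deterministically; the convention is shared with
#' interval centres, and any half-bp offset is below downstream bin sizes.
#'
#' @param fragments Fragment tibble.
#' @return Event tibble with columns `chrom`, `pos`.
#' @export
fragment_midpoints <- function(fragments) {
  tibble(chrom = fragments$chrom,
         pos = floor((fragments$start + fragments$end) / 2))
}
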