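#' Read a BED file into an interval tibble
#'
#' Parses BED3/BED6 (tab-separated, no header). `track` and `browser` lines
#' and `#` comments are skipped. Coordinates follow the BED convention:
#' 0-based, half-open `[start, end)`.
#'
#' @param file Path to a BED file (gzip transparent), or a literal character
#'   vector of BED lines when `text = TRUE`.
#' @param text If `TRUE`, `file` is treated as the lines themselves.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `strand`.
#'   `name`/`strand` are `NA` where the column was absent; input order is
#'   preserved.
#' @export
read_bed <- function(file, text = FALSE) {
  lines <- if (text) file else readr::read_lines(file)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    abort(sprintf("fewer than 3 columns at line %d", lineno[which(ncol < 3L)[1]]))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) {
    abort(sprintf("non-integer coordinates at line %d", lineno[which(bad)[1]]))
  }
  if (any(start >= end)) {
    abort(sprintf("start >= end at line %d", lineno[which(start >= end)[1]]))
  }
  nm <- ifelse(ncol >= 4L, vapply(fields, function(f) f[4L][1], ""), NA_character_)
  st <- ifelse(ncol >= 6L, vapply(fields, function(f) f[6L][1], ""), NA_character_)
  st[!is.na(st) & !st %in% c("+", "-", ".")] <- "."
  tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end, name = nm, strand = st
  )
}

#' Write an interval tibble as BED
#'
#' Writes BED6 when `name` or `strand` carry information, BED3 otherwise.
#' Missing names become `.` and missing strands `.` so the file round-trips
#' through [read_bed()].
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `strand`, `score`).
#' @param file Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, file) {
  x <- validate_intervals(x)
  has_meta <- any(!is.na(x$name)) || any(!is.na(x$strand) & x$strand != ".")
  if (has_meta) {
    score <- if ("score" %in% names(x)) x$score else 0
    out <- sprintf(
      "%s\t%d\t%d\t%s\t%s\t%s",
      x$chrom, as.integer(x$start), as.integer(x$end),
      ifelse(is.na(x$name), ".", x$name), format(score, trim = TRUE),
      ifelse(is.na(x$strand), ".", x$strand)
    )
  } else {
    out <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  readr::write_lines(out, file)
  invisible(x)
}

#' Read a chromosome-sizes table
#'
#' @param file Two-column TSV (chromosome name, length in bp), no header.
#' @return A tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(file) {
  x <- readr::read_tsv(file, col_names = c("chrom", "size"),
                       col_types = readr::cols(chrom = "c", size = "d"))
  validate_chrom_sizes(x)
}

validate_chrom_sizes <- function(sizes) {
  if (is.numeric(sizes) && !is.null(names(sizes))) {
    sizes <- tibble(chrom = names(sizes), size = unname(sizes))
  }
  stopifnot(all(c("chrom", "size") %in% names(sizes)))
  if (anyDuplicated(sizes$chrom)) abort("duplicated chromosome names in sizes table")
  if (any(sizes$size <= 0)) abort("chromosome lengths must be > 0")
  as_tibble(sizes[c("chrom", "size")])
}

#' Read TSS annotations from BED6
#'
#' Column 4 carries the gene symbol. The TSS coordinate is the strand-aware
#' 5' end of the interval: `start` on `+` (or unstranded), `end - 1` on `-`.
#'
#' @param file BED6 path.
#' @return A tibble with columns `chrom`, `pos` (0-based TSS), `gene`,
#'   `strand`.
#' @export
read_tss_bed <- function(file) {
  x <- read_bed(file)
  tss_from_intervals(x)
}

tss_from_intervals <- function(x) {
  tibble(
    chrom = x$chrom,
    pos = ifelse(!is.na(x$strand) & x$strand == "-", x$end - 1, x$start),
    gene = x$name,
    strand = ifelse(is.na(x$strand), ".", x$strand)
  )
}

empty_intervals <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         name = character(), strand = character())
}

#' Validate (and normalise) an interval tibble
#'
#' Checks the interval contract used throughout the package: `0 <= start <
#' end`, and `end <= size` per chromosome when a sizes table is supplied.
#' Adds missing `name`/`strand` columns as `NA`.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param chrom_sizes Optional sizes tibble or named vector.
#' @return The validated tibble.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x <- as_tibble(x)
  if (!"name" %in% names(x)) x$name <- NA_character_
  if (!"strand" %in% names(x)) x$strand <- NA_character_
  if (any(x$start < 0)) abort("negative start coordinate")
  if (any(x$start >= x$end)) abort("start >= end")
  if (!is.null(chrom_sizes)) {
    sizes <- validate_chrom_sizes(chrom_sizes)
    sz <- sizes$size[match(x$chrom, sizes$chrom)]
    if (anyNA(sz)) abort("interval on chromosome absent from sizes table")
    if (any(x$end > sz)) abort("interval end beyond chromosome length")
  }
  x
}

# interval centre under the BED convention: floor((start + end) / 2)
interval_center <- function(x) floor((x$start + x$end) / 2)

# IRanges view of an interval tibble (1-based closed, as IRanges expects)
as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# logical: does x[i] overlap (>= 1 shared bp, same chrom) anything in y?
overlaps_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  hit <- rep(FALSE, nrow(x))
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    ov <- IRanges::overlapsAny(as_iranges(x[xi, ]), as_iranges(y[yi, ]))
    hit[xi] <- ov
  }
  hit
}
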