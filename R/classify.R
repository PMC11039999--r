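#' Three-class accessibility classification of TF peaks
#'
#' Classifies each transcription-factor peak from transposase-accessibility
#' fragments collected before (`pre`, time 0) and after (`post`) factor
#' induction:
#'
#' * **newly_accessible** -- fold change `F > fc_threshold` at the peak
#'   centre (+/- `center_half` bp, depth-normalized, pseudocounted) *and*
#'   more than `flank_threshold` normalized reads in the post-induction
#'   +/- `flank_half` bp flank;
#' * otherwise **constitutively_accessible** -- more than `flank_threshold`
#'   normalized flank reads irrespective of induction (assessed on the
#'   pre-induction library by default, see `constitutive_on`);
#' * otherwise **constitutively_inaccessible**.
#'
#' All inequalities are strict, so boundary values fall through to the next
#' rule; the rule order is the only one making the three definitions
#' mutually exclusive, and every peak receives exactly one label.
#'
#' @param peaks Interval tibble of TF peaks.
#' @param pre,post Fragment tibbles (deduplicated per assay policy) or event
#'   tibbles (`chrom`, `pos`) for the two conditions.
#' @param fc_threshold Fold-change cutoff at the peak centre (strict `>`).
#' @param flank_threshold Normalized-read cutoff in the flank (strict).
#' @param center_half,flank_half Half-widths (bp) of the centre and flank
#'   windows.
#' @param pseudocount Added to both normalized centre counts in the fold
#'   change.
#' @param scale_pre,scale_post Depth scale factors; default
#'   `target / nrow(condition)`.
#' @param target Reference library size used for the default scale factors.
#' @param constitutive_on Which flank decides the constitutive split:
#'   `"pre"` (default -- "constitutive" describes the state before
#'   induction), `"post"`, or `"either"` (open if either flank exceeds the
#'   threshold).
#' @return `peaks` with added columns `center_pre`, `center_post`,
#'   `flank_pre`, `flank_post` (normalized counts), `fold_change_center`
#'   and `label`.
#' @export
classify_peaks <- function(peaks, pre, post,
                           fc_threshold = 2, flank_threshold = 30,
                           center_half = 200, flank_half = 1000,
                           pseudocount = 1,
                           scale_pre = NULL, scale_post = NULL,
                           target = 1e7,
                           constitutive_on = c("pre", "post", "either")) {
  constitutive_on <- match.arg(constitutive_on)
  peaks <- validate_intervals(peaks)
  if (nrow(peaks) == 0L) {
    return(mutate(peaks, center_pre = numeric(0), center_post = numeric(0),
                  flank_pre = numeric(0), flank_post = numeric(0),
                  fold_change_center = numeric(0), label = character(0)))
  }
  ev_pre <- as_events(pre)
  ev_post <- as_events(post)
  if (is.null(scale_pre)) scale_pre <- scale_factor(max(nrow(ev_pre), 1), target)
  if (is.null(scale_post)) scale_post <- scale_factor(max(nrow(ev_post), 1), target)
  missing <- setdiff(unique(peaks$chrom),
                     intersect(unique(ev_pre$chrom), unique(ev_post$chrom)))
  if (length(missing) > 0L) {
    warn(sprintf("peak chromosome(s) %s absent from one condition; counted as zero",
                 paste(missing, collapse = ", ")))
  }
  ctr_win <- center_window(peaks, center_half)
  flk_win <- center_window(peaks, flank_half)
  center_pre <- count_in_window(ev_pre, ctr_win) * scale_pre
  center_post <- count_in_window(ev_post, ctr_win) * scale_post
  flank_pre <- count_in_window(ev_pre, flk_win) * scale_pre
  flank_post <- count_in_window(ev_post, flk_win) * scale_post
  fc <- (center_post + pseudocount) / (center_pre + pseudocount)
  open_flank <- switch(constitutive_on,
    pre = flank_pre > flank_threshold,
    post = flank_post > flank_threshold,
    either = flank_pre > flank_threshold | flank_post > flank_threshold
  )
  label <- ifelse(fc > fc_threshold & flank_post > flank_threshold,
                  "newly_accessible",
                  ifelse(open_flank, "constitutively_accessible",
                         "constitutively_inaccessible"))
  mutate(peaks,
         center_pre = center_pre, center_post = center_post,
         flank_pre = flank_pre, flank_post = flank_post,
         fold_change_center = fc, label = label)
}

# accept fragments or ready-made events
as_events <- function(x) {
  if ("pos" %in% names(x)) as_tibble(x) else fragment_midpoints(x)
}

#' Per-class peak counts
#'
#' @param classified Output of [classify_peaks()].
#' @return Tibble `label`, `n` with all three classes present (zero filled).
#' @export
classify_summary <- function(classified) {
  lv <- c("newly_accessible", "constitutively_accessible",
          "constitutively_inaccessible")
  out <- count(classified, label = factor(.data$label, levels = lv),
               .drop = FALSE, name = "n")
  mutate(out, label = as.character(.data$label))
}

#' Raw count matrix over a reference peak set
#'
#' Counts fragments (by midpoint) in the +/- `window_half` bp window around
#' each reference peak centre for each sample -- the unscaled input expected
#' by external differential tools.
#'
#' @param reference_peaks Interval tibble.
#' @param fragment_sets Named list of fragment (or event) tibbles, one per
#'   sample.
#' @param window_half Half window width in bp.
#' @return Tibble with `peak_id`, `chrom`, `start`, `end` and one integer
#'   column per sample.
#' @export
build_count_matrix <- function(reference_peaks, fragment_sets, window_half = 200) {
  stopifnot(length(fragment_sets) >= 1L, !is.null(names(fragment_sets)))
  peaks <- validate_intervals(reference_peaks)
  win <- center_window(peaks, window_half)
  counts <- purrr::map(fragment_sets, ~ count_in_window(as_events(.x), win))
  peak_id <- ifelse(is.na(peaks$name), sprintf("peak_%d", seq_len(nrow(peaks))),
                    peaks$name)
  dplyr::bind_cols(
    tibble(peak_id = peak_id, chrom = peaks$chrom,
           start = peaks$start, end = peaks$end),
    as_tibble(counts)
  )
}

#' Write a count matrix as TSV
#'
#' @param x Output of [build_count_matrix()].
#' @param file Output path.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, file) {
  readr::write_tsv(x, file)
  invisible(x)
}
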