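#' Library-size scale factor
#'
#' Returns `target / total_fragments`, the multiplier that rescales raw
#' per-window counts to a common sequencing depth so that conditions and
#' thresholds (e.g. the ">30 normalized reads / +/-1 kb" accessibility
#' cutoff) are comparable across libraries.
#'
#' @param total_fragments Library size (fragments, > 0).
#' @param target Reference library size; default 10 million fragments.
#' @return Numeric scale factor.
#' @export
scale_factor <- function(total_fragments, target = 1e7) {
  if (length(total_fragments) != 1L || is.na(total_fragments) || total_fragments <= 0)
    abort("total_fragments must be a single positive number")
  target / total_fragments
}

#' Count point events in windows
#'
#' Counts event positions `p` with `start <= p < end` for each window.
#' Fragments are represented by their midpoints (see
#' [fragment_midpoints()]), so a fragment is counted in exactly one window
#' of a tiling.
#'
#' @param events Event tibble (`chrom`, `pos`).
#' @param windows Interval tibble.
#' @return Integer vector, one count per window row.
#' @export
count_in_window <- function(events, windows) {
  windows <- validate_intervals(windows)
  out <- integer(nrow(windows))
  if (nrow(events) == 0L) return(out)
  for (ch in intersect(unique(windows$chrom), unique(events$chrom))) {
    wi <- which(windows$chrom == ch)
    pos <- events$pos[events$chrom == ch]
    pir <- IRanges::IRanges(start = pos + 1L, width = 1L)
    out[wi] <- IRanges::countOverlaps(as_iranges(windows[wi, ]), pir)
  }
  out
}

#' Build an anchor-centred signal matrix
#'
#' The substrate of every metaplot and heatmap: entry `(i, j)` is the number
#' of events falling in `[c_i - flank + (j-1) * bin, c_i - flank + j * bin)`
#' where `c_i` is the centre of anchor `i`. With `scale_factor != 1` the
#' counts are multiplied through and the units become `normalized_count`.
#'
#' @param events Event tibble (`chrom`, `pos`) -- dyads or fragment
#'   midpoints.
#' @param anchors Interval tibble; row order is preserved in the matrix.
#' @param flank Flank in bp each side of the anchor centre.
#' @param bin Bin width in bp; `flank` must be divisible by `bin`.
#' @param scale_factor Depth scale factor (see [scale_factor()]).
#' @return A `signal_matrix` object: anchors x bins matrix plus metadata
#'   (`anchors`, `flank`, `bin`, `units`, `scale_factor`). Column names are
#'   bin-midpoint offsets relative to the anchor centre.
#' @export
build_signal_matrix <- function(events, anchors, flank = 1000, bin = 10,
                                scale_factor = 1) {
  anchors <- validate_intervals(anchors)
  if (flank %% bin != 0) abort("flank must be divisible by bin")
  nb <- as.integer(2 * flank / bin)
  vals <- matrix(0, nrow = nrow(anchors), ncol = nb)
  ctr <- interval_center(anchors)
  missing_chrom <- setdiff(unique(anchors$chrom), unique(events$chrom))
  if (length(missing_chrom) > 0L && nrow(anchors) > 0L) {
    warn(sprintf("no events on chromosome(s) %s; corresponding rows are zero",
                 paste(missing_chrom, collapse = ", ")))
  }
  if (nrow(events) > 0L) {
    for (ch in intersect(unique(anchors$chrom), unique(events$chrom))) {
      ai <- which(anchors$chrom == ch)
      pos <- events$pos[events$chrom == ch]
      win <- IRanges::IRanges(start = ctr[ai] - flank + 1L, width = 2L * flank)
      hits <- IRanges::findOverlaps(IRanges::IRanges(pos + 1L, width = 1L), win)
      if (length(hits) > 0L) {
        qi <- S4Vectors::queryHits(hits)
        si <- S4Vectors::subjectHits(hits)
        off <- pos[qi] - (ctr[ai][si] - flank)
        j <- off %/% bin + 1L
        flat <- (j - 1L) * nrow(vals) + ai[si]  # column-major cell index
        inc <- tabulate(flat, nbins = length(vals))
        vals <- vals + matrix(inc, nrow = nrow(vals))
      }
    }
  }
  units <- if (identical(scale_factor, 1)) "raw_count" else "normalized_count"
  vals <- vals * scale_factor
  colnames(vals) <- as.character(-flank + (seq_len(nb) - 0.5) * bin)
  rownames(vals) <- if (all(is.na(anchors$name))) as.character(seq_len(nrow(anchors))) else
    ifelse(is.na(anchors$name), as.character(seq_len(nrow(anchors))), anchors$name)
  structure(
    list(values = vals, anchors = anchors, flank = flank, bin = bin,
         units = units, scale_factor = scale_factor),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d anchors x %d bins (flank %d bp, bin %d bp, units %s)\n",
              nrow(x$values), ncol(x$values), x$flank, x$bin, x$units))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Long (tidy) form of a signal matrix
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `anchor` (row index), `name`, `offset`
#'   (bp from anchor centre, bin midpoint), `value`.
#' @export
tidy.signal_matrix <- function(x, ...) {
  nb <- ncol(x$values)
  tibble(
    anchor = rep(seq_len(nrow(x$values)), times = nb),
    name = rep(rownames(x$values), times = nb),
    offset = rep(as.numeric(colnames(x$values)), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Average profile across anchors (metaplot)
#'
#' Column means of the signal matrix: the per-anchor average signal at each
#' offset ("reads/peak"), invariant under anchor permutation and linear in
#' anchor-set mixtures.
#'
#' @param x A `signal_matrix` with at least one anchor row.
#' @return Tibble with columns `offset` (bp from anchor centre) and
#'   `signal`, carrying attributes `bin` and `n_anchors`.
#' @export
metaplot <- function(x) {
  stopifnot(inherits(x, "signal_matrix"))
  if (nrow(x$values) == 0L) abort("metaplot of an empty matrix")
  out <- tibble(offset = as.numeric(colnames(x$values)),
                signal = unname(colMeans(x$values)))
  attr(out, "bin") <- x$bin
  attr(out, "n_anchors") <- nrow(x$values)
  out
}

#' Normalize a signal matrix to a reference (time 0) matrix
#'
#' Entry-wise `log2((a + pseudocount) / (r + pseudocount))`. This is the
#' "relative to time 0 h" transform of dyad-frequency heatmaps; the
#' pseudocount keeps fully empty bins finite. Both matrices must share
#' anchors, flank and bin, and should be depth-scaled to the same target.
#'
#' @param x,reference `signal_matrix` objects of identical shape.
#' @param pseudocount Added to both numerator and reference.
#' @return A `signal_matrix` with units `log2_ratio`.
#' @export
normalize_to_reference <- function(x, reference, pseudocount = 1) {
  stopifnot(inherits(x, "signal_matrix"), inherits(reference, "signal_matrix"))
  if (!identical(dim(x$values), dim(reference$values)) ||
      x$flank != reference$flank || x$bin != reference$bin) {
    abort("matrix shapes (anchors/flank/bin) do not match")
  }
  out <- x
  out$values <- log2((x$values + pseudocount) / (reference$values + pseudocount))
  out$units <- "log2_ratio"
  out
}

#' Estimate nucleosome repeat length from a metaplot profile
#'
#' Finds the lag maximizing the autocorrelation of the demeaned average
#' profile within `lag_range` -- for a phased nucleosome array this recovers
#' the inter-dyad spacing.
#'
#' @param profile Metaplot tibble from [metaplot()] (or any tibble with
#'   `offset` and `signal` at constant spacing).
#' @param lag_range Numeric length-2: bp window in which to search for the
#'   autocorrelation peak (default 120-280 bp, bracketing typical
#'   nucleosome repeat lengths).
#' @return Estimated spacing in bp.
#' @export
estimate_spacing <- function(profile, lag_range = c(120, 280)) {
  bin <- diff(profile$offset[1:2])
  x <- profile$signal - mean(profile$signal)
  max_lag <- floor(lag_range[2] / bin)
  ac <- acf(x, lag.max = max_lag, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- (seq_along(ac) - 1) * bin
  ok <- lags >= lag_range[1] & lags <= lag_range[2]
  if (!any(ok)) abort("lag_range contains no whole bin lag")
  lags[ok][which.max(ac[ok])]
}

#' Write point-event coverage as bedGraph
#'
#' Aggregates events into per-position counts, multiplies by
#' `scale_factor`, and writes a sorted, run-length-merged 4-column bedGraph
#' (adjacent positions with equal value are merged into one line).
#'
#' @param events Event tibble (`chrom`, `pos`), or a pre-computed counter
#'   tibble (`chrom`, `pos`, `count`).
#' @param file Output path.
#' @param scale_factor Multiplier applied to counts.
#' @return The merged tibble (`chrom`, `start`, `end`, `value`), invisibly.
#' @export
write_bedgraph <- function(events, file, scale_factor = 1) {
  counter <- if ("count" %in% names(events)) as_tibble(events) else
    count(as_tibble(events), .data$chrom, .data$pos, name = "count")
  if (nrow(counter) == 0L) {
    readr::write_lines(character(), file)
    return(invisible(tibble(chrom = character(), start = numeric(),
                            end = numeric(), value = numeric())))
  }
  merged <- counter |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(.run = cumsum(
      row_number() == 1L | .data$pos != dplyr::lag(.data$pos, default = -2) + 1 |
        .data$count != dplyr::lag(.data$count, default = -1)
    )) |>
    group_by(.data$chrom, .data$.run) |>
    summarise(start = min(.data$pos), end = max(.data$pos) + 1,
              value = .data$count[1] * .env$scale_factor, .groups = "drop") |>
    select("chrom", "start", "end", "value")
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s", merged$chrom, as.integer(merged$start),
            as.integer(merged$end), format(merged$value, trim = TRUE, digits = 10)),
    file
  )
  invisible(merged)
}

#' Read a bedGraph file
#'
#' @param file Path to a 4-column bedGraph.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(file) {
  readr::read_tsv(file, col_names = c("chrom", "start", "end", "value"),
                  col_types = readr::cols("c", "d", "d", "d"))
}

#' Heatmap or metaplot view of a signal matrix
#'
#' @param object A `signal_matrix`.
#' @param type `"heatmap"` (anchors x offset raster) or `"metaplot"`
#'   (average profile).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_matrix <- function(object, type = c("heatmap", "metaplot"), ...) {
  type <- match.arg(type)
  if (type == "metaplot") {
    return(plot_metaplot(metaplot(object), units = object$units))
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$anchor,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = object$units) +
    ggplot2::labs(x = "offset from anchor centre (bp)", y = "anchor") +
    ggplot2::theme_minimal()
}

#' Plot one or more metaplot profiles
#'
#' @param profile Metaplot tibble, or a named list of them (one line each).
#' @param units y-axis label.
#' @return A ggplot object.
#' @export
plot_metaplot <- function(profile, units = "signal") {
  if (is.data.frame(profile)) profile <- list(profile = profile)
  df <- bind_rows(profile, .id = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$signal,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from anchor centre (bp)", y = units) +
    ggplot2::theme_minimal()
}
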