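#' Spread-out plots of tissue distribution
#'
#' A spread-out plot unrolls a vessel segment: columns are the analysed
#' cross-sections in pullback order (x = longitudinal position, mm) and
#' rows are the angular bins (y = circumferential position). Each cell
#' carries a multi-label flag set over the tissue types: a bin may be
#' simultaneously lipid (from the NIRS chemogram) and calcium (from the
#' IVUS arc); lipid- and calcium-burden indices are computed on the two
#' masks independently.
#'
#' @param segment a `segment_record` (see [segment_record()]).
#' @return object of class `spreadout_plot`: list with `masks` (named list
#'   of `n_bins x n_frames` logical matrices, one per tissue), `positions`
#'   (per-column mm), and `n_bins`.
#' @export
build_spreadout <- function(segment) {
  stopifnot(inherits(segment, "segment_record"))
  fr <- segment$frames
  n_bins <- segment$n_bins
  masks <- lapply(TISSUES, function(tis) {
    arcs <- fr[[paste0(tis, "_arcs")]]
    vapply(arcs, arcs_to_bins, logical(n_bins), n_bins = n_bins)
  })
  names(masks) <- TISSUES
  structure(list(masks = masks, positions = fr$position_mm, n_bins = n_bins),
            class = "spreadout_plot")
}

#' Burden indices on a spread-out plot
#'
#' The lipid-core burden index (LCBI) and calcium burden index (CaBI) are
#' the number of cells flagged with the tissue divided by the total number
#' of cells, times 1000. Every grid cell counts towards the denominator.
#'
#' @param plot a `spreadout_plot`.
#' @param tissue `"lipid"` or `"ca"` (any annotated tissue is accepted).
#' @return index on the 0-1000 scale.
#' @export
burden_index <- function(plot, tissue = c("lipid", "ca", "ft", "ff")) {
  stopifnot(inherits(plot, "spreadout_plot"))
  tissue <- match.arg(tissue)
  mask <- plot$masks[[tissue]]
  if (length(mask) == 0L) stop("empty spread-out grid")
  1000 * sum(mask) / length(mask)
}

#' Maximum LCBI in a 4 mm window
#'
#' Scans every maximal window of columns: the window anchored at column
#' `i` extends to the last column within `window_mm` of it, and is kept
#' only when it cannot be extended at either end without exceeding
#' `window_mm` (this makes the scan symmetric under reversal of the
#' pullback direction). The lipid burden index is computed on each such
#' sub-grid and the maximum is returned. Segments shorter than
#' `window_mm` return the whole-plot LCBI with a warning.
#'
#' @param plot a `spreadout_plot` with positions.
#' @param window_mm window length in mm (4 by convention).
#' @return index on the 0-1000 scale.
#' @export
max_lcbi_4mm <- function(plot, window_mm = 4) {
  stopifnot(inherits(plot, "spreadout_plot"))
  mask <- plot$masks$lipid
  if (length(mask) == 0L) stop("empty spread-out grid")
  pos <- plot$positions
  n <- length(pos)
  if (diff(range(pos)) < window_mm) {
    warning("segment shorter than ", window_mm,
            " mm; returning whole-segment LCBI")
    return(burden_index(plot, "lipid"))
  }
  counts <- colSums(mask)
  cum <- c(0, cumsum(counts))
  best <- 0
  for (i in seq_len(n)) {
    j <- findInterval(pos[i] + window_mm, pos)
    if (j < i) j <- i
    # skip windows that could still grow leftward: their left-extended
    # counterpart is scanned from its own anchor
    if (i > 1L && pos[j] - pos[i - 1L] <= window_mm) next
    idx <- 1000 * (cum[j + 1L] - cum[i]) / (plot$n_bins * (j - i + 1L))
    if (idx > best) best <- idx
  }
  best
}

#' Calcium arc from the calcium burden index
#'
#' The mean circumferential calcium arc of a segment is `360 x CaBI / 1000`
#' degrees.
#'
#' @param cabi calcium burden index on the 0-1000 scale.
#' @return arc in degrees.
#' @export
ca_arc_from_cabi <- function(cabi) {
  if (any(!is.finite(cabi)) || any(cabi < 0) || any(cabi > 1000)) {
    stop("cabi must lie in [0, 1000]")
  }
  360 * cabi / 1000
}

#' Export a spread-out plot as a dense flag-set CSV
#'
#' One row per angular bin, one column per frame (named by its position);
#' cells hold `|`-joined tissue flags, empty string for no tissue.
#'
#' @param plot a `spreadout_plot`.
#' @param path output file.
#' @export
write_spreadout_csv <- function(plot, path) {
  stopifnot(inherits(plot, "spreadout_plot"))
  n_frames <- length(plot$positions)
  cells <- matrix("", nrow = plot$n_bins, ncol = n_frames)
  for (tis in names(plot$masks)) {
    m <- plot$masks[[tis]]
    cells[m] <- ifelse(nzchar(cells[m]), paste0(cells[m], "|", tis), tis)
  }
  df <- tibble::as_tibble(as.data.frame(cells, stringsAsFactors = FALSE),
                          .name_repair = "minimal")
  names(df) <- paste0("pos_", format_num(plot$positions))
  df <- dplyr::bind_cols(tibble::tibble(bin = seq_len(plot$n_bins)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Render a spread-out plot
#'
#' Longitudinal position on x, circumferential bin on y; lipid in yellow,
#' calcium in white, fibrotic/fibro-fatty tissue in red over a dark
#' background, mirroring the usual chemogram display.
#'
#' @param plot a `spreadout_plot`.
#' @return a ggplot object.
#' @export
plot_spreadout <- function(plot) {
  stopifnot(inherits(plot, "spreadout_plot"))
  grid <- tidyr::expand_grid(bin = seq_len(plot$n_bins),
                             frame = seq_along(plot$positions))
  at <- function(tis) plot$masks[[tis]][cbind(grid$bin, grid$frame)]
  tissue <- rep("none", nrow(grid))
  tissue[at("ft") | at("ff")] <- "fibrous"
  tissue[at("lipid")] <- "lipid"
  tissue[at("ca")] <- "ca"
  grid$tissue <- factor(tissue, levels = c("none", "fibrous", "lipid", "ca"))
  grid$position <- plot$positions[grid$frame]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$position, y = .data$bin,
                                     fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(none = "grey20", fibrous = "red3",
                                          lipid = "yellow", ca = "grey95"),
                               drop = FALSE) +
    ggplot2::labs(x = "longitudinal position (mm)",
                  y = "circumferential bin", fill = "tissue") +
    ggplot2::theme_minimal()
}
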