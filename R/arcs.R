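#' Circumferential arc encoding
#'
#' Tissue annotations on a cross-section are stored as angular arcs on a
#' circle split into `n_bins` equal bins (default 360 bins of 1 degree).
#' Bin `b` (1-based) covers the half-open degree interval `[b - 1, b)`.
#' An arc set is a two-column matrix of half-open `[start, stop)` bin-edge
#' ranges with `0 <= start < stop <= n_bins`; the serialised form is
#' `"start:stop"` ranges joined by semicolons (empty string = no arc).
#' Arcs crossing the reference angle are written as two ranges.
#'
#' @param arcs numeric matrix with columns `start`, `stop` (bin edges), or
#'   `NULL` for no arc.
#' @param n_bins number of angular bins on the circle.
#' @return `arcs_to_bins()`: logical vector of length `n_bins`;
#'   `bins_to_arcs()`: arc matrix; `encode_arcs()`: character scalar;
#'   `decode_arcs()`: arc matrix.
#' @examples
#' arcs_to_bins(rbind(c(0, 90)), n_bins = 360)[85:95]
#' encode_arcs(rbind(c(0, 90), c(180, 270)))
#' @name arcs
NULL

empty_arcs <- function() {
  matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "stop")))
}

check_arcs <- function(arcs, n_bins = 360L) {
  if (is.null(arcs)) return(empty_arcs())
  arcs <- as.matrix(arcs)
  if (ncol(arcs) != 2L) stop("arc matrix must have two columns (start, stop)")
  colnames(arcs) <- c("start", "stop")
  if (nrow(arcs) == 0L) return(empty_arcs())
  if (any(!is.finite(arcs))) stop("arc boundaries must be finite")
  if (any(arcs[, 1L] < 0) || any(arcs[, 2L] > n_bins) ||
      any(arcs[, 1L] >= arcs[, 2L])) {
    stop("arcs must satisfy 0 <= start < stop <= ", n_bins)
  }
  arcs[order(arcs[, 1L]), , drop = FALSE]
}

#' @rdname arcs
#' @export
arcs_to_bins <- function(arcs, n_bins = 360L) {
  arcs <- check_arcs(arcs, n_bins)
  bins <- logical(n_bins)
  for (i in seq_len(nrow(arcs))) {
    # bins whose interval [b-1, b) intersects [start, stop)
    lo <- floor(arcs[i, 1L]) + 1L
    hi <- ceiling(arcs[i, 2L])
    bins[lo:hi] <- TRUE
  }
  bins
}

#' @rdname arcs
#' @param bins logical vector of per-bin flags.
#' @export
bins_to_arcs <- function(bins) {
  r <- rle(as.logical(bins))
  stop_idx <- cumsum(r$lengths)
  start_idx <- stop_idx - r$lengths
  keep <- r$values
  if (!any(keep)) return(empty_arcs())
  out <- cbind(start = start_idx[keep], stop = stop_idx[keep])
  rownames(out) <- NULL
  out
}

#' @rdname arcs
#' @export
encode_arcs <- function(arcs) {
  arcs <- check_arcs(arcs, n_bins = Inf)
  if (nrow(arcs) == 0L) return("")
  paste(paste0(format_num(arcs[, 1L]), ":", format_num(arcs[, 2L])),
        collapse = ";")
}

#' @rdname arcs
#' @param x serialised arc string.
#' @export
decode_arcs <- function(x, n_bins = 360L) {
  if (is.na(x) || !nzchar(x)) return(empty_arcs())
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  vals <- vapply(strsplit(parts, ":", fixed = TRUE), function(p) {
    if (length(p) != 2L) stop("malformed arc range: ", paste(p, collapse = ":"))
    as.numeric(p)
  }, numeric(2L))
  check_arcs(t(vals), n_bins)
}

#' @rdname arcs
#' @export
arc_extent <- function(arcs) {
  arcs <- check_arcs(arcs, n_bins = Inf)
  sum(arcs[, 2L] - arcs[, 1L])
}

# fixed-precision numeric formatting shared by all text serialisers so that
# write(read(x)) round-trips byte-identically
format_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 15, width = 1)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  gsub(" ", "", out)
}
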