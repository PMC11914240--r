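# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (loops, exhaustive enumeration) and stay
# independent of the package's vectorised implementations.

make_frames <- function(positions, lumen, vessel,
                        lipid = NULL, ca = NULL,
                        modality = "NIRS_IVUS",
                        subject = "S1", vessel_id = "V1",
                        n_bins = 360L, ca_area = NULL) {
  n <- length(positions)
  blank <- replicate(n, plaqueagree:::empty_arcs(), simplify = FALSE)
  ft <- tibble::tibble(
    subject_id = subject, vessel_id = vessel_id, modality = modality,
    position_mm = positions,
    lumen_area_mm2 = rep_len(lumen, n),
    vessel_area_mm2 = rep_len(vessel, n),
    lipid_arcs = if (is.null(lipid)) blank else lipid,
    ca_arcs = if (is.null(ca)) blank else ca,
    ft_arcs = blank, ff_arcs = blank)
  if (!is.null(ca_area)) ft$ca_area_mm2 <- rep_len(ca_area, n)
  as_frame_table(ft, n_bins = n_bins)
}

make_segment <- function(positions, lumen, vessel, ...) {
  ft <- make_frames(positions, lumen, vessel, ...)
  segment_record(ft, ft$subject_id[1], ft$vessel_id[1], ft$modality[1])
}

# a spread-out grid built directly from logical masks
make_plot <- function(lipid_mask, positions, ca_mask = NULL) {
  n_bins <- nrow(lipid_mask)
  empty <- matrix(FALSE, n_bins, ncol(lipid_mask))
  structure(list(masks = list(lipid = lipid_mask,
                              ca = if (is.null(ca_mask)) empty else ca_mask,
                              ft = empty, ff = empty),
                 positions = positions, n_bins = n_bins),
            class = "spreadout_plot")
}

# --- independent oracles ------------------------------------------------

trapz_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L)) {
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  }
  s
}

# exhaustive maximal-window maximum of the windowed lipid index: every
# (i, j) pair is tested for span <= window and non-extendability at both
# ends; O(n^2) by construction
maxlcbi_oracle <- function(counts, positions, n_bins, window = 4) {
  n <- length(positions)
  if (max(positions) - min(positions) < window) {
    return(1000 * sum(counts) / (n_bins * n))
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (positions[j] - positions[i] > window) break
      right_max <- j == n || positions[j + 1L] - positions[i] > window
      left_max <- i == 1L || positions[j] - positions[i - 1L] > window
      if (right_max && left_max) {
        val <- 1000 * sum(counts[i:j]) / (n_bins * (j - i + 1L))
        best <- max(best, val)
      }
    }
  }
  best
}

# run-and-merge fixpoint oracle for the lesion rule: enumerate maximal
# qualifying runs, merge pairwise until no two runs are mergeable, then
# keep groups containing a run of >= min_frames consecutive frames
lesion_oracle <- function(pb, positions, threshold = 40, min_frames = 3L,
                          gap_mm = 5) {
  qual <- pb >= threshold
  runs <- list()
  i <- 1L
  while (i <= length(qual)) {
    if (qual[i]) {
      j <- i
      while (j < length(qual) && qual[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- list(start = i, end = j,
                                        max_run = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0L) return(data.frame(start = integer(),
                                            end = integer()))
  repeat {
    merged <- FALSE
    for (a in seq_len(length(runs) - 1L)) {
      gap <- positions[runs[[a + 1L]]$start] - positions[runs[[a]]$end]
      if (gap < gap_mm) {
        runs[[a]] <- list(start = runs[[a]]$start, end = runs[[a + 1L]]$end,
                          max_run = max(runs[[a]]$max_run,
                                        runs[[a + 1L]]$max_run))
        runs[[a + 1L]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  keep <- Filter(function(r) r$max_run >= min_frames, runs)
  data.frame(start = vapply(keep, `[[`, integer(1L), "start"),
             end = vapply(keep, `[[`, integer(1L), "end"))
}

# pinball-loss minimiser by direct search over the data values
pinball_oracle <- function(x, tau) {
  loss <- vapply(x, function(q) {
    r <- x - q
    sum(r * (tau - (r < 0)))
  }, numeric(1L))
  min(x[abs(loss - min(loss)) < 1e-12])
}

# two-way ANOVA ICC(A,k) closed form (McGraw & Wong), unclipped
anova_icc_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  msr <- k * var(rowMeans(mat))
  msc <- n * var(colMeans(mat))
  sse <- sum((mat - mean(mat))^2) - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# Harrell's truncated-power restricted cubic spline written directly from
# the textbook formula, evaluated pointwise
rcs_oracle <- function(x, knots) {
  k <- length(knots)
  pp <- function(u) ifelse(u > 0, u^3, 0)
  sapply(seq_len(k - 1L), function(col) {
    if (col == 1L) return(x)
    j <- col - 1L
    (pp(x - knots[j]) -
       pp(x - knots[k - 1L]) * (knots[k] - knots[j]) /
         (knots[k] - knots[k - 1L]) +
       pp(x - knots[k]) * (knots[k - 1L] - knots[j]) /
         (knots[k] - knots[k - 1L])) / (knots[k] - knots[1L])^2
  })
}

quiet_max_lcbi <- function(plot, ...) {
  withCallingHandlers(max_lcbi_4mm(plot, ...),
                      warning = function(w) invokeRestart("muffleWarning"))
}
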