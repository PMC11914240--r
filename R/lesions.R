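#' Detect lesions from a plaque-burden profile
#'
#' A lesion is founded by at least `min_frames` consecutive frames with
#' plaque burden (PB) at or above `pb_threshold` percent. Two qualifying
#' runs belong to the same lesion when the sub-threshold gap between them
#' (last frame position of the earlier run to first frame position of the
#' later run) spans less than `merge_gap_mm`; a gap of `merge_gap_mm` or
#' more separates lesions. Merging chains transitively. Runs of fewer than
#' `min_frames` frames are absorbed into a neighbouring lesion when within
#' the merge distance, but can never found a lesion on their own.
#'
#' @param segment a `segment_record` with positive vessel areas.
#' @param pb_threshold qualifying plaque burden, percent.
#' @param min_frames minimum consecutive qualifying frames.
#' @param merge_gap_mm gap length separating lesions, mm.
#' @return tibble with one row per lesion: `lesion`, `start_frame`,
#'   `end_frame` (1-based inclusive indices into the ordered segment),
#'   `start_mm`, `end_mm`, `length_mm`, `n_frames`.
#' @export
detect_lesions <- function(segment, pb_threshold = 40, min_frames = 3L,
                           merge_gap_mm = 5) {
  stopifnot(inherits(segment, "segment_record"))
  fr <- segment$frames
  if (any(fr$vessel_area_mm2 <= 0)) {
    stop("plaque burden undefined: vessel_area must be positive")
  }
  pb <- 100 * (fr$vessel_area_mm2 - fr$lumen_area_mm2) / fr$vessel_area_mm2
  qual <- pb >= pb_threshold
  empty <- tibble::tibble(lesion = integer(), start_frame = integer(),
                          end_frame = integer(), start_mm = numeric(),
                          end_mm = numeric(), length_mm = numeric(),
                          n_frames = integer())
  if (!any(qual)) return(empty)

  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  # left-to-right chaining is already the fixpoint of pairwise merging
  group <- integer(nrow(runs))
  group[1L] <- 1L
  for (i in seq_len(nrow(runs))[-1L]) {
    gap <- fr$position_mm[runs$start[i]] - fr$position_mm[runs$end[i - 1L]]
    group[i] <- if (gap < merge_gap_mm) group[i - 1L] else group[i - 1L] + 1L
  }

  lesions <- lapply(split(runs, group), function(g) {
    if (max(g$end - g$start + 1L) < min_frames) return(NULL)
    tibble::tibble(start_frame = min(g$start), end_frame = max(g$end))
  })
  lesions <- dplyr::bind_rows(lesions)
  if (nrow(lesions) == 0L) return(empty)
  lesions$lesion <- seq_len(nrow(lesions))
  lesions$start_mm <- fr$position_mm[lesions$start_frame]
  lesions$end_mm <- fr$position_mm[lesions$end_frame]
  lesions$length_mm <- lesions$end_mm - lesions$start_mm
  lesions$n_frames <- lesions$end_frame - lesions$start_frame + 1L
  lesions[c("lesion", "start_frame", "end_frame", "start_mm", "end_mm",
            "length_mm", "n_frames")]
}

frame_pb <- function(fr) {
  100 * (fr$vessel_area_mm2 - fr$lumen_area_mm2) / fr$vessel_area_mm2
}

#' Lesion geometry: MLA, maximum PB, references and remodelling
#'
#' The minimum lumen area (MLA) and maximum plaque burden are scanned over
#' the lesion frames. The reference on each side is the least-diseased
#' frame (minimum PB) within `flank_mm` of the lesion edge, excluding
#' frames inside any detected lesion; reference lumen/vessel areas average
#' the two sides, falling back to a one-sided reference when only one side
#' has candidates. The remodelling index is the vessel area at the MLA
#' frame divided by the reference vessel area; reference fields are `NA`
#' (and `ref_sides = 0`) when no reference frame exists on either side.
#'
#' @param segment a `segment_record`.
#' @param lesion one row of the [detect_lesions()] table (or a list with
#'   `start_frame`, `end_frame`).
#' @param all_lesions the full [detect_lesions()] table for the segment,
#'   used to exclude lesion frames from references; defaults to the single
#'   lesion supplied.
#' @param flank_mm reference search distance beyond each lesion edge, mm.
#' @return list with `mla`, `mla_frame`, `max_pb`, `ref_lumen_area`,
#'   `ref_vessel_area`, `remodelling_index`, `ref_sides` (0, 1 or 2).
#' @export
lesion_geometry <- function(segment, lesion, all_lesions = NULL,
                            flank_mm = 5) {
  stopifnot(inherits(segment, "segment_record"))
  fr <- segment$frames
  pb <- frame_pb(fr)
  idx <- seq(lesion$start_frame, lesion$end_frame)
  mla_frame <- idx[which.min(fr$lumen_area_mm2[idx])]
  mla <- fr$lumen_area_mm2[mla_frame]
  max_pb <- max(pb[idx])

  if (is.null(all_lesions)) {
    all_lesions <- tibble::tibble(start_frame = lesion$start_frame,
                                  end_frame = lesion$end_frame)
  }
  in_lesion <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(all_lesions))) {
    in_lesion[seq(all_lesions$start_frame[i], all_lesions$end_frame[i])] <- TRUE
  }
  pos <- fr$position_mm
  prox <- which(!in_lesion & pos < pos[lesion$start_frame] &
                  pos >= pos[lesion$start_frame] - flank_mm)
  dist <- which(!in_lesion & pos > pos[lesion$end_frame] &
                  pos <= pos[lesion$end_frame] + flank_mm)
  ref_frames <- c(
    if (length(prox) > 0L) prox[which.min(pb[prox])],
    if (length(dist) > 0L) dist[which.min(pb[dist])]
  )
  if (length(ref_frames) == 0L) {
    ref_lumen <- ref_vessel <- ri <- NA_real_
  } else {
    ref_lumen <- mean(fr$lumen_area_mm2[ref_frames])
    ref_vessel <- mean(fr$vessel_area_mm2[ref_frames])
    ri <- fr$vessel_area_mm2[mla_frame] / ref_vessel
  }
  list(mla = mla, mla_frame = mla_frame, max_pb = max_pb,
       ref_lumen_area = ref_lumen, ref_vessel_area = ref_vessel,
       remodelling_index = ri, ref_sides = length(ref_frames))
}

#' Transfer NIRS-IVUS lesion spans onto the paired CTA frames
#'
#' Lesions are defined on NIRS-IVUS; the matched CTA cross-sections
#' covering the same span are classified as lesions on CTA regardless of
#' the CTA plaque burden. Frame indices within a segment equal pair
#' indices (frames are ordered by position on both sides), so the span
#' transfers index-for-index.
#'
#' @param lesions [detect_lesions()] table from the NIRS-IVUS segment.
#' @param dataset a `matched_dataset`.
#' @param segment_id `"subject:vessel"` identifier of the segment.
#' @return the lesion table with frame indices valid for the paired CTA
#'   segment (same `start_frame`/`end_frame`; positions re-read from the
#'   CTA frames).
#' @export
map_lesions_to_counterpart <- function(lesions, dataset, segment_id) {
  stopifnot(inherits(dataset, "matched_dataset"))
  pr <- dataset$pairs[dataset$pairs$segment_id == segment_id, ]
  if (nrow(pr) == 0L) stop("unknown segment: ", segment_id)
  out <- lesions
  if (nrow(lesions) > 0L && max(lesions$end_frame) > nrow(pr)) {
    stop("lesion span exceeds paired frames in segment ", segment_id,
         " (frame ", max(lesions$end_frame), " unpaired)")
  }
  cta_pos <- dataset$frames$position_mm[pr$cta_row[order(pr$pair)]]
  out$start_mm <- cta_pos[out$start_frame]
  out$end_mm <- cta_pos[out$end_frame]
  out$length_mm <- out$end_mm - out$start_mm
  out
}

lesion_subsegment <- function(segment, lesion) {
  sub <- segment
  sub$frames <- segment$frames[seq(lesion$start_frame, lesion$end_frame), ]
  sub$length_mm <- diff(range(sub$frames$position_mm))
  sub
}

#' Lesion table with full per-modality metrics
#'
#' Detects lesions on every NIRS-IVUS segment of a matched dataset, maps
#' each span to the paired CTA frames, and computes geometry
#' ([lesion_geometry()]) plus compositional metrics (LCBI, CaBI,
#' maxLCBI4mm, mean calcium area) on both modalities over the same span.
#'
#' @param dataset a `matched_dataset`.
#' @param pb_threshold,min_frames,merge_gap_mm passed to [detect_lesions()].
#' @param flank_mm passed to [lesion_geometry()].
#' @param ca_fallback passed to [mean_ca_area()].
#' @return tibble, one row per lesion per modality.
#' @export
lesion_table <- function(dataset, pb_threshold = 40, min_frames = 3L,
                         merge_gap_mm = 5, flank_mm = 5,
                         ca_fallback = "arc_fraction") {
  stopifnot(inherits(dataset, "matched_dataset"))
  segs <- unique(dataset$pairs[c("segment_id", "subject_id", "vessel_id")])
  rows <- list()
  for (i in seq_len(nrow(segs))) {
    nirs <- segment_record(dataset$frames, segs$subject_id[i],
                           segs$vessel_id[i], "NIRS_IVUS")
    cta <- segment_record(dataset$frames, segs$subject_id[i],
                          segs$vessel_id[i], "CTA")
    les <- detect_lesions(nirs, pb_threshold, min_frames, merge_gap_mm)
    if (nrow(les) == 0L) next
    les_cta <- map_lesions_to_counterpart(les, dataset, segs$segment_id[i])
    for (j in seq_len(nrow(les))) {
      for (mod in MODALITIES) {
        seg <- if (mod == "NIRS_IVUS") nirs else cta
        spans <- if (mod == "NIRS_IVUS") les else les_cta
        geo <- lesion_geometry(seg, spans[j, ], all_lesions = spans,
                               flank_mm = flank_mm)
        sub <- lesion_subsegment(seg, spans[j, ])
        sp <- build_spreadout(sub)
        cabi <- burden_index(sp, "ca")
        mlcbi <- withCallingHandlers(
          max_lcbi_4mm(sp),
          warning = function(w) invokeRestart("muffleWarning"))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          segment_id = segs$segment_id[i],
          subject_id = segs$subject_id[i],
          vessel_id = segs$vessel_id[i],
          lesion = spans$lesion[j],
          modality = mod,
          start_mm = spans$start_mm[j],
          end_mm = spans$end_mm[j],
          length_mm = spans$length_mm[j],
          n_frames = spans$n_frames[j],
          mla = geo$mla,
          max_pb = geo$max_pb,
          ref_lumen_area = geo$ref_lumen_area,
          ref_vessel_area = geo$ref_vessel_area,
          remodelling_index = geo$remodelling_index,
          ref_sides = geo$ref_sides,
          lcbi = burden_index(sp, "lipid"),
          cabi = cabi,
          max_lcbi_4mm = mlcbi,
          mean_ca_area = mean_ca_area(sub, fallback = ca_fallback),
          mean_ca_arc = ca_arc_from_cabi(cabi)
        )
      }
    }
  }
  if (length(rows) == 0L) return(tibble::tibble())
  dplyr::bind_rows(rows)
}
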