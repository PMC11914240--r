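#' Frame tables: the canonical paired-modality annotation schema
#'
#' One row per analysed cross-section. Mandatory columns:
#' `subject_id`, `vessel_id` (character), `modality` (`"NIRS_IVUS"` or
#' `"CTA"`), `position_mm` (longitudinal distance from the proximal end of
#' the segment of interest, increasing towards the distal end),
#' `lumen_area_mm2`, `vessel_area_mm2` (EEM area on IVUS, outer wall on
#' CTA). Tissue annotations are circumferential arcs (see [arcs]):
#' `lipid_arcs`, `ca_arcs`, `ft_arcs`, `ff_arcs` as list-columns of arc
#' matrices in memory and `"start:stop"` degree-range strings on disk.
#' Optional per-tissue cross-sectional areas (CTA plaque composition):
#' `lipid_area_mm2`, `ca_area_mm2`, `ft_area_mm2`, `ff_area_mm2`.
#'
#' @param frames data frame in the schema above (arc columns either
#'   serialised strings or list-columns of arc matrices).
#' @param n_bins angular resolution shared by every frame of a dataset.
#' @return `as_frame_table()` returns a tibble with arc list-columns and an
#'   `n_bins` attribute.
#' @export
as_frame_table <- function(frames, n_bins = 360L) {
  required <- c("subject_id", "vessel_id", "modality", "position_mm",
                "lumen_area_mm2", "vessel_area_mm2")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0L) {
    stop("frame table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(frames$modality), MODALITIES)
  if (length(bad) > 0L) {
    stop("unknown modality value(s): ", paste(bad, collapse = ", "))
  }
  ft <- tibble::as_tibble(frames)
  ft$subject_id <- as.character(ft$subject_id)
  ft$vessel_id <- as.character(ft$vessel_id)
  for (tis in TISSUES) {
    col <- paste0(tis, "_arcs")
    if (!col %in% names(ft)) {
      ft[[col]] <- replicate(nrow(ft), empty_arcs(), simplify = FALSE)
    } else if (is.character(ft[[col]])) {
      ft[[col]] <- lapply(ft[[col]], decode_arcs, n_bins = n_bins)
    } else {
      ft[[col]] <- lapply(ft[[col]], check_arcs, n_bins = n_bins)
    }
  }
  attr(ft, "n_bins") <- as.integer(n_bins)
  ft
}

#' @rdname as_frame_table
#' @export
frame_n_bins <- function(frames) {
  nb <- attr(frames, "n_bins")
  if (is.null(nb)) 360L else as.integer(nb)
}

#' Read and write frame tables
#'
#' The canonical on-disk forms are a flat CSV (one row per frame, arcs as
#' `"start:stop"` degree ranges joined by `";"`) and a JSON mirror nested
#' as subject / vessel / modality / frames. Both are UTF-8; the CSV has a
#' mandatory header row. `write_frame_table()` followed by
#' `read_frame_table()` reproduces the table exactly.
#'
#' @param path file path.
#' @param n_bins angular resolution used to validate arcs.
#' @return a frame table tibble (see [as_frame_table()]).
#' @export
read_frame_table <- function(path, n_bins = 360L) {
  arc_cols <- paste0(TISSUES, "_arcs")
  spec <- do.call(readr::cols,
                  setNames(rep(list(readr::col_character()),
                               length(arc_cols)), arc_cols))
  raw <- readr::read_csv(path, col_types = spec, show_col_types = FALSE,
                         progress = FALSE)
  for (col in intersect(arc_cols, names(raw))) {
    raw[[col]][is.na(raw[[col]])] <- ""
  }
  as_frame_table(raw, n_bins = n_bins)
}

#' @rdname read_frame_table
#' @param frames frame table.
#' @export
write_frame_table <- function(frames, path) {
  frames <- as_frame_table(frames, n_bins = frame_n_bins(frames))
  out <- frames
  for (tis in TISSUES) {
    col <- paste0(tis, "_arcs")
    out[[col]] <- vapply(out[[col]], encode_arcs, character(1L))
  }
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], format_num)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_frame_table
#' @export
write_frames_json <- function(frames, path) {
  frames <- as_frame_table(frames, n_bins = frame_n_bins(frames))
  arc_cols <- paste0(TISSUES, "_arcs")
  nest <- lapply(split(frames, frames$subject_id), function(sub) {
    lapply(split(sub, sub$vessel_id), function(ves) {
      lapply(split(ves, ves$modality), function(m) {
        m <- m[order(m$position_mm), ]
        rows <- lapply(seq_len(nrow(m)), function(i) {
          rec <- as.list(m[i, setdiff(names(m), c("subject_id", "vessel_id",
                                                  "modality", arc_cols))])
          for (col in arc_cols) rec[[col]] <- encode_arcs(m[[col]][[i]])
          rec
        })
        rows
      })
    })
  })
  jsonlite::write_json(list(n_bins = frame_n_bins(frames), subjects = nest),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname read_frame_table
#' @export
read_frames_json <- function(path) {
  doc <- jsonlite::read_json(path)
  n_bins <- as.integer(doc$n_bins)
  rows <- list()
  for (sid in names(doc$subjects)) {
    for (vid in names(doc$subjects[[sid]])) {
      for (mod in names(doc$subjects[[sid]][[vid]])) {
        for (rec in doc$subjects[[sid]][[vid]][[mod]]) {
          rec[vapply(rec, is.null, logical(1L))] <- NA  # JSON null -> NA
          num <- grepl("_mm2?$|^position", names(rec))
          rec[num] <- lapply(rec[num], as.numeric)
          rec <- c(list(subject_id = sid, vessel_id = vid, modality = mod),
                   rec)
          rows[[length(rows) + 1L]] <- tibble::as_tibble(rec)
        }
      }
    }
  }
  as_frame_table(dplyr::bind_rows(rows), n_bins = n_bins)
}

#' Pair NIRS-IVUS and CTA frames into a matched dataset
#'
#' Matching itself (co-registration) happens upstream; this constructor
#' receives a frame table in which each (subject, vessel) carries the same
#' number of frames per modality, already in corresponding order, and
#' records the pairing explicitly. Segments of interest are identified by
#' `subject_id:vessel_id`.
#'
#' @param frames frame table containing both modalities.
#' @return an object of class `matched_dataset`: list with `frames` (the
#'   frame table) and `pairs` (tibble with `segment_id`, `subject_id`,
#'   `vessel_id`, `pair`, `nirs_row`, `cta_row` row indices into `frames`).
#' @export
matched_dataset <- function(frames) {
  frames <- as_frame_table(frames, n_bins = frame_n_bins(frames))
  key <- paste(frames$subject_id, frames$vessel_id, sep = ":")
  pairs <- lapply(split(seq_len(nrow(frames)), key), function(idx) {
    sub <- frames[idx, ]
    n_idx <- idx[sub$modality == "NIRS_IVUS"]
    c_idx <- idx[sub$modality == "CTA"]
    if (length(n_idx) != length(c_idx)) {
      stop("segment ", key[idx[1L]], " has ", length(n_idx),
           " NIRS-IVUS frames but ", length(c_idx), " CTA frames")
    }
    n_idx <- n_idx[order(frames$position_mm[n_idx])]
    c_idx <- c_idx[order(frames$position_mm[c_idx])]
    tibble::tibble(
      segment_id = key[idx[1L]],
      subject_id = frames$subject_id[idx[1L]],
      vessel_id = frames$vessel_id[idx[1L]],
      pair = seq_along(n_idx),
      nirs_row = n_idx,
      cta_row = c_idx
    )
  })
  structure(list(frames = frames, pairs = dplyr::bind_rows(pairs)),
            class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  cat("<matched_dataset>\n",
      "  segments: ", length(unique(x$pairs$segment_id)), "\n",
      "  matched cross-sections: ", nrow(x$pairs), "\n", sep = "")
  invisible(x)
}

#' Validate a matched dataset against the schema invariants
#'
#' Pure reporting operation: returns a tibble with one row per violation
#' (empty when all invariants hold) naming the segment, frame position,
#' field, and rule violated. Checked rules: `vessel_area >= lumen_area >= 0`,
#' strictly increasing positions within each segment and modality, arcs
#' within the configured angular range, and (when per-tissue areas are
#' present) tissue-area sum not exceeding plaque area beyond `tol`.
#'
#' @param dataset a `matched_dataset` or a frame table.
#' @param tol absolute tolerance (mm^2) for the tissue-area sum check.
#' @return tibble with columns `segment_id`, `modality`, `position_mm`,
#'   `field`, `rule`.
#' @export
validate_dataset <- function(dataset, tol = 1e-6) {
  frames <- if (inherits(dataset, "matched_dataset")) dataset$frames else
    as_frame_table(dataset, n_bins = frame_n_bins(dataset))
  n_bins <- frame_n_bins(frames)
  viol <- list()
  note <- function(seg, mod, pos, field, rule) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      segment_id = seg, modality = mod, position_mm = pos,
      field = field, rule = rule)
  }
  seg <- paste(frames$subject_id, frames$vessel_id, sep = ":")

  bad <- which(frames$lumen_area_mm2 < 0)
  for (i in bad) note(seg[i], frames$modality[i], frames$position_mm[i],
                      "lumen_area_mm2", "lumen_area >= 0")
  bad <- which(frames$vessel_area_mm2 < frames$lumen_area_mm2)
  for (i in bad) note(seg[i], frames$modality[i], frames$position_mm[i],
                      "vessel_area_mm2", "vessel_area >= lumen_area")

  for (idx in split(seq_len(nrow(frames)), paste(seg, frames$modality))) {
    pos <- sort(frames$position_mm[idx])
    if (length(idx) > 1L && any(diff(pos) <= 0)) {
      i <- idx[1L]
      note(seg[i], frames$modality[i], pos[which(diff(pos) <= 0)[1L]],
           "position_mm", "positions strictly increasing")
    }
  }

  for (tis in TISSUES) {
    col <- paste0(tis, "_arcs")
    ok <- vapply(frames[[col]], function(a) {
      nrow(a) == 0L || (min(a[, 1L]) >= 0 && max(a[, 2L]) <= n_bins)
    }, logical(1L))
    for (i in which(!ok)) note(seg[i], frames$modality[i],
                               frames$position_mm[i], col,
                               paste0("arcs within [0, ", n_bins, "]"))
  }

  area_cols <- intersect(paste0(TISSUES, "_area_mm2"), names(frames))
  if (length(area_cols) > 0L) {
    tot <- rowSums(as.matrix(frames[area_cols]), na.rm = TRUE)
    has <- rowSums(!is.na(as.matrix(frames[area_cols]))) > 0L
    plaque <- frames$vessel_area_mm2 - frames$lumen_area_mm2
    bad <- which(has & tot > plaque + tol)
    for (i in bad) note(seg[i], frames$modality[i], frames$position_mm[i],
                        "tissue areas", "sum(tissue areas) <= plaque area")
  }

  if (length(viol) == 0L) {
    tibble::tibble(segment_id = character(), modality = character(),
                   position_mm = numeric(), field = character(),
                   rule = character())
  } else {
    dplyr::bind_rows(viol)
  }
}

#' Extract one segment of interest as an ordered record
#'
#' @param frames frame table.
#' @param subject_id,vessel_id,modality segment selector.
#' @return a `segment_record`: list with the selected frames ordered by
#'   position, plus `length_mm` and `n_bins`.
#' @export
segment_record <- function(frames, subject_id, vessel_id, modality) {
  sel <- frames$subject_id == subject_id & frames$vessel_id == vessel_id &
    frames$modality == modality
  sub <- frames[sel, ]
  if (nrow(sub) < 2L) {
    stop("segment ", subject_id, ":", vessel_id, " [", modality,
         "] needs at least 2 frames")
  }
  sub <- sub[order(sub$position_mm), ]
  if (any(diff(sub$position_mm) <= 0)) {
    stop("segment positions must be strictly increasing")
  }
  structure(list(frames = sub,
                 subject_id = subject_id, vessel_id = vessel_id,
                 modality = modality,
                 length_mm = diff(range(sub$position_mm)),
                 n_bins = frame_n_bins(frames)),
            class = "segment_record")
}

#' @rdname segment_record
#' @param dataset a `matched_dataset`.
#' @return `dataset_segments()`: tibble with one row per
#'   (segment, modality) and a `record` list-column of `segment_record`s.
#' @export
dataset_segments <- function(dataset) {
  stopifnot(inherits(dataset, "matched_dataset"))
  segs <- unique(dataset$pairs[c("segment_id", "subject_id", "vessel_id")])
  grid <- tidyr::expand_grid(segs, modality = MODALITIES)
  grid$record <- lapply(seq_len(nrow(grid)), function(i) {
    segment_record(dataset$frames, grid$subject_id[i], grid$vessel_id[i],
                   grid$modality[i])
  })
  grid
}
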