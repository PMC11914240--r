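# segments engineered through the lumen/vessel areas: vessel 10 throughout,
# lumen set so PB = 100*(10-lumen)/10 takes the values we want
pb_segment <- function(pb, spacing = 0.5) {
  make_segment(positions = (seq_along(pb) - 1) * spacing,
               lumen = 10 * (1 - pb / 100), vessel = 10)
}

test_that("lesion detection applies the run-and-merge rule", {
  expect_identical(nrow(detect_lesions(pb_segment(rep(30, 20)))), 0L)

  pb <- c(rep(20, 5), rep(55, 10), rep(20, 5))
  les <- detect_lesions(pb_segment(pb))
  expect_identical(nrow(les), 1L)
  expect_identical(c(les$start_frame, les$end_frame), c(6L, 15L))

  # two 5-frame runs, 3 mm sub-threshold gap -> merged (gap < 5 mm)
  mk <- function(gap_frames) {
    c(rep(50, 5), rep(20, gap_frames), rep(50, 5))
  }
  merged <- detect_lesions(pb_segment(mk(6)))   # gap spans 3.5 mm
  expect_identical(nrow(merged), 1L)
  expect_identical(c(merged$start_frame, merged$end_frame), c(1L, 16L))

  # 6.5 mm gap -> separate lesions
  split2 <- detect_lesions(pb_segment(mk(12)))
  expect_identical(nrow(split2), 2L)

  # gap of exactly 5 mm separates (merge iff gap < 5)
  exact <- detect_lesions(pb_segment(mk(9)))    # gap spans 5.0 mm
  expect_identical(nrow(exact), 2L)

  # 1-2 frame runs never found a lesion but are absorbed by a merge
  tiny <- detect_lesions(pb_segment(c(rep(50, 2), rep(20, 18))))
  expect_identical(nrow(tiny), 0L)
  absorbed <- detect_lesions(pb_segment(c(rep(50, 2), rep(20, 2),
                                          rep(50, 5), rep(20, 10))))
  expect_identical(nrow(absorbed), 1L)
  expect_identical(absorbed$start_frame, 1L)
})

test_that("detection matches the brute-force fixpoint oracle on random profiles", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    spacing <- sample(c(0.5, 1, 1.25), 1)
    pb <- runif(n, 0, 80)
    # sprinkle exact-threshold and plateau values to hit edge cases
    pb[sample(n, ceiling(n / 5))] <- 40
    seg <- pb_segment(pb, spacing)
    got <- detect_lesions(seg)
    want <- lesion_oracle(pb, seg$frames$position_mm)
    expect_identical(got$start_frame, as.integer(want$start))
    expect_identical(got$end_frame, as.integer(want$end))
  }
})

test_that("lesion spans are disjoint, sorted, and reflect under reversal", {
  set.seed(15)
  for (i in 1:25) {
    n <- 40L
    pb <- runif(n, 10, 70)
    seg <- pb_segment(pb)
    les <- detect_lesions(seg)
    if (nrow(les) > 1) {
      expect_true(all(diff(les$start_frame) > 0))
      expect_true(all(les$start_frame[-1] > les$end_frame[-nrow(les)]))
    }
    seg_rev <- pb_segment(rev(pb))
    les_rev <- detect_lesions(seg_rev)
    expect_identical(nrow(les), nrow(les_rev))
    if (nrow(les) > 0) {
      expect_identical(sort(n + 1L - les_rev$end_frame), les$start_frame)
    }
  }
})

test_that("chained runs with all gaps under 5 mm collapse to one lesion", {
  pb <- rep(c(rep(50, 3), rep(20, 4)), 5)  # gaps of 2.5 mm at 0.5 mm spacing
  les <- detect_lesions(pb_segment(pb))
  expect_identical(nrow(les), 1L)
})

test_that("lesion geometry recovers constants and handles edges", {
  # flat lesion with flat references
  pb <- c(rep(20, 4), rep(60, 5), rep(20, 4))
  seg <- pb_segment(pb)
  les <- detect_lesions(seg)
  geo <- lesion_geometry(seg, les[1, ], all_lesions = les)
  expect_equal(geo$mla, 4)          # lumen at PB 60 on vessel 10
  expect_equal(geo$max_pb, 60)
  expect_equal(geo$ref_lumen_area, 8)
  expect_equal(geo$ref_vessel_area, 10)
  expect_equal(geo$remodelling_index, 1)
  expect_identical(geo$ref_sides, 2L)

  # lesion at the proximal edge: one-sided (distal) reference
  pb <- c(rep(60, 5), rep(20, 8))
  seg <- pb_segment(pb)
  les <- detect_lesions(seg)
  geo <- lesion_geometry(seg, les[1, ], all_lesions = les)
  expect_identical(geo$ref_sides, 1L)
  expect_equal(geo$ref_vessel_area, 10)

  # no reference on either side: fields flagged missing, geometry kept
  pb <- rep(60, 6)
  seg <- pb_segment(pb)
  les <- detect_lesions(seg)
  geo <- lesion_geometry(seg, les[1, ], all_lesions = les)
  expect_identical(geo$ref_sides, 0L)
  expect_true(is.na(geo$remodelling_index))
  expect_equal(geo$max_pb, 60)
})

test_that("lesion geometry equals a straight-line scan oracle on random data", {
  set.seed(16)
  for (i in 1:30) {
    n <- 30
    lum <- runif(n, 2, 9)
    ves <- lum + runif(n, 0.5, 9)
    pos <- (seq_len(n) - 1) * 0.5
    seg <- make_segment(pos, lum, ves)
    les <- detect_lesions(seg)
    if (nrow(les) == 0) next
    pb <- 100 * (ves - lum) / ves
    l <- les[1, ]
    geo <- lesion_geometry(seg, l, all_lesions = les)
    idx <- l$start_frame:l$end_frame
    expect_equal(geo$mla, min(lum[idx]))
    expect_equal(geo$max_pb, max(pb[idx]))
    in_lesion <- rep(FALSE, n)
    for (j in seq_len(nrow(les))) {
      in_lesion[les$start_frame[j]:les$end_frame[j]] <- TRUE
    }
    cand_p <- which(!in_lesion & pos < pos[l$start_frame] &
                      pos >= pos[l$start_frame] - 5)
    cand_d <- which(!in_lesion & pos > pos[l$end_frame] &
                      pos <= pos[l$end_frame] + 5)
    refs <- c(if (length(cand_p)) cand_p[which.min(pb[cand_p])],
              if (length(cand_d)) cand_d[which.min(pb[cand_d])])
    if (length(refs)) {
      expect_equal(geo$ref_vessel_area, mean(ves[refs]))
      mla_frame <- idx[which.min(lum[idx])]
      expect_equal(geo$remodelling_index, ves[mla_frame] / mean(ves[refs]))
    } else {
      expect_identical(geo$ref_sides, 0L)
    }
  }
})

test_that("lesion spans transfer to CTA index-for-index regardless of CTA burden", {
  nirs_pb <- c(rep(20, 4), rep(60, 6), rep(20, 4))
  n <- length(nirs_pb)
  pos <- (seq_len(n) - 1) * 0.5
  nirs <- make_frames(pos, 10 * (1 - nirs_pb / 100), 10)
  cta <- make_frames(pos, 8, 10, modality = "CTA")  # CTA PB 20% throughout
  ds <- matched_dataset(dplyr::bind_rows(nirs, cta))
  seg <- segment_record(ds$frames, "S1", "V1", "NIRS_IVUS")
  les <- detect_lesions(seg)
  mapped <- map_lesions_to_counterpart(les, ds, "S1:V1")
  expect_identical(mapped$start_frame, les$start_frame)
  expect_identical(mapped$end_frame, les$end_frame)
  # the CTA side is still treated as a lesion in the joint table
  tab <- lesion_table(ds)
  expect_identical(sort(unique(tab$modality)), sort(c("CTA", "NIRS_IVUS")))
  expect_true(all(tab$max_pb[tab$modality == "CTA"] < 40))
  expect_error(map_lesions_to_counterpart(les, ds, "S9:V9"),
               "unknown segment")
})
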