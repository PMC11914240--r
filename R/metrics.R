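#' Segment-level volumes and atheroma burden
#'
#' Lumen and vessel volumes are trapezoidal integrals of the per-frame
#' areas over longitudinal position (handles irregular end-diastolic
#' frame spacing); total atheroma volume (TAV) is vessel minus lumen
#' volume and percent atheroma volume (PAV) is `100 x TAV / vessel
#' volume`.
#'
#' @param segment a `segment_record` with at least 2 frames.
#' @return list with `lumen_volume`, `vessel_volume`, `tav` (mm^3), and
#'   `pav` (percent).
#' @export
compute_volumes <- function(segment) {
  stopifnot(inherits(segment, "segment_record"))
  fr <- segment$frames
  if (nrow(fr) < 2L) stop("volume integration needs at least 2 frames")
  lumen <- pracma::trapz(fr$position_mm, fr$lumen_area_mm2)
  vessel <- pracma::trapz(fr$position_mm, fr$vessel_area_mm2)
  if (vessel <= 0) stop("vessel volume is zero; PAV undefined")
  tav <- vessel - lumen
  list(lumen_volume = lumen, vessel_volume = vessel, tav = tav,
       pav = 100 * tav / vessel)
}

#' Mean calcium area of a segment
#'
#' Calcium volume (trapezoidal integral of per-frame calcium area)
#' divided by segment length. Per-frame calcium areas come from the
#' `ca_area_mm2` column when present (CTA plaque composition); when
#' absent, `fallback = "arc_fraction"` derives them as the calcium arc
#' fraction times the plaque area of the frame.
#'
#' @param segment a `segment_record`.
#' @param fallback `"none"` (error when areas missing) or `"arc_fraction"`.
#' @return mean calcium area, mm^2.
#' @export
mean_ca_area <- function(segment, fallback = c("none", "arc_fraction")) {
  stopifnot(inherits(segment, "segment_record"))
  fallback <- match.arg(fallback)
  fr <- segment$frames
  ca <- if ("ca_area_mm2" %in% names(fr)) fr$ca_area_mm2 else
    rep(NA_real_, nrow(fr))
  if (anyNA(ca)) {
    if (fallback == "none") {
      stop("per-frame calcium areas missing and no fallback configured")
    }
    frac <- vapply(fr$ca_arcs, arc_extent, numeric(1L)) / segment$n_bins
    plaque <- fr$vessel_area_mm2 - fr$lumen_area_mm2
    ca[is.na(ca)] <- (frac * plaque)[is.na(ca)]
  }
  pracma::trapz(fr$position_mm, ca) / segment$length_mm
}

#' All segment-level metrics in one call
#'
#' @param segment a `segment_record`.
#' @param ca_fallback passed to [mean_ca_area()].
#' @return one-row tibble with `lumen_volume`, `vessel_volume`, `tav`,
#'   `pav`, `lcbi`, `cabi`, `max_lcbi_4mm`, `mean_ca_area`,
#'   `mean_ca_arc`.
#' @export
segment_metrics <- function(segment, ca_fallback = "arc_fraction") {
  vols <- compute_volumes(segment)
  sp <- build_spreadout(segment)
  cabi <- burden_index(sp, "ca")
  tibble::tibble(
    subject_id = segment$subject_id,
    vessel_id = segment$vessel_id,
    modality = segment$modality,
    length_mm = segment$length_mm,
    lumen_volume = vols$lumen_volume,
    vessel_volume = vols$vessel_volume,
    tav = vols$tav,
    pav = vols$pav,
    lcbi = burden_index(sp, "lipid"),
    cabi = cabi,
    max_lcbi_4mm = max_lcbi_4mm(sp),
    mean_ca_area = mean_ca_area(segment, fallback = ca_fallback),
    mean_ca_arc = ca_arc_from_cabi(cabi)
  )
}

#' Hounsfield-unit cut-off configuration for CTA plaque composition
#'
#' CTA plaque composition is classified per voxel/sample by HU interval:
#' necrotic core (NC) below the first threshold, fibro-fatty (FF) and
#' fibrotic (FT) between, calcium (CA) at and above the last. The shipped
#' defaults (76 / 131 / 351 HU) follow the commonly used histology-derived
#' cut-offs from the CT plaque-characterisation literature and are
#' deliberately configuration, not constants.
#'
#' @param nc_ff,ff_ft,ft_ca strictly increasing HU thresholds.
#' @return object of class `hu_cutoffs`.
#' @export
hu_cutoffs <- function(nc_ff = 76, ff_ft = 131, ft_ca = 351) {
  th <- c(nc_ff = nc_ff, ff_ft = ff_ft, ft_ca = ft_ca)
  if (any(!is.finite(th)) || any(diff(th) <= 0)) {
    stop("HU thresholds must be finite and strictly increasing")
  }
  structure(list(thresholds = th), class = "hu_cutoffs")
}

#' Classify HU samples into plaque tissue types
#'
#' Interval membership is half-open `[low, high)`: a value exactly at a
#' threshold belongs to the upper class.
#'
#' @param hu numeric vector of Hounsfield units.
#' @param config a [hu_cutoffs()] object.
#' @return factor with levels `NC`, `FF`, `FT`, `CA`.
#' @export
classify_hu <- function(hu, config = hu_cutoffs()) {
  stopifnot(inherits(config, "hu_cutoffs"))
  if (any(!is.finite(hu))) stop("HU values must be finite")
  classes <- c("NC", "FF", "FT", "CA")
  idx <- findInterval(hu, config$thresholds) + 1L
  factor(classes[idx], levels = classes)
}
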