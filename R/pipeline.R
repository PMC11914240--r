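#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Exactly one input
#' source is used: an in-memory `matched_dataset`, a frame-table CSV
#' path, or a synthetic-cohort spec/preset name.
#'
#' @param dataset optional `matched_dataset`.
#' @param input optional frame-table CSV path.
#' @param preset optional [scenario_preset()] name.
#' @param spec optional [cohort_spec()] (overrides `preset`).
#' @param levels analysis levels to run, subset of
#'   `c("segment", "lesion", "frame")`.
#' @param strata stratification scheme for the calcium groups
#'   (`"terciles"` or `"deciles"`).
#' @param n_knots named RCS knot counts per level.
#' @param boot bootstrap resamples for unadjusted ICC CIs (closed-form
#'   engine; cheap).
#' @param boot_adjusted bootstrap resamples for adjusted (mixed-model)
#'   ICC CIs; 0 skips the adjusted CI and the overlap comparison.
#' @param seed mandatory seed for every stochastic step.
#' @param output_dir directory for the report bundle; `NULL` returns
#'   results without writing.
#' @param pb_threshold,min_frames,merge_gap_mm,flank_mm lesion policy.
#' @param ca_fallback per-frame calcium source fallback, see
#'   [mean_ca_area()].
#' @param model_vars named list of variables to model per level.
#' @param cluster_models use subject-clustered robust interaction tests
#'   at frame level.
#' @param verbose stage-level logging.
#' @return a `run_config` list.
#' @export
run_config <- function(dataset = NULL, input = NULL, preset = NULL,
                       spec = NULL,
                       levels = c("segment", "lesion", "frame"),
                       strata = "terciles",
                       n_knots = c(segment = 3L, lesion = 3L, frame = 5L),
                       boot = 200L, boot_adjusted = 0L, seed = NULL,
                       output_dir = NULL,
                       pb_threshold = 40, min_frames = 3L,
                       merge_gap_mm = 5, flank_mm = 5,
                       ca_fallback = "arc_fraction",
                       model_vars = list(segment = "pav",
                                         lesion = "max_pb",
                                         frame = c("lumen_area", "pb")),
                       cluster_models = TRUE, verbose = TRUE) {
  if (is.null(seed)) stop("a seed is mandatory")
  levels <- match.arg(levels, several.ok = TRUE)
  if (!all(n_knots %in% c(3L, 5L))) stop("knot counts must be 3 or 5")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

level_variables <- list(
  segment = c("lumen_volume", "vessel_volume", "tav", "pav", "lcbi",
              "cabi", "max_lcbi_4mm"),
  lesion = c("mla", "max_pb", "ref_lumen_area", "ref_vessel_area",
             "remodelling_index", "lcbi", "cabi", "max_lcbi_4mm"),
  frame = c("lumen_area", "vessel_area", "plaque_area", "pb",
            "lipid_frac", "ca_frac")
)

# wide table (one row per unit, NIRS/CTA columns) -> tidy agreement rows
agree_one_level <- function(wide, level, variables, ca_cov, cfg) {
  ba_mode <- if (level == "frame") "parametric" else "nonparametric"
  knots <- cfg$n_knots[[level]]
  strat <- stratify(ca_cov, cfg$strata)
  out <- list()
  het <- list()
  for (v in variables) {
    x <- wide[[paste0(v, "_nirs")]]
    y <- wide[[paste0(v, "_cta")]]
    keep <- complete.cases(x, y)
    xs <- x[keep]; ys <- y[keep]
    long <- tibble::tibble(
      unit = rep(wide$unit[keep], 2L),
      cluster = rep(wide$cluster[keep], 2L),
      modality = rep(MODALITIES, each = sum(keep)),
      value = c(xs, ys),
      ca_cov = rep(ca_cov[keep], 2L))
    p_wsr <- tryCatch(wilcoxon_paired(xs, ys), error = function(e) NA_real_)
    ba <- bland_altman(xs - ys, mode = ba_mode)
    icc_u <- icc_mixed(long, ci_boot = cfg$boot, cluster = "cluster",
                       seed = cfg$seed + 17L)
    icc_a <- icc_mixed(long, covariate = "ca_cov", n_knots = knots,
                       ci_boot = cfg$boot_adjusted, cluster = "cluster",
                       seed = cfg$seed + 29L)
    sig <- if (cfg$boot_adjusted > 0L && cfg$boot > 0L) {
      compare_adjusted_icc(icc_u, icc_a)
    } else NA
    row <- function(stratum, n, p, bb, ic, note = "") {
      tibble::tibble(level = level, variable = v, stratum = stratum,
                     n = n, p_value = p, bias = bb$bias,
                     loa_low = bb$loa_low, loa_high = bb$loa_high,
                     ba_mode = bb$mode, icc = ic$icc,
                     icc_lo = ic$ci[1], icc_hi = ic$ci[2],
                     icc_band = as.character(icc_band(ic$icc)),
                     note = note)
    }
    out[[length(out) + 1L]] <- row("all", sum(keep), p_wsr, ba, icc_u)
    out[[length(out) + 1L]] <- row(
      "all_adjusted", sum(keep), p_wsr, ba, icc_a,
      note = paste0("rcs", knots, "-adjusted ICC; CI-overlap significant: ",
                    sig))
    # per-stratum agreement and heterogeneity of the stratum ICCs
    st_icc <- list()
    for (g in levels(strat)) {
      sel <- keep & strat == g
      if (sum(sel) < 5L) next
      lg <- long[long$unit %in% wide$unit[sel], ]
      icc_g <- tryCatch(
        icc_mixed(lg, ci_boot = cfg$boot, cluster = "cluster",
                  seed = cfg$seed + 31L),
        error = function(e) NULL)
      if (is.null(icc_g)) next
      ba_g <- bland_altman(x[sel] - y[sel], mode = ba_mode)
      p_g <- tryCatch(wilcoxon_paired(x[sel], y[sel]),
                      error = function(e) NA_real_)
      out[[length(out) + 1L]] <- row(paste0("ca_", g), sum(sel), p_g,
                                     ba_g, icc_g)
      st_icc[[g]] <- icc_g
    }
    if (length(st_icc) >= 2L) {
      hp <- tryCatch({
        h <- icc_heterogeneity(
          vapply(st_icc, `[[`, numeric(1L), "icc"),
          vapply(st_icc, function(z) z$ci[1], numeric(1L)),
          vapply(st_icc, function(z) z$ci[2], numeric(1L)))
        tibble::tibble(level = level, variable = v, Q = h$Q, df = h$df,
                       tau2 = h$tau2, p_heterogeneity = h$p_value)
      }, error = function(e) NULL)
      if (!is.null(hp)) het[[length(het) + 1L]] <- hp
    }
  }
  list(agreement = dplyr::bind_rows(out),
       heterogeneity = dplyr::bind_rows(het))
}

models_one_level <- function(wide, level, variables, ca_cov, cfg) {
  knots <- cfg$n_knots[[level]]
  cl <- if (level == "frame" && cfg$cluster_models) wide$cluster else NULL
  fits <- list()
  curves <- list()
  for (v in variables) {
    x <- wide[[paste0(v, "_nirs")]]
    y <- wide[[paste0(v, "_cta")]]
    keep <- complete.cases(x, y, ca_cov)
    fit <- tryCatch({
      if (level == "frame") {
        fit_ols_interaction(x[keep], y[keep], ca_cov[keep],
                            n_knots = knots, cluster = cl[keep])
      } else {
        fit_prop_odds(x[keep], y[keep], ca_cov[keep], n_knots = knots,
                      cluster = NULL)
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      stop("model stage failed for ", level, "/", v, ": ",
           conditionMessage(fit))
    }
    fits[[v]] <- list(model = fit$model, n = fit$n,
                      interaction_p = fit$interaction_p,
                      coefficients = fit$coefficients)
    cv <- difference_curves(fit)
    cv$level <- level
    cv$variable <- v
    curves[[v]] <- cv
  }
  list(fits = fits, curves = dplyr::bind_rows(curves))
}

#' Run the full multi-level comparison pipeline
#'
#' Executes metrics, lesion detection, agreement statistics, and
#' interaction models for each requested level, and (when `output_dir`
#' is set) writes the tidy report bundle: per-level metric tables,
#' the agreement table (bias, limits of agreement, Wilcoxon p, ICC with
#' CI, per-calcium-stratum rows), the stratum-heterogeneity table, the
#' model report JSON, difference-curve CSV, and a run manifest (package
#' version, seed, configuration hash, record counts). Identical
#' configuration and seed reproduce every output file byte-identically.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the report tables and, if written,
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  say <- function(...) if (cfg$verbose) message("[plaqueagree] ", ...)

  # ---- input stage ----
  if (!is.null(cfg$dataset)) {
    ds <- cfg$dataset
    say("using in-memory dataset")
  } else if (!is.null(cfg$input)) {
    say("reading ", cfg$input)
    ds <- matched_dataset(read_frame_table(cfg$input))
  } else {
    sp <- cfg$spec
    if (is.null(sp)) {
      sp <- scenario_preset(if (is.null(cfg$preset)) "paper-like" else
        cfg$preset, seed = cfg$seed)
    }
    say("generating synthetic cohort (", sp$n_subjects, " subjects)")
    ds <- generate_cohort(sp)$dataset
  }
  viol <- validate_dataset(ds)
  if (nrow(viol) > 0L) {
    stop("validation stage: ", nrow(viol), " invariant violation(s); first: ",
         viol$segment_id[1L], " ", viol$field[1L], " (", viol$rule[1L], ")")
  }
  say(nrow(ds$pairs), " matched cross-sections in ",
      length(unique(ds$pairs$segment_id)), " segments")

  segs <- unique(ds$pairs[c("segment_id", "subject_id", "vessel_id")])
  results <- list(config = cfg)

  # ---- metric stage ----
  seg_tab <- dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(i) {
    dplyr::bind_rows(lapply(MODALITIES, function(m) {
      segment_metrics(segment_record(ds$frames, segs$subject_id[i],
                                     segs$vessel_id[i], m),
                      ca_fallback = cfg$ca_fallback)
    }))
  }))
  seg_tab$segment_id <- paste(seg_tab$subject_id, seg_tab$vessel_id,
                              sep = ":")
  results$segment_metrics <- seg_tab

  les_tab <- lesion_table(ds, cfg$pb_threshold, cfg$min_frames,
                          cfg$merge_gap_mm, cfg$flank_mm, cfg$ca_fallback)
  results$lesion_metrics <- les_tab
  say("lesions detected: ",
      if (nrow(les_tab)) nrow(les_tab) / 2L else 0L)

  fr <- ds$frames
  frame_tab <- tibble::tibble(
    segment_id = rep(ds$pairs$segment_id, 2L),
    subject_id = rep(ds$pairs$subject_id, 2L),
    unit = rep(paste0(ds$pairs$segment_id, ":", ds$pairs$pair), 2L),
    modality = rep(MODALITIES,
                   each = nrow(ds$pairs)),
    row = c(ds$pairs$nirs_row, ds$pairs$cta_row))
  frame_tab$position_mm <- fr$position_mm[frame_tab$row]
  frame_tab$lumen_area <- fr$lumen_area_mm2[frame_tab$row]
  frame_tab$vessel_area <- fr$vessel_area_mm2[frame_tab$row]
  frame_tab$plaque_area <- frame_tab$vessel_area - frame_tab$lumen_area
  frame_tab$pb <- 100 * frame_tab$plaque_area / frame_tab$vessel_area
  nb <- frame_n_bins(fr)
  frame_tab$lipid_frac <- vapply(fr$lipid_arcs[frame_tab$row], arc_extent,
                                 numeric(1L)) / nb
  frame_tab$ca_frac <- vapply(fr$ca_arcs[frame_tab$row], arc_extent,
                              numeric(1L)) / nb
  frame_tab$ca_area <- if ("ca_area_mm2" %in% names(fr))
    fr$ca_area_mm2[frame_tab$row] else NA_real_
  results$frame_metrics <- frame_tab[setdiff(names(frame_tab), "row")]

  # ---- wide per-level tables keyed by unit + CTA calcium covariate ----
  wides <- list()
  if ("segment" %in% cfg$levels) {
    w <- tidyr::pivot_wider(
      seg_tab[c("segment_id", "subject_id", "modality",
                level_variables$segment, "mean_ca_area")],
      names_from = "modality",
      values_from = c(level_variables$segment, "mean_ca_area"))
    names(w) <- sub("_NIRS_IVUS$", "_nirs", names(w))
    names(w) <- sub("_CTA$", "_cta", names(w))
    w$unit <- w$segment_id
    w$cluster <- w$subject_id
    wides$segment <- list(wide = w, ca = w$mean_ca_area_cta)
  }
  if ("lesion" %in% cfg$levels && nrow(les_tab) > 0L) {
    w <- tidyr::pivot_wider(
      les_tab[c("segment_id", "subject_id", "lesion", "modality",
                level_variables$lesion, "mean_ca_area")],
      names_from = "modality",
      values_from = c(level_variables$lesion, "mean_ca_area"))
    names(w) <- sub("_NIRS_IVUS$", "_nirs", names(w))
    names(w) <- sub("_CTA$", "_cta", names(w))
    w$unit <- paste0(w$segment_id, ":L", w$lesion)
    w$cluster <- w$subject_id
    wides$lesion <- list(wide = w, ca = w$mean_ca_area_cta)
  }
  if ("frame" %in% cfg$levels) {
    w <- tidyr::pivot_wider(
      frame_tab[c("unit", "subject_id", "modality",
                  level_variables$frame, "ca_area")],
      names_from = "modality",
      values_from = c(level_variables$frame, "ca_area"))
    names(w) <- sub("_NIRS_IVUS$", "_nirs", names(w))
    names(w) <- sub("_CTA$", "_cta", names(w))
    w$cluster <- w$subject_id
    ca <- w$ca_area_cta
    if (anyNA(ca)) ca <- w$ca_frac_cta * w$plaque_area_cta
    wides$frame <- list(wide = w, ca = ca)
  }

  # ---- agreement + model stages ----
  agreement <- list(); heterogeneity <- list(); model_fits <- list()
  curves <- list()
  for (lv in names(wides)) {
    say("agreement stage: ", lv, " level (", nrow(wides[[lv]]$wide),
        " units)")
    ag <- agree_one_level(wides[[lv]]$wide, lv, level_variables[[lv]],
                          wides[[lv]]$ca, cfg)
    agreement[[lv]] <- ag$agreement
    heterogeneity[[lv]] <- ag$heterogeneity
    mv <- intersect(cfg$model_vars[[lv]], level_variables[[lv]])
    if (length(mv) > 0L) {
      say("model stage: ", lv, " level (",
          paste(mv, collapse = ", "), ")")
      mo <- models_one_level(wides[[lv]]$wide, lv, mv, wides[[lv]]$ca, cfg)
      model_fits[[lv]] <- mo$fits
      curves[[lv]] <- mo$curves
    }
  }
  results$agreement <- dplyr::bind_rows(agreement)
  results$heterogeneity <- dplyr::bind_rows(heterogeneity)
  results$models <- model_fits
  results$difference_curves <- dplyr::bind_rows(curves)

  # ---- report stage ----
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$output_dir, f)
    num_csv <- function(df, f) {
      num <- vapply(df, is.numeric, logical(1L))
      df[num] <- lapply(df[num], function(x) format_num(round(x, 10)))
      readr::write_csv(df, out(f), progress = FALSE)
    }
    num_csv(seg_tab[setdiff(names(seg_tab), "segment_id")],
            "segment_metrics.csv")
    if (nrow(les_tab) > 0L) num_csv(les_tab, "lesion_metrics.csv")
    num_csv(results$frame_metrics, "frame_metrics.csv")
    num_csv(results$agreement, "agreement.csv")
    if (nrow(results$heterogeneity) > 0L) {
      num_csv(results$heterogeneity, "heterogeneity.csv")
    }
    if (nrow(results$difference_curves) > 0L) {
      num_csv(results$difference_curves, "difference_curves.csv")
    }
    model_json <- lapply(model_fits, function(lv) {
      lapply(lv, function(m) {
        m$coefficients <- as.data.frame(m$coefficients)
        m
      })
    })
    jsonlite::write_json(model_json, out("models.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
    manifest <- list(
      package = "plaqueagree",
      version = as.character(utils::packageVersion("plaqueagree")),
      seed = cfg$seed,
      config_hash = rlang::hash(cfg[setdiff(names(cfg),
                                            c("output_dir", "verbose",
                                              "dataset"))]),
      levels = cfg$levels,
      n_segments = length(unique(ds$pairs$segment_id)),
      n_pairs = nrow(ds$pairs),
      n_lesions = if (nrow(les_tab)) nrow(les_tab) / 2L else 0L)
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$paths <- list.files(cfg$output_dir, full.names = TRUE)
    say("report written to ", cfg$output_dir)
  }
  invisible(results)
}
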