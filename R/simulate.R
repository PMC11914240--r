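#' Synthetic matched-cohort specification
#'
#' Generative parameters for paired NIRS-IVUS/CTA pullback data with
#' known ground truth. Areas live on the log scale: noise and modality
#' bias are multiplicative, since areas are positive and observed
#' between-modality biases scale with vessel size. Longitudinal
#' smoothness comes from AR(1) processes on the log areas so that
#' high-burden frames form contiguous lesions. Calcium is a zero-inflated
#' gamma with within-vessel persistence (two-state Markov chain over
#' frames); lipid arcs follow a two-state Markov chain with a drifting
#' contiguous angular block. CTA measurements are the true areas times
#' `exp(delta0 + delta1 * ca_area)` noise — separate coefficients for the
#' lumen and the plaque (CTA vessel = CTA lumen + CTA plaque, keeping the
#' geometry consistent); NIRS-IVUS measures the truth with noise only,
#' mirroring its reference-standard role.
#'
#' Scale defaults echo the study design this generator emulates: 64
#' subjects with 3 vessels each and about 120 matched end-diastolic
#' cross-sections per vessel, i.e. tens of thousands of frames.
#'
#' @param n_subjects,vessels_per_subject,frames_per_segment,frame_spacing
#'   cohort dimensions; spacing in mm.
#' @param subject_sd,vessel_sd,modality_sd,residual_sd log-area random
#'   effect and noise SDs.
#' @param log_vessel_mu,long_sd,ar_coef marginal log vessel-area mean,
#'   stationary SD and AR(1) coefficient of the longitudinal process.
#' @param pb_mu,pb_sd,pb_ar plaque-burden fraction on the logit scale:
#'   mean, stationary SD, AR(1) coefficient.
#' @param ca_zero_inflation stationary probability that a frame carries
#'   no calcium.
#' @param ca_stay Markov stay-probability of the calcified state.
#' @param ca_gamma_shape,ca_gamma_scale calcium-area gamma marginal
#'   within calcified frames (mm^2).
#' @param delta0_lumen,delta1_lumen,delta0_plaque,delta1_plaque CTA
#'   log-bias: baseline and per-mm^2-calcium slope, for lumen and plaque
#'   areas.
#' @param ca_bloom_log,ca_miss_area,ca_miss_prob CTA calcium measurement:
#'   log-scale overestimation (blooming), and the area below which CTA
#'   misses a deposit with the given probability.
#' @param lipid_rate,lipid_stay,lipid_arc_mean lipid patch stationary
#'   probability, Markov stay-probability, mean arc width (degrees).
#' @param lipid_mask_coef per-mm^2-calcium log-attenuation of the CTA
#'   lipid arc (blooming masks the lipid signal).
#' @param seed mandatory RNG seed.
#' @return object of class `cohort_spec` (a validated parameter list).
#' @export
cohort_spec <- function(n_subjects = 64L, vessels_per_subject = 3L,
                        frames_per_segment = 120L, frame_spacing = 0.5,
                        subject_sd = 0.35, vessel_sd = 0.15,
                        modality_sd = 0.05, residual_sd = 0.10,
                        log_vessel_mu = log(13), long_sd = 0.25,
                        ar_coef = 0.9,
                        pb_mu = qlogis(0.38), pb_sd = 0.5, pb_ar = 0.9,
                        ca_zero_inflation = 0.65, ca_stay = 0.95,
                        ca_gamma_shape = 1.6, ca_gamma_scale = 1.5,
                        delta0_lumen = -0.29, delta1_lumen = -0.015,
                        delta0_plaque = -1.2, delta1_plaque = 0.12,
                        ca_bloom_log = 0.2, ca_miss_area = 0.3,
                        ca_miss_prob = 0.5,
                        lipid_rate = 0.3, lipid_stay = 0.93,
                        lipid_arc_mean = 90, lipid_mask_coef = 0.04,
                        seed = NULL) {
  spec <- as.list(environment())
  if (is.null(seed)) stop("a seed is mandatory")
  sds <- c(subject_sd, vessel_sd, modality_sd, residual_sd, long_sd,
           pb_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  probs <- c(ca_zero_inflation, ca_stay, ca_miss_prob, lipid_rate,
             lipid_stay)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(ar_coef) >= 1 || abs(pb_ar) >= 1) stop("AR coefficients in (-1, 1)")
  structure(spec, class = "cohort_spec")
}

#' Named scenario presets
#'
#' `"null"`: no modality bias, no calcium dependence (downstream biases
#' are zero and ICCs approach their noise-only limits). `"paper-like"`:
#' the default cohort dimensions and bias structure (64 subjects, 3
#' vessels each, ~120 frames per vessel). `"high-calcium"`: the same with
#' twice the calcified fraction and larger deposits.
#'
#' @param name preset name; omit to list available presets.
#' @param seed seed passed through to [cohort_spec()].
#' @param ... overrides forwarded to [cohort_spec()].
#' @return a `cohort_spec` (or the preset names when `name` is missing).
#' @export
scenario_preset <- function(name, seed = 1L, ...) {
  presets <- list(
    "null" = list(modality_sd = 0, delta0_lumen = 0, delta1_lumen = 0,
                  delta0_plaque = 0, delta1_plaque = 0, ca_bloom_log = 0,
                  ca_miss_prob = 0, lipid_mask_coef = 0),
    "paper-like" = list(),
    "high-calcium" = list(ca_zero_inflation = 0.35, ca_stay = 0.97,
                          ca_gamma_scale = 2.5)
  )
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  do.call(cohort_spec, modifyList(presets[[name]],
                                  c(list(seed = seed), list(...))))
}

# stationary AR(1) path of length n with marginal sd `s`
ar1_path <- function(n, coef, s) {
  if (s == 0 || n == 0L) return(numeric(n))
  x <- numeric(n)
  x[1L] <- rnorm(1L, 0, s)
  if (n > 1L) {
    innov <- rnorm(n - 1L, 0, s * sqrt(1 - coef^2))
    for (j in 2L:n) x[j] <- coef * x[j - 1L] + innov[j - 1L]
  }
  x
}

# two-state Markov chain started from its stationary distribution;
# pi = stationary probability of state TRUE, stay = P(TRUE -> TRUE)
markov_state <- function(n, pi, stay) {
  if (pi <= 0) return(rep(FALSE, n))
  if (pi >= 1) return(rep(TRUE, n))
  enter <- pi * (1 - stay) / (1 - pi)
  if (enter > 1) enter <- 1  # stay too low for this pi; saturate
  s <- logical(n)
  s[1L] <- runif(1L) < pi
  for (j in seq_len(n - 1L)) {
    p <- if (s[j]) stay else enter
    s[j + 1L] <- runif(1L) < p
  }
  s
}

# a contiguous angular block [centre - w/2, centre + w/2) on a 0..360
# circle, split at the reference angle when it wraps
angular_block <- function(centre, width) {
  width <- max(0, min(359.5, width))
  if (width < 0.5) return(empty_arcs())
  a <- (centre - width / 2) %% 360
  b <- a + width
  if (b <= 360) {
    arcs <- cbind(start = a, stop = b)
  } else {
    arcs <- rbind(cbind(start = a, stop = 360),
                  cbind(start = 0, stop = b - 360))
  }
  arcs <- round(arcs, 1)
  arcs[arcs[, 2L] - arcs[, 1L] >= 0.1, , drop = FALSE]
}

#' Generate a synthetic matched NIRS-IVUS/CTA cohort
#'
#' Draws a cohort under a [cohort_spec()] and returns the paired frame
#' data together with the full ground truth (true areas, calcium, and the
#' generating parameters), so downstream estimates can be checked against
#' known values. Regeneration under the same spec (including seed) is
#' byte-identical.
#'
#' @param spec a `cohort_spec`.
#' @return list with `dataset` (a [matched_dataset()]) and `truth`
#'   (tibble of per-frame true values plus the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_f <- spec$frames_per_segment
  pos <- (seq_len(n_f) - 1L) * spec$frame_spacing
  mod_shift <- rnorm(2L, 0, spec$modality_sd)  # NIRS, CTA
  rows <- list()
  truth_rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%03d", i)
    b_subj <- rnorm(1L, 0, spec$subject_sd)
    for (v in seq_len(spec$vessels_per_subject)) {
      vid <- sprintf("V%d", v)
      b_ves <- rnorm(1L, 0, spec$vessel_sd)
      log_vessel <- spec$log_vessel_mu + b_subj + b_ves +
        ar1_path(n_f, spec$ar_coef, spec$long_sd)
      pb <- plogis(spec$pb_mu + ar1_path(n_f, spec$pb_ar, spec$pb_sd))
      vessel_t <- exp(log_vessel)
      plaque_t <- vessel_t * pb
      lumen_t <- vessel_t - plaque_t

      ca_state <- markov_state(n_f, 1 - spec$ca_zero_inflation,
                               spec$ca_stay)
      ca_level <- exp(ar1_path(n_f, 0.8, 0.4))
      ca_t <- ifelse(ca_state,
                     rgamma(n_f, spec$ca_gamma_shape,
                            scale = spec$ca_gamma_scale) * ca_level, 0)
      ca_t <- pmin(ca_t, 0.9 * plaque_t)  # calcium is part of the plaque

      lipid_state <- markov_state(n_f, spec$lipid_rate, spec$lipid_stay)
      lipid_centre <- (runif(1L, 0, 360) +
                         cumsum(rnorm(n_f, 0, 8))) %% 360
      lipid_width <- pmax(0, spec$lipid_arc_mean *
                            exp(ar1_path(n_f, 0.9, 0.3)))
      ca_centre <- (runif(1L, 0, 360) + cumsum(rnorm(n_f, 0, 5))) %% 360

      # measured areas: NIRS = truth x noise; CTA = truth x calcium-
      # dependent bias x noise, vessel rebuilt as lumen + plaque
      eps <- function() rnorm(n_f, 0, spec$residual_sd)
      lumen_n <- lumen_t * exp(mod_shift[1L] + eps())
      plaque_n <- plaque_t * exp(mod_shift[1L] + eps())
      vessel_n <- lumen_n + plaque_n
      lumen_c <- lumen_t * exp(spec$delta0_lumen +
                                 spec$delta1_lumen * ca_t +
                                 mod_shift[2L] + eps())
      plaque_c <- plaque_t * exp(spec$delta0_plaque +
                                   spec$delta1_plaque * ca_t +
                                   mod_shift[2L] + eps())
      vessel_c <- lumen_c + plaque_c

      # CTA calcium: blooming overestimation, small deposits missed
      ca_c <- ca_t * exp(spec$ca_bloom_log + rnorm(n_f, 0, 0.15))
      missed <- ca_t > 0 & ca_t < spec$ca_miss_area &
        runif(n_f) < spec$ca_miss_prob
      ca_c[missed] <- 0
      ca_c <- pmin(ca_c, plaque_c)

      # a deposit occupies only part of the plaque thickness, so its arc
      # is narrower than the full-thickness fraction would suggest
      ca_arc_n <- ifelse(ca_t > 0,
                         pmin(300, 360 * ca_t / (3 * pmax(plaque_t, 1))), 0)
      ca_arc_c <- ifelse(ca_c > 0,
                         pmin(300, 360 * ca_c / (3 * pmax(plaque_c, 1))), 0)
      lip_w_n <- ifelse(lipid_state, lipid_width, 0)
      lip_w_c <- lip_w_n * exp(rnorm(n_f, 0, 0.2) -
                                 spec$lipid_mask_coef * ca_t)

      mk_arcs <- function(widths, centres) {
        lapply(seq_len(n_f), function(j) {
          if (widths[j] <= 0) empty_arcs() else
            angular_block(centres[j], widths[j])
        })
      }
      fib_arcs <- replicate(n_f, cbind(start = 0, stop = 360),
                            simplify = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, vessel_id = vid, modality = "NIRS_IVUS",
        position_mm = pos, lumen_area_mm2 = lumen_n,
        vessel_area_mm2 = vessel_n,
        lipid_arcs = mk_arcs(lip_w_n, lipid_centre),
        ca_arcs = mk_arcs(ca_arc_n, ca_centre),
        ft_arcs = fib_arcs,
        ff_arcs = replicate(n_f, empty_arcs(), simplify = FALSE),
        ca_area_mm2 = NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, vessel_id = vid, modality = "CTA",
        position_mm = pos, lumen_area_mm2 = lumen_c,
        vessel_area_mm2 = vessel_c,
        lipid_arcs = mk_arcs(lip_w_c, lipid_centre),
        ca_arcs = mk_arcs(ca_arc_c, ca_centre),
        ft_arcs = fib_arcs,
        ff_arcs = replicate(n_f, empty_arcs(), simplify = FALSE),
        ca_area_mm2 = ca_c)
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        subject_id = sid, vessel_id = vid, position_mm = pos,
        lumen_true = lumen_t, vessel_true = vessel_t,
        plaque_true = plaque_t, ca_true = ca_t,
        lipid_state = lipid_state)
    }
  }
  frames <- as_frame_table(dplyr::bind_rows(rows))
  list(dataset = matched_dataset(frames),
       truth = list(spec = unclass(spec),
                    modality_shift = mod_shift,
                    frames = dplyr::bind_rows(truth_rows)))
}
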