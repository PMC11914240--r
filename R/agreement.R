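#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test of paired modality measurements. Zero
#' differences are dropped; the exact null distribution is used for
#' `n <= 25` remaining pairs without ties in the absolute differences,
#' and the normal approximation with continuity and tie correction
#' otherwise.
#'
#' @param x,y paired measurement vectors of equal length.
#' @return two-sided p-value.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    stop("degenerate data: all paired differences are zero")
  }
  if (length(nz) < 5L) stop("need at least 5 non-zero paired differences")
  ex <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  suppressWarnings(
    wilcox.test(nz, exact = ex, correct = TRUE)$p.value
  )
}

#' Bland-Altman bias and limits of agreement
#'
#' Parametric mode: bias is the mean difference and the limits of
#' agreement are `mean +/- 1.96 * sd` (sample standard deviation, n - 1).
#' Non-parametric mode (used at segment and lesion level where
#' differences are few and skewed): the median bias and the 2.5th/97.5th
#' percentiles from intercept-only quantile regression, i.e. the
#' pinball-loss minimisers (see [pinball_quantile()]).
#'
#' @param diffs vector of paired differences (method 1 minus method 2).
#' @param mode `"parametric"` or `"nonparametric"`.
#' @return list with `bias`, `loa_low`, `loa_high`, `mode`, `n`.
#' @export
bland_altman <- function(diffs, mode = c("parametric", "nonparametric")) {
  mode <- match.arg(mode)
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 3L) stop("need at least 3 differences")
  if (mode == "parametric") {
    b <- mean(diffs)
    s <- sd(diffs)
    out <- list(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s)
  } else {
    q <- pinball_quantile(diffs, c(0.5, 0.025, 0.975))
    out <- list(bias = q[1L], loa_low = q[2L], loa_high = q[3L])
  }
  c(out, list(mode = mode, n = length(diffs)))
}

# closed-form two-way ANOVA / REML variance components for the balanced
# layout (one value per unit x modality); mat is n_units x 2
icc_components_moment <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  msr <- k * var(rowMeans(mat))
  msc <- n * var(colMeans(mat))
  grand <- mean(mat)
  sst <- sum((mat - grand)^2)
  sse <- sst - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  c(unit = max(0, (msr - mse) / k),
    modality = max(0, (msc - mse) / n),
    residual = max(0, mse))
}

icc_from_components <- function(vc, k = 2) {
  denom <- vc[["unit"]] + (vc[["modality"]] + vc[["residual"]]) / k
  if (denom <= 0) return(0)
  min(1, max(-1, vc[["unit"]] / denom))
}

icc_fit_once <- function(data, covariate, n_knots, engine) {
  if (engine == "moment") {
    wide <- tapply(data$value, list(data$unit, data$modality), mean)
    vc <- icc_components_moment(wide)
  } else {
    df <- data.frame(value = data$value, unit = factor(data$unit),
                     modality = factor(data$modality))
    form <- value ~ (1 | unit) + (1 | modality)
    if (!is.null(covariate)) {
      basis <- rcs_basis(data[[covariate]], n_knots = n_knots)
      for (j in seq_len(ncol(basis))) {
        df[[paste0("cov_", colnames(basis)[j])]] <- basis[, j]
      }
      form <- as.formula(paste(
        "value ~", paste(paste0("cov_", colnames(basis)), collapse = " + "),
        "+ (1 | unit) + (1 | modality)"))
    }
    fit <- lme4::lmer(form, data = df, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = FALSE))
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(unit = vcdf$vcov[vcdf$grp == "unit"],
            modality = vcdf$vcov[vcdf$grp == "modality"],
            residual = vcdf$vcov[vcdf$grp == "Residual"])
  }
  list(icc = icc_from_components(vc), components = vc)
}

#' Mixed-model intraclass correlation, ICC(A,2)
#'
#' Agreement between the two modalities under the two-way random-effects
#' model `value = mu + fixed(covariate) + u_unit + m_modality + e`,
#' absolute agreement, average of the k = 2 measurements:
#' `ICC = s2_unit / (s2_unit + (s2_modality + s2_residual) / 2)`.
#' Variance components are estimated by REML (`engine = "lmer"`); for the
#' balanced unadjusted layout (each unit measured exactly once per
#' modality) the closed-form two-way ANOVA moment estimator is identical
#' and far faster (`engine = "moment"`, picked automatically). Negative
#' component estimates are floored at zero and the ICC is clipped to
#' `[-1, 1]`. The adjusted ICC adds the covariate as a restricted cubic
#' spline fixed effect (3 knots at segment/lesion level, 5 at frame
#' level by the package's conventions) and always uses the mixed model.
#'
#' The confidence interval is a cluster non-parametric bootstrap:
#' clusters (default the units; set `cluster` to the patient column for
#' multi-vessel data) are resampled with replacement and the percentile
#' interval of the re-estimated ICCs is reported.
#'
#' @param data long-format data frame with columns `unit`, `modality`,
#'   `value`, plus the covariate / cluster columns when used.
#' @param covariate optional column name of the adjustment covariate.
#' @param n_knots RCS knots for the covariate (3 or 5).
#' @param engine `"auto"`, `"moment"`, or `"lmer"`.
#' @param ci_boot number of bootstrap resamples (0 = no CI).
#' @param cluster optional column name defining bootstrap clusters;
#'   defaults to `unit`.
#' @param seed RNG seed for the bootstrap (required when `ci_boot > 0`).
#' @param conf confidence level.
#' @return object of class `icc_result`: list with `icc`, `ci`,
#'   `components`, `engine`, `n_units`, `n_boot`, `adjusted`.
#' @export
icc_mixed <- function(data, covariate = NULL, n_knots = 3L,
                      engine = c("auto", "moment", "lmer"),
                      ci_boot = 0L, cluster = NULL, seed = NULL,
                      conf = 0.95) {
  engine <- match.arg(engine)
  data <- as.data.frame(data)
  stopifnot(all(c("unit", "modality", "value") %in% names(data)))
  tab <- table(data$unit, data$modality)
  if (ncol(tab) != 2L) stop("need exactly 2 modalities")
  complete <- rowSums(tab > 0) == 2L
  if (sum(complete) < 2L) stop("need >= 2 units with both modalities")
  balanced <- all(tab == 1L)
  if (engine == "auto") {
    engine <- if (balanced && is.null(covariate)) "moment" else "lmer"
  }
  if (engine == "moment" && (!balanced || !is.null(covariate))) {
    stop("moment engine requires a balanced unadjusted layout")
  }
  fit <- icc_fit_once(data, covariate, n_knots, engine)

  ci <- c(NA_real_, NA_real_)
  if (ci_boot > 0L) {
    if (is.null(seed)) stop("bootstrap CI needs a seed")
    cl <- if (is.null(cluster)) data$unit else data[[cluster]]
    boot_icc <- if (engine == "moment") {
      # balanced layout: resample whole clusters of wide-matrix rows
      wide <- tapply(data$value, list(data$unit, data$modality), mean)
      unit_cl <- tapply(as.character(cl), data$unit, `[`, 1L)
      unit_cl <- unit_cl[rownames(wide)]
      cl_rows <- split(seq_len(nrow(wide)), unit_cl)
      with_seed(seed, {
        vapply(seq_len(ci_boot), function(b) {
          take <- sample.int(length(cl_rows), replace = TRUE)
          mat <- wide[unlist(cl_rows[take], use.names = FALSE), ,
                      drop = FALSE]
          icc_from_components(icc_components_moment(mat))
        }, numeric(1L))
      })
    } else {
      cl_ids <- unique(cl)
      cl_rows <- split(seq_len(nrow(data)), match(cl, cl_ids))
      with_seed(seed, {
        vapply(seq_len(ci_boot), function(b) {
          take <- sample.int(length(cl_ids), replace = TRUE)
          rows <- unlist(cl_rows[take], use.names = FALSE)
          copy <- rep.int(seq_along(take),
                          vapply(cl_rows[take], length, integer(1L)))
          bd <- data[rows, , drop = FALSE]
          bd$unit <- paste(copy, bd$unit)  # duplicated clusters stay distinct
          tryCatch(icc_fit_once(bd, covariate, n_knots, engine)$icc,
                   error = function(e) NA_real_)
        }, numeric(1L))
      })
    }
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boot_icc, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(list(icc = fit$icc, ci = ci, components = fit$components,
                 engine = engine, n_units = nrow(tab), n_boot = ci_boot,
                 adjusted = !is.null(covariate), conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,2) = %.3f", x$icc))
  if (!anyNA(x$ci)) cat(sprintf(" (%.0f%% CI %.3f, %.3f; %d cluster resamples)",
                                100 * x$conf, x$ci[1], x$ci[2], x$n_boot))
  cat(sprintf("\n  engine: %s (REML)%s; units: %d\n", x$engine,
              if (x$adjusted) ", covariate-adjusted" else "", x$n_units))
  invisible(x)
}

#' Compare adjusted and unadjusted ICCs by CI overlap
#'
#' The covariate effect on agreement is called significant only when the
#' confidence intervals of the unadjusted and adjusted ICCs are disjoint.
#'
#' @param unadjusted,adjusted `icc_result` objects carrying CIs.
#' @return logical: `TRUE` when the CIs do not overlap.
#' @export
compare_adjusted_icc <- function(unadjusted, adjusted) {
  ci1 <- unadjusted$ci; ci2 <- adjusted$ci
  if (anyNA(ci1) || anyNA(ci2)) stop("both results must carry CIs")
  ci1[2] < ci2[1] || ci2[2] < ci1[1]
}

#' Qualitative interpretation band of an ICC
#'
#' Conventional thresholds: below 0.50 poor, 0.50 to below 0.75 moderate,
#' 0.75 to 0.90 good, above 0.90 excellent.
#'
#' @param icc numeric vector of ICC values.
#' @return factor with levels `poor`, `moderate`, `good`, `excellent`.
#' @export
icc_band <- function(icc) {
  out <- ifelse(icc < 0.50, "poor",
                ifelse(icc < 0.75, "moderate",
                       ifelse(icc <= 0.90, "good", "excellent")))
  factor(out, levels = c("poor", "moderate", "good", "excellent"))
}

#' Heterogeneity of stratum ICCs (tau-based meta-analysis)
#'
#' Each stratum ICC is Fisher z-transformed; its standard error on the z
#' scale is recovered from the CI width, `se = (z_hi - z_lo) / (2 * 1.96)`.
#' Cochran's Q with inverse-variance weights tests homogeneity (chi-square
#' with G - 1 df) and the DerSimonian-Laird moment estimate of the
#' between-stratum variance tau^2 is reported.
#'
#' @param icc,ci_low,ci_high equal-length vectors over strata.
#' @return list with `Q`, `df`, `p_value`, `tau2`, `z`, `se_z`.
#' @export
icc_heterogeneity <- function(icc, ci_low, ci_high) {
  g <- length(icc)
  if (g < 2L) stop("need at least 2 strata")
  if (length(ci_low) != g || length(ci_high) != g) {
    stop("icc, ci_low, ci_high must have equal length")
  }
  z <- atanh(icc)
  se <- (atanh(ci_high) - atanh(ci_low)) / (2 * qnorm(0.975))
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("zero-width or invalid CI: cannot weight stratum")
  }
  w <- 1 / se^2
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  df <- g - 1L
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, p_value = pchisq(Q, df, lower.tail = FALSE),
       tau2 = tau2, z = z, se_z = se)
}

# evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
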