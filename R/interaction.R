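# Shared design construction for the interaction models: the reference
# modality measurement enters as a restricted cubic spline, the calcium
# area (when adjusting) as a 3-knot spline, and the interaction as the
# product of the two linear terms only — keeping the interaction test at
# 1 df, which matters at lesion-level sample sizes.
interaction_design <- function(cta, ca = NULL, n_knots = 3L) {
  Xc <- rcs_basis(cta, n_knots = n_knots)
  colnames(Xc) <- paste0("cta_", colnames(Xc))
  knots_cta <- attr(Xc, "knots")
  knots_ca <- NULL
  X <- Xc
  if (!is.null(ca)) {
    Xa <- rcs_basis(ca, n_knots = 3L)
    colnames(Xa) <- paste0("ca_", colnames(Xa))
    knots_ca <- attr(Xa, "knots")
    X <- cbind(Xc, Xa, cta_x_ca = cta * ca)
  }
  make <- function(cta_new, ca_new = NULL) {
    Xc2 <- rcs_basis(cta_new, n_knots = n_knots, knots = knots_cta)
    colnames(Xc2) <- paste0("cta_", colnames(Xc2))
    if (is.null(knots_ca)) return(Xc2)
    Xa2 <- rcs_basis(ca_new, n_knots = 3L, knots = knots_ca)
    colnames(Xa2) <- paste0("ca_", colnames(Xa2))
    cbind(Xc2, Xa2, cta_x_ca = cta_new * ca_new)
  }
  list(X = X, int_col = if (is.null(ca)) character(0) else "cta_x_ca",
       make = make, knots_cta = knots_cta, knots_ca = knots_ca)
}

new_interaction_fit <- function(...) {
  structure(list(...), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("<interaction_fit: %s, %s%s>\n", x$model,
              if (x$adjusted) "calcium-adjusted" else "unadjusted",
              if (x$adjusted) sprintf(", interaction p = %.4g",
                                      x$interaction_p) else ""))
  print(x$coefficients)
  invisible(x)
}

#' Proportional-odds model of NIRS-IVUS measurements on CTA
#'
#' Cumulative-logit regression of the NIRS-IVUS measurement (ordinal over
#' its distinct observed values) on the CTA measurement, used at segment
#' and lesion level. The CTA value enters as a restricted cubic spline
#' (3 knots); the adjusted model adds the CTA calcium area (3-knot
#' spline) and the linear-by-linear calcium-by-measurement interaction,
#' whose p-value is the likelihood-ratio test of the interaction term
#' (or a cluster-robust Wald test when `cluster` is supplied, for data
#' with several segments per patient).
#'
#' @param nirs,cta paired measurement vectors (NIRS-IVUS outcome, CTA
#'   predictor).
#' @param ca_area CTA calcium area per observation; `NULL` for the
#'   unadjusted model (which then contains no calcium terms and no
#'   interaction test).
#' @param n_knots spline knots for the CTA measurement (3 or 5).
#' @param cluster optional cluster (patient) labels for robust inference.
#' @param se compute coefficient standard errors (inverse observed
#'   information); disable in large simulation loops.
#' @return an `interaction_fit` with `coefficients` (estimate, se),
#'   `interaction_p`, `logLik`, `fit` (the `cumlogit_fit`), and the
#'   design generator used by [difference_curves()].
#' @export
fit_prop_odds <- function(nirs, cta, ca_area = NULL, n_knots = 3L,
                          cluster = NULL, se = TRUE) {
  des <- interaction_design(cta, ca_area, n_knots = n_knots)
  full <- cumlogit_fit(nirs, des$X)
  interaction_p <- NA_real_
  if (length(des$int_col) > 0L) {
    if (is.null(cluster)) {
      reduced <- cumlogit_fit(nirs, des$X[, setdiff(colnames(des$X),
                                                    des$int_col),
                                          drop = FALSE])
      lrt <- max(0, 2 * (full$logLik - reduced$logLik))
      interaction_p <- pchisq(lrt, df = length(des$int_col),
                              lower.tail = FALSE)
    } else {
      V <- cumlogit_vcov_cluster(full, cluster)
      b <- full$beta[des$int_col]
      z <- b / sqrt(V[des$int_col, des$int_col])
      interaction_p <- 2 * pnorm(-abs(z))
    }
  }
  ses <- rep(NA_real_, length(full$beta))
  if (se) ses <- sqrt(diag(if (is.null(cluster)) cumlogit_vcov(full) else
    cumlogit_vcov_cluster(full, cluster)))
  new_interaction_fit(
    model = "prop_odds", adjusted = !is.null(ca_area),
    coefficients = tibble::tibble(term = names(full$beta),
                                  estimate = unname(full$beta),
                                  se = unname(ses)),
    interaction_p = unname(interaction_p), logLik = full$logLik,
    fit = full, design = des, cta = cta, ca_area = ca_area,
    n = length(nirs))
}

#' Ordinary-least-squares model of NIRS-IVUS measurements on CTA
#'
#' The cross-sectional (frame-level) analogue of [fit_prop_odds()]: same
#' design (CTA measurement as a restricted cubic spline, 5 knots by the
#' package's frame-level convention; calcium area as a 3-knot spline;
#' linear-by-linear interaction) fitted by least squares. The interaction
#' p-value is the F-test of the interaction term, or a cluster-robust
#' Wald test (sandwich CR0 by subject) when `cluster` is supplied —
#' frames within a patient are far from independent.
#'
#' @inheritParams fit_prop_odds
#' @return an `interaction_fit`; `fit` is the underlying `lm`.
#' @export
fit_ols_interaction <- function(nirs, cta, ca_area = NULL, n_knots = 5L,
                                cluster = NULL, se = TRUE) {
  des <- interaction_design(cta, ca_area, n_knots = n_knots)
  df <- data.frame(.y = nirs, des$X, check.names = FALSE)
  full <- lm(.y ~ ., data = df)
  if (anyNA(coef(full))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  interaction_p <- NA_real_
  if (length(des$int_col) > 0L) {
    if (is.null(cluster)) {
      reduced <- lm(.y ~ ., data = df[, c(".y", setdiff(colnames(des$X),
                                                        des$int_col))])
      interaction_p <- anova(reduced, full)[["Pr(>F)"]][2L]
    } else {
      V <- sandwich::vcovCL(full, cluster = cluster)
      b <- coef(full)[des$int_col]
      W <- drop(b %*% solve(V[des$int_col, des$int_col, drop = FALSE]) %*% b)
      interaction_p <- pchisq(W, df = length(des$int_col),
                              lower.tail = FALSE)
    }
  }
  Vc <- if (!se) NULL else if (is.null(cluster)) vcov(full) else
    sandwich::vcovCL(full, cluster = cluster)
  cf <- coef(full)
  new_interaction_fit(
    model = "ols", adjusted = !is.null(ca_area),
    coefficients = tibble::tibble(
      term = names(cf), estimate = unname(cf),
      se = if (se) sqrt(diag(Vc)) else rep(NA_real_, length(cf))),
    interaction_p = unname(interaction_p), logLik = unname(logLik(full)),
    fit = full, design = des, cta = cta, ca_area = ca_area,
    n = length(nirs))
}

#' Predicted NIRS-minus-CTA difference as a function of calcium
#'
#' Evaluates the fitted model's predicted NIRS-IVUS value minus the CTA
#' value over a calcium-area grid (default: the observed 1st-99th
#' percentile range, 50 points) at representative CTA values (observed
#' quartiles). For the proportional-odds model the prediction is the
#' modelled median; for the least-squares model the fitted mean. A
#' user-supplied grid outside the observed calcium range is clipped with
#' a warning.
#'
#' @param fit a calcium-adjusted `interaction_fit`.
#' @param ca_grid optional calcium-area grid.
#' @param cta_probs quantile levels defining the representative CTA
#'   values.
#' @param n_grid grid size when `ca_grid` is `NULL`.
#' @return tibble with `ca_area`, `cta_value`, `predicted_nirs`,
#'   `difference`.
#' @export
difference_curves <- function(fit, ca_grid = NULL,
                              cta_probs = c(0.25, 0.5, 0.75),
                              n_grid = 50L) {
  stopifnot(inherits(fit, "interaction_fit"))
  if (!fit$adjusted) stop("difference curves need a calcium-adjusted fit")
  rng <- quantile(fit$ca_area, c(0.01, 0.99), names = FALSE)
  if (is.null(ca_grid)) {
    ca_grid <- seq(rng[1L], rng[2L], length.out = n_grid)
  } else if (any(ca_grid < min(fit$ca_area) | ca_grid > max(fit$ca_area))) {
    warning("calcium grid clipped to the observed range")
    ca_grid <- pmin(pmax(ca_grid, min(fit$ca_area)), max(fit$ca_area))
  }
  cta_vals <- quantile(fit$cta, cta_probs, names = FALSE)
  grid <- tidyr::expand_grid(ca_area = ca_grid, cta_value = cta_vals)
  newX <- fit$design$make(grid$cta_value, grid$ca_area)
  pred <- if (fit$model == "prop_odds") {
    cumlogit_median(fit$fit, newX)
  } else {
    drop(cbind(1, newX) %*% coef(fit$fit))
  }
  tibble::tibble(ca_area = grid$ca_area, cta_value = grid$cta_value,
                 predicted_nirs = pred,
                 difference = pred - grid$cta_value)
}
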