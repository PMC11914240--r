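#' Pinball-loss sample quantile
#'
#' The quantile convention used throughout the package (non-parametric
#' Bland-Altman bounds, tercile/decile cut-points) is the minimiser of the
#' pinball (check) loss `sum(rho_tau(x - q))` — the intercept-only
#' quantile-regression solution. For `tau * n` non-integer this is the
#' `ceiling(tau * n)`-th order statistic; at integer `tau * n` the
#' minimiser set is an interval and its lower endpoint `x_(tau*n)` is
#' returned, so results are reproducible across platforms.
#'
#' @param x numeric vector (NAs dropped).
#' @param tau quantile level(s) in (0, 1).
#' @return numeric vector, one value per `tau`.
#' @export
pinball_quantile <- function(x, tau) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) stop("no data")
  if (any(tau <= 0 | tau >= 1)) stop("tau must lie in (0, 1)")
  vapply(tau, function(t) {
    m <- t * n
    k <- if (abs(m - round(m)) < 1e-9) round(m) else ceiling(m)
    x[max(1L, k)]
  }, numeric(1L))
}

#' Quantile-group stratification
#'
#' Splits a covariate (typically the mean calcium area) into terciles or
#' deciles by empirical quantile cut-points. Ties exactly at a cut-point
#' go to the lower group. When the covariate is degenerate (all values
#' equal) every observation lands in group 1 with a warning.
#'
#' @param values numeric vector.
#' @param scheme `"terciles"`, `"deciles"`, or an integer number of groups.
#' @return factor of group labels `1..G` (all levels kept).
#' @export
stratify <- function(values, scheme = c("terciles", "deciles")) {
  g <- if (is.numeric(scheme)) as.integer(scheme) else
    switch(match.arg(scheme), terciles = 3L, deciles = 10L)
  if (g < 2L) stop("need at least 2 groups")
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA")
  if (length(values) < g) {
    stop("need at least ", g, " observations for ", g, " groups")
  }
  cuts <- pinball_quantile(values, seq_len(g - 1L) / g)
  if (length(unique(values)) == 1L) {
    warning("degenerate strata: all values identical; single group")
  }
  labels <- vapply(values, function(v) sum(cuts < v) + 1L, integer(1L))
  factor(labels, levels = seq_len(g))
}
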