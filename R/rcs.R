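#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline (natural spline constrained to
#' linearity beyond the outer knots), in Harrell's parameterisation: with
#' knots `t_1 < ... < t_k` the basis has `k - 1` columns, the linear term
#' plus, for `j = 1..k-2`,
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2.}
#' Default knot placement follows the usual outer/inner quantiles:
#' 0.10/0.50/0.90 for 3 knots and 0.05/0.275/0.50/0.725/0.95 for 5 knots.
#'
#' @param x numeric vector.
#' @param n_knots 3 or 5.
#' @param knots optional explicit knot locations (overrides `n_knots`
#'   placement; length must be `n_knots`).
#' @return numeric matrix with `k - 1` columns (`lin`, `rcs1`, ...) and a
#'   `knots` attribute.
#' @export
rcs_basis <- function(x, n_knots = 3L, knots = NULL) {
  if (!n_knots %in% c(3L, 5L)) stop("n_knots must be 3 or 5")
  if (is.null(knots)) {
    probs <- if (n_knots == 3L) c(0.10, 0.50, 0.90) else
      c(0.05, 0.275, 0.50, 0.725, 0.95)
    if (length(unique(x[!is.na(x)])) < n_knots) {
      stop("need at least ", n_knots, " distinct values for knot placement")
    }
    knots <- unname(quantile(x, probs, na.rm = TRUE, type = 7))
    if (any(diff(knots) <= 0)) {
      # heavily tied covariates (e.g. zero-inflated calcium areas) tie the
      # raw quantile knots; fall back to quantiles of the distinct values
      knots <- unname(quantile(unique(x[!is.na(x)]), probs, type = 7))
    }
    if (any(diff(knots) <= 0)) stop("degenerate knot placement: tied knots")
  }
  k <- length(knots)
  if (k != n_knots) stop("knots must have length n_knots")
  tk <- knots[k]; tk1 <- knots[k - 1L]
  norm <- (knots[k] - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                        pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("lin", paste0("rcs", seq_len(k - 2L)))
  attr(out, "knots") <- knots
  out
}
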