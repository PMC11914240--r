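#' Cumulative-logit (proportional odds) maximum likelihood
#'
#' Semiparametric ordinal regression: every distinct observed outcome
#' value is its own category, so with n distinct values the model carries
#' n - 1 ordered intercepts. The likelihood is maximised over
#' `theta = (alpha_1, log(alpha_2 - alpha_1), ..., beta)` — the
#' log-increment parameterisation keeps the intercepts ordered by
#' construction — with analytic gradients; per-observation terms touch
#' only the two thresholds bracketing the observed category, so one
#' gradient evaluation is O(n) regardless of the category count.
#'
#' @param y numeric outcome vector (its sorted distinct values become the
#'   ordinal categories).
#' @param X numeric design matrix without an intercept (the thresholds
#'   absorb it); may have zero columns for an intercept-only fit.
#' @param maxit,reltol optimiser control.
#' @return object of class `cumlogit_fit`: list with `alpha` (ordered
#'   thresholds), `beta`, `values` (category values), `logLik`, `df`,
#'   `n`, `converged`, plus internals used by the variance routines.
#' @export
cumlogit_fit <- function(y, X = NULL, maxit = 2000L, reltol = 1e-12) {
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  X <- as.matrix(X)
  if (any(!is.finite(y)) || (ncol(X) > 0L && any(!is.finite(X)))) {
    stop("outcome and predictors must be finite")
  }
  values <- sort(unique(y))
  K <- length(values)
  if (K < 3L) stop("need at least 3 distinct outcome values")
  ki <- match(y, values)
  n <- length(y)
  p <- ncol(X)
  km1 <- K - 1L
  up <- which(ki <= km1)   # observations with a finite upper threshold
  lo <- which(ki >= 2L)    # ... finite lower threshold

  unpack <- function(theta) {
    alpha <- cumsum(c(theta[1L], exp(theta[seq_len(km1 - 1L) + 1L])))
    beta <- if (p > 0L) theta[km1 + seq_len(p)] else numeric(0)
    list(alpha = alpha, beta = beta)
  }

  pieces <- function(theta) {
    par <- unpack(theta)
    eta <- if (p > 0L) drop(X %*% par$beta) else numeric(n)
    Fu <- rep(1, n); Fl <- rep(0, n)
    Fu[up] <- plogis(par$alpha[ki[up]] - eta[up])
    Fl[lo] <- plogis(par$alpha[ki[lo] - 1L] - eta[lo])
    fu <- numeric(n); fl <- numeric(n)
    fu[up] <- dlogis(par$alpha[ki[up]] - eta[up])
    fl[lo] <- dlogis(par$alpha[ki[lo] - 1L] - eta[lo])
    list(par = par, pr = pmax(Fu - Fl, 1e-300), fu = fu, fl = fl)
  }

  nll <- function(theta) -sum(log(pieces(theta)$pr))

  # per-observation gradient matrix in theta space (n x (km1 + p))
  grad_obs <- function(theta) {
    pc <- pieces(theta)
    ga <- matrix(0, nrow = n, ncol = km1)
    ga[cbind(up, ki[up])] <- -pc$fu[up] / pc$pr[up]
    ga[cbind(lo, ki[lo] - 1L)] <- ga[cbind(lo, ki[lo] - 1L)] +
      pc$fl[lo] / pc$pr[lo]
    # chain rule alpha -> (a1, log increments): reverse cumulative sums
    rc <- ga %*% lower.tri(diag(km1), diag = TRUE)  # rc[, m] = sum_{j >= m}
    G <- matrix(0, nrow = n, ncol = km1 + p)
    G[, 1L] <- rc[, 1L]
    if (km1 > 1L) {
      G[, 2L:km1] <- sweep(rc[, 2L:km1, drop = FALSE], 2L,
                           exp(theta[2L:km1]), "*")
    }
    if (p > 0L) G[, km1 + seq_len(p)] <- X * ((pc$fu - pc$fl) / pc$pr)
    G
  }

  gr <- function(theta) {
    pc <- pieces(theta)
    ga <- numeric(km1)
    a1 <- rowsum(-pc$fu[up] / pc$pr[up], ki[up])
    ga[as.integer(rownames(a1))] <- a1[, 1L]
    a2 <- rowsum(pc$fl[lo] / pc$pr[lo], ki[lo] - 1L)
    i2 <- as.integer(rownames(a2))
    ga[i2] <- ga[i2] + a2[, 1L]
    rc <- rev(cumsum(rev(ga)))
    g <- numeric(km1 + p)
    g[1L] <- rc[1L]
    if (km1 > 1L) g[2L:km1] <- exp(theta[2L:km1]) * rc[2L:km1]
    if (p > 0L) {
      g[km1 + seq_len(p)] <- drop(crossprod(X, (pc$fu - pc$fl) / pc$pr))
    }
    g
  }

  counts <- tabulate(ki, K)
  cum <- pmin(pmax(cumsum(counts[-K]) / n, 0.5 / n), 1 - 0.5 / n)
  a0 <- qlogis(cum)
  theta0 <- c(a0[1L], if (km1 > 1L) log(pmax(diff(a0), 1e-6)), rep(0, p))
  opt <- optim(theta0, nll, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0L) {
    stop("cumulative-logit fit did not converge (optim code ",
         opt$convergence, ")")
  }
  par <- unpack(opt$par)
  beta <- par$beta
  names(beta) <- colnames(X)
  structure(list(alpha = par$alpha, beta = beta, values = values,
                 logLik = -opt$value, df = km1 + p, n = n, km1 = km1,
                 converged = TRUE, theta = opt$par,
                 nll_fn = nll, gr_fn = gr, grad_obs_fn = grad_obs),
            class = "cumlogit_fit")
}

#' @export
print.cumlogit_fit <- function(x, ...) {
  cat("Cumulative-logit fit:", length(x$values), "categories,",
      length(x$beta), "slope(s), logLik", sprintf("%.2f", x$logLik), "\n")
  if (length(x$beta) > 0L) print(x$beta)
  invisible(x)
}

#' Predicted median outcome of a cumulative-logit fit
#'
#' The modelled median at linear predictor `eta` is the smallest category
#' whose cumulative probability reaches 0.5, i.e. the first category `m`
#' with threshold `alpha_m >= eta` (the largest category when none does).
#'
#' @param fit a `cumlogit_fit`.
#' @param newX design matrix matching the fit's columns.
#' @return vector of predicted median outcome values.
#' @export
cumlogit_median <- function(fit, newX) {
  stopifnot(inherits(fit, "cumlogit_fit"))
  newX <- as.matrix(newX)
  eta <- if (length(fit$beta) > 0L) drop(newX %*% fit$beta) else
    numeric(nrow(newX))
  idx <- findInterval(eta, fit$alpha) + 1L  # first m with alpha_m >= eta
  fit$values[pmin(idx, length(fit$values))]
}

# model-based covariance of beta (inverse observed information block)
cumlogit_vcov <- function(fit) {
  p <- length(fit$beta)
  if (p == 0L) return(matrix(numeric(0), 0L, 0L))
  H <- optimHess(fit$theta, fit$nll_fn, fit$gr_fn)
  V <- solve(H)[fit$km1 + seq_len(p), fit$km1 + seq_len(p), drop = FALSE]
  dimnames(V) <- list(names(fit$beta), names(fit$beta))
  V
}

# cluster-robust (CR0) sandwich covariance of beta
cumlogit_vcov_cluster <- function(fit, cluster) {
  p <- length(fit$beta)
  if (p == 0L) return(matrix(numeric(0), 0L, 0L))
  G <- rowsum(fit$grad_obs_fn(fit$theta), cluster)
  H <- optimHess(fit$theta, fit$nll_fn, fit$gr_fn)
  Hi <- solve(H)
  V <- (Hi %*% crossprod(G) %*% Hi)[fit$km1 + seq_len(p),
                                    fit$km1 + seq_len(p), drop = FALSE]
  dimnames(V) <- list(names(fit$beta), names(fit$beta))
  V
}
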