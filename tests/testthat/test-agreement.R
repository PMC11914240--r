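test_that("paired Wilcoxon uses the exact tail for small untied samples", {
  set.seed(40)
  x <- rnorm(20)
  y <- x + runif(20, 1, 2)  # all differences negative: extreme rank sum
  # exact two-sided signed-rank p for a one-sided extreme: 2 / 2^n
  expect_equal(wilcoxon_paired(x, y), 2 / 2^20)
  expect_error(wilcoxon_paired(x, x), "degenerate")
  expect_error(wilcoxon_paired(x, c(y, 1)), "equal length")
})

test_that("Wilcoxon p-values are uniform under the null", {
  set.seed(42)
  p <- replicate(400, {
    d <- rnorm(40)
    wilcoxon_paired(d, rep(0, 40))
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(p < 0.05) , 0.01)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("Bland-Altman parametric limits follow mean +/- 1.96 sd", {
  ba <- bland_altman(rep(2, 10), "parametric")
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(2, 2, 2))

  ba <- bland_altman(c(-1, 0, 1), "parametric")
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_error(bland_altman(c(1, 2), "parametric"), "at least 3")
})

test_that("non-parametric Bland-Altman bounds are pinball-loss minimisers", {
  set.seed(77)
  d <- rnorm(10000)
  ba <- bland_altman(d, "nonparametric")
  expect_lt(abs(ba$bias), 0.05)
  expect_lt(abs(ba$loa_low + 1.96), 0.08)
  expect_lt(abs(ba$loa_high - 1.96), 0.08)

  for (i in 1:20) {
    x <- rnorm(sample(20:80, 1), sd = runif(1, 0.5, 3))
    ba <- bland_altman(x, "nonparametric")
    expect_equal(ba$bias, pinball_oracle(x, 0.5))
    expect_equal(ba$loa_low, pinball_oracle(x, 0.025))
    expect_equal(ba$loa_high, pinball_oracle(x, 0.975))
  }
})

test_that("ICC reaches 1 for perfectly agreeing modalities", {
  d <- data.frame(unit = rep(1:20, 2),
                  modality = rep(c("NIRS_IVUS", "CTA"), each = 20),
                  value = rep(rnorm(20, 10, 3), 2))
  expect_equal(icc_mixed(d)$icc, 1)
})

test_that("REML mixed-model ICC matches the two-way ANOVA closed form", {
  set.seed(30)
  n <- 150
  subj <- rnorm(n, 0, 2)
  y <- c(subj + rnorm(n, 0, 1), subj + 0.8 + rnorm(n, 0, 1))
  d <- data.frame(unit = rep(seq_len(n), 2),
                  modality = rep(c("A", "B"), each = n), value = y)
  mat <- cbind(y[1:n], y[n + 1:n])
  expect_equal(icc_mixed(d, engine = "lmer")$icc, anova_icc_oracle(mat),
               tolerance = 1e-4)
  expect_equal(icc_mixed(d, engine = "moment")$icc, anova_icc_oracle(mat),
               tolerance = 1e-10)
})

test_that("ICC is monotone non-increasing in the residual variance", {
  set.seed(31)
  n <- 300
  subj <- rnorm(n, 0, sqrt(3))
  base <- rnorm(2 * n)
  prev <- Inf
  for (s_e in c(0.5, 1, 2, 4)) {
    y <- rep(subj, 2) + sqrt(s_e) * base
    d <- data.frame(unit = rep(seq_len(n), 2),
                    modality = rep(c("A", "B"), each = n), value = y)
    cur <- icc_mixed(d)$icc
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("adjusted-vs-unadjusted comparison is CI disjointness", {
  mk <- function(icc, lo, hi) structure(list(icc = icc, ci = c(lo, hi)),
                                        class = "icc_result")
  expect_true(compare_adjusted_icc(mk(0.4, 0.2, 0.5), mk(0.7, 0.6, 0.8)))
  expect_false(compare_adjusted_icc(mk(0.4, 0.2, 0.5), mk(0.5, 0.4, 0.7)))
  expect_false(compare_adjusted_icc(mk(0.4, 0.2, 0.5), mk(0.4, 0.2, 0.5)))
  expect_error(compare_adjusted_icc(mk(0.4, NA, NA), mk(0.4, 0.2, 0.5)),
               "CIs")
})

test_that("RCS basis has k-1 columns, linear tails, and smooth knots", {
  set.seed(55)
  x <- rnorm(400)
  for (k in c(3L, 5L)) {
    B <- rcs_basis(x, k)
    expect_identical(ncol(B), k - 1L)
    knots <- attr(B, "knots")
    expect_identical(length(knots), k)

    # numeric second derivative vanishes on both tails
    h <- 1e-3
    d2 <- function(t) {
      (rcs_basis(c(t - h, t, t + h), k, knots = knots)[, -1, drop = FALSE])
    }
    for (t in c(min(knots) - 1, max(knots) + 1)) {
      m <- d2(t)
      curv <- (m[1, ] - 2 * m[2, ] + m[3, ]) / h^2
      expect_true(all(abs(curv) < 1e-5))
    }
    # continuity of value and first derivative across every knot
    for (t in knots) {
      for (fun in list(
        function(s) rcs_basis(s, k, knots = knots)[1, -1],
        function(s) (rcs_basis(s + h, k, knots = knots)[1, -1] -
                       rcs_basis(s - h, k, knots = knots)[1, -1]) / (2 * h)
      )) {
        expect_lt(max(abs(fun(t - 1e-6) - fun(t + 1e-6))), 1e-4)
      }
    }
    # matches the textbook truncated-power formula
    grid <- seq(min(x), max(x), length.out = 50)
    expect_equal(unname(rcs_basis(grid, k, knots = knots)),
                 unname(rcs_oracle(grid, knots)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(rcs_basis(rep(1, 10), 3), "distinct")
  expect_error(rcs_basis(rnorm(10), 4), "must be 3 or 5")
})

test_that("stratification balances groups and sends ties to the lower group", {
  g <- stratify(1:9, "terciles")
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  expect_warning(g1 <- stratify(rep(2, 10), "terciles"), "degenerate")
  expect_true(all(g1 == 1))

  set.seed(66)
  u <- runif(1000)
  d <- stratify(u, "deciles")
  expect_true(all(abs(as.vector(table(d)) - 100) <= 1))

  # a value exactly at a cut-point belongs to the lower group
  v <- c(1, 2, 3, 3, 5, 6, 7, 8, 9)
  cuts <- pinball_quantile(v, c(1 / 3, 2 / 3))
  g <- stratify(v, "terciles")
  expect_true(all(g[v == cuts[1]] == 1))
  expect_error(stratify(1:2, "terciles"), "at least 3")
})

test_that("heterogeneity p reduces to the two-group z-test and 1 under homogeneity", {
  h <- icc_heterogeneity(rep(0.6, 3), rep(0.4, 3), rep(0.75, 3))
  expect_equal(h$Q, 0)
  expect_equal(h$p_value, 1)
  expect_equal(h$tau2, 0)

  icc <- c(0.30, 0.55); lo <- c(0.20, 0.45); hi <- c(0.40, 0.64)
  h <- icc_heterogeneity(icc, lo, hi)
  z <- atanh(icc); se <- (atanh(hi) - atanh(lo)) / (2 * qnorm(0.975))
  zstat <- (z[1] - z[2]) / sqrt(sum(se^2))
  expect_equal(h$p_value, 2 * pnorm(-abs(zstat)))
  expect_error(icc_heterogeneity(0.5, 0.4, 0.6), "at least 2")
  expect_error(icc_heterogeneity(c(0.5, 0.6), c(0.5, 0.4), c(0.5, 0.8)),
               "zero-width")
})

test_that("heterogeneity matches metafor's fixed/DL computation", {
  skip_if_not_installed("metafor")
  set.seed(70)
  icc <- c(0.27, 0.36, 0.20)
  lo <- icc - c(0.03, 0.04, 0.05)
  hi <- icc + c(0.02, 0.03, 0.05)
  h <- icc_heterogeneity(icc, lo, hi)
  se <- (atanh(hi) - atanh(lo)) / (2 * qnorm(0.975))
  m <- metafor::rma(yi = atanh(icc), sei = se, method = "DL")
  expect_equal(h$Q, m$QE, tolerance = 1e-10)
  expect_equal(h$p_value, m$QEp, tolerance = 1e-10)
  expect_equal(h$tau2, m$tau2, tolerance = 1e-8)
  expect_lt(h$p_value, 0.001)  # narrow frame-level CIs: clear heterogeneity
})
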