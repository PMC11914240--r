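test_that("volumes integrate areas over position", {
  seg <- make_segment(0:10, lumen = 5, vessel = 10)
  v <- compute_volumes(seg)
  expect_equal(v$lumen_volume, 50)
  expect_equal(v$vessel_volume, 100)
  expect_equal(v$tav, 50)
  expect_equal(v$pav, 50)

  flat <- make_segment(0:5, lumen = 7, vessel = 7)
  v <- compute_volumes(flat)
  expect_equal(v$tav, 0)
  expect_equal(v$pav, 0)

  # irregular spacing against the naive trapezoid oracle
  set.seed(21)
  for (i in 1:10) {
    pos <- sort(runif(8, 0, 30))
    lum <- runif(8, 2, 6)
    ves <- lum + runif(8, 1, 8)
    seg <- make_segment(pos, lum, ves)
    v <- compute_volumes(seg)
    expect_equal(v$lumen_volume, trapz_oracle(pos, lum))
    expect_equal(v$vessel_volume, trapz_oracle(pos, ves))
    expect_equal(v$tav, v$vessel_volume - v$lumen_volume)
  }
})

test_that("PAV is invariant under uniform scaling of all areas", {
  set.seed(8)
  pos <- sort(runif(10, 0, 20))
  lum <- runif(10, 2, 5)
  ves <- lum + runif(10, 1, 6)
  p1 <- compute_volumes(make_segment(pos, lum, ves))$pav
  p2 <- compute_volumes(make_segment(pos, 3.7 * lum, 3.7 * ves))$pav
  expect_equal(p1, p2)
})

test_that("spread-out plots map arcs to grid columns without resampling", {
  seg <- make_segment(c(0, 1, 2), lumen = 5, vessel = 10)
  sp <- build_spreadout(seg)
  expect_false(any(sp$masks$lipid) || any(sp$masks$ca))
  expect_identical(ncol(sp$masks$lipid), 3L)

  lip <- list(rbind(c(0, 90)), plaqueagree:::empty_arcs(),
              plaqueagree:::empty_arcs())
  seg <- make_segment(c(0, 1, 2), 5, 10, lipid = lip)
  sp <- build_spreadout(seg)
  expect_equal(sum(sp$masks$lipid[, 1]), 90)
  expect_equal(sum(sp$masks$lipid[, 2:3]), 0)

  # overlapping lipid and calcium arcs stay multi-label
  seg <- make_segment(c(0, 1), 5, 10,
                      lipid = list(rbind(c(0, 180)), rbind(c(0, 180))),
                      ca = list(rbind(c(90, 270)), rbind(c(90, 270))))
  sp <- build_spreadout(seg)
  both <- sp$masks$lipid[, 1] & sp$masks$ca[, 1]
  expect_equal(sum(both), 90)
  expect_true(all(which(both) %in% 91:180))
})

test_that("burden indices are cell counts over total cells x 1000", {
  full <- make_plot(matrix(TRUE, 360, 5), positions = 0:4)
  expect_equal(burden_index(full, "lipid"), 1000)
  expect_equal(burden_index(full, "ca"), 0)

  m <- matrix(FALSE, 360, 20)
  m[sample.int(7200, 1800)] <- TRUE
  pl <- make_plot(m, positions = seq(0, 9.5, by = 0.5))
  expect_equal(burden_index(pl, "lipid"), 1000 * 1800 / 7200)
  expect_equal(burden_index(pl, "lipid"), 250)
})

test_that("burden index is invariant to column permutation", {
  set.seed(5)
  m <- matrix(runif(360 * 12) < 0.3, 360, 12)
  p1 <- make_plot(m, positions = 0:11)
  p2 <- make_plot(m[, sample(12)], positions = 0:11)
  expect_equal(burden_index(p1, "lipid"), burden_index(p2, "lipid"))
})

test_that("maxLCBI4mm equals the exhaustive window oracle", {
  # uniform lipid fraction: window index equals the whole-plot LCBI
  m <- matrix(FALSE, 36, 21)
  m[1:9, ] <- TRUE
  pl <- make_plot(m, positions = seq(0, 10, by = 0.5))
  expect_equal(max_lcbi_4mm(pl), burden_index(pl, "lipid"))

  # single 2 mm full-circumference block inside a 20 mm pullback
  pos <- seq(0, 20, by = 0.5)
  m <- matrix(FALSE, 36, length(pos))
  block <- which(pos >= 8 & pos <= 10)
  m[, block] <- TRUE
  pl <- make_plot(m, positions = pos)
  expect_equal(max_lcbi_4mm(pl),
               maxlcbi_oracle(colSums(m), pos, 36))

  # empty chemogram
  expect_equal(max_lcbi_4mm(make_plot(matrix(FALSE, 36, 21),
                                      positions = seq(0, 10, 0.5))), 0)

  # random grids, irregular spacing
  set.seed(33)
  for (i in 1:50) {
    nc <- sample(10:60, 1)
    pos <- sort(runif(nc, 0, 25))
    m <- matrix(runif(24 * nc) < runif(1, 0.05, 0.6), 24, nc)
    pl <- make_plot(m, positions = pos)
    expect_equal(quiet_max_lcbi(pl),
                 maxlcbi_oracle(colSums(m), pos, 24))
  }
})

test_that("maxLCBI4mm is invariant to pullback reversal and warns below 4 mm", {
  set.seed(9)
  pos <- seq(0, 12, by = 0.4)
  m <- matrix(runif(36 * length(pos)) < 0.25, 36, length(pos))
  fwd <- max_lcbi_4mm(make_plot(m, positions = pos))
  rev_pl <- make_plot(m[, rev(seq_along(pos))],
                      positions = max(pos) - rev(pos))
  expect_equal(fwd, max_lcbi_4mm(rev_pl))

  short <- make_plot(matrix(TRUE, 36, 4), positions = c(0, 1, 2, 3))
  expect_warning(v <- max_lcbi_4mm(short), "shorter than 4")
  expect_equal(v, 1000)
})

test_that("mean calcium area divides calcium volume by segment length", {
  seg <- make_segment(seq(0, 10), 5, 12, ca_area = 2)
  expect_equal(mean_ca_area(seg), 2)
  seg0 <- make_segment(seq(0, 10), 5, 12, ca_area = 0)
  expect_equal(mean_ca_area(seg0), 0)

  # triangular profile against the trapezoid oracle
  pos <- 0:8
  ca <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  seg <- make_segment(pos, 5, 12, ca_area = ca)
  expect_equal(mean_ca_area(seg), trapz_oracle(pos, ca) / 8)

  # missing areas: error without fallback, arc fraction with
  seg_na <- make_segment(0:4, 5, 12)
  expect_error(mean_ca_area(seg_na, fallback = "none"), "missing")
  arcs <- replicate(5, rbind(c(0, 90)), simplify = FALSE)
  seg_arc <- make_segment(0:4, 5, 13, ca = arcs)
  expect_equal(mean_ca_area(seg_arc, fallback = "arc_fraction"),
               (90 / 360) * 8)
})

test_that("calcium arc is linear in CaBI and round-trips", {
  expect_equal(ca_arc_from_cabi(0), 0)
  expect_equal(ca_arc_from_cabi(500), 180)
  expect_equal(ca_arc_from_cabi(1000), 360)
  expect_error(ca_arc_from_cabi(1200), "must lie in")
  arcs <- seq(0, 360, by = 7.5)
  expect_equal(ca_arc_from_cabi(1000 / 360 * arcs), arcs)
})

test_that("spread-out exports carry every cell flag", {
  seg <- make_segment(c(0, 1), 5, 10,
                      lipid = list(rbind(c(0, 2)), rbind(c(0, 2))),
                      ca = list(rbind(c(1, 3)), plaqueagree:::empty_arcs()))
  sp <- build_spreadout(seg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spreadout_csv(sp, f)
  grid <- readr::read_csv(f, show_col_types = FALSE)
  expect_identical(nrow(grid), 360L)
  expect_identical(grid[[2]][2], "lipid|ca")  # bin 2 carries both tissues
  expect_identical(grid[[2]][3], "ca")
  p <- plot_spreadout(sp)
  expect_s3_class(p, "ggplot")
})

test_that("HU classification is half-open with ties to the upper class", {
  cfg <- hu_cutoffs(76, 131, 351)
  expect_equal(as.character(classify_hu(c(-50, 75, 76, 130, 131, 350, 351,
                                          1200), cfg)),
               c("NC", "NC", "FF", "FF", "FT", "FT", "CA", "CA"))
  expect_error(classify_hu(NA_real_, cfg), "finite")
  expect_error(hu_cutoffs(100, 90, 351), "strictly increasing")
})
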