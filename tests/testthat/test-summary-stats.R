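test_that("g, L, O and D match independent brute-force implementations to 1e-10", {
  grid <- distance_grid(bandwidth = 0.05, r_max = 0.25, smoothing_span = 3)
  w <- owin_rect(c(0, 1), c(0, 1))
  for (n in c(5, 20, 50)) {
    xy <- fixture_points(n)
    oracle <- brute_pair_curves(xy, c(0, 1), c(0, 1), grid$nbins,
                                grid$bandwidth)
    g <- estimate_pcf(xy, w, grid)
    expect_equal(g$values, brute_smooth(oracle$g, 3), tolerance = 1e-10)
    L <- estimate_L(xy, w, grid)
    expect_equal(attr(L, "K"), oracle$K, tolerance = 1e-10)
    expect_equal(L$values, sqrt(oracle$K / pi), tolerance = 1e-10)
    o <- estimate_oring(xy, w, grid)
    expect_equal(o$values, n * brute_smooth(oracle$g, 3), tolerance = 1e-10)
    d <- estimate_nn(xy, w, grid)
    expect_equal(d$values, brute_nn(xy, c(0, 1), c(0, 1), grid),
                 tolerance = 1e-10)
  }
})

test_that("bivariate cross-PCF matches the brute-force cross-pair oracle", {
  grid <- distance_grid(0.05, 0.25, 1)
  w <- owin_rect(c(0, 1), c(0, 1))
  xya <- fixture_points(3)
  xyb <- fixture_points(3, c(0.2, 0.9), c(0.1, 0.8))
  g <- estimate_pcf_bivariate(xya, xyb, w, grid)
  expect_equal(g$values, brute_cross_pcf(xya, xyb, c(0, 1), c(0, 1), grid),
               tolerance = 1e-10)
  # symmetric estimator
  g2 <- estimate_pcf_bivariate(xyb, xya, w, grid)
  expect_equal(g$values, g2$values, tolerance = 1e-12)
})

test_that("two-point geometry puts the PCF mass at the pair distance", {
  w <- owin_rect(c(0, 20), c(0, 20))
  xy <- cbind(x = c(10, 10.47), y = c(10, 10))
  grid <- distance_grid(0.1, 2, 1)
  g <- estimate_pcf(xy, w, grid)
  expect_equal(which.max(g$values), which.min(abs(g$r - 0.47)))
  expect_true(all(g$values[abs(g$r - 0.47) > 0.1] == 0))

  gb <- estimate_pcf_bivariate(cbind(10, 10), cbind(10.33, 10), w, grid)
  expect_equal(which.max(gb$values), which.min(abs(gb$r - 0.33)))
})

test_that("estimators agree with CSR closed forms at moderate n", {
  w <- owin_rect(c(0, 10), c(0, 10))
  set.seed(42)
  p <- simulate_csr(n = 2000, window = w)
  grid <- distance_grid(0.1, 2, 3)
  L <- estimate_L(p, w, grid)
  expect_lt(max(abs(L$values - L$r)), 0.05)
  o <- estimate_oring(p, w, grid)
  expect_equal(mean(o$values), 20, tolerance = 0.05)
  d <- estimate_nn(p, w, grid)
  theory <- 1 - exp(-20 * pi * grid$r^2)
  expect_lt(max(abs(d$values - theory), na.rm = TRUE), 0.05)
})

test_that("smoothing with span 1 equals the unsmoothed estimate", {
  w <- owin_rect(c(0, 1), c(0, 1))
  xy <- fixture_points(30)
  g1 <- estimate_pcf(xy, w, distance_grid(0.05, 0.25, 1))
  g3 <- estimate_pcf(xy, w, distance_grid(0.05, 0.25, 3))
  expect_equal(brute_smooth(g1$values, 3), g3$values, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g1$values, g3$values)))
})

test_that("estimates are invariant under rigid motion of pattern and window", {
  xy <- fixture_points(30, c(0, 2), c(0, 1))
  w <- owin_rect(c(0, 2), c(0, 1))
  grid <- distance_grid(0.05, 0.25, 3)
  g0 <- estimate_pcf(xy, w, grid)
  L0 <- estimate_L(xy, w, grid)

  th <- pi / 7
  xyr <- rotate_xy(xy, th) + matrix(rep(c(3, 4), each = 30), ncol = 2)
  vr <- rotate_xy(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)), th)
  wr <- owin_poly(vr[, 1] + 3, vr[, 2] + 4)
  gr <- estimate_pcf(xyr, wr, grid)
  expect_equal(gr$values, g0$values, tolerance = 1e-8)
  Lr <- estimate_L(xyr, wr, grid)
  expect_equal(Lr$values, L0$values, tolerance = 1e-8)
})

test_that("nearest-neighbour distribution on a lattice jumps at the spacing", {
  gg <- expand.grid(x = 1:8, y = 1:8)
  w <- owin_rect(c(0, 9), c(0, 9))
  grid <- distance_grid(0.25, 2, 1)
  d <- estimate_nn(as.matrix(gg), w, grid)
  expect_true(all(d$values[d$r < 1] == 0, na.rm = TRUE))
  expect_true(all(d$values[d$r > 1] == 1, na.rm = TRUE))
})

test_that("degenerate inputs raise typed errors and big r draws a warning", {
  w <- owin_rect(c(0, 1), c(0, 1))
  expect_error(estimate_pcf(cbind(0.5, 0.5), w), class = "sppa_undefined_curve")
  expect_error(estimate_L(cbind(0.5, 0.5), w), class = "sppa_undefined_curve")
  expect_error(estimate_pcf_bivariate(cbind(x = numeric(0), y = numeric(0)),
                                      cbind(0.5, 0.5), w),
               class = "sppa_undefined_curve")
  expect_warning(estimate_pcf(fixture_points(10), w, distance_grid(0.1, 1, 1)),
                 "diameter")
})

test_that("curves serialize to the documented CSV schema", {
  w <- owin_rect(c(0, 1), c(0, 1))
  g <- estimate_pcf(fixture_points(20), w, distance_grid(0.05, 0.25, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_curve(g, path)
  df <- read.csv(path)
  expect_named(df, c("r_m", "value", "envelope_lo", "envelope_hi", "kind",
                     "n_sims"))
  expect_equal(df$value, g$values)
})
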