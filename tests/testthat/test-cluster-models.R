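test_that("Thomas closed forms behave as the theory dictates", {
  p <- thomas_params(0.1, 1, 10)
  expect_equal(p$mu, 10)
  expect_equal(thomas_pcf(p, 0), 1 + 1 / (4 * pi * 0.01), tolerance = 1e-12)
  expect_equal(thomas_pcf(p, 50), 1, tolerance = 1e-9)
  r <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(thomas_pcf(p, r)) < 0))          # decreasing in r
  p2 <- thomas_params(0.1, 2, 10)
  expect_true(all(thomas_pcf(p2, r) < thomas_pcf(p, r)))  # decreasing in rho
  # excess scales as 1/rho
  expect_equal((thomas_pcf(p, r) - 1) / (thomas_pcf(p2, r) - 1),
               rep(2, length(r)), tolerance = 1e-9)
  # K and g are consistent: dK/dr = 2 pi r g
  K <- thomas_K(p, r)
  num_g <- diff(K) / diff(r) / (2 * pi * (r[-1] - 0.005))
  expect_equal(num_g, thomas_pcf(p, r[-1] - 0.005), tolerance = 1e-3)

  expect_error(thomas_params(-0.1, 1, 1))
  expect_equal(mean_cluster_size(thomas_params(0.1, 1, 1)), 1)
  expect_equal(mean_cluster_size(thomas_params(0.2, 3.11, 36.83)), 11.842,
               tolerance = 1e-3)
})

test_that("the Thomas simulator matches its intensity and dispersal law", {
  w <- owin_rect(c(0, 10), c(0, 10))
  p <- thomas_params(0.1, 1, 10)
  expect_equal(nrow(simulate_thomas(thomas_params(0.1, 1, 1e-9), w, seed = 1)),
               0, tolerance = 1)  # mu ~ 0
  set.seed(2)
  counts <- replicate(200, nrow(simulate_thomas(p, w)))
  expect_equal(mean(counts), 1000, tolerance = 0.05)

  # offspring displacements are per-axis Gaussian: radial Rayleigh(sigma)
  set.seed(3)
  off <- sppa:::scatter_offspring(cbind(0, 0), 3000, 0.1,
                                  owin_rect(c(-5, 5), c(-5, 5)))
  d <- sqrt(rowSums(off^2))
  ks <- suppressWarnings(stats::ks.test(d, function(q) 1 - exp(-q^2 / (2 * 0.01))))
  expect_lt(as.numeric(ks$statistic), 0.05)

  # simulator and closed form agree: envelope of simulated PCFs contains g
  grid <- distance_grid(0.05, 1, 1)
  set.seed(4)
  sims <- sapply(1:199, function(i)
    estimate_pcf(simulate_thomas(p, w), w, grid)$values)
  lo <- apply(sims, 1, function(v) sort(v)[5])
  hi <- apply(sims, 1, function(v) sort(v, decreasing = TRUE)[5])
  gtheory <- thomas_pcf(p, grid$r)
  expect_true(all(gtheory >= lo & gtheory <= hi))
})

test_that("nested double clusters show both scales and chain intensities", {
  w <- owin_rect(c(0, 10), c(0, 10))
  large <- thomas_params(0.5, 0.2, 1)   # mu1 = 5
  dp <- double_thomas_params(large, 0.05, 4)
  expect_equal(dp$lambda_total, 4)
  set.seed(5)
  counts <- replicate(200, nrow(simulate_double_thomas(dp, w)))
  expect_equal(mean(counts), 0.2 * 5 * 4 * 100, tolerance = 0.05)

  # closed form: small-scale excess well above the outer-scale excess
  expect_gt(double_thomas_pcf(dp, 0.05), double_thomas_pcf(dp, 1))
  # empirical PCF shows the same two-scale ordering
  grid <- distance_grid(0.05, 1.5, 1)
  sims <- sapply(1:60, function(i)
    estimate_pcf(simulate_double_thomas(dp, w), w, grid)$values)
  m <- rowMeans(sims)
  expect_gt(m[which.min(abs(grid$r - 0.05))], m[which.min(abs(grid$r - 1))])
  expect_equal(m, double_thomas_pcf(dp, grid$r), tolerance = 0.2)

  expect_warning(double_thomas_params(large, 0.9, 2), "not smaller")
})

test_that("inhomogeneous thinning masks points without reshaping clusters", {
  w <- owin_rect(c(0, 10), c(0, 10))
  p <- thomas_params(0.1, 1, 10)
  expect_equal(nrow(simulate_inhom_thomas(p, constant_intensity(0), w)), 0)

  # half-window mask: retention 0 on the right half
  mask <- intensity_surface(function(x, y) as.numeric(x < 5), "mask", lmax = 1)
  pm <- simulate_inhom_thomas(p, mask, w, seed = 6)
  expect_true(all(pm[, 1] < 5))

  # constant surface: thinning is uniform, counts and PCF unchanged
  const <- constant_intensity(7)
  set.seed(7)
  counts <- replicate(100, nrow(simulate_inhom_thomas(p, const, w)))
  expect_equal(mean(counts), 1000, tolerance = 0.07)
  grid <- distance_grid(0.05, 0.5, 1)
  sims <- sapply(1:50, function(i)
    estimate_pcf(simulate_inhom_thomas(p, const, w), w, grid)$values)
  expect_equal(rowMeans(sims), thomas_pcf(p, grid$r), tolerance = 0.12)

  # rescaled thinning restores the target intensity but keeps the parent
  # density (PCF invariance under independent thinning)
  grad <- gradient_intensity("gradient_x", 0, 0.3, window = w)
  set.seed(8)
  counts2 <- replicate(100, nrow(simulate_inhom_thomas(p, grad, w,
                                                       rescale = TRUE)))
  expect_equal(mean(counts2), 1000, tolerance = 0.07)
})

test_that("minimal contrast recovers parameters exactly on closed-form input", {
  grid <- distance_grid(0.1, 2.5, 1)
  truth <- thomas_params(0.15, 2, 20)
  g <- sppa:::new_curve("pcf", grid, thomas_pcf(truth, grid$r), 2000, 100)
  L <- sppa:::new_curve("L", grid, sqrt(thomas_K(truth, grid$r) / pi),
                        2000, 100)
  attr(L, "K") <- thomas_K(truth, grid$r)
  for (basis in c("PCF+L", "PCF", "L")) {
    fit <- fit_minimal_contrast(g, L, "TC", basis)
    expect_equal(fit$sigma, 0.15, tolerance = 1e-4)
    expect_equal(fit$rho, 2, tolerance = 1e-4)
  }
  # no aggregation signal: typed error
  flat <- sppa:::new_curve("pcf", grid, rep(1, grid$nbins), 2000, 100)
  expect_error(fit_minimal_contrast(flat, L, "TC"),
               class = "sppa_no_aggregation")
})

test_that("minimal contrast recovers simulated Thomas parameters", {
  w <- owin_rect(c(0, 10), c(0, 10))
  truth <- thomas_params(0.1, 1, 10)
  grid <- distance_grid(0.1, 2.5, 3)
  set.seed(9)
  ests <- replicate(8, {
    p <- simulate_thomas(truth, w)
    f <- fit_minimal_contrast(estimate_pcf(p, w, grid),
                              estimate_L(p, w, grid), "TC", "PCF+L")
    c(f$sigma, f$rho, mean_cluster_size(f))
  })
  expect_lte(median(abs(ests[1, ] - 0.1) / 0.1), 0.25)
  expect_lte(median(abs(ests[2, ] - 1)), 0.25)
  expect_equal(median(ests[3, ]), 10, tolerance = 0.3)
})

test_that("the fitting ladder classifies canonical patterns", {
  w <- owin_rect(c(0, 10), c(0, 10))
  cfg <- sppa_config(n_sims = 199, envelope_rank = 10, n_sims_select = 19)

  # bandwidth fine enough to resolve the 0.2 m hard core
  cfg_h <- sppa_config(bandwidth = 0.05, r_max = 1.5, n_sims = 199,
                       envelope_rank = 10, n_sims_select = 19)
  hard <- simulate_inhibition(500, 0.2, w, seed = 10)
  fit_h <- fit_protocol(hard, w, cfg_h, seed = 1)
  expect_equal(fit_h$kind, "SEGREGATED")

  tp <- thomas_params(0.1, 1, 10)
  fit_t <- fit_protocol(simulate_thomas(tp, w, seed = 11), w, cfg, seed = 2)
  expect_true(fit_t$kind %in% c("TC", "DTC"))
  if (fit_t$kind == "TC")
    expect_equal(fit_t$params$sigma, 0.1, tolerance = 0.25)

  expect_error(fit_protocol(fixture_points(5), w, cfg),
               class = "sppa_insufficient_data")
})

test_that("the ladder never reports clustering without an upward excursion", {
  w <- owin_rect(c(0, 10), c(0, 10))
  cfg <- sppa_config(n_sims = 99, envelope_rank = 5, n_sims_select = 19)
  set.seed(12)
  kinds <- character(6)
  for (i in 1:6) {
    f <- fit_protocol(simulate_csr(n = 200, window = w), w, cfg)
    kinds[i] <- f$kind
    if (f$kind %in% c("TC", "DTC", "ITC", "HP")) {
      exc <- f$envelopes[["CSR"]]$excursions
      expect_true(any(exc$direction == "above"))
    }
  }
  expect_true(all(kinds %in% c("CSR", "SEGREGATED", "TC", "DTC", "ITC",
                               "HP")))
})
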