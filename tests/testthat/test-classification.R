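fake_fit <- function(kind) {
  structure(list(kind = kind, params = NULL,
                 candidates = data.frame(model = kind, p_d_pcf = 0.5,
                                         p_d_nn = 0.5, accepted = TRUE,
                                         note = ""),
                 n = 100), class = "sppa_fit")
}

fake_biv <- function(independent, direction = "none") {
  structure(list(taxon_a = "a", taxon_b = "b", n_a = 50, n_b = 50,
                 independent = independent, direction = direction,
                 density_change_pct = if (independent) 0 else 40),
            class = "bivariate_result")
}

test_that("the niche/neutral mapping is total and follows the assignment rules", {
  expect_equal(classify_univariate(fake_fit("CSR"))$process, "neutral")
  expect_equal(classify_univariate(fake_fit("TC"))$process, "neutral")
  expect_equal(classify_univariate(fake_fit("DTC"))$process, "neutral")
  expect_equal(classify_univariate(fake_fit("HP"))$process, "niche")
  expect_equal(classify_univariate(fake_fit("ITC"))$process, "niche")
  expect_equal(classify_univariate(fake_fit("SEGREGATED"))$process, "niche")
  expect_error(classify_univariate(fake_fit("WAT")), "unknown")

  expect_equal(classify_bivariate(fake_biv(TRUE))$process, "neutral")
  expect_equal(classify_bivariate(fake_biv(FALSE, "aggregated"))$process,
               "niche")
  expect_equal(classify_bivariate(fake_biv(FALSE, "segregated"))$process,
               "niche")
})

test_that("surface summaries count and proportion the model kinds", {
  res <- lapply(c("CSR", "CSR", "CSR"), function(k)
    classify_univariate(fake_fit(k)))
  s <- summarize_surface(res, "s1")
  expect_equal(as.numeric(s$model_proportions["CSR"]), 1)
  expect_equal(s$univariate_neutral, 3)
  expect_equal(s$univariate_niche, 0)

  res2 <- lapply(c("CSR", "TC", "ITC"), function(k)
    classify_univariate(fake_fit(k)))
  s2 <- summarize_surface(res2, "s2")
  expect_equal(sort(as.numeric(s2$model_proportions)), rep(1 / 3, 3))
  expect_equal(sum(s2$model_proportions), 1, tolerance = 1e-12)
  expect_equal(s2$univariate_neutral, 2)
  expect_equal(s2$univariate_niche, 1)

  s3 <- summarize_surface(c(res2, list(classify_bivariate(fake_biv(FALSE,
                                                                   "mixed")))),
                          "s3")
  expect_equal(s3$bivariate_niche, 1)
})

test_that("the pipeline writes schema-stable, seed-deterministic reports", {
  w <- owin_rect(c(0, 8), c(0, 8))
  spec <- community_spec(
    w,
    list(taxon_spec("rando", "CSR", 120, size_distribution = NULL),
         taxon_spec("clumpy", "TC", 350, list(sigma = 0.12, rho = 0.6),
                    size_distribution = NULL)),
    surface_name = "toy")
  map <- generate_community(spec, seed = 40)$map
  cfg <- sppa_config(n_sims = 99, envelope_rank = 5, n_sims_select = 19,
                     abundance_threshold = 30)

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_pipeline(list(map), cfg, out_dir = out1, seed = 5,
                     make_plots = FALSE)
  r2 <- run_pipeline(list(map), cfg, out_dir = out2, seed = 5,
                     make_plots = FALSE)

  files <- c("toy_bias_report.csv", "toy_fit_table.csv",
             "toy_bivariate_table.csv", "toy_surface_summary.csv")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  ft <- read.csv(file.path(out1, "toy_fit_table.csv"))
  expect_true(all(c("surface", "taxon", "n", "model_fit", "sigma", "rho",
                    "mean_cluster", "fit_basis", "p_d_pcf_CSR",
                    "p_d_nn_CSR") %in% names(ft)))
  expect_setequal(ft$taxon, c("rando", "clumpy"))

  # a failing surface is reported without aborting the others
  bad <- bed_map(data.frame(taxon = "x", x = 0.5, y = 0.5),
                 window = owin_rect(c(0, 1), c(0, 1)), surface_name = "bad")
  suppressMessages(r3 <- run_pipeline(list(bad, map), cfg, out_dir = NULL,
                                      seed = 5))
  expect_false(is.null(r3[[1]]$error))
  expect_null(r3$toy$error)
})

test_that("one taxon generated twice under the same process looks consistent", {
  # same-generator consistency across two surfaces: each observed PCF stays
  # inside the other surface's null-model envelope for its fitted cluster
  w <- owin_rect(c(0, 10), c(0, 10))
  tp <- thomas_params(0.15, 0.7, 7)
  grid <- distance_grid(0.1, 1.5, 3)
  g1 <- estimate_pcf(simulate_thomas(tp, w, seed = 61), w, grid)
  set.seed(62)
  sims <- sapply(1:99, function(i)
    estimate_pcf(simulate_thomas(tp, w), w, grid)$values)
  env <- sppa:::envelope_from_sims(g1, sims, 5)
  exc <- env$excursions
  expect_true(is.null(exc) || all(exc$n_steps <= grid$smoothing_span))
})
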