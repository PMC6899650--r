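test_that("census-scale file round-trips through CSV + WKT sidecar", {
  w <- owin_rect(c(0, 14.4), c(0, 115.16 / 14.4))  # 115.16 m2
  set.seed(101)
  n <- 761
  rec <- data.frame(
    specimen_id = seq_len(n),
    taxon = sample(c("charnia", "charniodiscus", "primocandelabrum"), n,
                   replace = TRUE),
    group_class = "described_taxon",
    x = runif(n, 0, 14.4), y = runif(n, 0, 115.16 / 14.4),
    disc_width = runif(n, 0.01, 0.08), disc_length = runif(n, 0.01, 0.08))
  map <- bed_map(rec, window = w, surface_name = "fixture")
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_map(map, path)
  m2 <- read_surface_map(path, surface_name = "fixture")
  expect_equal(nrow(m2$records), 761)
  expect_equal(window_area(m2$window), 115.16, tolerance = 1e-9)
  for (col in c("specimen_id", "taxon", "group_class", "x", "y",
                "disc_width", "disc_length"))
    expect_equal(m2$records[[col]], map$records[[col]])
  expect_equal(m2$surface_name, map$surface_name)
})

test_that("empty maps and all-absent optional columns survive the round trip", {
  w <- owin_rect(c(0, 2), c(0, 2))
  empty <- bed_map(data.frame(taxon = character(0), x = numeric(0),
                              y = numeric(0)), window = w)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_map(empty, path)
  back <- read_surface_map(path)
  expect_equal(nrow(back$records), 0)

  rec <- data.frame(taxon = "a", x = 1, y = 1, disc_width = NA_real_,
                    disc_length = NA_real_)
  map <- bed_map(rec, window = w)
  write_surface_map(map, path)
  hdr <- names(read.csv(path))
  expect_false(any(c("disc_width", "disc_length") %in% hdr))
})

test_that("malformed files raise typed errors; outside records are reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = "a", x_m = 1, y_m = 2), path,
            row.names = FALSE)
  expect_error(read_surface_map(path), class = "sppa_format_error")
  m <- read_surface_map(path, format_spec = c(taxon = "species"))
  expect_equal(m$records$taxon, "a")

  write.csv(data.frame(taxon = c("a", "b"), x_m = c("1.0", "oops"),
                       y_m = c(1, 2)), path, row.names = FALSE)
  err <- tryCatch(read_surface_map(path), error = function(e) e)
  expect_s3_class(err, "sppa_parse_error")
  expect_match(conditionMessage(err), "2")

  write.csv(data.frame(taxon = c("a", "b"), x_m = c(0.5, 9), y_m = c(0.5, 9)),
            path, row.names = FALSE)
  expect_warning(m <- read_surface_map(path, window = c(0, 0, 1, 1)),
                 "outside")
  expect_equal(nrow(m$records), 1)
  expect_equal(nrow(attr(m, "rejected")), 1)
})

test_that("abundance and group-class filtering follows the census rules", {
  w <- owin_rect(c(0, 10), c(0, 10))
  mk <- function(taxon, n, cls = "described_taxon")
    data.frame(taxon = taxon, group_class = cls,
               x = seq(0.1, 9.9, length.out = n),
               y = rep(5, n) + seq(0, 0.9, length.out = n))
  rec <- rbind(mk("rare", 29), mk("boundary", 30), mk("common", 40),
               mk("sb_low", 18), mk("ives", 35, "taphomorph"),
               mk("hiemalora", 40, "organ_taxon"), mk("discs", 50, "bin_group"))
  rec$specimen_id <- seq_len(nrow(rec))
  map <- bed_map(rec, window = w)

  f30 <- filter_analysis_taxa(map, 30)
  expect_setequal(unique(f30$records$taxon), c("boundary", "common"))
  rem <- attr(f30, "removed")
  expect_true("rare" %in% rem$low_abundance)
  expect_true("ives" %in% rem$taphomorph)

  f16 <- filter_analysis_taxa(map, 16)  # sparse-surface override
  expect_true(all(c("sb_low", "boundary", "common") %in%
                  unique(f16$records$taxon)))
  expect_false("hiemalora" %in% unique(f16$records$taxon))

  # idempotence
  expect_equal(filter_analysis_taxa(f30, 30)$records, f30$records)

  only_taph <- bed_map(mk("ives", 35, "taphomorph"), window = w)
  expect_equal(nrow(filter_analysis_taxa(only_taph, 30)$records), 0)
})

test_that("rectangular sub-windows clip exactly", {
  w <- owin_rect(c(0, 1), c(0, 1))
  xy <- fixture_points(100)
  map <- bed_map(data.frame(taxon = "t", x = xy[, 1], y = xy[, 2]),
                 window = w)
  full <- extract_rect_subwindow(map, c(0, 0, 1, 1))
  expect_equal(full$records$x, map$records$x)

  left <- extract_rect_subwindow(map, c(0, 0, 0.5, 1))
  expect_true(all(left$records$x <= 0.5))
  expect_equal(nrow(left$records), sum(xy[, 1] <= 0.5))
  expect_gt(nrow(left$records), 30)  # ~half of 100 uniform-ish points
  expect_lt(nrow(left$records), 70)

  empty <- extract_rect_subwindow(map, c(0.998, 0.998, 0.999, 0.999))
  expect_equal(nrow(empty$records), 0)
  expect_equal(window_area(empty$window), 1e-3^2, tolerance = 1e-9)

  expect_error(extract_rect_subwindow(map, c(0, 0, 2, 1)), "beyond")
})
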