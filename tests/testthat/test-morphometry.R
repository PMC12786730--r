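square_roi <- function(x0 = 0, y0 = 0, x1 = 10, y1 = 10) {
  roi(list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))))
}

test_that("apply_roi keeps interior/boundary points, drops exterior", {
  nt <- make_nucleus_table(c(5, 15, 10, 0), c(5, 5, 10, 0), rep(0.2, 4))
  kept <- apply_roi(nt, square_roi())
  # interior (5,5) kept; exterior (15,5) dropped; corners/edges inside
  expect_identical(kept$x_um, c(5, 10, 0))
  expect_error(roi(list()), "empty ROI")
  empty <- apply_roi(nt[0, ], square_roi())
  expect_identical(nrow(empty), 0L)
})

test_that("apply_roi equals the brute-force ray-casting oracle", {
  set.seed(13)
  ring <- cbind(c(0, 40, 55, 30, 10), c(0, 5, 35, 50, 30))  # convex-ish
  region <- roi(list(ring))
  nt <- make_nucleus_table(runif(100, -5, 60), runif(100, -5, 60),
                           rep(0.2, 100))
  kept <- apply_roi(nt, region)
  want <- vapply(seq_len(nrow(nt)), function(i)
    oracle_point_in_polygon(nt$x_um[i], nt$y_um[i], ring), TRUE)
  expect_identical(kept$nucleus_id, nt$nucleus_id[want])
})

test_that("GeoJSON ROIs load in um or pixel units", {
  path <- withr::local_tempfile(fileext = ".geojson")
  evocquant:::write_rect_roi_geojson(path, 0, 0, 100, 80, label = "tumor")
  r1 <- read_roi_geojson(path)
  expect_identical(r1$label, "tumor")
  expect_equal(max(r1$polygons[[1]][, 1]), 100)
  r2 <- read_roi_geojson(path, pixel_size_um = 0.5)  # pixel-unit dialect
  expect_equal(max(r2$polygons[[1]][, 1]), 50)
  writeLines('{"type": "FeatureCollection", "features": []}', path)
  expect_error(read_roi_geojson(path), "no Polygon")
})

test_that("count_cells produces the marker-specific quantities", {
  nt <- make_nucleus_table(seq_len(200), rep(1, 200), rep(0, 200))
  nt$positive <- c(rep(TRUE, 90), rep(FALSE, 110))
  ki <- count_cells(nt, "Ki67", sample_id = "S01", day = 0)
  expect_equal(ki$ocn, 200)
  expect_equal(ki$pi_percent, 45.0)
  expect_true(is.na(ki$tcn))

  nt2 <- make_nucleus_table(seq_len(150), rep(1, 150), rep(0, 150),
                            marker = "PLAP")
  nt2$positive <- c(rep(TRUE, 120), rep(FALSE, 30))
  pl <- count_cells(nt2, "PLAP", sample_id = "S01", day = 0)
  expect_equal(pl$tcn, 120)
  expect_equal(pl$stromal, 30)
  expect_equal(pl$tcn + pl$stromal, pl$ocn)  # conservation
  expect_true(is.na(pl$pi_percent))

  zero <- count_cells(nt[0, ], "Ki67")
  expect_true(is.na(zero$pi_percent))   # null, not 0
  expect_true(zero$flag_empty)
  expect_error(count_cells(nt2, "Ki67"), "marker")
})

test_that("assemble_timecourse validates schedule, duplicates, gaps", {
  recs <- do.call(rbind, lapply(c(0, 3, 7, 10), function(d)
    make_count_row("S01", d, "Ki67", 100, 50)))
  tc <- assemble_timecourse(recs)
  expect_identical(tc$day, c(0, 3, 7, 10))
  expect_identical(nrow(attr(tc, "missing_days")), 0L)

  expect_error(assemble_timecourse(rbind(recs, recs[3, ])), "duplicate")
  expect_error(assemble_timecourse(make_count_row("S01", 5, "Ki67", 10, 5)),
               "schedule")

  gap <- assemble_timecourse(recs[c(1, 3), ])
  expect_equal(attr(gap, "missing_days")$day, c(3, 10))
})

test_that("summarize_cohort: decreases, quartiles, CI and exclusions", {
  # planted decreases {10,20,30,40,50}% against baseline 100
  m <- cbind(rep(100, 5), 100 - c(10, 20, 30, 40, 50))
  colnames(m) <- c(0, 7)
  s <- summarize_cohort(m, "OCN")
  expect_equal(s$decrease$median_pct_decrease, 30)
  expect_equal(s$decrease$iqr_low, 20)
  expect_equal(s$decrease$iqr_high, 40)

  # single-sample arithmetic and the constant case
  m2 <- cbind(rep(100, 12), rep(50, 12)); colnames(m2) <- c(0, 10)
  s2 <- summarize_cohort(m2, "TCN")
  expect_equal(s2$decrease$median_pct_decrease, 50)
  expect_equal(s2$decrease$iqr_low, 50)
  expect_equal(s2$decrease$iqr_high, 50)
  expect_equal(100 * (100 - 67.4) / 100, 32.6)  # the statistic's definition

  # per-day t CI matches a direct computation
  set.seed(4)
  m3 <- matrix(rnorm(24, 100, 10), 12, 2); colnames(m3) <- c(0, 7)
  s3 <- summarize_cohort(m3, "OCN")
  ci <- t.test(m3[, 1])$conf.int
  expect_equal(s3$per_day$ci95_low[1], ci[1], tolerance = 1e-10)
  expect_equal(s3$per_day$ci95_high[1], ci[2], tolerance = 1e-10)

  # non-positive baseline excluded with a warning
  m4 <- m3; m4[1, 1] <- 0
  expect_warning(s4 <- summarize_cohort(m4, "OCN"), "baseline")
  expect_equal(s4$decrease$n, 11)
})

test_that("cohort survival fraction s recovers 100*(1-s) as noise -> 0", {
  for (s in c(0.9, 0.5, 0.25)) {
    spec <- cohort_sim_spec(tumor_survival = c(1, s, s^2, s^3),
                            stromal_survival = c(1, s, s^2, s^3),
                            baseline_ocn_sd = 0, sample_effect_sd = 0,
                            day_noise_cv = 0, pi_sd = 0, seed = 1)
    rec <- simulate_cohort(spec)$records
    m <- quantity_matrix(rec, "TCN")
    sm <- summarize_cohort(m, "TCN")
    expect_equal(sm$decrease$median_pct_decrease,
                 100 * (1 - s^(1:3)), tolerance = 1e-9)
  }
})

test_that("counts CSV round trip preserves the schema", {
  recs <- rbind(make_count_row("S01", 0, "Ki67", 100, 90),
                make_count_row("S01", 0, "PLAP", 120, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts_csv(recs, path)
  back <- read_counts_csv(path)
  expect_equal(back$ocn, recs$ocn)
  expect_equal(back$pi_percent, recs$pi_percent)
  expect_identical(names(back),
                   c("sample_id", "day", "marker", "ocn", "positive_count",
                     "pi_percent", "tcn", "stromal"))
})
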