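# helper: hematoxylin OD map with planted disks (no rendering round trip)
disk_map <- function(dim_px, centers_um, radii_um, od = 0.8, psz = 0.5) {
  m <- matrix(0, dim_px[1], dim_px[2])
  for (n in seq_len(nrow(centers_um))) {
    r_px <- radii_um[n] / psz
    ci <- centers_um[n, 2] / psz; cj <- centers_um[n, 1] / psz
    for (i in 0:(dim_px[1] - 1)) for (j in 0:(dim_px[2] - 1))
      if ((i - ci)^2 + (j - cj)^2 <= r_px^2) m[i + 1, j + 1] <- od
  }
  m
}

test_that("parameter validation catches bad blocks", {
  expect_error(detection_params(min_radius_um = 10, max_radius_um = 5),
               "min_radius_um < max_radius_um")
  expect_error(detection_params(pixel_size_um = 0), "pixel_size_um")
  expect_error(detection_params(dab_od_threshold = -1), ">= 0")
  expect_error(detect_nuclei(matrix(0, 5, 5), detection_params(),
                             pixel_size_um = NA), "pixel size")
})

test_that("all-zero map yields an empty detection table", {
  nuc <- detect_nuclei(matrix(0, 60, 60), detection_params(),
                       pixel_size_um = 0.5)
  expect_s3_class(nuc, "nucleus_table")
  expect_identical(nrow(nuc), 0L)
})

test_that("noiseless synthetic tile is recovered exactly (40 disks, r = 7)", {
  spec <- image_sim_spec(n_nuclei = 40, radius_um_range = c(7, 7),
                         min_separation_um = 25, noise_sd = 0,
                         positive_fraction = 0.4, seed = 21)
  tile <- simulate_ihc_tile(spec)
  ch <- unmix(rgb_to_od(tile$rgb, pixel_size_um = tile$pixel_size_um))
  nuc <- detect_nuclei(ch, detection_params(), marker = "Ki67")
  expect_identical(nrow(nuc), 40L)
  expect_true(all(abs(nuc$equiv_radius_um - 7) <= 0.5))
  cmp <- ground_truth_compare(nuc, tile$truth, match_radius_um = 3)
  expect_equal(cmp$f1, 1)
  expect_equal(cmp$positivity_agreement, 1)
  # ordering is deterministic by (y, x)
  expect_true(!is.unsorted(nuc$y_um))
})

test_that("size gate drops nuclei outside the 5-10 um radius window", {
  centers <- rbind(c(30, 30), c(90, 30))   # um
  m <- disk_map(c(240, 240), centers, radii_um = c(3, 7))
  nuc <- detect_nuclei(m, detection_params(), pixel_size_um = 0.5)
  expect_identical(nrow(nuc), 1L)
  expect_equal(nuc$x_um, 90, tolerance = 0.5)
  # invariant: nothing outside the gate on a busier tile
  spec <- image_sim_spec(n_nuclei = 50, seed = 3)
  tile <- simulate_ihc_tile(spec)
  ch <- unmix(rgb_to_od(tile$rgb, pixel_size_um = 0.5))
  nuc2 <- detect_nuclei(ch, detection_params())
  expect_true(all(nuc2$equiv_radius_um >= 5 & nuc2$equiv_radius_um <= 10))
})

test_that("watershed splits touching nuclei via the prominence threshold", {
  # two peaked (Gaussian-profile) nuclei whose foreground masks fuse into
  # one blob; the saddle between the peaks sits ~0.58 OD below them, so a
  # 0.15 split threshold separates them and a 0.7 threshold does not
  psz <- 0.5
  ii <- 0:199; jj <- 0:199
  bump <- function(cx_um, cy_um, s_um) {
    d2 <- outer((ii * psz - cy_um)^2, (jj * psz - cx_um)^2, "+")
    0.8 * exp(-d2 / (2 * s_um^2))
  }
  m <- pmin(bump(44, 50, 3) + bump(56, 50, 3), 1.2)
  nuc <- detect_nuclei(m, detection_params(), pixel_size_um = psz)
  expect_identical(nrow(nuc), 2L)
  expect_equal(sort(nuc$x_um), c(44, 56), tolerance = 2)
  nuc_merged <- detect_nuclei(
    m, detection_params(splitting_threshold = 0.7, max_radius_um = 12),
    pixel_size_um = psz)
  expect_identical(nrow(nuc_merged), 1L)
})

test_that("positivity is strict at the DAB threshold", {
  nt <- make_nucleus_table(c(10, 20, 30), c(10, 10, 10),
                           mean_dab_od = c(0.16, 0.15, 0.14))
  out <- classify_positive(nt, threshold = 0.15)
  expect_identical(out$positive, c(TRUE, FALSE, FALSE))
  expect_identical(out$nucleus_id, nt$nucleus_id)  # order preserved
})

test_that("mean nuclear DAB OD is measured on the nucleus mask", {
  centers <- rbind(c(40, 40))
  m <- disk_map(c(160, 160), centers, radii_um = 7)
  dab <- matrix(0.05, 160, 160)
  dab[m > 0] <- 0.4
  nuc <- detect_nuclei(m, detection_params(), dab_map = dab,
                       pixel_size_um = 0.5)
  expect_identical(nrow(nuc), 1L)
  expect_equal(nuc$mean_dab_od, 0.4, tolerance = 1e-9)
  expect_true(nuc$positive)
})

test_that("detection is byte-identical across reruns", {
  spec <- image_sim_spec(n_nuclei = 30, seed = 9)
  tile <- simulate_ihc_tile(spec)
  ch <- unmix(rgb_to_od(tile$rgb, pixel_size_um = 0.5))
  n1 <- detect_nuclei(ch, detection_params())
  n2 <- detect_nuclei(ch, detection_params())
  expect_identical(as.data.frame(n1), as.data.frame(n2))
})

test_that("expand_cells dilates and stays disjoint (vs brute force)", {
  # single disk r = 5 um, expansion 3 um -> territory ~ disk r = 8 um
  m <- disk_map(c(120, 120), rbind(c(30, 30)), radii_um = 5)
  nuc <- detect_nuclei(m, detection_params(), pixel_size_um = 0.5)
  ex <- expand_cells(nuc, expansion_um = 3)
  terr_r <- sqrt(ex$table$area_um2 / pi)
  expect_equal(terr_r, 8, tolerance = 0.5)
  # expansion 0 is the identity
  ex0 <- expand_cells(nuc, expansion_um = 0)
  expect_identical(ex0$territories, attr(nuc, "label_mask"))

  # two nuclei 10 um apart: disjoint territories, boundary equidistant
  m2 <- disk_map(c(140, 140), rbind(c(30, 30), c(40, 30)), radii_um = c(4, 4))
  nuc2 <- detect_nuclei(m2, detection_params(min_radius_um = 3),
                        pixel_size_um = 0.5)
  expect_identical(nrow(nuc2), 2L)
  ex2 <- expand_cells(nuc2, expansion_um = 3)
  lab <- attr(nuc2, "label_mask")
  terr <- ex2$territories
  # brute-force nearest-nucleus oracle over every expanded pixel
  px1 <- which(lab == 1L, arr.ind = TRUE) - 1L
  px2 <- which(lab == 2L, arr.ind = TRUE) - 1L
  ring <- which(terr > 0L & lab == 0L)
  mismatch_margin <- vapply(ring, function(p) {
    i <- (p - 1L) %% nrow(terr); j <- (p - 1L) %/% nrow(terr)
    d1 <- sqrt(min((px1[, 1] - i)^2 + (px1[, 2] - j)^2))
    d2 <- sqrt(min((px2[, 1] - i)^2 + (px2[, 2] - j)^2))
    expected <- if (d1 < d2) 1L else if (d2 < d1) 2L else terr[p]
    if (expected == terr[p]) 0 else abs(d1 - d2)
  }, 0)
  # any disagreement with the oracle sits within one pixel of the midline
  expect_true(all(mismatch_margin <= 1))
  # territories contain their nuclei and are disjoint by construction
  expect_true(all(terr[lab == 1L] == 1L) && all(terr[lab == 2L] == 2L))
})
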