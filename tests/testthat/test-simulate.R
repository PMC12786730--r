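test_that("empty tile spec renders a blank white tile", {
  tile <- simulate_ihc_tile(image_sim_spec(tile_px = c(64, 64),
                                           n_nuclei = 0, noise_sd = 0,
                                           seed = 1))
  expect_true(all(tile$rgb == 255L))
  expect_identical(nrow(tile$truth), 0L)
})

test_that("positive count follows round-half-even of the fraction", {
  spec <- image_sim_spec(n_nuclei = 50, positive_fraction = 0.4,
                         noise_sd = 0, seed = 2)
  tile <- simulate_ihc_tile(spec)
  expect_identical(sum(tile$truth$positive), 20L)
  # 0.5 * 25 = 12.5 -> banker's rounding to 12
  spec2 <- image_sim_spec(n_nuclei = 25, positive_fraction = 0.5,
                          noise_sd = 0, seed = 2)
  expect_identical(sum(simulate_ihc_tile(spec2)$truth$positive), 12L)
})

test_that("tiles are byte-identical under the same seed", {
  s <- image_sim_spec(n_nuclei = 20, seed = 33)
  t1 <- simulate_ihc_tile(s)
  t2 <- simulate_ihc_tile(s)
  expect_identical(t1$rgb, t2$rgb)
  expect_identical(t1$truth, t2$truth)
  t3 <- simulate_ihc_tile(image_sim_spec(n_nuclei = 20, seed = 34))
  expect_false(identical(t1$rgb, t3$rgb))
})

test_that("planted nuclei honour the minimum separation", {
  tile <- simulate_ihc_tile(image_sim_spec(n_nuclei = 60,
                                           min_separation_um = 24,
                                           seed = 5))
  tt <- tile$truth
  dmin <- min(dist(cbind(tt$x_um, tt$y_um)))
  expect_gte(dmin, 24)
})

test_that("infeasible packing raises a capacity error", {
  expect_error(simulate_ihc_tile(image_sim_spec(tile_px = c(80, 80),
                                                n_nuclei = 100,
                                                min_separation_um = 30,
                                                seed = 1)),
               "infeasible packing")
})

test_that("forward render + unmix recovers per-nucleus DAB within 0.02", {
  spec <- image_sim_spec(n_nuclei = 30, seed = 11)
  tile <- simulate_ihc_tile(spec)
  ch <- unmix(rgb_to_od(tile$rgb, pixel_size_um = tile$pixel_size_um))
  psz <- tile$pixel_size_um
  err <- vapply(seq_len(nrow(tile$truth)), function(n) {
    tt <- tile$truth[n, ]
    r_px <- (tt$radius_um - 1) / psz   # interior, away from the edge mix
    ci <- tt$y_um / psz; cj <- tt$x_um / psz
    ii <- which(outer((seq_len(nrow(ch$dab)) - 1 - ci)^2,
                      (seq_len(ncol(ch$dab)) - 1 - cj)^2, "+") <= r_px^2)
    abs(mean(ch$dab[ii]) - tt$dab_od)
  }, 0)
  expect_lt(max(err), 0.02)
})

test_that("cohort generator: identities, determinism, structure", {
  # all survival 1, all sds 0 -> constant across days
  spec0 <- cohort_sim_spec(tumor_survival = rep(1, 4),
                           stromal_survival = rep(1, 4),
                           baseline_ocn_sd = 0, sample_effect_sd = 0,
                           day_noise_cv = 0, pi_sd = 0, seed = 3)
  rec0 <- simulate_cohort(spec0)$records
  m0 <- quantity_matrix(rec0, "OCN")
  expect_true(all(abs(m0 - m0[, 1]) < 1e-9))

  # tumor survival 0.5 at day 7, zero noise -> TCN exactly halves
  spec1 <- cohort_sim_spec(tumor_survival = c(1, 1, 0.5, 0.25),
                           stromal_survival = c(1, 1, 0.9, 0.8),
                           sample_effect_sd = 0, day_noise_cv = 0,
                           seed = 4)
  m1 <- quantity_matrix(simulate_cohort(spec1)$records, "TCN")
  expect_equal(m1[, "7"], m1[, "0"] / 2, tolerance = 1e-12)

  # conservation and PI bounds on a noisy cohort
  rec <- simulate_cohort(cohort_sim_spec(seed = 6))$records
  plap <- rec[rec$marker == "PLAP", ]
  expect_equal(plap$tcn + plap$stromal, plap$ocn, tolerance = 1e-9)
  ki <- rec[rec$marker == "Ki67", ]
  expect_true(all(ki$pi_percent >= 0 & ki$pi_percent <= 100))
  expect_true(all(rec$positive_count <= rec$ocn + 1e-9))

  # determinism
  expect_identical(simulate_cohort(cohort_sim_spec(seed = 7))$records,
                   simulate_cohort(cohort_sim_spec(seed = 7))$records)

  # records pass the timecourse validator
  expect_silent(assemble_timecourse(rec))

  # invalid specs rejected
  expect_error(cohort_sim_spec(tumor_survival = c(1, 0.5, 0.7, 0.3)))
  expect_error(cohort_sim_spec(pi_curve = c(101, 90, 80, 70)))
})

test_that("per-day cohort means converge to the configured calibration", {
  # scaled-down law-of-large-numbers check: 60 cohorts x 12 samples
  mats <- lapply(1:60, function(s)
    quantity_matrix(simulate_cohort(cohort_sim_spec(seed = 1000 + s))$records,
                    "OCN"))
  grand <- colMeans(do.call(rbind, mats))
  spec <- cohort_sim_spec()
  # expected day-0 mean: baseline OCN (lognormal factors have mean ~1)
  expect_equal(unname(grand["0"]), spec$baseline_ocn_mean, tolerance = 0.02)
  # expected day-10 mean under the survival mixture
  exp10 <- spec$baseline_ocn_mean *
    (spec$tumor_fraction_mean * spec$tumor_survival[4] +
     (1 - spec$tumor_fraction_mean) * spec$stromal_survival[4])
  expect_equal(unname(grand["10"]), exp10, tolerance = 0.02)
})

test_that("simulate_quantity_cohort calibrates to per-day means/SDs", {
  mu <- c(47595.2, 42166.7, 32109.4, 21413.17)
  sd <- c(3617.6, 3494.2, 3649.9, 1933.9)
  m <- simulate_quantity_cohort(mu, sd, n_samples = 2000, seed = 13)
  expect_equal(unname(colMeans(m)), mu, tolerance = 0.02)
  # shared sample effect induces positive within-subject correlation
  expect_gt(cor(m[, 1], m[, 4]), 0.2)
})

test_that("ground_truth_compare: perfect, displaced, partial", {
  det <- make_nucleus_table(c(10, 20, 30), c(10, 20, 30), rep(0.4, 3))
  det$positive <- c(TRUE, FALSE, TRUE)
  truth <- data.frame(x_um = c(10, 20, 30), y_um = c(10, 20, 30),
                      positive = c(TRUE, FALSE, TRUE))
  perfect <- ground_truth_compare(det, truth, 3)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$positivity_agreement, 1)

  shifted <- det; shifted$x_um <- shifted$x_um + 6  # 2x match radius
  none <- ground_truth_compare(shifted, truth, 3)
  expect_equal(none$recall, 0)

  truth10 <- data.frame(x_um = seq(10, 100, 10), y_um = rep(5, 10),
                        positive = rep(TRUE, 10))
  det8 <- make_nucleus_table(seq(10, 80, 10), rep(5, 8), rep(0.4, 8))
  det8$positive <- TRUE
  part <- ground_truth_compare(det8, truth10, 3)
  expect_equal(part$recall, 0.8)
  expect_equal(part$precision, 1)
  expect_equal(part$f1, 2 * 0.8 / 1.8, tolerance = 1e-12)
})
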