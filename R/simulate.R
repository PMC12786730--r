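# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rnorm_trunc_pos <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (all(sd == 0)) return(pmin(pmax(rep_len(mean, n), lower), upper))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x > upper)
  tries <- 0L
  while (length(bad) > 0 && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), rep_len(mean, n)[bad],
                           rep_len(sd, n)[bad])
    bad <- which(x <= lower | x > upper)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(rep_len(mean, n)[bad], lower), upper)
  x
}

#' Specification for a synthetic H-DAB tile
#'
#' Defaults render the detection module's stated world: a 512 x 512 px tile
#' at 0.5 um/pixel (256 x 256 um), 40 disk nuclei with radii drawn in the
#' detector's 5-10 um gate, hematoxylin OD 0.8 +/- 0.05, DAB OD 0.4 +/-
#' 0.05 in positive nuclei versus 0.02 background-level DAB in negatives,
#' per-channel OD noise 0.02 and a 24 um minimum centre separation (nuclei
#' never overlap; splitting is exercised by blur, not contact).
#'
#' @param tile_px `(h, w)` tile size in pixels.
#' @param pixel_size_um um per pixel.
#' @param n_nuclei number of nuclei to plant.
#' @param radius_um_range `(min, max)` disk radius range, um.
#' @param positive_fraction fraction of DAB-positive nuclei in `[0, 1]`;
#'   the positive count is `round(fraction * n)` (round-half-even).
#' @param h_od_mean,h_od_sd hematoxylin OD of nuclei.
#' @param dab_od_pos_mean,dab_od_pos_sd DAB OD of positive nuclei.
#' @param dab_od_neg_mean DAB OD of negative nuclei.
#' @param noise_sd per-channel Gaussian OD noise.
#' @param min_separation_um minimum centre-to-centre distance.
#' @param seed integer seed (`NULL` = caller's RNG stream).
#' @return An `image_sim_spec` list.
#' @export
image_sim_spec <- function(tile_px = c(512L, 512L), pixel_size_um = 0.5,
                           n_nuclei = 40L, radius_um_range = c(5, 10),
                           positive_fraction = 0.5,
                           h_od_mean = 0.8, h_od_sd = 0.05,
                           dab_od_pos_mean = 0.4, dab_od_pos_sd = 0.05,
                           dab_od_neg_mean = 0.02, noise_sd = 0.02,
                           min_separation_um = 24, seed = NULL) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1,
            min_separation_um >= 0, noise_sd >= 0, pixel_size_um > 0,
            all(c(h_od_mean, dab_od_pos_mean, dab_od_neg_mean) >= 0),
            radius_um_range[1] > 0,
            radius_um_range[2] >= radius_um_range[1])
  structure(list(tile_px = as.integer(tile_px),
                 pixel_size_um = pixel_size_um,
                 n_nuclei = as.integer(n_nuclei),
                 radius_um_range = radius_um_range,
                 positive_fraction = positive_fraction,
                 h_od_mean = h_od_mean, h_od_sd = h_od_sd,
                 dab_od_pos_mean = dab_od_pos_mean,
                 dab_od_pos_sd = dab_od_pos_sd,
                 dab_od_neg_mean = dab_od_neg_mean,
                 noise_sd = noise_sd,
                 min_separation_um = min_separation_um, seed = seed),
            class = "image_sim_spec")
}

#' Render a ground-truthed synthetic H-DAB tile
#'
#' Plants disk nuclei by seeded rejection sampling honouring the minimum
#' separation, assigns per-nucleus hematoxylin/DAB optical densities, mixes
#' them through the Beer-Lambert forward model (`OD = h*h_vec + dab*dab_vec`
#' per pixel), adds Gaussian OD noise and renders to 8-bit RGB via
#' `I_c = 255 * 10^(-OD_c)`. The same seed yields a byte-identical tile.
#'
#' @param spec an [image_sim_spec()].
#' @param vectors stain vectors used for rendering.
#' @return list with `rgb` (integer `h x w x 3`), `truth` (data.frame
#'   `nucleus_id, x_um, y_um, radius_um, h_od, dab_od, positive`) and
#'   `pixel_size_um`.
#' @export
simulate_ihc_tile <- function(spec, vectors = default_hdab_vectors()) {
  stopifnot(inherits(spec, "image_sim_spec"))
  with_local_seed(spec$seed, {
    h_px <- spec$tile_px[1]; w_px <- spec$tile_px[2]
    psz <- spec$pixel_size_um
    n <- spec$n_nuclei
    truth <- data.frame(nucleus_id = integer(), x_um = numeric(),
                        y_um = numeric(), radius_um = numeric(),
                        h_od = numeric(), dab_od = numeric(),
                        positive = logical())
    h_conc <- matrix(0, h_px, w_px)
    dab_conc <- matrix(0, h_px, w_px)
    if (n > 0) {
      radii <- stats::runif(n, spec$radius_um_range[1],
                            spec$radius_um_range[2])
      xs <- ys <- numeric(n)
      max_try <- 2000L * n
      tries <- 0L
      for (i in seq_len(n)) {
        ok <- FALSE
        while (!ok) {
          tries <- tries + 1L
          if (tries > max_try)
            stop("infeasible packing: cannot place ", n, " nuclei at ",
                 spec$min_separation_um, " um separation in a ",
                 w_px * psz, " x ", h_px * psz, " um tile")
          x <- stats::runif(1, radii[i], w_px * psz - radii[i])
          y <- stats::runif(1, radii[i], h_px * psz - radii[i])
          if (i == 1 || all((xs[seq_len(i - 1)] - x)^2 +
                            (ys[seq_len(i - 1)] - y)^2 >=
                            spec$min_separation_um^2)) {
            xs[i] <- x; ys[i] <- y; ok <- TRUE
          }
        }
      }
      n_pos <- round(spec$positive_fraction * n)
      pos <- rep(FALSE, n)
      if (n_pos > 0) pos[sample.int(n, n_pos)] <- TRUE
      h_od <- rnorm_trunc_pos(n, spec$h_od_mean, spec$h_od_sd)
      dab_od <- ifelse(pos,
                       rnorm_trunc_pos(n, spec$dab_od_pos_mean,
                                       spec$dab_od_pos_sd),
                       spec$dab_od_neg_mean)
      for (i in seq_len(n)) {
        r_px <- radii[i] / psz
        ci <- ys[i] / psz; cj <- xs[i] / psz  # 0-based pixel coords
        i0 <- max(0L, floor(ci - r_px)); i1 <- min(h_px - 1L, ceiling(ci + r_px))
        j0 <- max(0L, floor(cj - r_px)); j1 <- min(w_px - 1L, ceiling(cj + r_px))
        ii <- (i0:i1); jj <- (j0:j1)
        d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
        inside <- d2 <= r_px^2
        sub_h <- h_conc[ii + 1L, jj + 1L]
        sub_d <- dab_conc[ii + 1L, jj + 1L]
        sub_h[inside] <- h_od[i]
        sub_d[inside] <- dab_od[i]
        h_conc[ii + 1L, jj + 1L] <- sub_h
        dab_conc[ii + 1L, jj + 1L] <- sub_d
      }
      truth <- data.frame(nucleus_id = seq_len(n), x_um = xs, y_um = ys,
                          radius_um = radii, h_od = h_od, dab_od = dab_od,
                          positive = pos)
    }
    od <- render_od(h_conc, dab_conc, vectors, pixel_size_um = psz)
    if (spec$noise_sd > 0)
      od$od <- pmax(od$od + stats::rnorm(length(od$od), 0, spec$noise_sd), 0)
    list(rgb = od_to_rgb(od), truth = truth, pixel_size_um = psz)
  })
}

#' Specification for a simulated longitudinal cohort
#'
#' Defaults are calibrated to the published per-day morphometry of the
#' 12-patient seminoma EVOC cohort: baseline overall cell number
#' 47,595.2 +/- 3,617.6 cells, tumor (PLAP+) fraction 0.853, per-day tumor
#' and stromal survival fractions equal to the published per-day mean
#' ratios, and a Ki-67 proliferation-index curve of (89.47, 88.05, 68.0,
#' 43.9)% with the published per-day SDs. A shared per-sample lognormal
#' effect (`sample_effect_sd`) induces within-subject correlation; an
#' independent per-(sample, day) lognormal factor (`day_noise_cv`) models
#' measurement/sampling noise (without it the repeated-measures error
#' variance of a no-decline cohort would be exactly zero).
#'
#' @param n_samples cohort size.
#' @param days culture-day schedule.
#' @param baseline_ocn_mean,baseline_ocn_sd day-0 OCN distribution (cells).
#' @param tumor_fraction_mean fraction of OCN that is tumor (PLAP+) at
#'   baseline.
#' @param tumor_survival,stromal_survival per-day fractions of the baseline
#'   tumor / stromal count (first element 1), non-increasing in `[0, 1]`.
#' @param pi_curve per-day mean PI (%).
#' @param pi_sd per-day PI SD (scalar or per-day vector).
#' @param sample_effect_sd sdlog of the shared per-sample effect.
#' @param day_noise_cv sdlog of the per-(sample, day) measurement factor.
#' @param seed integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_samples = 12L, days = c(0L, 3L, 7L, 10L),
                            baseline_ocn_mean = 47595.2,
                            baseline_ocn_sd = 3617.6,
                            tumor_fraction_mean = 40611.89 / 47595.2,
                            tumor_survival =
                              c(40611.89, 37960.3, 29408.2, 18986.72) /
                              40611.89,
                            stromal_survival =
                              c(5983.3, 4206.4, 2695.17, 2426.44) / 5983.3,
                            pi_curve = c(89.47, 88.05, 68.002, 43.886),
                            pi_sd = c(5.522, 6.424, 7.013, 5.501),
                            sample_effect_sd = 0.05,
                            day_noise_cv = 0.08,
                            seed = NULL) {
  k <- length(days)
  stopifnot(n_samples >= 2, k >= 2,
            length(tumor_survival) == k, length(stromal_survival) == k,
            length(pi_curve) == k,
            all(tumor_survival >= 0), all(tumor_survival <= 1),
            all(diff(tumor_survival) <= 0),
            all(stromal_survival >= 0), all(stromal_survival <= 1),
            all(diff(stromal_survival) <= 0),
            all(pi_curve >= 0), all(pi_curve <= 100),
            tumor_fraction_mean >= 0, tumor_fraction_mean <= 1,
            baseline_ocn_mean > 0, baseline_ocn_sd >= 0,
            sample_effect_sd >= 0, day_noise_cv >= 0)
  structure(list(n_samples = as.integer(n_samples), days = as.integer(days),
                 baseline_ocn_mean = baseline_ocn_mean,
                 baseline_ocn_sd = baseline_ocn_sd,
                 tumor_fraction_mean = tumor_fraction_mean,
                 tumor_survival = tumor_survival,
                 stromal_survival = stromal_survival,
                 pi_curve = pi_curve,
                 pi_sd = rep_len(pi_sd, k),
                 sample_effect_sd = sample_effect_sd,
                 day_noise_cv = day_noise_cv, seed = seed),
            class = "cohort_sim_spec")
}

#' Simulate a longitudinal EVOC cohort
#'
#' Structural generator: per sample, a truncated-normal baseline OCN is
#' split into tumor (`tumor_fraction`) and stromal compartments; each
#' compartment declines by its per-day survival fraction, multiplied by the
#' shared per-sample lognormal effect and an independent per-(sample, day)
#' lognormal measurement factor; `OCN = TCN + stromal` by construction.
#' PI is drawn per day from a `[0, 100]`-truncated normal. Counts are kept
#' real-valued (expected counts) so exact-scaling identities hold; the PLAP
#' record's `positive_count` is the TCN and the Ki-67 record's is
#' `PI/100 * OCN`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return A `simulated_cohort`: list with `records` (counts data.frame in
#'   the [write_counts_csv()] schema) and `truth` (the spec).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples; days <- spec$days; k <- length(days)
    ids <- sprintf("S%02d", seq_len(n))
    eps <- if (spec$sample_effect_sd > 0)
      exp(stats::rnorm(n, 0, spec$sample_effect_sd)) else rep(1, n)
    ocn0 <- rnorm_trunc_pos(n, spec$baseline_ocn_mean, spec$baseline_ocn_sd)
    tcn0 <- spec$tumor_fraction_mean * ocn0
    str0 <- ocn0 - tcn0
    recs <- vector("list", 2L * n * k)
    r <- 0L
    for (i in seq_len(n)) {
      for (d in seq_len(k)) {
        eta_t <- if (spec$day_noise_cv > 0)
          exp(stats::rnorm(1, 0, spec$day_noise_cv)) else 1
        eta_s <- if (spec$day_noise_cv > 0)
          exp(stats::rnorm(1, 0, spec$day_noise_cv)) else 1
        tcn <- tcn0[i] * spec$tumor_survival[d] * eps[i] * eta_t
        str <- str0[i] * spec$stromal_survival[d] * eps[i] * eta_s
        ocn <- tcn + str
        pi <- rnorm_trunc_pos(1, spec$pi_curve[d], spec$pi_sd[d],
                              lower = 0, upper = 100)
        r <- r + 1L
        recs[[r]] <- data.frame(sample_id = ids[i], day = days[d],
                                marker = "PLAP", ocn = ocn,
                                positive_count = tcn, pi_percent = NA_real_,
                                tcn = tcn, stromal = str,
                                stringsAsFactors = FALSE)
        r <- r + 1L
        recs[[r]] <- data.frame(sample_id = ids[i], day = days[d],
                                marker = "Ki67", ocn = ocn,
                                positive_count = pi / 100 * ocn,
                                pi_percent = pi, tcn = NA_real_,
                                stromal = NA_real_, stringsAsFactors = FALSE)
      }
    }
    structure(list(records = do.call(rbind, recs), truth = spec),
              class = "simulated_cohort")
  })
}

#' Simulate one quantity calibrated to per-day means and SDs
#'
#' Direct calibration generator used for published-table recovery: each
#' sample's per-day value is an independent truncated-normal draw from the
#' configured per-day mean/SD, multiplied by a shared per-sample lognormal
#' effect (which induces within-subject correlation and cancels in
#' per-sample ratios).
#'
#' @param day_means,day_sds per-day means and SDs (same length as `days`).
#' @param n_samples cohort size (default 12).
#' @param days day labels for the matrix columns.
#' @param sample_effect_sd sdlog of the shared per-sample effect.
#' @param seed integer seed.
#' @return n x k numeric matrix (rows samples, cols days).
#' @export
simulate_quantity_cohort <- function(day_means, day_sds, n_samples = 12L,
                                     days = c(0L, 3L, 7L, 10L),
                                     sample_effect_sd = 0.05, seed = NULL) {
  k <- length(days)
  stopifnot(length(day_means) == k, length(day_sds) == k)
  with_local_seed(seed, {
    eps <- if (sample_effect_sd > 0)
      exp(stats::rnorm(n_samples, 0, sample_effect_sd)) else rep(1, n_samples)
    m <- sapply(seq_len(k), function(d)
      rnorm_trunc_pos(n_samples, day_means[d], day_sds[d]))
    m <- m * eps
    dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                        as.character(days))
    m
  })
}

#' Compare detections against a ground-truth table
#'
#' Greedy nearest-neighbour matching: among all (detection, truth) pairs
#' within `match_radius_um`, repeatedly match the globally closest pair,
#' removing both. Reports precision, recall, F1 and, over matched pairs,
#' agreement of the positivity call.
#'
#' @param detections a `nucleus_table` (needs `x_um`, `y_um`, `positive`).
#' @param truth a ground-truth data.frame (`x_um`, `y_um`, `positive`).
#' @param match_radius_um maximum matching distance.
#' @return list `precision, recall, f1, n_matched, positivity_agreement`.
#' @export
ground_truth_compare <- function(detections, truth, match_radius_um = 3) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(precision = if (nd == 0 && nt == 0) 1 else 0,
                recall = if (nt == 0) 1 else 0,
                f1 = if (nd == 0 && nt == 0) 1 else 0,
                n_matched = 0L, positivity_agreement = NA_real_))
  dx <- outer(detections$x_um, truth$x_um, "-")
  dy <- outer(detections$y_um, truth$y_um, "-")
  dist <- sqrt(dx^2 + dy^2)
  dist[dist > match_radius_um] <- Inf
  pairs <- integer(0)
  agree <- logical(0)
  while (any(is.finite(dist))) {
    ij <- arrayInd(which.min(dist), dim(dist))
    i <- ij[1]; j <- ij[2]
    pairs <- c(pairs, i)
    agree <- c(agree, isTRUE(detections$positive[i] == truth$positive[j]))
    dist[i, ] <- Inf
    dist[, j] <- Inf
  }
  nm <- length(pairs)
  precision <- nm / nd
  recall <- nm / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, n_matched = nm,
       positivity_agreement = if (nm > 0) mean(agree) else NA_real_)
}
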