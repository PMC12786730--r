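# Independent oracles used across the suite. These deliberately use
# different code paths (explicit loops, base-R fitters) than the package.

# Brute-force repeated-measures sums-of-squares decomposition, written as
# explicit loops over cells.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_time <- 0
  for (j in seq_len(k)) ss_time <- ss_time + n * (mean(m[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (m[i, j] - grand)^2
  ss_err <- ss_tot - ss_time - ss_subj
  f <- (ss_time / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  # epsilons from the double-centered covariance, element by element
  S <- cov(m)
  Sc <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    Sc[a, b] <- S[a, b] - mean(S[a, ]) - mean(S[, b]) + mean(S)
  tr <- sum(diag(Sc))
  eps_gg <- tr^2 / ((k - 1) * sum(Sc^2))
  eps_hf <- if (k == 2) 1 else
    min(1, (n * (k - 1) * eps_gg - 2) /
             ((k - 1) * (n - 1 - (k - 1) * eps_gg)))
  list(f = unname(f), eps_gg = unname(eps_gg),
       eps_hf = unname(max(eps_hf, eps_gg)),
       eta_p2 = unname(ss_time / (ss_time + ss_err)))
}

# Per-point ray-casting point-in-polygon (even-odd), loop form, with an
# explicit on-boundary check.
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    nk <- if (k == n) 1 else k + 1
    x2 <- ring[nk, 1]; y2 <- ring[nk, 2]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    if (abs(cross) < 1e-9 &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12)
      return(TRUE)
    if ((y1 > py) != (y2 > py) &&
        px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      inside <- !inside
  }
  inside
}

# Fine Riemann (midpoint) integral of a function on [a, b].
oracle_riemann <- function(f, a, b, n = 1e6) {
  h <- (b - a) / n
  x <- a + (seq_len(n) - 0.5) * h
  sum(f(x)) * h
}

# Build a counts data.frame for one sample/day pair quickly.
make_count_row <- function(sample_id, day, marker, ocn, pos) {
  data.frame(sample_id = sample_id, day = day, marker = marker, ocn = ocn,
             positive_count = pos,
             pi_percent = if (marker == "Ki67" && ocn > 0) 100 * pos / ocn
                          else NA_real_,
             tcn = if (marker == "PLAP") pos else NA_real_,
             stromal = if (marker == "PLAP") ocn - pos else NA_real_,
             stringsAsFactors = FALSE)
}

# A tiny nucleus_table built by hand (no detection run), for contract tests.
make_nucleus_table <- function(x_um, y_um, mean_dab_od,
                               marker = "Ki67", pixel_size_um = 0.5) {
  n <- length(x_um)
  df <- data.frame(nucleus_id = seq_len(n), x_um = x_um, y_um = y_um,
                   area_um2 = rep(pi * 7^2, n),
                   equiv_radius_um = rep(7, n),
                   mean_h_od = rep(0.8, n), mean_dab_od = mean_dab_od,
                   positive = NA, marker = marker,
                   stringsAsFactors = FALSE)
  structure(df, class = c("nucleus_table", "data.frame"),
            label_mask = matrix(0L, 1, 1), pixel_size_um = pixel_size_um)
}
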