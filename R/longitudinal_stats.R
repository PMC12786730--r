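#' Repeated-measures matrix
#'
#' Complete-case n x k matrix of one outcome: rows are patient-derived
#' samples, columns are culture days.
#'
#' @param values numeric matrix (or data.frame) with no missing cells.
#' @param subjects optional subject ids (default rownames or S1..Sn).
#' @param timepoints optional day labels (default colnames or 1..k).
#' @return An `rm_matrix` object (a numeric matrix with dimnames set).
#' @export
rm_matrix <- function(values, subjects = NULL, timepoints = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) stop("need n >= 2 subjects and k >= 2 timepoints")
  if (any(!is.finite(m))) stop("repeated-measures matrix must be complete (no missing cells)")
  rownames(m) <- if (!is.null(subjects)) subjects else
    if (!is.null(rownames(m))) rownames(m) else paste0("S", seq_len(nrow(m)))
  colnames(m) <- if (!is.null(timepoints)) as.character(timepoints) else
    if (!is.null(colnames(m))) colnames(m) else as.character(seq_len(ncol(m)))
  structure(m, class = c("rm_matrix", "matrix", "array"))
}

#' Shapiro-Wilk normality screen per time point
#'
#' Runs `stats::shapiro.test` on each column of the matrix. Zero-variance
#' columns are flagged as degenerate (`W = NA`) rather than erroring the
#' whole screen.
#'
#' @param data an [rm_matrix()] (or coercible matrix), n in 3..5000.
#' @return data.frame `timepoint, n, W, p, degenerate`.
#' @export
normality_check <- function(data) {
  m <- as.matrix(data)
  if (nrow(m) < 3 || nrow(m) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  labs <- if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else
    colnames(m)
  do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (stats::sd(v) == 0)
      return(data.frame(timepoint = labs[j], n = length(v),
                        W = NA_real_, p = NA_real_, degenerate = TRUE))
    sw <- stats::shapiro.test(v)
    data.frame(timepoint = labs[j], n = length(v),
               W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
  }))
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Classical within-subject decomposition: `SS_total = SS_subject + SS_time
#' + SS_error`, `F = MS_time / MS_error` on `(k-1), (n-1)(k-1)` df.
#' Sphericity is assessed with Mauchly's W (chi-square approximation);
#' when `mauchly_p < sphericity_alpha` the Huynh-Feldt epsilon rescales the
#' degrees of freedom for the corrected p-value, otherwise the uncorrected
#' p is reported as corrected. Greenhouse-Geisser epsilon is computed from
#' the double-centered covariance matrix; Huynh-Feldt as
#' `min(1, (n(k-1)e_GG - 2) / ((k-1)(n - 1 - (k-1)e_GG)))`, floored at
#' `e_GG`. Effect size is partial eta squared
#' `SS_time / (SS_time + SS_error)`.
#'
#' For `k = 2` sphericity holds trivially (`W = 1`) and `F` equals the
#' squared paired t statistic.
#'
#' @param data an [rm_matrix()] or complete numeric matrix (rows subjects,
#'   cols timepoints).
#' @param sphericity_alpha Mauchly p-value below which the correction is
#'   applied (default 0.05).
#' @return An `rm_anova_result` list: `f_stat`, `df_time`, `df_error`,
#'   `df_time_corrected`, `df_error_corrected`, `ss_time`, `ss_subject`,
#'   `ss_error`, `epsilon_gg`, `epsilon_hf`, `mauchly_w`, `mauchly_p`,
#'   `p_uncorrected`, `p_corrected`, `correction_applied`, `eta_p2`,
#'   `degenerate` (TRUE when the error variance is zero and F is infinite).
#' @export
rm_anova <- function(data, sphericity_alpha = 0.05) {
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need n >= 2 and k >= 2")
  if (any(!is.finite(m))) stop("matrix must be complete")

  grand <- mean(m)
  col_mu <- colMeans(m)
  row_mu <- rowMeans(m)
  ss_time <- n * sum((col_mu - grand)^2)
  ss_subj <- k * sum((row_mu - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  if (ss_err < 0) ss_err <- 0  # numerical guard

  df_t <- k - 1
  df_e <- (n - 1) * (k - 1)
  ms_t <- ss_time / df_t
  ms_e <- ss_err / df_e
  degenerate <- ms_e <= .Machine$double.eps * max(1, ms_t)
  f <- if (degenerate) {
    if (ms_t <= .Machine$double.eps) 0 else Inf
  } else ms_t / ms_e
  eta_p2 <- if (ss_time + ss_err <= 0) 0 else ss_time / (ss_time + ss_err)

  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- stats::cov(m)
  J <- diag(k) - matrix(1 / k, k, k)
  Sc <- J %*% S %*% J
  tr <- sum(diag(Sc))
  eps_gg <- if (sum(Sc^2) <= 0) 1 else tr^2 / (df_t * sum(Sc^2))
  eps_gg <- min(max(eps_gg, 1 / df_t), 1)
  eps_hf <- if (k == 2) 1 else {
    num <- n * df_t * eps_gg - 2
    den <- df_t * (n - 1 - df_t * eps_gg)
    if (den <= 0) 1 else min(1, num / den)
  }
  eps_hf <- min(max(eps_hf, eps_gg), 1)

  # Mauchly's test of sphericity on orthonormal contrasts
  if (k == 2 || degenerate) {
    mauchly_w <- 1; mauchly_p <- 1
  } else {
    C <- contrast_orthonormal(k)
    Sct <- t(C) %*% S %*% C
    p <- k - 1
    dets <- det(Sct)
    mauchly_w <- if (dets <= 0) 0 else dets / (sum(diag(Sct)) / p)^p
    if (mauchly_w <= 0 || n - 1 <= p) {
      mauchly_p <- 0
    } else {
      dcoef <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
      chi2 <- -(n - 1) * dcoef * log(mauchly_w)
      dfm <- p * (p + 1) / 2 - 1
      mauchly_p <- stats::pchisq(chi2, dfm, lower.tail = FALSE)
    }
  }

  p_unc <- if (degenerate) {
    if (is.infinite(f)) 0 else 1
  } else stats::pf(f, df_t, df_e, lower.tail = FALSE)
  apply_corr <- is.finite(mauchly_p) && mauchly_p < sphericity_alpha
  dft_c <- if (apply_corr) df_t * eps_hf else df_t
  dfe_c <- if (apply_corr) df_e * eps_hf else df_e
  p_cor <- if (!apply_corr || degenerate) p_unc else
    stats::pf(f, dft_c, dfe_c, lower.tail = FALSE)

  structure(list(f_stat = f, df_time = df_t, df_error = df_e,
                 df_time_corrected = dft_c, df_error_corrected = dfe_c,
                 ss_time = ss_time, ss_subject = ss_subj, ss_error = ss_err,
                 epsilon_gg = eps_gg, epsilon_hf = eps_hf,
                 mauchly_w = mauchly_w, mauchly_p = mauchly_p,
                 p_uncorrected = p_unc, p_corrected = p_cor,
                 correction_applied = apply_corr, eta_p2 = eta_p2,
                 degenerate = degenerate, n = n, k = k),
            class = "rm_anova_result")
}

# k x (k-1) orthonormal contrast matrix (Helmert, normalized)
contrast_orthonormal <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d, k = %d)\n", x$n, x$k))
  cat(sprintf("  F(%g, %g) = %.4f, p = %.4g (uncorrected)\n",
              x$df_time, x$df_error, x$f_stat, x$p_uncorrected))
  cat(sprintf("  Mauchly W = %.4f (p = %.4g); eps_GG = %.4f, eps_HF = %.4f\n",
              x$mauchly_w, x$mauchly_p, x$epsilon_gg, x$epsilon_hf))
  if (x$correction_applied)
    cat(sprintf("  Huynh-Feldt corrected: F(%.2f, %.2f), p = %.4g\n",
                x$df_time_corrected, x$df_error_corrected, x$p_corrected))
  else cat("  sphericity not rejected; corrected p = uncorrected p\n")
  cat(sprintf("  partial eta^2 = %.4f\n", x$eta_p2))
  invisible(x)
}

#' Post hoc pairwise comparisons between time points
#'
#' All `k(k-1)/2` pairs. `"bonferroni_paired_t"` (default) runs a paired t
#' test per pair and multiplies p by the number of pairs (capped at 1);
#' `"tukey_hsd"` uses the studentized range on the repeated-measures error
#' term (`q = |mean_i - mean_j| / sqrt(MS_error / n)` referred to
#' `ptukey(k, df_error)`). Both report the mean difference with a t-based
#' 95% CI on the paired differences and Cohen's dz
#' (`mean(diff) / sd(diff)`, `NA` with a flag when `sd(diff) = 0`).
#'
#' @param data an [rm_matrix()] or complete matrix.
#' @param method `"bonferroni_paired_t"` or `"tukey_hsd"`.
#' @param conf CI level (default 0.95).
#' @return data.frame `day_a, day_b, mean_diff, ci_low, ci_high, p_adjusted,
#'   method, cohen_dz, dz_defined`.
#' @export
posthoc_pairwise <- function(data,
                             method = c("bonferroni_paired_t", "tukey_hsd"),
                             conf = 0.95) {
  method <- match.arg(method)
  m <- as.matrix(data)
  n <- nrow(m); k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  aov_res <- if (method == "tukey_hsd") rm_anova(m) else NULL
  out <- lapply(seq_len(n_pairs), function(idx) {
    a <- pairs[1, idx]; b <- pairs[2, idx]
    d <- m[, a] - m[, b]
    md <- mean(d); sdd <- stats::sd(d)
    se <- sdd / sqrt(n)
    tcrit <- stats::qt(1 - (1 - conf) / 2, n - 1)
    dz_def <- sdd > 0
    dz <- if (dz_def) md / sdd else NA_real_
    if (method == "bonferroni_paired_t") {
      p <- if (dz_def)
        min(1, 2 * stats::pt(abs(md / se), n - 1, lower.tail = FALSE) *
              n_pairs)
      else if (md == 0) 1 else 0
    } else {
      q <- abs(md) / sqrt(aov_res$ss_error / aov_res$df_error / n)
      p <- stats::ptukey(q, k, aov_res$df_error, lower.tail = FALSE)
    }
    data.frame(day_a = colnames(m)[a], day_b = colnames(m)[b],
               mean_diff = md, ci_low = md - tcrit * se,
               ci_high = md + tcrit * se, p_adjusted = p, method = method,
               cohen_dz = dz, dz_defined = dz_def,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Friedman rank test across time points
#'
#' Non-parametric sensitivity analysis for the repeated-measures design:
#' values are ranked within each subject (mid-ranks for ties) and
#' `chi2 = 12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)` is referred to a
#' chi-square with `k - 1` df. No tie correction is applied (the classical
#' statistic); with heavy ties the test is conservative.
#'
#' @param data an [rm_matrix()] or complete matrix, `k >= 3`.
#' @return list `chi2, df, p`.
#' @export
friedman_test <- function(data) {
  m <- as.matrix(data)
  n <- nrow(m); k <- ncol(m)
  if (k < 3) stop("Friedman test needs k >= 3 timepoints")
  if (n < 2) stop("Friedman test needs n >= 2 subjects")
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  df <- k - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Full statistical report for one quantity
#'
#' Bundles the §-style battery: per-day normality screen, RM-ANOVA with
#' sphericity handling, post hoc pairwise contrasts and the Friedman
#' sensitivity test.
#'
#' @param mat complete n x k matrix (rows samples, cols days).
#' @param quantity label.
#' @param posthoc_method passed to [posthoc_pairwise()].
#' @param sphericity_alpha passed to [rm_anova()].
#' @return A `stats_report` list.
#' @export
stats_battery <- function(mat, quantity = "quantity",
                          posthoc_method = "bonferroni_paired_t",
                          sphericity_alpha = 0.05) {
  m <- as.matrix(mat)
  ok <- apply(is.finite(m), 1, all)
  m <- m[ok, , drop = FALSE]
  res <- list(quantity = quantity,
              n = nrow(m), k = ncol(m),
              normality = normality_check(m),
              anova = rm_anova(m, sphericity_alpha = sphericity_alpha),
              posthoc = posthoc_pairwise(m, method = posthoc_method),
              friedman = if (ncol(m) >= 3) friedman_test(m) else NULL)
  class(res) <- "stats_report"
  res
}

#' @export
print.stats_report <- function(x, ...) {
  cat("==", x$quantity, sprintf("(n = %d, k = %d) ==\n", x$n, x$k))
  cat("\nShapiro-Wilk per day:\n"); print(x$normality, row.names = FALSE)
  cat("\n"); print(x$anova)
  cat("\nPost hoc pairwise:\n")
  ph <- x$posthoc
  ph$mean_diff <- round(ph$mean_diff, 3)
  ph$ci_low <- round(ph$ci_low, 3); ph$ci_high <- round(ph$ci_high, 3)
  ph$p_adjusted <- signif(ph$p_adjusted, 3)
  ph$cohen_dz <- round(ph$cohen_dz, 3)
  print(ph, row.names = FALSE)
  if (!is.null(x$friedman))
    cat(sprintf("\nFriedman: chi2(%d) = %.3f, p = %.4g\n",
                x$friedman$df, x$friedman$chi2, x$friedman$p))
  invisible(x)
}
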