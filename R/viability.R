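#' Trapezoidal area under a time course
#'
#' `AUC = sum_i (d[i+1] - d[i]) * (v[i] + v[i+1]) / 2`, handling the
#' non-uniform culture grid (days 0, 3, 7, 10). Units are value-units times
#' days (e.g. %·day for a proliferation-index curve).
#'
#' @param days strictly increasing numeric vector (>= 2 points).
#' @param values non-negative values, same length as `days`.
#' @return The AUC (scalar).
#' @export
trapezoid_auc <- function(days, values) {
  days <- as.numeric(days); values <- as.numeric(values)
  if (length(days) < 2) stop("need at least 2 time points")
  if (length(days) != length(values)) stop("days and values lengths differ")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  sum(diff(days) * (values[-length(values)] + values[-1]) / 2)
}

#' Per-sample trajectory container
#'
#' @param sample_id sample identifier.
#' @param quantity one of `"OCN"`, `"TCN"`, `"stromal"`, `"PI"`.
#' @param days strictly increasing culture days.
#' @param values non-negative values (cells, or % for PI).
#' @return A `trajectory_series` list.
#' @export
trajectory_series <- function(sample_id, quantity, days, values) {
  quantity <- match.arg(quantity, c("OCN", "TCN", "stromal", "PI"))
  days <- as.numeric(days); values <- as.numeric(values)
  if (length(days) != length(values)) stop("days and values lengths differ")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (any(values < 0)) stop("values must be >= 0")
  structure(list(sample_id = sample_id, quantity = quantity,
                 days = days, values = values),
            class = "trajectory_series")
}

#' EVOC score: control-to-experimental AUC ratio
#'
#' `score = AUC(control PI curve) / AUC(experimental PI curve)`, the
#' integrative viability comparison between two culture arms of the same
#' tumor. Scores above 1 indicate lower proliferative viability in the
#' experimental arm. Both series must be PI trajectories on identical day
#' grids; no interpolation is performed across mismatched grids.
#'
#' @param control,experimental `trajectory_series` of quantity `"PI"` (or
#'   plain lists with `days`/`values`/`quantity`).
#' @return An `evoc_score` list: `score`, `auc_control`,
#'   `auc_experimental`, `orientation` (documentation string).
#' @export
evoc_score <- function(control, experimental) {
  chk <- function(s, nm) {
    if (!is.null(s$quantity) && s$quantity != "PI")
      stop(nm, " series must be a PI trajectory")
    if (is.null(s$days) || is.null(s$values)) stop(nm, " series malformed")
    s
  }
  control <- chk(control, "control")
  experimental <- chk(experimental, "experimental")
  if (length(control$days) != length(experimental$days) ||
      any(control$days != experimental$days))
    stop("day grids differ between arms; no interpolation is performed")
  auc_c <- trapezoid_auc(control$days, control$values)
  auc_e <- trapezoid_auc(experimental$days, experimental$values)
  if (auc_e <= 0) stop("experimental AUC is 0; EVOC score undefined")
  structure(list(score = auc_c / auc_e, auc_control = auc_c,
                 auc_experimental = auc_e,
                 orientation = paste("score > 1 indicates lower",
                                     "proliferative viability in the",
                                     "experimental arm")),
            class = "evoc_score")
}

#' @export
print.evoc_score <- function(x, ...) {
  cat(sprintf("EVOC score: %.4f (control AUC %.2f / experimental AUC %.2f)\n",
              x$score, x$auc_control, x$auc_experimental))
  cat(" ", x$orientation, "\n")
  invisible(x)
}

#' Per-sample AUCs for a quantity matrix
#'
#' @param mat n x k matrix from [quantity_matrix()], columns named by day.
#' @param quantity label stored on each result.
#' @return data.frame `sample_id, quantity, auc` (samples with missing
#'   values are dropped with a warning).
#' @export
auc_table <- function(mat, quantity = "PI") {
  days <- as.numeric(colnames(mat))
  ok <- apply(is.finite(mat), 1, all)
  if (any(!ok))
    warning(sum(!ok), " sample(s) dropped from AUC: incomplete series")
  data.frame(sample_id = rownames(mat)[ok], quantity = quantity,
             auc = apply(mat[ok, , drop = FALSE], 1, function(v)
               trapezoid_auc(days, v)),
             row.names = NULL, stringsAsFactors = FALSE)
}
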