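#' Region of interest (tumor ROI)
#'
#' A set of closed polygon rings in micrometre coordinates, as delineated by
#' a pathologist on the slide. Rings need not repeat their first vertex.
#'
#' @param polygons a list of two-column matrices (x_um, y_um), each with at
#'   least 3 vertices.
#' @param label free-text label.
#' @return An object of class `roi`.
#' @export
roi <- function(polygons, label = "tumor") {
  if (!is.list(polygons) || length(polygons) == 0)
    stop("empty ROI: supply at least one polygon")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("polygon rings must be two-column (x, y)")
    # drop an explicit closing vertex
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3) stop("polygon rings need >= 3 distinct vertices")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  structure(list(polygons = polygons, label = label), class = "roi")
}

#' Read a tumor ROI from GeoJSON
#'
#' Accepts a FeatureCollection (or bare geometry) of Polygon/MultiPolygon
#' features. Coordinates are taken as micrometres; for QuPath-style exports
#' whose coordinates are pixels, pass the slide's `pixel_size_um` to convert
#' on load. Only exterior rings are used (tumor ROIs are solid regions).
#'
#' @param path GeoJSON file path.
#' @param pixel_size_um when non-`NULL`, coordinates are pixels and are
#'   multiplied by this scale.
#' @param label ROI label; defaults to the first feature's
#'   `properties$classification$name` or `"tumor"`.
#' @return An `roi` object.
#' @export
read_roi_geojson <- function(path, pixel_size_um = NULL, label = NULL) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- list()
  grab <- function(geom) {
    if (is.null(geom$type)) return()
    if (geom$type == "Polygon") {
      geoms[[length(geoms) + 1]] <<- geom$coordinates[[1]]
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates)
        geoms[[length(geoms) + 1]] <<- poly[[1]]
    }
  }
  if (identical(g$type, "FeatureCollection")) {
    for (f in g$features) {
      grab(f$geometry)
      if (is.null(label) && !is.null(f$properties$classification$name))
        label <- f$properties$classification$name
    }
  } else if (identical(g$type, "Feature")) grab(g$geometry)
  else grab(g)
  if (length(geoms) == 0) stop("no Polygon/MultiPolygon geometry in ", path)
  polys <- lapply(geoms, function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    if (!is.null(pixel_size_um)) m <- m * pixel_size_um
    m
  })
  roi(polys, label = if (is.null(label)) "tumor" else label)
}

# Even-odd point-in-polygon with boundary counted as inside.
pip_even_odd <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # boundary test: point within the segment's bounding box and collinear
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- abs(cross) < 1e-9 * max(1, abs(x2 - x1) + abs(y2 - y1)) &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Restrict detections to a region of interest
#'
#' Keeps nuclei whose centroid lies inside (or exactly on the boundary of)
#' any ROI polygon, by the even-odd rule. Coordinates of nuclei and ROI must
#' share the same micrometre frame.
#'
#' @param nuclei a `nucleus_table` (or any data.frame with `x_um`, `y_um`).
#' @param region an [roi()] object.
#' @return The filtered table (attributes preserved).
#' @export
apply_roi <- function(nuclei, region) {
  if (!inherits(region, "roi")) stop("`region` must be an roi object")
  if (nrow(nuclei) == 0) return(nuclei)
  keep <- rep(FALSE, nrow(nuclei))
  for (ring in region$polygons)
    keep <- keep | pip_even_odd(nuclei$x_um, nuclei$y_um, ring)
  out <- nuclei[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("label_mask", "pixel_size_um"))
    attr(out, a) <- attr(nuclei, a)
  out
}

#' Count cells for one sample and time point
#'
#' Produces the morphometric quantities for one stained section: OCN (all
#' detections in the ROI), the positive count, and the marker-specific
#' readout -- the proliferation index `PI = 100 * positive / OCN` (%) for
#' Ki-67 sections, or the tumor cell number `TCN = positive` and stromal
#' count `OCN - TCN` for PLAP sections.
#'
#' @param nuclei_in_roi detection table already restricted to the tumor ROI;
#'   its `positive` column must be filled.
#' @param marker `"Ki67"` or `"PLAP"`.
#' @param sample_id,day identifiers stored on the record.
#' @return A one-row data.frame with columns `sample_id, day, marker, ocn,
#'   positive_count, pi_percent, tcn, stromal` plus a logical `flag_empty`
#'   set when `ocn == 0` (PI is `NA`, never 0, in that case).
#' @export
count_cells <- function(nuclei_in_roi, marker = c("Ki67", "PLAP"),
                        sample_id = NA_character_, day = NA_integer_) {
  marker <- match.arg(marker)
  if (nrow(nuclei_in_roi) > 0 && any(is.na(nuclei_in_roi$positive)))
    stop("positivity not called; run classify_positive() first")
  if (nrow(nuclei_in_roi) > 0) {
    mk <- unique(stats::na.omit(nuclei_in_roi$marker))
    if (length(mk) > 1 || (length(mk) == 1 && mk != marker))
      stop("mixed or mismatched marker labels in detection table")
  }
  ocn <- nrow(nuclei_in_roi)
  pos <- if (ocn == 0) 0L else sum(nuclei_in_roi$positive)
  data.frame(sample_id = sample_id, day = as.integer(day), marker = marker,
             ocn = ocn, positive_count = pos,
             pi_percent = if (marker == "Ki67" && ocn > 0)
               100 * pos / ocn else NA_real_,
             tcn = if (marker == "PLAP") pos else NA_integer_,
             stromal = if (marker == "PLAP") ocn - pos else NA_integer_,
             flag_empty = ocn == 0,
             stringsAsFactors = FALSE)
}

#' Assemble per-sample time courses from count records
#'
#' Validates and orders count records into per-sample trajectories on the
#' culture-day schedule.
#'
#' @param records data.frame of stacked [count_cells()] rows (or a counts
#'   CSV read back in).
#' @param schedule expected culture days; default `c(0, 3, 7, 10)`.
#' @return A data.frame sorted by (sample, marker, day) with a logical
#'   attribute-free column `missing_days` attached as an attribute:
#'   a data.frame listing (sample_id, marker, day) combinations absent from
#'   `records`. Duplicate (sample, day, marker) rows are an error.
#' @export
assemble_timecourse <- function(records, schedule = c(0L, 3L, 7L, 10L)) {
  req <- c("sample_id", "day", "marker")
  if (!all(req %in% names(records)))
    stop("records must have sample_id, day, marker columns")
  key <- interaction(records$sample_id, records$day, records$marker,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (sample, day, marker) records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  bad_day <- setdiff(unique(records$day), schedule)
  if (length(bad_day))
    stop("days outside the configured schedule: ",
         paste(bad_day, collapse = ", "))
  out <- records[order(records$sample_id, records$marker, records$day), ,
                 drop = FALSE]
  rownames(out) <- NULL
  combos <- unique(out[, c("sample_id", "marker")])
  miss <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    have <- out$day[out$sample_id == combos$sample_id[i] &
                    out$marker == combos$marker[i]]
    md <- setdiff(schedule, have)
    if (length(md) == 0) return(NULL)
    data.frame(sample_id = combos$sample_id[i], marker = combos$marker[i],
               day = md, stringsAsFactors = FALSE)
  }))
  attr(out, "missing_days") <- if (is.null(miss))
    data.frame(sample_id = character(), marker = character(),
               day = integer()) else miss
  out
}

#' Extract one quantity as a per-sample series matrix
#'
#' Helper shared by the summary and statistics stages: wide n x k matrix of
#' one quantity (rows = samples, cols = days in `schedule` order).
#'
#' @param records assembled count records.
#' @param quantity one of `"OCN"`, `"TCN"`, `"stromal"`, `"PI"`.
#' @param schedule culture days.
#' @return numeric matrix with sample ids as rownames and days as colnames;
#'   missing cells are `NA`.
#' @export
quantity_matrix <- function(records, quantity = c("OCN", "TCN", "stromal", "PI"),
                            schedule = c(0L, 3L, 7L, 10L)) {
  quantity <- match.arg(quantity)
  col <- switch(quantity, OCN = "ocn", TCN = "tcn", stromal = "stromal",
                PI = "pi_percent")
  marker <- if (quantity == "PI") "Ki67" else if (quantity == "OCN")
    NA_character_ else "PLAP"
  rec <- records
  if (!is.na(marker)) rec <- rec[rec$marker == marker, , drop = FALSE]
  if (quantity == "OCN" && all(c("Ki67", "PLAP") %in% rec$marker)) {
    # OCN is defined on every slide; prefer the PLAP series when both exist
    rec <- rec[rec$marker == "PLAP", , drop = FALSE]
  }
  samples <- sort(unique(rec$sample_id))
  m <- matrix(NA_real_, length(samples), length(schedule),
              dimnames = list(samples, schedule))
  for (i in seq_len(nrow(rec))) {
    d <- match(rec$day[i], schedule)
    if (!is.na(d)) m[rec$sample_id[i], d] <- rec[[col]][i]
  }
  m
}

#' Cohort summary: per-day statistics and median percent decreases
#'
#' For each culture day: mean, SD (n-1 denominator) and a t-based 95% CI of
#' the cohort values. For each day after baseline: the per-sample percent
#' decrease `100 * (x0 - xd) / x0` against that sample's own day-0 value,
#' summarized as the cohort median with IQR (linear-interpolation quartiles,
#' R type 7). Samples with baseline `x0 <= 0` are excluded with a warning.
#'
#' @param mat n x k matrix from [quantity_matrix()] (cols named by day).
#' @param quantity label stored on the output.
#' @param conf confidence level for the per-day CI.
#' @return A `cohort_summary`: list with `per_day` (day, n, mean, sd,
#'   ci95_low, ci95_high) and `decrease` (day, median_pct_decrease, iqr_low,
#'   iqr_high) data.frames.
#' @export
summarize_cohort <- function(mat, quantity = "quantity", conf = 0.95) {
  mat <- as.matrix(mat)
  days <- as.integer(colnames(mat))
  if (nrow(mat) < 2) stop("need >= 2 samples to summarize a cohort")
  per_day <- do.call(rbind, lapply(seq_along(days), function(j) {
    v <- mat[, j][is.finite(mat[, j])]
    n <- length(v)
    mu <- mean(v); sdv <- stats::sd(v)
    half <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) * sdv / sqrt(n)
            else NA_real_
    data.frame(day = days[j], n = n, mean = mu, sd = sdv,
               ci95_low = mu - half, ci95_high = mu + half)
  }))
  x0 <- mat[, 1]
  ok <- is.finite(x0) & x0 > 0
  if (any(!ok))
    warning(sum(!ok), " sample(s) excluded: baseline <= 0 or missing")
  dec <- do.call(rbind, lapply(which(days > days[1]), function(j) {
    d <- 100 * (x0[ok] - mat[ok, j]) / x0[ok]
    d <- d[is.finite(d)]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(day = days[j], n = length(d), median_pct_decrease = q[2],
               iqr_low = q[1], iqr_high = q[3])
  }))
  structure(list(quantity = quantity, per_day = per_day, decrease = dec),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$quantity, "\n\nPer-day (mean ± SD, 95% CI):\n")
  print(transform(x$per_day, mean = round(mean, 2), sd = round(sd, 2),
                  ci95_low = round(ci95_low, 2),
                  ci95_high = round(ci95_high, 2)), row.names = FALSE)
  cat("\nPercent decrease vs baseline (median [IQR]):\n")
  print(transform(x$decrease,
                  median_pct_decrease = round(median_pct_decrease, 1),
                  iqr_low = round(iqr_low, 1), iqr_high = round(iqr_high, 1)),
        row.names = FALSE)
  invisible(x)
}

#' Write/read the counts table CSV
#'
#' Schema: `sample_id, day, marker, ocn, positive_count, pi_percent, tcn,
#' stromal`.
#'
#' @param records counts data.frame.
#' @param path CSV path.
#' @return `path` (write) or the records data.frame (read).
#' @export
write_counts_csv <- function(records, path) {
  cols <- c("sample_id", "day", "marker", "ocn", "positive_count",
            "pi_percent", "tcn", "stromal")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
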