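#' Nucleus detection parameters
#'
#' Parameter block for [detect_nuclei()], defaulting to the positive-cell
#' detection settings used for seminoma H-DAB slides: analysis pixel size
#' 0.5 um/pixel, nucleus radius gate 5-10 um (on the equivalent circular
#' radius), nucleus splitting threshold 0.15 OD (minimum hematoxylin-OD
#' prominence separating two watershed markers), cell expansion 3 um and a
#' DAB positivity threshold of 0.15 OD on the mean nuclear DAB signal. The
#' foreground hematoxylin threshold (0.1 OD) and smoothing sigma (1 um) are
#' implementation parameters exposed so users can match their staining.
#'
#' @param pixel_size_um analysis pixel size, um/pixel.
#' @param min_radius_um,max_radius_um size gate on the equivalent circular
#'   radius of a detected nucleus, um.
#' @param splitting_threshold minimum OD prominence between watershed
#'   markers (h-maxima depth), OD units.
#' @param cell_expansion_um outward expansion defining the cell territory.
#' @param dab_od_threshold mean nuclear DAB OD above which (strictly) a
#'   nucleus is called positive.
#' @param smoothing_sigma_um Gaussian smoothing sigma for marker finding.
#' @param h_od_threshold hematoxylin OD foreground threshold.
#' @return A `detection_params` list.
#' @export
detection_params <- function(pixel_size_um = 0.5,
                             min_radius_um = 5,
                             max_radius_um = 10,
                             splitting_threshold = 0.15,
                             cell_expansion_um = 3,
                             dab_od_threshold = 0.15,
                             smoothing_sigma_um = 1.0,
                             h_od_threshold = 0.1) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (!(min_radius_um > 0 && min_radius_um < max_radius_um))
    stop("need 0 < min_radius_um < max_radius_um")
  thr <- c(splitting_threshold, cell_expansion_um, dab_od_threshold,
           smoothing_sigma_um, h_od_threshold)
  if (any(thr < 0)) stop("thresholds must be >= 0")
  structure(list(pixel_size_um = pixel_size_um,
                 min_radius_um = min_radius_um,
                 max_radius_um = max_radius_um,
                 splitting_threshold = splitting_threshold,
                 cell_expansion_um = cell_expansion_um,
                 dab_od_threshold = dab_od_threshold,
                 smoothing_sigma_um = smoothing_sigma_um,
                 h_od_threshold = h_od_threshold),
            class = "detection_params")
}

#' Detect nuclei on a hematoxylin OD map
#'
#' Watershed-based nucleus detection: the hematoxylin map is smoothed
#' (Gaussian, `smoothing_sigma_um`); markers are the h-maxima of the
#' smoothed map with prominence exceeding `splitting_threshold`; a
#' marker-based watershed on the negated smoothed map splits touching
#' nuclei; the foreground support is the raw map thresholded at
#' `h_od_threshold` with holes filled (measuring on the raw mask avoids the
#' radius inflation a smoothed mask would introduce); components are size
#' gated on the equivalent circular radius. Detections are ordered by
#' centroid (y, then x) and are fully deterministic.
#'
#' Coordinates are micrometres from the tile top-left, 0-based pixel
#' indices, pixel-centre convention (`um = pixel_index * pixel_size_um`).
#'
#' @param h_map numeric matrix of hematoxylin OD (rows = y, cols = x), or a
#'   `stain_channels` object (its `h` map is used).
#' @param params a [detection_params()] block.
#' @param dab_map optional DAB OD matrix; when supplied, `mean_dab_od` is
#'   measured and positivity is called via [classify_positive()].
#' @param marker marker label stored on each detection (`"Ki67"` or
#'   `"PLAP"`), or `NA`.
#' @param pixel_size_um pixel size; taken from `h_map` when it is a
#'   `stain_channels`, else from `params`.
#' @return A `nucleus_table`: data.frame with columns `nucleus_id`, `x_um`,
#'   `y_um`, `area_um2`, `equiv_radius_um`, `mean_h_od`, `mean_dab_od`,
#'   `positive`, `marker`; the integer label mask is attached as attribute
#'   `"label_mask"` (0 = background), `"pixel_size_um"` carries the scale.
#' @export
detect_nuclei <- function(h_map, params = detection_params(),
                          dab_map = NULL, marker = NA_character_,
                          pixel_size_um = NULL) {
  if (inherits(h_map, "stain_channels")) {
    if (is.null(pixel_size_um)) pixel_size_um <- h_map$pixel_size_um
    if (is.null(dab_map)) dab_map <- h_map$dab
    h_map <- h_map$h
  }
  if (is.null(pixel_size_um)) pixel_size_um <- params$pixel_size_um
  if (is.null(pixel_size_um) || !is.finite(pixel_size_um) ||
      pixel_size_um <= 0)
    stop("pixel size missing: supply pixel_size_um or a stain_channels map")
  h_map <- as.matrix(h_map)
  psz <- pixel_size_um

  sigma_px <- params$smoothing_sigma_um / psz
  smoothed <- cpp_gaussian_blur(h_map, sigma_px)
  fg <- cpp_fill_holes(h_map > params$h_od_threshold)

  # markers: h-maxima of the smoothed map with prominence > split threshold
  hmax <- cpp_reconstruct(smoothed - params$splitting_threshold, smoothed)
  eps <- 1e-7
  rmax <- (hmax - cpp_reconstruct(hmax - eps, hmax)) > eps / 2
  markers <- cpp_label(rmax & fg, 8L)

  labels <- cpp_watershed(-smoothed, markers, fg)

  empty <- data.frame(nucleus_id = integer(), x_um = numeric(),
                      y_um = numeric(), area_um2 = numeric(),
                      equiv_radius_um = numeric(), mean_h_od = numeric(),
                      mean_dab_od = numeric(), positive = logical(),
                      marker = character(), stringsAsFactors = FALSE)
  make <- function(df, labmat) {
    structure(df, class = c("nucleus_table", "data.frame"),
              label_mask = labmat, pixel_size_um = psz)
  }
  if (max(labels) == 0L) return(make(empty, labels))

  sel <- which(labels > 0L)
  lab <- labels[sel]
  rows0 <- (sel - 1L) %% nrow(labels)        # 0-based row (y)
  cols0 <- (sel - 1L) %/% nrow(labels)       # 0-based col (x)
  npx <- tabulate(lab)
  ids <- which(npx > 0)
  area <- npx[ids] * psz^2
  eqr <- sqrt(area / pi)
  keep <- eqr >= params$min_radius_um & eqr <= params$max_radius_um

  sum_by <- function(v) {
    s <- rep(0, max(lab))
    t <- tapply(v, lab, sum)
    s[as.integer(names(t))] <- t
    s[ids]
  }
  cx <- sum_by(cols0) / npx[ids] * psz
  cy <- sum_by(rows0) / npx[ids] * psz
  mh <- sum_by(h_map[sel]) / npx[ids]
  md <- if (is.null(dab_map)) rep(NA_real_, length(ids)) else
    sum_by(as.matrix(dab_map)[sel]) / npx[ids]

  kept_ids <- ids[keep]
  # drop filtered labels from the mask, then renumber in (y, x) order
  relab <- integer(max(lab))
  ord <- order(cy[keep], cx[keep])
  relab[kept_ids[ord]] <- seq_along(kept_ids)
  labmat <- matrix(0L, nrow(labels), ncol(labels))
  m <- relab[lab]
  m[is.na(m)] <- 0L
  labmat[sel] <- m

  df <- data.frame(nucleus_id = seq_along(kept_ids),
                   x_um = cx[keep][ord], y_um = cy[keep][ord],
                   area_um2 = area[keep][ord],
                   equiv_radius_um = eqr[keep][ord],
                   mean_h_od = mh[keep][ord],
                   mean_dab_od = md[keep][ord],
                   positive = NA, marker = marker,
                   stringsAsFactors = FALSE)
  out <- make(df, labmat)
  if (!is.null(dab_map))
    out <- classify_positive(out, dab_map, params$dab_od_threshold)
  out
}

#' Call DAB positivity on detected nuclei
#'
#' A nucleus is positive when its mean nuclear DAB OD strictly exceeds the
#' threshold ("exceeding" = `>`; a nucleus at exactly the threshold is
#' negative). Positivity is measured on the nuclear mask only, not the
#' expanded cell territory. Input order is preserved.
#'
#' @param nuclei a `nucleus_table` from [detect_nuclei()].
#' @param dab_map DAB OD matrix matching the detection raster; when `NULL`,
#'   the stored `mean_dab_od` column is used.
#' @param threshold DAB OD threshold (default 0.15).
#' @return The `nucleus_table` with `mean_dab_od` and `positive` filled in.
#' @export
classify_positive <- function(nuclei, dab_map = NULL, threshold = 0.15) {
  stopifnot(inherits(nuclei, "nucleus_table"))
  if (!is.null(dab_map)) {
    labmat <- attr(nuclei, "label_mask")
    dab_map <- as.matrix(dab_map)
    if (!all(dim(dab_map) == dim(labmat)))
      stop("dab_map dimensions do not match the detection raster")
    if (nrow(nuclei) > 0) {
      sel <- which(labmat > 0L)
      lab <- labmat[sel]
      mu <- tapply(dab_map[sel], lab, mean)
      nuclei$mean_dab_od[as.integer(names(mu))] <- as.numeric(mu)
    }
  }
  nuclei$positive <- nuclei$mean_dab_od > threshold
  nuclei
}

#' Expand nuclei into disjoint cell territories
#'
#' Dilates each nucleus mask outward by `expansion_um`, assigning contested
#' pixels to the nearest nucleus (Euclidean distance to the nearest nucleus
#' pixel), so territories are pairwise disjoint and each contains its
#' nucleus. `expansion_um = 0` returns the nucleus masks unchanged.
#'
#' @param nuclei a `nucleus_table` with its label mask.
#' @param expansion_um outward expansion in micrometres (>= 0).
#' @return list with `territories` (integer label matrix) and `table`
#'   (data.frame `nucleus_id`, `area_um2` of each territory).
#' @export
expand_cells <- function(nuclei, expansion_um = 3) {
  stopifnot(inherits(nuclei, "nucleus_table"))
  if (expansion_um < 0) stop("expansion_um must be >= 0")
  labmat <- attr(nuclei, "label_mask")
  psz <- attr(nuclei, "pixel_size_um")
  terr <- cpp_expand_labels(labmat, expansion_um / psz)
  npx <- tabulate(terr[terr > 0L], nbins = max(nrow(nuclei), 1L))
  tab <- data.frame(nucleus_id = nuclei$nucleus_id,
                    area_um2 = npx[nuclei$nucleus_id] * psz^2)
  list(territories = terr, table = tab)
}

#' Write a detection table to CSV
#'
#' Columns: `nucleus_id, x_um, y_um, area_um2, equiv_radius_um, mean_h_od,
#' mean_dab_od, positive (0/1), marker`.
#'
#' @param nuclei a `nucleus_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(nuclei, path) {
  df <- as.data.frame(nuclei)
  df$positive <- as.integer(df$positive)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
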