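#' Stain vector set for H-DAB color deconvolution
#'
#' Bundles unit-norm optical-density (OD) vectors for hematoxylin, DAB and a
#' residual stain into the 3x3 mixing matrix used by [unmix()]. Stain OD
#' vectors are unitless RGB triples: the per-channel absorbance signature of
#' a unit concentration of the stain (Beer-Lambert mixing is additive in OD
#' space).
#'
#' @param h,dab numeric length-3 OD vectors (R, G, B) for hematoxylin and
#'   DAB; normalized to unit Euclidean norm internally. All components must
#'   be non-negative.
#' @param residual optional length-3 residual vector; default is the
#'   normalized cross product of `h` and `dab`, which is orthogonal to both.
#' @param name free-text label carried through to reports.
#' @return An object of class `stain_vectors`: list with `h`, `dab`,
#'   `residual` (unit vectors), `matrix` (columns h, dab, residual) and
#'   `name`.
#' @seealso [default_hdab_vectors()], [unmix()]
#' @export
stain_vectors <- function(h, dab, residual = NULL, name = "custom") {
  h <- as.numeric(h); dab <- as.numeric(dab)
  if (length(h) != 3L || length(dab) != 3L)
    stop("stain vectors must have 3 components (R, G, B)")
  if (any(h < 0) || any(dab < 0))
    stop("hematoxylin and DAB vector components must be >= 0")
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n <= 0) stop("stain vector has zero norm")
    v / n
  }
  h <- unit(h); dab <- unit(dab)
  if (is.null(residual)) {
    residual <- c(h[2] * dab[3] - h[3] * dab[2],
                  h[3] * dab[1] - h[1] * dab[3],
                  h[1] * dab[2] - h[2] * dab[1])
    if (sqrt(sum(residual^2)) < 1e-12)
      stop("h and dab vectors are collinear; cannot build residual")
  }
  residual <- unit(as.numeric(residual))
  m <- cbind(h = h, dab = dab, residual = residual)
  if (abs(det(m)) < 1e-12)
    stop("stain matrix is singular; vectors must be linearly independent")
  structure(list(h = h, dab = dab, residual = residual,
                 matrix = m, name = name),
            class = "stain_vectors")
}

#' Standard H-DAB stain vectors (Ruifrok-Johnson)
#'
#' The de facto standard H-DAB deconvolution vectors of Ruifrok & Johnston
#' (2001), as shipped by mainstream digital-pathology software:
#' hematoxylin (0.651, 0.701, 0.290) and DAB (0.269, 0.568, 0.778), each
#' re-normalized to unit norm, with the residual taken as their normalized
#' cross product.
#'
#' @return A `stain_vectors` object named `"H-DAB (Ruifrok-Johnson)"`.
#' @export
default_hdab_vectors <- function() {
  stain_vectors(h = c(0.651, 0.701, 0.290),
                dab = c(0.269, 0.568, 0.778),
                name = "H-DAB (Ruifrok-Johnson)")
}

#' @export
print.stain_vectors <- function(x, ...) {
  cat("Stain vector set:", x$name, "\n")
  m <- t(x$matrix)
  dimnames(m) <- list(c("hematoxylin", "DAB", "residual"),
                      c("R", "G", "B"))
  print(round(m, 4))
  invisible(x)
}

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert relation per channel,
#' `OD_c = log10(i0 / max(I_c, 1))`, flooring intensities at 1 so fully
#' opaque pixels map to a finite OD (log10(i0)). Negative ODs (intensities
#' above the white point, possible only when `i0 < 255`) are clipped to 0.
#'
#' @param image_rgb integer/numeric array `h x w x 3` of 8-bit intensities,
#'   or a list with element `rgb` as produced by [read_tiff_rgb()].
#' @param i0 white-point intensity (> 0), default 255.
#' @param pixel_size_um physical pixel size in micrometres; taken from the
#'   input object when present.
#' @return An `od_image`: list with `od` (`h x w x 3` array, base-10 OD) and
#'   `pixel_size_um`.
#' @export
rgb_to_od <- function(image_rgb, i0 = 255, pixel_size_um = NULL) {
  if (is.list(image_rgb) && !is.null(image_rgb$rgb)) {
    if (is.null(pixel_size_um)) pixel_size_um <- image_rgb$pixel_size_um
    image_rgb <- image_rgb$rgb
  }
  if (i0 <= 0) stop("white point i0 must be > 0")
  d <- dim(image_rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected a 3-channel RGB image (h x w x 3)")
  od <- log10(i0 / pmax(as.numeric(image_rgb), 1))
  od <- pmax(od, 0)
  dim(od) <- d
  structure(list(od = od, pixel_size_um = pixel_size_um),
            class = "od_image")
}

#' Render an OD image back to 8-bit RGB intensities
#'
#' Inverse of [rgb_to_od()] up to 8-bit quantization:
#' `I_c = round(i0 * 10^(-OD_c))`, clipped to `[0, 255]`.
#'
#' @param od `h x w x 3` OD array or an `od_image`.
#' @param i0 white point, default 255.
#' @return Integer array `h x w x 3`.
#' @export
od_to_rgb <- function(od, i0 = 255) {
  if (inherits(od, "od_image")) od <- od$od
  d <- dim(od)
  v <- as.integer(pmin(pmax(round(i0 * 10^(-as.numeric(od))), 0), 255))
  dim(v) <- d
  v
}

#' Unmix an OD image into stain concentration channels
#'
#' Solves, per pixel, the 3x3 linear system `od = M c` where the columns of
#' `M` are the stain OD vectors, yielding per-stain concentration maps.
#' Negative concentrations (noise pushing a pixel outside the stain simplex)
#' are clipped to 0: concentrations are physical quantities.
#'
#' @param od_image an `od_image` from [rgb_to_od()].
#' @param vectors a `stain_vectors` set; default [default_hdab_vectors()].
#' @return A `stain_channels` object: list with matrices `h`, `dab`,
#'   `residual` (rows y, cols x) and `pixel_size_um`.
#' @export
unmix <- function(od_image, vectors = default_hdab_vectors()) {
  stopifnot(inherits(od_image, "od_image"))
  if (!inherits(vectors, "stain_vectors"))
    stop("`vectors` must be a stain_vectors object")
  m <- vectors$matrix
  if (!is.finite(rcond(m)) || rcond(m) < 1e-12)
    stop("stain matrix is singular or ill-conditioned")
  d <- dim(od_image$od)
  npix <- d[1] * d[2]
  odmat <- matrix(od_image$od, nrow = npix, ncol = 3)  # pixels x channels
  conc <- t(solve(m, t(odmat)))                        # pixels x stains
  conc[conc < 0] <- 0
  shape <- function(k) matrix(conc[, k], nrow = d[1], ncol = d[2])
  structure(list(h = shape(1), dab = shape(2), residual = shape(3),
                 pixel_size_um = od_image$pixel_size_um),
            class = "stain_channels")
}

#' Render stain concentrations to an OD image (forward Beer-Lambert model)
#'
#' Composes per-pixel OD as `h_conc * h_vec + dab_conc * dab_vec`
#' (+ optional residual term). This is the forward model whose inverse is
#' [unmix()]; the synthetic tile generator uses it to rasterize tiles.
#'
#' @param h_conc,dab_conc numeric matrices of stain concentrations (same
#'   dimensions); `dab_conc` may be `NULL` for hematoxylin-only renders.
#' @param vectors a `stain_vectors` set.
#' @param pixel_size_um pixel size carried into the result.
#' @return An `od_image`.
#' @export
render_od <- function(h_conc, dab_conc = NULL,
                      vectors = default_hdab_vectors(),
                      pixel_size_um = NULL) {
  h_conc <- as.matrix(h_conc)
  if (is.null(dab_conc)) dab_conc <- matrix(0, nrow(h_conc), ncol(h_conc))
  dab_conc <- as.matrix(dab_conc)
  stopifnot(all(dim(h_conc) == dim(dab_conc)))
  d <- dim(h_conc)
  od <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3)
    od[, , ch] <- h_conc * vectors$h[ch] + dab_conc * vectors$dab[ch]
  structure(list(od = od, pixel_size_um = pixel_size_um),
            class = "od_image")
}
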