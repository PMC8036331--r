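# Vigour-map workflow: NDVI, canopy segmentation, masked NDVI, IDW
# interpolation to a continuous surface, quintile three-class zoning; plus
# the unsegmented satellite path where the pixel is larger than the row
# spacing and canopy/background separation is impossible.

#' Compute NDVI from a multispectral scene
#'
#' `NDVI = (NIR - R) / (NIR + R)` per pixel. Pixels with `NIR + R = 0` are
#' marked missing.
#'
#' @param scene an [ms_scene()] with `R` and `NIR` bands (both the `UAV5`
#'   and `SAT4` dialects qualify).
#' @return An [ndvi_grid()].
#' @export
compute_ndvi <- function(scene) {
  stopifnot(inherits(scene, "ms_scene"))
  if (!all(c("R", "NIR") %in% names(scene$bands)))
    stop(sprintf("scene (dialect %s) lacks an R or NIR band", band_dialect(scene)),
         call. = FALSE)
  nir <- scene$bands$NIR; red <- scene$bands$R
  den <- nir + red
  v <- (nir - red) / den
  v[den == 0] <- NA_real_
  ndvi_grid(v, scene$transform, scene$crs)
}

#' Segment canopy pixels by NDVI threshold
#'
#' Pixels with NDVI strictly above the threshold are canopy (1), the rest
#' background (0). The reference field workflow set the threshold manually by
#' visual inspection per flight; `threshold = "otsu"` (default) replaces that
#' with a reproducible bimodal histogram split (Otsu's method via
#' `EBImage::otsu` on NDVI rescaled to \[0, 1\]).
#'
#' @param ndvi an [ndvi_grid()].
#' @param threshold numeric NDVI cut, or `"otsu"` for automatic selection.
#' @return A list of class `canopy_mask`: `values` (0/1 matrix, `NA` where
#'   the input is missing), `threshold_used`, `method`.
#' @export
segment_canopy <- function(ndvi, threshold = "otsu") {
  stopifnot(inherits(ndvi, "ndvi_grid"))
  fin <- is.finite(ndvi$values)
  if (!any(fin)) stop("NDVI grid has no finite cells", call. = FALSE)
  if (identical(threshold, "otsu")) {
    v01 <- (ndvi$values[fin] + 1) / 2
    thr <- EBImage::otsu(matrix(v01, ncol = 1), range = c(0, 1)) * 2 - 1
    method <- "otsu"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    thr <- threshold
    method <- "manual"
  }
  m <- matrix(NA_real_, nrow(ndvi$values), ncol(ndvi$values))
  m[fin] <- as.numeric(ndvi$values[fin] > thr)
  structure(list(values = m, threshold_used = thr, method = method,
                 transform = ndvi$transform, crs = ndvi$crs),
            class = "canopy_mask")
}

#' Apply a canopy mask to an NDVI grid
#'
#' Canopy pixels keep their NDVI; background pixels become exactly 0 (a
#' value, distinct from missing). Missing input cells stay missing.
#'
#' @param ndvi an [ndvi_grid()].
#' @param mask a `canopy_mask` aligned to it.
#' @return An [ndvi_grid()].
#' @export
mask_ndvi <- function(ndvi, mask) {
  stopifnot(inherits(ndvi, "ndvi_grid"), inherits(mask, "canopy_mask"))
  if (!identical(dim(ndvi$values), dim(mask$values)))
    stop("NDVI grid and mask are not aligned", call. = FALSE)
  v <- ndvi$values
  bg <- is.finite(mask$values) & mask$values == 0
  v[bg] <- 0
  ndvi_grid(v, ndvi$transform, ndvi$crs)
}

#' Inverse-distance-weighting interpolation onto a grid
#'
#' Value at a cell centre is the weighted mean of the `k` nearest anchors
#' with weights `distance^(-p)`; a cell coincident with an anchor returns the
#' anchor value exactly. In the vigour workflow the anchors are the canopy
#' pixels' centre coordinates and NDVI values (see [interpolate_vigour()]).
#'
#' @param anchors data.frame with columns `x`, `y`, `value`.
#' @param transform output grid transform (see [ms_scene()]).
#' @param dims output grid `c(nrow, ncol)`.
#' @param p IDW power (> 0), default 2.
#' @param k neighbourhood size, default 12.
#' @param crs CRS label for the output grid.
#' @return An [ndvi_grid()] when values are NDVI-like; the raw matrix is in
#'   `$values`.
#' @export
idw_interpolate <- function(anchors, transform, dims, p = 2, k = 12,
                            crs = "local-metric") {
  if (!nrow(anchors)) stop("idw: zero anchors", call. = FALSE)
  stopifnot(p > 0, all(c("x", "y", "value") %in% names(anchors)))
  check_transform(transform)
  m <- idw_grid_cpp(anchors$x, anchors$y, anchors$value,
                    as.integer(dims[1]), as.integer(dims[2]),
                    transform$origin_x, transform$origin_y,
                    transform$pixel_size, p, as.integer(k))
  ndvi_grid(m, transform, crs)
}

#' Interpolate a continuous vigour surface from masked NDVI
#'
#' Takes the canopy pixels (mask = 1) as anchors and interpolates their NDVI
#' over the whole grid by IDW, producing the continuous NDVI map that feeds
#' quintile classification.
#'
#' @param masked_ndvi output of [mask_ndvi()].
#' @param mask the `canopy_mask` used.
#' @inheritParams idw_interpolate
#' @export
interpolate_vigour <- function(masked_ndvi, mask, p = 2, k = 12) {
  can <- is.finite(mask$values) & mask$values == 1
  if (!any(can)) stop("no canopy pixels to anchor the interpolation", call. = FALSE)
  dims <- dim(masked_ndvi$values)
  ax <- cell_axes(masked_ndvi$transform, dims)
  idx <- which(can, arr.ind = TRUE)
  anchors <- data.frame(x = ax$x[idx[, 2]], y = ax$y[idx[, 1]],
                        value = masked_ndvi$values[can])
  idw_interpolate(anchors, masked_ndvi$transform, dims, p = p, k = k,
                  crs = masked_ndvi$crs)
}

#' Classify a continuous NDVI surface into three vigour zones by quintiles
#'
#' Thresholds are the empirical 20th/40th/60th/80th percentiles (linear
#' interpolation, `quantile type 7`) of the finite cells. Cells below P20 are
#' low vigour, above P80 high, everything else (including values exactly at
#' P20 or P80) medium. Quintiles are computed per grid -- i.e. per plot and
#' date -- never pooled across plots.
#'
#' @param continuous an [ndvi_grid()], e.g. from [interpolate_vigour()].
#' @param clip optional polygon (n x 2 matrix); cells whose centres fall
#'   outside are excluded from the percentiles and classified `nodata`.
#' @return Object of class `vigour_map`: `continuous` (the input grid),
#'   `classes` (integer matrix, 1 = low, 2 = medium, 3 = high, `NA` nodata)
#'   and `thresholds` (named P20/P40/P60/P80).
#' @export
classify_quintiles <- function(continuous, clip = NULL) {
  stopifnot(inherits(continuous, "ndvi_grid"))
  v <- continuous$values
  use <- is.finite(v)
  if (!is.null(clip)) {
    ax <- cell_axes(continuous$transform, dim(v))
    inside <- matrix(point_in_polygon(rep(ax$x, each = nrow(v)),
                                      rep(ax$y, times = ncol(v)), clip),
                     nrow = nrow(v))
    use <- use & inside
  }
  if (sum(use) < 5)
    stop("need at least 5 finite cells for quintile classification", call. = FALSE)
  qs <- quantile(v[use], c(0.2, 0.4, 0.6, 0.8), names = FALSE, type = 7)
  names(qs) <- c("P20", "P40", "P60", "P80")
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  if (qs[1] == qs[4]) {
    warning("constant NDVI surface: all cells classified medium vigour")
    cls[use] <- 2L
  } else {
    cls[use] <- 2L
    cls[use & v < qs[1]] <- 1L
    cls[use & v > qs[4]] <- 3L
  }
  structure(list(continuous = continuous, classes = cls, thresholds = qs),
            class = "vigour_map")
}

#' @export
print.vigour_map <- function(x, ...) {
  tab <- table(factor(x$classes, 1:3, c("low", "medium", "high")))
  cat("<vigour_map>", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      sprintf("| P20=%.3f P80=%.3f\n", x$thresholds["P20"], x$thresholds["P80"]))
  invisible(x)
}

#' Plot a three-class vigour map
#'
#' Low vigour red, medium yellow, high green, the conventional palette for
#' vigour prescription maps.
#'
#' @param x a `vigour_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.vigour_map <- function(x, ...) {
  cls <- x$classes
  # image() draws column-major from bottom; flip rows so north stays up
  z <- t(cls[nrow(cls):1, , drop = FALSE])
  image(z, zlim = c(1, 3), col = c("#d7191c", "#ffffbf", "#1a9641"),
        axes = FALSE, asp = nrow(cls) / ncol(cls), ...)
  title(main = "Vigour zones (red low / yellow medium / green high)")
  invisible(x)
}

#' Satellite vigour map (unsegmented path)
#'
#' At 3 m resolution the pixel exceeds the row spacing, so canopy cannot be
#' segmented from background; the raw NDVI grid is classified directly into
#' quintile vigour zones, optionally clipped to the plot boundary first.
#'
#' @param ndvi an [ndvi_grid()] from a coarse-resolution scene.
#' @param clip optional plot boundary polygon; outside pixels are excluded
#'   from the percentiles and set to nodata.
#' @return A `vigour_map` (continuous field = the input grid).
#' @export
satellite_vigour <- function(ndvi, clip = NULL) {
  classify_quintiles(ndvi, clip = clip)
}

#' Full fine-resolution vigour-map workflow
#'
#' NDVI, canopy segmentation, masking, IDW interpolation, quintile
#' classification -- the complete map-generation chain for a fine-resolution
#' scene.
#'
#' @param scene an [ms_scene()] at fine resolution.
#' @param threshold see [segment_canopy()].
#' @param p,k IDW parameters, see [idw_interpolate()].
#' @param clip optional plot boundary for the percentile support.
#' @return list with `ndvi`, `mask`, `masked`, `continuous`, `map`
#'   (a `vigour_map`).
#' @export
uav_vigour_workflow <- function(scene, threshold = "otsu", p = 2, k = 12,
                                clip = NULL) {
  ndvi <- compute_ndvi(scene)
  mask <- segment_canopy(ndvi, threshold)
  masked <- mask_ndvi(ndvi, mask)
  continuous <- interpolate_vigour(masked, mask, p = p, k = k)
  map <- classify_quintiles(continuous, clip = clip)
  list(ndvi = ndvi, mask = mask, masked = masked,
       continuous = continuous, map = map)
}
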