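#' Lightweight georeferenced raster containers
#'
#' The package represents imagery as plain numeric matrices bundled with a
#' north-up affine transform in a projected metric coordinate system (the
#' convention throughout is ETRS89-UTM-style metric x/y). The transform is a
#' list with `origin_x`, `origin_y` (the outer corner of the top-left pixel)
#' and `pixel_size` (metres per pixel, square pixels). Row indices grow
#' southwards, column indices eastwards, both 1-based.
#'
#' @param bands named list of numeric matrices (reflectance in \[0, 1\]),
#'   all with identical dimensions. Recognised band dialects: `UAV5`
#'   (`R`, `G`, `B`, `RE`, `NIR`) and `SAT4` (`B`, `G`, `R`, `NIR`).
#' @param transform list with `origin_x`, `origin_y`, `pixel_size`.
#' @param crs character label of the projected CRS (free text, carried along;
#'   no reprojection is ever attempted).
#' @return An object of class `ms_scene`.
#' @export
ms_scene <- function(bands, transform, crs = "local-metric") {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)),
            all(vapply(bands, is.matrix, logical(1))))
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1)
    stop("all bands must share the same dimensions", call. = FALSE)
  check_transform(transform)
  rng <- range(unlist(lapply(bands, range, na.rm = TRUE)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("reflectance values must lie in [0, 1]", call. = FALSE)
  structure(list(bands = bands, transform = transform, crs = crs),
            class = "ms_scene")
}

check_transform <- function(tr) {
  stopifnot(is.list(tr),
            all(c("origin_x", "origin_y", "pixel_size") %in% names(tr)))
  if (!is.finite(tr$pixel_size) || tr$pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  invisible(tr)
}

#' @export
print.ms_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<ms_scene> %d x %d px, %.4g m/px, bands: %s (%s)\n",
              d[1], d[2], x$transform$pixel_size,
              paste(names(x$bands), collapse = ","), band_dialect(x)))
  invisible(x)
}

#' Identify the band dialect of a scene
#'
#' @param scene an [ms_scene()].
#' @return `"UAV5"`, `"SAT4"` or `"other"`.
#' @export
band_dialect <- function(scene) {
  nm <- sort(names(scene$bands))
  if (identical(nm, sort(c("R", "G", "B", "RE", "NIR")))) return("UAV5")
  if (identical(nm, sort(c("B", "G", "R", "NIR")))) return("SAT4")
  "other"
}

#' Construct an NDVI grid
#'
#' @param values numeric matrix of NDVI values in \[-1, 1\]; `NA` marks
#'   missing cells (e.g. zero-denominator pixels). A zero produced by canopy
#'   masking is a valid value, distinct from missing.
#' @inheritParams ms_scene
#' @return An object of class `ndvi_grid`.
#' @export
ndvi_grid <- function(values, transform, crs = "local-metric") {
  stopifnot(is.matrix(values))
  check_transform(transform)
  fin <- values[is.finite(values)]
  if (length(fin) && (min(fin) < -1 - 1e-9 || max(fin) > 1 + 1e-9))
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  structure(list(values = values, transform = transform, crs = crs),
            class = "ndvi_grid")
}

#' @export
print.ndvi_grid <- function(x, ...) {
  d <- dim(x$values)
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("<ndvi_grid> %d x %d px, %.4g m/px, range [%.3f, %.3f], %d NA\n",
              d[1], d[2], x$transform$pixel_size,
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA,
              sum(!is.finite(x$values))))
  invisible(x)
}

# centre coordinates of every cell; returns list(x = col centres, y = row centres)
cell_axes <- function(transform, dims) {
  px <- transform$pixel_size
  list(x = transform$origin_x + (seq_len(dims[2]) - 0.5) * px,
       y = transform$origin_y - (seq_len(dims[1]) - 0.5) * px)
}

# world (x, y) -> fractional (row, col); cell (r, c) covers
# rows (r-1, r] in pixel units from the top edge
world_to_rc <- function(transform, x, y) {
  px <- transform$pixel_size
  list(row = (transform$origin_y - y) / px, col = (x - transform$origin_x) / px)
}

raster_extent <- function(obj) {
  g <- if (inherits(obj, "ms_scene")) obj$bands[[1]] else obj$values
  tr <- obj$transform
  c(xmin = tr$origin_x, xmax = tr$origin_x + ncol(g) * tr$pixel_size,
    ymin = tr$origin_y - nrow(g) * tr$pixel_size, ymax = tr$origin_y)
}

# ---- raster I/O: float-32 TIFF with a JSON georeferencing sidecar ----------

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write / read a multispectral scene
#'
#' Scenes are stored as multi-directory 32-bit float TIFF (one directory per
#' band) with a JSON sidecar (`<path>.aux.json`) carrying band names, the
#' affine transform and the CRS label. Reflectance round-trips within
#' single-precision accuracy (~1e-7).
#'
#' @param scene an [ms_scene()].
#' @param path output file path (`.tif`).
#' @return `write_scene()` returns `path` invisibly; `read_scene()` returns
#'   an [ms_scene()].
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "ms_scene"))
  tiff::writeTIFF(scene$bands, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(kind = "ms_scene", bands = names(scene$bands),
               transform = scene$transform, crs = scene$crs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  mats <- tiff::readTIFF(path, all = TRUE)
  names(mats) <- meta$bands
  ms_scene(mats, as.list(meta$transform), meta$crs)
}

#' Write / read an NDVI grid
#'
#' NDVI in \[-1, 1\] is affinely rescaled to \[0, 1\] for storage
#' (`stored = (ndvi + 1) / 2`); a second TIFF directory stores a validity
#' mask so that missing cells survive the round trip. Values round-trip
#' within 1e-6.
#'
#' @param grid an [ndvi_grid()].
#' @param path output file path (`.tif`).
#' @export
write_ndvi <- function(grid, path) {
  stopifnot(inherits(grid, "ndvi_grid"))
  v <- grid$values
  valid <- ifelse(is.finite(v), 1, 0)
  stored <- (ifelse(is.finite(v), v, -1) + 1) / 2
  tiff::writeTIFF(list(stored, valid), path, bits.per.sample = 32L)
  meta <- list(kind = "ndvi_grid", scaling = "stored = (ndvi + 1)/2",
               transform = grid$transform, crs = grid$crs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ndvi
#' @export
read_ndvi <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  mats <- tiff::readTIFF(path, all = TRUE)
  v <- mats[[1]] * 2 - 1
  v[mats[[2]] < 0.5] <- NA_real_
  ndvi_grid(v, as.list(meta$transform), meta$crs)
}
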