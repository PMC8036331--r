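# Synthetic vineyard scene generator. Emulates the data the analysis expects:
# row-structured plantations (row spacing 2.2-2.8 m, vine spacing 1.2 m),
# three phenological stages (BBCH 59 / 75 / 81) with a 1.5x dimensional jump
# from stage one to two and a plateau afterwards, spatially smooth vigour
# variation driving both canopy size and canopy NDVI, soil/weed/shadow/road
# background, a fine ~6.5 cm grid and a coarse 3 m grid with pixel mixing.

BBCH_STAGES <- c("BBCH59", "BBCH75", "BBCH81")
# dimensional growth plateaus after BBCH 75
stage_scale <- function(stage) c(BBCH59 = 1, BBCH75 = 1.5, BBCH81 = 1.5)[stage]

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Describe a vineyard plot
#'
#' @param boundary n x 2 matrix of boundary vertices in projected metric
#'   coordinates (simple polygon, not closed).
#' @param row_spacing distance between rows (m); commercial vineyards in the
#'   emulated system use 2.2--2.8 m.
#' @param vine_spacing distance between vines along a row (m), typically 1.2.
#' @param row_azimuth row direction, degrees clockwise from north.
#' @param plot_id,variety labels carried into outputs.
#' @return Object of class `field_spec`.
#' @export
field_spec <- function(boundary, row_spacing = 2.2, vine_spacing = 1.2,
                       row_azimuth = 0, plot_id = "A", variety = "Chardonnay") {
  stopifnot(is.matrix(boundary), ncol(boundary) == 2, nrow(boundary) >= 3)
  if (row_spacing <= 0 || vine_spacing <= 0)
    stop("row_spacing and vine_spacing must be > 0", call. = FALSE)
  if (polygon_area(boundary) <= 0)
    stop("boundary must enclose a positive area", call. = FALSE)
  structure(list(boundary = boundary, row_spacing = row_spacing,
                 vine_spacing = vine_spacing, row_azimuth = row_azimuth,
                 plot_id = plot_id, variety = variety),
            class = "field_spec")
}

#' Axis-aligned rectangular plot boundary
#'
#' @param width,height extent in metres.
#' @param origin lower-left corner `(x, y)`.
#' @export
rect_boundary <- function(width, height, origin = c(0, 0)) {
  rbind(origin, origin + c(width, 0), origin + c(width, height),
        origin + c(0, height))
}

#' Ground sample distance of a nadir camera
#'
#' `gsd = altitude * pixel_pitch / focal_length`, all in metres.
#'
#' @param altitude flight height above ground (m).
#' @param focal_length lens focal length (m).
#' @param pixel_pitch physical sensor pixel size (m).
#' @return metres per pixel.
#' @examples
#' gsd(95, 5.5e-3, 3.75e-6) # ~0.0648 m for the reference multispectral camera
#' @export
gsd <- function(altitude, focal_length, pixel_pitch) {
  stopifnot(altitude > 0, focal_length > 0, pixel_pitch > 0)
  altitude * pixel_pitch / focal_length
}

#' Generate vine positions on a row grid
#'
#' Rows are parallel lines `row_spacing` apart, oriented along `row_azimuth`;
#' vines sit every `vine_spacing` along each row. The grid is anchored half a
#' spacing inside the boundary's rotated bounding box, and only centres
#' strictly inside the boundary are kept. A boundary too small for a single
#' vine yields a zero-row layout, not an error.
#'
#' @param field a [field_spec()].
#' @param seed integer; reserved for optional positional jitter (`jitter_sd`).
#' @param jitter_sd standard deviation (m) of optional isotropic planting
#'   jitter; 0 (default) gives the deterministic nominal grid.
#' @return `data.frame` with columns `vine_id`, `row_index`, `vine_index`,
#'   `along_row_position`, `x`, `y`.
#' @export
generate_layout <- function(field, seed = 1L, jitter_sd = 0) {
  stopifnot(inherits(field, "field_spec"))
  a <- field$row_azimuth * pi / 180
  u <- c(sin(a), cos(a))    # along-row direction
  v <- c(cos(a), -sin(a))   # across-row direction
  bu <- field$boundary %*% u
  bv <- field$boundary %*% v
  rs <- field$row_spacing; vs <- field$vine_spacing
  row_pos <- seq(min(bv) + rs / 2, by = rs,
                 length.out = max(0, floor((diff(range(bv)) - rs / 2) / rs + 1e-9) + 1))
  vine_pos <- seq(min(bu) + vs / 2, by = vs,
                  length.out = max(0, floor((diff(range(bu)) - vs / 2) / vs + 1e-9) + 1))
  if (!length(row_pos) || !length(vine_pos))
    return(data.frame(vine_id = character(), row_index = integer(),
                      vine_index = integer(), along_row_position = numeric(),
                      x = numeric(), y = numeric()))
  g <- expand.grid(vine_index = seq_along(vine_pos), row_index = seq_along(row_pos))
  x <- vine_pos[g$vine_index] * u[1] + row_pos[g$row_index] * v[1]
  y <- vine_pos[g$vine_index] * u[2] + row_pos[g$row_index] * v[2]
  if (jitter_sd > 0) {
    jit <- with_seed(seed, matrix(rnorm(2 * length(x), 0, jitter_sd), ncol = 2))
    x <- x + jit[, 1]; y <- y + jit[, 2]
  }
  keep <- point_in_polygon(x, y, field$boundary)
  out <- data.frame(
    vine_id = sprintf("%s-r%02d-v%03d", field$plot_id, g$row_index, g$vine_index),
    row_index = g$row_index, vine_index = g$vine_index,
    along_row_position = vine_pos[g$vine_index] - min(bu),
    x = x, y = y, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$row_index, out$along_row_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parameters of the latent vigour surface
#'
#' Vigour is a smooth spatial field in \[0, 1\]: a linear trend across the
#' plot plus a few Gaussian bumps plus iid noise, clamped. Bump centres,
#' signs and the trend direction are drawn from the seed passed to
#' [assign_truth()].
#'
#' @param base mean vigour level.
#' @param trend peak-to-peak amplitude of the linear trend across the plot.
#' @param n_bumps number of Gaussian bumps (low/high pockets).
#' @param bump_amp absolute bump amplitude.
#' @param bump_scale bump length scale (m).
#' @param noise_sd iid per-vine noise standard deviation.
#' @export
vigour_params <- function(base = 0.5, trend = 0.3, n_bumps = 3,
                          bump_amp = 0.25, bump_scale = 8, noise_sd = 0.05) {
  list(base = base, trend = trend, n_bumps = n_bumps,
       bump_amp = bump_amp, bump_scale = bump_scale, noise_sd = noise_sd)
}

#' Canopy dimension limits per unit vigour
#'
#' Height and width at BBCH 59 interpolate linearly in vigour between the
#' `*_min` and `*_max` values; later stages multiply by the stage scale
#' (1.5 from BBCH 59 to BBCH 75, plateau to BBCH 81).
#'
#' @param h_min,h_max canopy height range (m) at vigour 0 and 1.
#' @param w_min,w_max canopy width range (m) at vigour 0 and 1.
#' @export
dimension_params <- function(h_min = 0.4, h_max = 0.9,
                             w_min = 0.2, w_max = 0.45) {
  if (h_min > h_max || w_min > w_max)
    stop("dimension minima must not exceed maxima", call. = FALSE)
  if (h_min < 0 || w_min < 0)
    stop("dimensions must be non-negative", call. = FALSE)
  list(h_min = h_min, h_max = h_max, w_min = w_min, w_max = w_max)
}

#' Assign ground-truth vigour and canopy dimensions to a layout
#'
#' @param layout output of [generate_layout()] (non-empty).
#' @param field the [field_spec()] the layout came from.
#' @param stage one of `"BBCH59"`, `"BBCH75"`, `"BBCH81"`.
#' @param vp vigour surface parameters, see [vigour_params()].
#' @param dp dimension parameters, see [dimension_params()].
#' @param seed integer RNG seed; results are a pure function of
#'   `(layout, stage, vp, dp, seed)`. The same seed across stages keeps the
#'   spatial vigour pattern fixed while dimensions grow with the stage.
#' @return The layout with columns `stage`, `vigour_true`, `height_true`,
#'   `width_true` appended.
#' @export
assign_truth <- function(layout, field, stage = "BBCH59",
                         vp = vigour_params(), dp = dimension_params(),
                         seed = 1L) {
  if (!nrow(layout)) stop("layout is empty", call. = FALSE)
  stage <- match.arg(stage, BBCH_STAGES)
  bb <- field$boundary
  ctr <- colMeans(bb)
  diag_len <- sqrt(diff(range(bb[, 1]))^2 + diff(range(bb[, 2]))^2)
  vig <- with_seed(seed, {
    ang <- runif(1, 0, 2 * pi)
    proj <- ((layout$x - ctr[1]) * cos(ang) + (layout$y - ctr[2]) * sin(ang)) / diag_len
    val <- vp$base + vp$trend * proj
    if (vp$n_bumps > 0) {
      bx <- runif(vp$n_bumps, min(bb[, 1]), max(bb[, 1]))
      by <- runif(vp$n_bumps, min(bb[, 2]), max(bb[, 2]))
      bs <- sample(c(-1, 1), vp$n_bumps, replace = TRUE)
      for (i in seq_len(vp$n_bumps)) {
        d2 <- (layout$x - bx[i])^2 + (layout$y - by[i])^2
        val <- val + bs[i] * vp$bump_amp * exp(-d2 / (2 * vp$bump_scale^2))
      }
    }
    val + rnorm(nrow(layout), 0, vp$noise_sd)
  })
  vig <- pmin(1, pmax(0, vig))
  sc <- stage_scale(stage)
  out <- layout
  out$stage <- stage
  out$vigour_true <- vig
  out$height_true <- (dp$h_min + (dp$h_max - dp$h_min) * vig) * sc
  out$width_true <- (dp$w_min + (dp$w_max - dp$w_min) * vig) * sc
  if (any(out$width_true >= field$row_spacing))
    stop("width_true reaches row_spacing; reduce w_max", call. = FALSE)
  out
}

#' Scene rendering parameters
#'
#' Reflectance model for the synthetic imagery. Canopy red and NIR are affine
#' in vigour (`R = r0 + r1 * vigour`, `NIR = nir0 + nir1 * vigour`); soil,
#' weed, shadow and road (outside-plot) surfaces are constants. Defaults give
#' noiseless canopy NDVI 0.60--0.89, soil 0.15, weeds 0.36, road 0.03, so the
#' canopy is separable from every background surface. The raster extent pads
#' the plot with road surface, so coarse-scale aggregation mixes road signal
#' into border pixels (the edge-contamination mechanism).
#'
#' @param gsd metres per pixel; default the fine UAV-scale 0.0648 m.
#' @param band_set `"UAV5"` (R,G,B,RE,NIR) or `"SAT4"` (B,G,R,NIR).
#' @param canopy list with `r0`, `r1`, `nir0`, `nir1`.
#' @param soil,weed,shadow,road named reflectance vectors (`R`, `NIR`).
#' @param weed_patch_density weed patches per hectare.
#' @param weed_radius patch radius (m).
#' @param shadow_offset gap between canopy edge and shadow strip (m).
#' @param shadow_width strip width (m), cast north of each row.
#' @param noise_sd additive Gaussian reflectance noise, truncated to \[0, 1\].
#' @param pad road margin around the plot boundary (m).
#' @export
scene_params <- function(gsd = 0.0648, band_set = c("UAV5", "SAT4"),
                         canopy = list(r0 = 0.10, r1 = -0.06,
                                       nir0 = 0.40, nir1 = 0.30),
                         soil = c(R = 0.22, NIR = 0.30),
                         weed = c(R = 0.14, NIR = 0.30),
                         shadow = c(R = 0.05, NIR = 0.07),
                         road = c(R = 0.28, NIR = 0.30),
                         weed_patch_density = 20, weed_radius = 1,
                         shadow_offset = 0.1, shadow_width = 0.3,
                         noise_sd = 0.01, pad = 6) {
  band_set <- match.arg(band_set)
  stopifnot(gsd > 0)
  refl <- c(canopy$r0, canopy$r0 + canopy$r1, canopy$nir0, canopy$nir0 + canopy$nir1,
            soil, weed, shadow, road)
  if (any(refl < 0 | refl > 1))
    stop("all model reflectances must lie in [0, 1]", call. = FALSE)
  ndvi_c_min <- min((canopy$nir0 - canopy$r0) / (canopy$nir0 + canopy$r0),
                    (canopy$nir0 + canopy$nir1 - canopy$r0 - canopy$r1) /
                      (canopy$nir0 + canopy$nir1 + canopy$r0 + canopy$r1))
  ndvi_soil <- (soil["NIR"] - soil["R"]) / (soil["NIR"] + soil["R"])
  if (ndvi_c_min <= ndvi_soil)
    stop("noiseless canopy NDVI must exceed soil NDVI", call. = FALSE)
  list(gsd = gsd, band_set = band_set, canopy = canopy, soil = soil,
       weed = weed, shadow = shadow, road = road,
       weed_patch_density = weed_patch_density, weed_radius = weed_radius,
       shadow_offset = shadow_offset, shadow_width = shadow_width,
       noise_sd = noise_sd, pad = pad)
}

# secondary bands (not used by NDVI) per surface type
aux_band_levels <- function() {
  list(canopy = c(G = 0.08, B = 0.04, RE = 0.30),
       soil   = c(G = 0.20, B = 0.14, RE = 0.26),
       weed   = c(G = 0.15, B = 0.08, RE = 0.26),
       shadow = c(G = 0.05, B = 0.04, RE = 0.06),
       road   = c(G = 0.27, B = 0.24, RE = 0.29))
}

# paint value into band matrices for pixels whose centres satisfy `member`
# over the bounding box of a shape
paint_rows_cols <- function(dims, transform, xlim, ylim) {
  px <- transform$pixel_size
  c0 <- max(1L, floor((xlim[1] - transform$origin_x) / px) + 1L)
  c1 <- min(dims[2], ceiling((xlim[2] - transform$origin_x) / px))
  r0 <- max(1L, floor((transform$origin_y - ylim[2]) / px) + 1L)
  r1 <- min(dims[1], ceiling((transform$origin_y - ylim[1]) / px))
  if (c0 > c1 || r0 > r1) return(NULL)
  list(rows = r0:r1, cols = c0:c1)
}

#' Render a multispectral scene from vine ground truth
#'
#' Each vine paints a rectangle oriented along its row (length
#' `min(vine_spacing, 1.2)` m, width `width_true`) with vigour-dependent
#' canopy reflectance. Background inside the plot is soil with optional weed
#' patches and a shadow strip north of each vine; outside the plot is road
#' surface. Additive Gaussian noise is truncated to \[0, 1\]. Rendering is a
#' pure function of `(truths, field, params, seed)`.
#'
#' @param truths output of [assign_truth()] (may have zero rows for an empty
#'   scene).
#' @param field the [field_spec()].
#' @param params a [scene_params()] list.
#' @param seed integer RNG seed for weed placement and noise.
#' @return An [ms_scene()]; the painted canopy footprint (logical matrix) is
#'   attached as attribute `"canopy_footprint"`.
#' @export
render_scene <- function(truths, field, params = scene_params(), seed = 1L) {
  bb <- field$boundary
  xr <- range(bb[, 1]) + c(-1, 1) * params$pad
  yr <- range(bb[, 2]) + c(-1, 1) * params$pad
  px <- params$gsd
  nc <- ceiling((xr[2] - xr[1]) / px)
  nr <- ceiling((yr[2] - yr[1]) / px)
  if (nc < 1 || nr < 1)
    stop("gsd larger than the field extent: degenerate raster", call. = FALSE)
  transform <- list(origin_x = xr[1], origin_y = yr[2], pixel_size = px)
  band_names <- if (params$band_set == "UAV5") c("R", "G", "B", "RE", "NIR")
                else c("B", "G", "R", "NIR")
  aux <- aux_band_levels()
  surf_level <- function(surface, band) {
    if (band %in% c("R", "NIR")) unname(params[[surface]][band])
    else unname(aux[[surface]][band])
  }
  ax <- cell_axes(transform, c(nr, nc))
  # surface id grid: 1 road, 2 soil, 3 weed, 4 shadow; canopy painted after
  inside <- matrix(point_in_polygon(rep(ax$x, each = nr), rep(ax$y, times = nc), bb),
                   nrow = nr)
  surface <- matrix(1L, nr, nc); surface[inside] <- 2L
  canopy_v <- matrix(NA_real_, nr, nc)   # vigour of canopy pixels

  with_seed(seed, {
    # weed patches
    n_weed <- round(params$weed_patch_density * polygon_area(bb) / 1e4)
    if (n_weed > 0) {
      wx <- runif(n_weed, min(bb[, 1]), max(bb[, 1]))
      wy <- runif(n_weed, min(bb[, 2]), max(bb[, 2]))
      for (i in seq_len(n_weed)) {
        rc <- paint_rows_cols(c(nr, nc), transform,
                              wx[i] + c(-1, 1) * params$weed_radius,
                              wy[i] + c(-1, 1) * params$weed_radius)
        if (is.null(rc)) next
        dx <- ax$x[rc$cols]; dy <- ax$y[rc$rows]
        hit <- outer(dy, dx, function(Y, X) (X - wx[i])^2 + (Y - wy[i])^2) <=
          params$weed_radius^2
        blk <- surface[rc$rows, rc$cols, drop = FALSE]
        blk[hit & blk == 2L] <- 3L
        surface[rc$rows, rc$cols] <- blk
      }
    }
    # shadows then canopy, vine by vine
    if (nrow(truths)) {
      along <- min(field$vine_spacing, 1.2)
      for (i in seq_len(nrow(truths))) {
        w <- truths$width_true[i]
        # shadow strip north of the canopy rectangle
        sh <- rect_polygon(c(truths$x[i], truths$y[i] + w / 2 +
                               params$shadow_offset + params$shadow_width / 2),
                           along, params$shadow_width, field$row_azimuth)
        cp <- rect_polygon(c(truths$x[i], truths$y[i]), along, w,
                           field$row_azimuth)
        for (shape in list(list(p = sh, id = 4L), list(p = cp, id = 5L))) {
          rc <- paint_rows_cols(c(nr, nc), transform,
                                range(shape$p[, 1]), range(shape$p[, 2]))
          if (is.null(rc)) next
          gx <- rep(ax$x[rc$cols], each = length(rc$rows))
          gy <- rep(ax$y[rc$rows], times = length(rc$cols))
          hit <- matrix(point_in_polygon(gx, gy, shape$p), nrow = length(rc$rows))
          blk <- surface[rc$rows, rc$cols, drop = FALSE]
          if (shape$id == 4L) {
            blk[hit & (blk == 2L | blk == 3L)] <- 4L
          } else {
            blk[hit] <- 5L
            vblk <- canopy_v[rc$rows, rc$cols, drop = FALSE]
            vblk[hit] <- truths$vigour_true[i]
            canopy_v[rc$rows, rc$cols] <- vblk
          }
          surface[rc$rows, rc$cols] <- blk
        }
      }
    }
    bands <- vector("list", length(band_names))
    names(bands) <- band_names
    surf_names <- c("road", "soil", "weed", "shadow")
    for (b in band_names) {
      m <- matrix(0, nr, nc)
      for (s in 1:4) m[surface == s] <- surf_level(surf_names[s], b)
      can <- surface == 5L
      if (any(can)) {
        v <- canopy_v[can]
        m[can] <- if (b == "R") params$canopy$r0 + params$canopy$r1 * v
          else if (b == "NIR") params$canopy$nir0 + params$canopy$nir1 * v
          else surf_level("canopy", b)
      }
      if (params$noise_sd > 0)
        m <- m + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
      bands[[b]] <- pmin(pmax(m, 0), 1)
    }
    out <- ms_scene(bands, transform, "local-metric")
    attr(out, "canopy_footprint") <- surface == 5L
    out
  })
}

#' Aggregate a fine scene to satellite resolution
#'
#' Per-band area-weighted block mean: every output pixel averages the input
#' reflectance it covers, with partial input pixels at block and raster edges
#' weighted by their covered fraction (no truncation). Non-integer
#' aggregation factors are exact. NDVI should be computed after aggregation,
#' which is what produces the coarse-scale spectral mixing.
#'
#' @param scene an [ms_scene()] at fine resolution.
#' @param target_gsd output pixel size (m), default 3.
#' @return An [ms_scene()] with the `SAT4` band subset (when available) at
#'   `target_gsd` resolution.
#' @export
degrade_to_satellite <- function(scene, target_gsd = 3) {
  stopifnot(inherits(scene, "ms_scene"))
  px <- scene$transform$pixel_size
  if (target_gsd <= px)
    stop("target_gsd must exceed the scene pixel size", call. = FALSE)
  f <- target_gsd / px
  dims <- dim(scene$bands[[1]])
  wmat <- function(n_in) {
    n_out <- ceiling(n_in / f)
    W <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * f; hi <- min(i * f, n_in)
      j0 <- floor(lo) + 1; j1 <- ceiling(hi)
      for (j in j0:j1) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) W[i, j] <- ov
      }
    }
    W
  }
  Wr <- wmat(dims[1]); Wc <- wmat(dims[2])
  norm <- rowSums(Wr) %o% rowSums(Wc)
  keep <- intersect(c("B", "G", "R", "NIR"), names(scene$bands))
  if (!all(c("R", "NIR") %in% keep)) keep <- names(scene$bands)
  bands <- lapply(scene$bands[keep], function(m) (Wr %*% m %*% t(Wc)) / norm)
  ms_scene(bands,
           list(origin_x = scene$transform$origin_x,
                origin_y = scene$transform$origin_y, pixel_size = target_gsd),
           scene$crs)
}

# ---- ground-truth / layout I/O ---------------------------------------------

#' Write and read ground-truth tables
#'
#' CSV schema: `vine_id, plot, stage, height_true, width_true, vigour_true,
#' x, y`. Round-trips exactly (values written at full precision).
#'
#' @param truths output of [assign_truth()].
#' @param plot_id plot label recorded in the file.
#' @param path CSV path.
#' @export
write_truth <- function(truths, path, plot_id = "A") {
  df <- data.frame(vine_id = truths$vine_id, plot = plot_id,
                   stage = truths$stage, height_true = truths$height_true,
                   width_true = truths$width_true,
                   vigour_true = truths$vigour_true,
                   x = truths$x, y = truths$y)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  num <- c("height_true", "width_true", "vigour_true", "x", "y")
  df[num] <- lapply(df[num], as.numeric)
  df
}

#' Write a layout (or any point table) as GeoJSON points
#'
#' @param layout data.frame with `x`, `y` and attribute columns.
#' @param path output path.
#' @param crs_label free-text CRS note stored in the file.
#' @export
write_layout_geojson <- function(layout, path, crs_label = "local-metric") {
  props <- layout[setdiff(names(layout), c("x", "y"))]
  feats <- lapply(seq_len(nrow(layout)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(layout$x[i], layout$y[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", crs_note = crs_label, features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1], y = cc[2]), f$properties)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write polygons (plot boundary or vine polygons) as GeoJSON
#'
#' @param polys named list of n x 2 vertex matrices.
#' @param path output path.
#' @param crs_label free-text CRS note.
#' @export
write_polygons_geojson <- function(polys, path, crs_label = "local-metric") {
  feats <- lapply(names(polys), function(nm) {
    p <- polys[[nm]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(id = nm))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", crs_note = crs_label, features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring[-nrow(ring), , drop = FALSE]
  })
  names(out) <- vapply(gj$features, function(f) as.character(f$properties$id), "")
  out
}
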