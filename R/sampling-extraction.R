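# Systematic uniform random (SUR) sampling of vines and per-vine feature
# extraction: UAV-scale NDVI mean, projected canopy area and vigour class
# within each vine polygon; satellite-scale area-weighted NDVI and class;
# edge-point flagging; assembly of the per-vine database.

#' Systematic uniform random sampling of a vine layout
#'
#' Multi-stage SUR design: rows `start_row, start_row + row_period, ...` are
#' sampled, and within each sampled row the vines at positions
#' `start_vine, start_vine + vine_period, ...` (ordering by
#' `(row_index, along_row_position)`). Random starts are integers drawn
#' uniformly on `{1..period}`; fixed starts may be supplied to reproduce a
#' recorded design.
#'
#' @param layout output of [generate_layout()].
#' @param row_period,vine_period sampling periods (>= 1).
#' @param seed integer RNG seed for the random starts.
#' @param start_row,start_vine optional fixed starts (1-based).
#' @return Object of class `sur_design`: `row_period`, `vine_period`,
#'   `start_row`, `start_vine`, `selected` (vine ids).
#' @export
sur_sample <- function(layout, row_period, vine_period, seed = 1L,
                       start_row = NULL, start_vine = NULL) {
  stopifnot(row_period >= 1, vine_period >= 1)
  layout <- layout[order(layout$row_index, layout$along_row_position), ]
  n_rows <- length(unique(layout$row_index))
  if (row_period > n_rows || vine_period > max(table(layout$row_index)))
    warning("sampling period exceeds population extent; ",
            "only the start unit can be selected in that stage")
  starts <- with_seed(seed, c(sample.int(row_period, 1), sample.int(vine_period, 1)))
  if (is.null(start_row)) start_row <- starts[1]
  if (is.null(start_vine)) start_vine <- starts[2]
  stopifnot(start_row >= 1, start_row <= row_period,
            start_vine >= 1, start_vine <= vine_period)
  rows_present <- sort(unique(layout$row_index))
  sel_rows <- if (start_row > length(rows_present)) integer(0) else
    rows_present[seq(start_row, length(rows_present), by = row_period)]
  sel <- unlist(lapply(sel_rows, function(r) {
    ids <- layout$vine_id[layout$row_index == r]
    if (start_vine > length(ids)) return(character(0))
    ids[seq(start_vine, length(ids), by = vine_period)]
  }))
  if (is.null(sel)) sel <- character(0)
  structure(list(row_period = row_period, vine_period = vine_period,
                 start_row = start_row, start_vine = start_vine,
                 selected = sel),
            class = "sur_design")
}

#' @export
print.sur_design <- function(x, ...) {
  cat(sprintf("<sur_design> periods (row %d, vine %d), starts (%d, %d), %d vines\n",
              x$row_period, x$vine_period, x$start_row, x$start_vine,
              length(x$selected)))
  invisible(x)
}

#' Sampling polygon of a vine
#'
#' Rectangle centred on the vine: 1.2 m along the row (the canopy length
#' assigned to one sampling vine) by `row_spacing` across, oriented by the
#' row azimuth.
#'
#' @param vine one row of a layout/truth data.frame (needs `x`, `y`).
#' @param row_spacing plot row spacing (m).
#' @param azimuth row azimuth (degrees from north).
#' @param along along-row length (m), default 1.2.
#' @return 4 x 2 corner matrix (see [rect_polygon()]).
#' @export
vine_polygon <- function(vine, row_spacing, azimuth = 0, along = 1.2) {
  rect_polygon(c(vine$x, vine$y), along, row_spacing, azimuth)
}

#' Extract UAV-scale features for one vine polygon
#'
#' Canopy cells are the mask = 1 cells whose centres fall inside the polygon.
#' `NDVI_D` is their mean NDVI, `Prj_area_D` their count times the pixel
#' area (the polygonised canopy contour area), and the vigour class the
#' majority class of those cells (ties resolved to medium).
#'
#' @param poly vine polygon (4 x 2 matrix).
#' @param ndvi [ndvi_grid()] at fine resolution.
#' @param mask aligned `canopy_mask`.
#' @param vmap aligned `vigour_map`.
#' @return list `ndvi_d`, `prj_area_d`, `c_vigour_d` ("low"/"medium"/"high"),
#'   `n_cells`, `missing` (TRUE when the polygon holds no canopy cell; then
#'   `ndvi_d` is `NA` and `prj_area_d` 0).
#' @export
extract_uav_features <- function(poly, ndvi, mask, vmap) {
  if (!identical(dim(ndvi$values), dim(mask$values)))
    stop("NDVI grid and mask are not aligned", call. = FALSE)
  dims <- dim(ndvi$values)
  tr <- ndvi$transform
  rc <- paint_rows_cols(dims, tr, range(poly[, 1]), range(poly[, 2]))
  if (is.null(rc))
    return(list(ndvi_d = NA_real_, prj_area_d = 0, c_vigour_d = NA_character_,
                n_cells = 0L, missing = TRUE))
  ax <- cell_axes(tr, dims)
  gx <- rep(ax$x[rc$cols], each = length(rc$rows))
  gy <- rep(ax$y[rc$rows], times = length(rc$cols))
  inside <- matrix(point_in_polygon(gx, gy, poly), nrow = length(rc$rows))
  sub_mask <- mask$values[rc$rows, rc$cols, drop = FALSE]
  can <- inside & is.finite(sub_mask) & sub_mask == 1
  n <- sum(can)
  if (n == 0)
    return(list(ndvi_d = NA_real_, prj_area_d = 0, c_vigour_d = NA_character_,
                n_cells = 0L, missing = TRUE))
  sub_ndvi <- ndvi$values[rc$rows, rc$cols, drop = FALSE]
  sub_cls <- vmap$classes[rc$rows, rc$cols, drop = FALSE]
  cls_counts <- tabulate(sub_cls[can], nbins = 3)
  top <- which(cls_counts == max(cls_counts))
  c_vig <- if (length(top) > 1) "medium" else c("low", "medium", "high")[top]
  list(ndvi_d = mean(sub_ndvi[can]),
       prj_area_d = n * tr$pixel_size^2,
       c_vigour_d = c_vig, n_cells = as.integer(n), missing = FALSE)
}

#' Extract satellite-scale features for one vine polygon
#'
#' Coarse pixels are larger than the polygon, so cell-centre membership is
#' replaced by exact geometry: `NDVI_S` is the overlap-area-weighted mean of
#' the pixels intersecting the polygon, and the class comes from the pixel
#' with the largest overlap.
#'
#' @param poly vine polygon (4 x 2 matrix, convex).
#' @param ndvi_s [ndvi_grid()] at coarse resolution.
#' @param vmap_s aligned satellite `vigour_map`.
#' @return list `ndvi_s`, `c_vigour_s`, `missing`.
#' @export
extract_sat_features <- function(poly, ndvi_s, vmap_s) {
  dims <- dim(ndvi_s$values)
  tr <- ndvi_s$transform
  rc <- paint_rows_cols(dims, tr, range(poly[, 1]), range(poly[, 2]))
  if (is.null(rc))
    return(list(ndvi_s = NA_real_, c_vigour_s = NA_character_, missing = TRUE))
  px <- tr$pixel_size
  wsum <- 0; vsum <- 0; best_ov <- 0; best_cls <- NA_integer_
  for (r in rc$rows) for (cc in rc$cols) {
    v <- ndvi_s$values[r, cc]
    if (!is.finite(v)) next
    xmin <- tr$origin_x + (cc - 1) * px; xmax <- xmin + px
    ymax <- tr$origin_y - (r - 1) * px; ymin <- ymax - px
    clipped <- clip_polygon_rect(poly, xmin, xmax, ymin, ymax)
    if (nrow(clipped) < 3) next
    ov <- polygon_area(clipped)
    if (ov <= 0) next
    wsum <- wsum + ov; vsum <- vsum + ov * v
    if (ov > best_ov) { best_ov <- ov; best_cls <- vmap_s$classes[r, cc] }
  }
  if (wsum == 0)
    return(list(ndvi_s = NA_real_, c_vigour_s = NA_character_, missing = TRUE))
  list(ndvi_s = vsum / wsum,
       c_vigour_s = if (is.na(best_cls)) NA_character_
                    else c("low", "medium", "high")[best_cls],
       missing = FALSE)
}

#' Flag edge points
#'
#' A sampling vine is an edge point when its polygon centroid lies within
#' `buffer` metres of the plot border, where coarse pixels mix in adjacent
#' land cover.
#'
#' @param poly vine polygon.
#' @param plot_boundary plot boundary polygon (n x 2 matrix).
#' @param buffer inner buffer width (m), default 3.
#' @return logical.
#' @export
classify_edge <- function(poly, plot_boundary, buffer = 3) {
  ctr <- polygon_centroid(poly)
  dist_to_ring(ctr[1], ctr[2], plot_boundary) < buffer
}

#' Assemble the per-vine database
#'
#' Joins the manual summary, UAV features, satellite features and plot
#' metadata into one record per sampled vine per stage, adds the composite
#' predictor `NDVI_D x Prj_area_D`, and derives `LWA_M` / `TRV_M` from the
#' manual means via [lwa()] and [trv()]. Keys that fail to join are reported.
#'
#' @param manual_summary output of [summarise_manual()] without the LWA/TRV
#'   columns (they are recomputed here), keyed by `vine_id`, `stage`.
#' @param uav data.frame keyed by `vine_id`, `stage` with `NDVI_D`,
#'   `Prj_area_D`, `C_vigour_D`.
#' @param sat data.frame keyed by `vine_id`, `stage` with `NDVI_S`,
#'   `C_vigour_S`, `Edge_pnt`.
#' @param plot_meta list with `plot`, `variety`, `year`, `row_spacing`.
#' @return data.frame of vine records (one row per vine-stage) with the
#'   database schema columns `Plot`, `Variety`, `Year`, `BBCH`, `Vine_id`,
#'   `NDVI_D`, `C_vigour_D`, `Prj_area_D`, `NDVI_D_x_Prj_area_D`, `H_M`,
#'   `W_M`, `LWA_M`, `TRV_M`, `NDVI_S`, `C_vigour_S`, `Edge_pnt`.
#' @export
assemble_records <- function(manual_summary, uav, sat, plot_meta) {
  key <- function(d) paste(d$vine_id, d$stage, sep = "|")
  km <- key(manual_summary); ku <- key(uav); ks <- key(sat)
  orphans <- c(setdiff(km, ku), setdiff(km, ks),
               setdiff(ku, km), setdiff(ks, km))
  if (length(orphans))
    stop("join mismatch; orphan keys: ", paste(unique(orphans), collapse = ", "),
         call. = FALSE)
  u <- uav[match(km, ku), ]
  s <- sat[match(km, ks), ]
  out <- data.frame(
    Plot = plot_meta$plot, Variety = plot_meta$variety, Year = plot_meta$year,
    BBCH = sub("^BBCH", "", manual_summary$stage),
    Vine_id = manual_summary$vine_id,
    NDVI_D = u$NDVI_D, C_vigour_D = u$C_vigour_D, Prj_area_D = u$Prj_area_D,
    NDVI_D_x_Prj_area_D = u$NDVI_D * u$Prj_area_D,
    H_M = manual_summary$H_M, W_M = manual_summary$W_M,
    LWA_M = lwa(manual_summary$H_M, plot_meta$row_spacing),
    TRV_M = trv(manual_summary$H_M, manual_summary$W_M, plot_meta$row_spacing),
    NDVI_S = s$NDVI_S, C_vigour_S = s$C_vigour_S, Edge_pnt = s$Edge_pnt,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read vine-record tables
#'
#' CSV with the database schema column names (see [assemble_records()]).
#' Numeric values are written at full precision so records round-trip.
#'
#' @param records vine-record data.frame.
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(BBCH = "character"))
  df$Edge_pnt <- as.logical(df$Edge_pnt)
  df
}
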