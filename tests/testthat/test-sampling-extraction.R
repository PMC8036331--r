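test_that("SUR sampling selects every m-th unit after the starts", {
  layout <- generate_layout(small_field())
  # census: both periods 1
  all_d <- sur_sample(layout, 1, 1, seed = 1)
  expect_setequal(all_d$selected, layout$vine_id)
  # 10 x 10 grid, periods (5, 3), starts (2, 1): rows {2,7}, vines {1,4,7,10}
  d <- sur_sample(layout, 5, 3, start_row = 2, start_vine = 1)
  expect_equal(length(d$selected), 8)
  expect_setequal(d$selected, sur_oracle(layout, 5, 3, 2, 1))
  sel_rows <- unique(layout$row_index[layout$vine_id %in% d$selected])
  expect_setequal(sel_rows, c(2, 7))
  # reference plot-A configuration runs without error at desk scale
  expect_warning(d2 <- sur_sample(layout, 5, 30, start_row = 3, start_vine = 6),
                 "period exceeds")
  expect_setequal(d2$selected, sur_oracle(layout, 5, 30, 3, 6))
  # random starts are within {1..m} and reproducible
  d3 <- sur_sample(layout, 4, 4, seed = 99)
  expect_true(d3$start_row %in% 1:4 && d3$start_vine %in% 1:4)
  expect_identical(d3$selected, sur_sample(layout, 4, 4, seed = 99)$selected)
})

test_that("SUR selection equals the enumeration oracle on random layouts", {
  set.seed(5)
  for (i in 1:50) {
    w <- runif(1, 6, 40); h <- runif(1, 6, 30)
    f <- field_spec(rect_boundary(w, h), row_spacing = runif(1, 2, 3),
                    vine_spacing = runif(1, 1, 1.5))
    layout <- generate_layout(f)
    if (!nrow(layout)) next
    mr <- sample(1:4, 1); mv <- sample(1:5, 1)
    sr <- sample(1:mr, 1); sv <- sample(1:mv, 1)
    d <- suppressWarnings(sur_sample(layout, mr, mv, start_row = sr,
                                     start_vine = sv))
    expect_identical(sort(d$selected),
                     sort(sur_oracle(layout, mr, mv, sr, sv)))
  }
})

test_that("vine polygons have the assigned row-cell geometry", {
  vine <- list(x = 3, y = 4)
  p <- vine_polygon(vine, row_spacing = 2.2)
  expect_equal(polygon_area(p), 1.2 * 2.2)
  expect_true(point_in_polygon(3, 4, p))
  pr <- vine_polygon(vine, row_spacing = 2.2, azimuth = 35)
  expect_equal(polygon_area(pr), 1.2 * 2.2)
})

test_that("UAV feature extraction matches hand computation on a toy grid", {
  tr <- list(origin_x = 0, origin_y = 4, pixel_size = 1)
  vals <- matrix(NA_real_, 4, 4)
  vals[] <- seq(0.1, 1.6, by = 0.1)   # column-major: cell (r,c) = 0.1*(4(c-1)+r)
  g <- ndvi_grid(pmin(vals, 1), tr)
  mvals <- matrix(0, 4, 4); mvals[2:3, 2:3] <- 1
  mask <- structure(list(values = mvals, threshold_used = 0.05,
                         method = "manual", transform = tr, crs = g$crs),
                    class = "canopy_mask")
  cls <- matrix(2L, 4, 4); cls[2, 2] <- 3L; cls[3, 2] <- 3L; cls[2, 3] <- 3L
  vmap <- structure(list(continuous = g, classes = cls,
                         thresholds = c(P20 = 0.2, P40 = 0.4, P60 = 0.6,
                                        P80 = 0.8)), class = "vigour_map")
  # polygon covering the whole 4 x 4 block
  poly <- rect_polygon(c(2, 2), 4, 4, 0)
  got <- extract_uav_features(poly, g, mask, vmap)
  # canopy cells: (2,2)=0.6, (3,2)=0.7, (2,3)=1.0, (3,3)=1.0 (clamped)
  expect_equal(got$n_cells, 4L)
  expect_equal(got$ndvi_d, mean(c(0.6, 0.7, 1.0, 1.0)))
  expect_equal(got$prj_area_d, 4)
  expect_identical(got$c_vigour_d, "high")   # 3 high vs 1 medium
  # constant canopy fully under the polygon: ndvi_d equals the constant
  g2 <- ndvi_grid(matrix(0.72, 4, 4), tr)
  m2 <- mask; m2$values <- matrix(1, 4, 4)
  got2 <- extract_uav_features(poly, g2, m2, vmap)
  expect_equal(got2$ndvi_d, 0.72)
  # empty mask: missing flag, zero area
  m0 <- mask; m0$values <- matrix(0, 4, 4)
  got0 <- extract_uav_features(poly, g, m0, vmap)
  expect_true(got0$missing)
  expect_equal(got0$prj_area_d, 0)
  expect_true(is.na(got0$ndvi_d))
})

test_that("majority-class ties resolve to medium", {
  tr <- list(origin_x = 0, origin_y = 2, pixel_size = 1)
  g <- ndvi_grid(matrix(0.5, 2, 2), tr)
  mask <- structure(list(values = matrix(1, 2, 2), threshold_used = 0,
                         method = "manual", transform = tr, crs = g$crs),
                    class = "canopy_mask")
  cls <- matrix(c(1L, 1L, 3L, 3L), 2, 2)
  vmap <- structure(list(continuous = g, classes = cls,
                         thresholds = c(P20 = 0, P40 = 0, P60 = 0, P80 = 0)),
                    class = "vigour_map")
  got <- extract_uav_features(rect_polygon(c(1, 1), 2, 2, 0), g, mask, vmap)
  expect_identical(got$c_vigour_d, "medium")
})

test_that("satellite extraction is an exact overlap-weighted mean", {
  tr <- list(origin_x = 0, origin_y = 6, pixel_size = 3)
  vals <- matrix(c(0.2, 0.5, 0.3, 0.6), 2, 2)
  g <- ndvi_grid(vals, tr)
  vmap <- structure(list(continuous = g,
                         classes = matrix(c(1L, 2L, 2L, 3L), 2, 2),
                         thresholds = c(P20 = 0, P40 = 0, P60 = 0, P80 = 0)),
                    class = "vigour_map")
  # polygon inside one pixel
  inside <- rect_polygon(c(1.5, 4.5), 1, 1, 0)
  expect_equal(extract_sat_features(inside, g, vmap)$ndvi_s, 0.2)
  # 50/50 split across pixels (1,1) and (2,1): mean of the two
  split <- rect_polygon(c(1.5, 3), 1.2, 2, 0)
  got <- extract_sat_features(split, g, vmap)
  expect_equal(got$ndvi_s, (0.2 + 0.5) / 2)
  # arbitrary axis-aligned placement vs interval-overlap oracle
  set.seed(31)
  for (i in 1:20) {
    ctr <- runif(2, 0.8, 5.2); along <- runif(1, 0.5, 2); across <- runif(1, 0.5, 2.5)
    poly <- rect_polygon(ctr, along, across, 0)
    x0 <- ctr[1] - across / 2; x1 <- ctr[1] + across / 2
    y0 <- ctr[2] - along / 2; y1 <- ctr[2] + along / 2
    wsum <- 0; vsum <- 0
    for (r in 1:2) for (cc in 1:2) {
      ox <- max(0, min(x1, cc * 3) - max(x0, (cc - 1) * 3))
      oy <- max(0, min(y1, 6 - (r - 1) * 3) - max(y0, 6 - r * 3))
      wsum <- wsum + ox * oy; vsum <- vsum + ox * oy * vals[r, cc]
    }
    expect_equal(extract_sat_features(poly, g, vmap)$ndvi_s, vsum / wsum,
                 tolerance = 1e-10)
  }
  # class comes from the dominant-overlap pixel
  expect_identical(got$c_vigour_s, "low")
})

test_that("edge classification uses the 3 m centroid buffer", {
  plot100 <- rect_boundary(100, 100)
  centre_poly <- rect_polygon(c(50, 50), 1.2, 2.2, 0)
  expect_false(classify_edge(centre_poly, plot100))
  border_poly <- rect_polygon(c(0, 50), 1.2, 2.2, 0)   # centroid on the ring
  expect_true(classify_edge(border_poly, plot100))
  near <- rect_polygon(c(2.9, 50), 1.2, 2.2, 0)
  expect_true(classify_edge(near, plot100))
  at3 <- rect_polygon(c(3.01, 50), 1.2, 2.2, 0)
  expect_false(classify_edge(at3, plot100))   # strict inequality at the buffer
  # random centroids vs the analytic rectangle distance oracle
  set.seed(17)
  px <- runif(30, 0, 100); py <- runif(30, 0, 100)
  for (i in seq_along(px)) {
    poly <- rect_polygon(c(px[i], py[i]), 1.2, 2.2, 0)
    expect_identical(classify_edge(poly, plot100),
                     min(px[i], 100 - px[i], py[i], 100 - py[i]) < 3)
  }
})

test_that("edge flags match the inner-ring area fraction", {
  field <- small_field()
  layout <- generate_layout(field)
  polys <- lapply(seq_len(nrow(layout)), function(i)
    vine_polygon(layout[i, ], field$row_spacing))
  edge <- vapply(polys, classify_edge, logical(1),
                 plot_boundary = field$boundary, buffer = 3)
  # ring area fraction for a 22 x 12 plot: 1 - (16*6)/(22*12)
  frac_area <- 1 - (16 * 6) / (22 * 12)
  expect_equal(mean(edge), frac_area, tolerance = 0.15)
})

test_that("record assembly derives the composite and dose variables", {
  ms <- data.frame(vine_id = c("v1", "v2"), stage = "BBCH75",
                   H_M = c(0.78, 1.0), W_M = c(0.33, 0.4))
  uav <- data.frame(vine_id = c("v1", "v2"), stage = "BBCH75",
                    NDVI_D = c(0.72, 0.8), Prj_area_D = c(0.17, 0),
                    C_vigour_D = c("medium", "high"))
  sat <- data.frame(vine_id = c("v1", "v2"), stage = "BBCH75",
                    NDVI_S = c(0.54, 0.5), C_vigour_S = c("medium", "high"),
                    Edge_pnt = c(FALSE, TRUE))
  rec <- assemble_records(ms, uav, sat,
                          list(plot = "A", variety = "Chardonnay",
                               year = 2019, row_spacing = 2.2))
  expect_equal(round(rec$NDVI_D_x_Prj_area_D[1], 2), 0.12)
  expect_equal(rec$NDVI_D_x_Prj_area_D[2], 0)      # zero-area vine
  expect_equal(round(rec$LWA_M[1], 2), 7090.91)
  expect_equal(round(rec$TRV_M[1], 2), 1170.00)
  expect_equal(rec$BBCH, c("75", "75"))
  # orphan keys are reported
  expect_error(assemble_records(ms, uav[1, ], sat,
                                list(plot = "A", variety = "x", year = 2019,
                                     row_spacing = 2.2)),
               "orphan.*v2", ignore.case = TRUE)
})

test_that("projected area never exceeds the polygon and recovers truth", {
  fx <- noiseless_scene(stage = "BBCH75")
  wf <- uav_vigour_workflow(fx$scene, clip = fx$field$boundary)
  field <- fx$field
  poly_area <- 1.2 * field$row_spacing
  sel <- fx$truths[seq(1, 100, by = 7), ]
  for (i in seq_len(nrow(sel))) {
    poly <- vine_polygon(sel[i, ], field$row_spacing)
    got <- extract_uav_features(poly, wf$ndvi, wf$mask, wf$map)
    expect_lte(got$prj_area_d, poly_area + 1e-9)
    truth_area <- sel$width_true[i] * 1.2
    expect_lt(abs(got$prj_area_d - truth_area) / truth_area, 0.10)
  }
})
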