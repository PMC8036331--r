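# Shared fixture builders. Everything is generated in code; no binary data.

# a tiny two-band scene with hand-set reflectances
toy_scene <- function(nir, red, pixel_size = 1, origin = c(0, 10)) {
  ms_scene(list(R = red, NIR = nir),
           list(origin_x = origin[1], origin_y = origin[2],
                pixel_size = pixel_size))
}

# default small study: 22 x 12 m plot, 10 x 10 vines at 2.2 / 1.2 m spacing
small_field <- function(azimuth = 0) {
  field_spec(rect_boundary(22, 12), row_spacing = 2.2, vine_spacing = 1.2,
             row_azimuth = azimuth, plot_id = "A", variety = "Chardonnay")
}

# noiseless render of a small field for geometric checks
noiseless_scene <- function(field = small_field(), stage = "BBCH59",
                            seed = 7, weed_density = 0) {
  layout <- generate_layout(field)
  truths <- assign_truth(layout, field, stage,
                         vp = vigour_params(noise_sd = 0), seed = seed)
  params <- scene_params(noise_sd = 0, weed_patch_density = weed_density)
  list(truths = truths,
       scene = render_scene(truths, field, params, seed = seed),
       params = params, field = field)
}

# brute-force IDW oracle: double loop over query cells and anchors
idw_oracle <- function(anchors, transform, dims, p = 2, k = 12) {
  out <- matrix(NA_real_, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    for (cc in seq_len(dims[2])) {
      qx <- transform$origin_x + (cc - 0.5) * transform$pixel_size
      qy <- transform$origin_y - (r - 0.5) * transform$pixel_size
      d <- sqrt((anchors$x - qx)^2 + (anchors$y - qy)^2)
      near <- order(d)[seq_len(min(k, nrow(anchors)))]
      if (d[near[1]] < 1e-12) {
        out[r, cc] <- anchors$value[near[1]]
      } else {
        w <- d[near]^(-p)
        out[r, cc] <- sum(w * anchors$value[near]) / sum(w)
      }
    }
  }
  out
}

# SUR enumeration oracle: explicit loops over rows and within-row positions
sur_oracle <- function(layout, row_period, vine_period, start_row, start_vine) {
  layout <- layout[order(layout$row_index, layout$along_row_position), ]
  sel <- character(0)
  rows <- sort(unique(layout$row_index))
  r <- start_row
  while (r <= length(rows)) {
    ids <- layout$vine_id[layout$row_index == rows[r]]
    v <- start_vine
    while (v <= length(ids)) {
      sel <- c(sel, ids[v])
      v <- v + vine_period
    }
    r <- r + row_period
  }
  sel
}

# vine records with a known log-linear data-generating process:
# ln(response) = a + b * ln(predictor) + N(0, sigma)
synthetic_records <- function(n, a, b, sigma, seed,
                              predictor_range = c(0.05, 0.5)) {
  set.seed(seed)
  x <- exp(runif(n, log(predictor_range[1]), log(predictor_range[2])))
  y <- exp(a + b * log(x) + rnorm(n, 0, sigma))
  data.frame(NDVI_D_x_Prj_area_D = x, TRV_M = y)
}

# full desk-scale pipeline runs are expensive; compute them once per session
# and share across acceptance checks
.pipeline_cache <- new.env(parent = emptyenv())
cached_runs <- function(n_seeds = 20) {
  key <- paste0("runs", n_seeds)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- lapply(seq_len(n_seeds), function(s)
      suppressWarnings(run_pipeline(default_config(seed = s),
                                    outdir = tempfile("vcaccept"),
                                    write_rasters = FALSE)))
  }
  .pipeline_cache[[key]]
}
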