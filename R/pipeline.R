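# Operational shell: run configuration, the end-to-end pipeline
# (simulate -> map vigour -> extract -> analyse) and artefact writing with
# metadata sidecars. Every random operation draws from a named seed derived
# from the run seed, so a rerun with the same config reproduces every number.

#' Default run configuration
#'
#' Desk-scale study conditions: one rectangular plot holding a 10 x 10 vine
#' grid (22 m x 12 m at 2.2 m row and 1.2 m vine spacing, the commonest plot
#' geometry in the emulated system), three stages (BBCH 59/75/81), fine
#' 0.0648 m and coarse 3 m resolutions, SUR sampling with periods (2, 2).
#'
#' @param seed master run seed; all operation seeds derive from it.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    plot = list(plot_id = "A", variety = "Chardonnay", width = 22, height = 12,
                origin = c(0, 0), row_spacing = 2.2, vine_spacing = 1.2,
                row_azimuth = 0, year = 2018),
    stages = c("BBCH59", "BBCH75", "BBCH81"),
    scene = list(gsd = 0.0648, noise_sd = 0.01, weed_patch_density = 20,
                 pad = 6),
    sat_gsd = 3,
    vigour = vigour_params(),
    dims = dimension_params(),
    manual = list(error_sd = 0.03, n_replicates = 6L),
    sampling = list(row_period = 2L, vine_period = 2L),
    mapping = list(threshold = "otsu", idw_p = 2, idw_k = 12),
    analysis = list(alpha = 0.05, gate = "ks", edge_buffer = 3,
                    sat_edge_rejected = TRUE),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' Configurations round-trip unchanged through serialisation.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  merged <- modifyList(base, cfg)
  merged$plot$origin <- as.numeric(merged$plot$origin)
  merged$seed <- as.integer(merged$seed)
  merged$sampling <- lapply(merged$sampling, as.integer)
  merged$manual$n_replicates <- as.integer(merged$manual$n_replicates)
  structure(merged, class = "run_config")
}

config_field <- function(config) {
  p <- config$plot
  field_spec(rect_boundary(p$width, p$height, p$origin),
             row_spacing = p$row_spacing, vine_spacing = p$vine_spacing,
             row_azimuth = p$row_azimuth, plot_id = p$plot_id,
             variety = p$variety)
}

config_scene_params <- function(config) {
  scene_params(gsd = config$scene$gsd, noise_sd = config$scene$noise_sd,
               weed_patch_density = config$scene$weed_patch_density,
               pad = config$scene$pad)
}

# deterministic per-operation seeds derived from the run seed
op_seed <- function(seed, stage_idx, op) {
  offsets <- c(truth = 11, manual = 29, render = 47, design = 71)
  as.integer((as.numeric(seed) * 131 + stage_idx * 17 + offsets[[op]]) %%
               2147483647)
}

#' Simulate the study's field and imagery for one run
#'
#' Generates the layout, per-stage ground truth (same spatial vigour pattern
#' across stages, canopy growing by the stage scale), simulated manual
#' measurement campaigns, fine-resolution scenes and their 3 m degraded
#' counterparts.
#'
#' @param config a `run_config` (see [default_config()]).
#' @return list with `field`, `layout`, and per-stage `truths`, `manual`,
#'   `scenes`, `sat_scenes`.
#' @export
simulate_study <- function(config = default_config()) {
  field <- config_field(config)
  layout <- generate_layout(field, seed = config$seed)
  if (!nrow(layout)) stop("plot too small for any vine", call. = FALSE)
  sp <- config_scene_params(config)
  truths <- list(); manual <- list(); scenes <- list(); sats <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[i]
    # one truth seed for all stages: vigour is a property of the plot
    truths[[st]] <- assign_truth(layout, field, stage = st,
                                 vp = do.call(vigour_params, config$vigour),
                                 dp = do.call(dimension_params, config$dims),
                                 seed = op_seed(config$seed, 0L, "truth"))
    manual[[st]] <- simulate_manual(truths[[st]],
                                    error_sd = config$manual$error_sd,
                                    n_replicates = config$manual$n_replicates,
                                    seed = op_seed(config$seed, i, "manual"))
    scenes[[st]] <- render_scene(truths[[st]], field, sp,
                                 seed = op_seed(config$seed, i, "render"))
    sats[[st]] <- degrade_to_satellite(scenes[[st]], config$sat_gsd)
  }
  list(field = field, layout = layout, truths = truths, manual = manual,
       scenes = scenes, sat_scenes = sats)
}

#' Build vigour maps for every stage of a simulated study
#'
#' @param sim output of [simulate_study()].
#' @param config the `run_config` used.
#' @return per-stage list with the fine-resolution workflow products
#'   (`uav`, see [uav_vigour_workflow()]) and the satellite map (`sat_ndvi`,
#'   `sat_map`).
#' @export
map_vigour_study <- function(sim, config = default_config()) {
  boundary <- sim$field$boundary
  out <- list()
  for (st in names(sim$scenes)) {
    uav <- uav_vigour_workflow(sim$scenes[[st]],
                               threshold = config$mapping$threshold,
                               p = config$mapping$idw_p,
                               k = config$mapping$idw_k, clip = boundary)
    sat_ndvi <- compute_ndvi(sim$sat_scenes[[st]])
    sat_map <- satellite_vigour(sat_ndvi, clip = boundary)
    out[[st]] <- list(uav = uav, sat_ndvi = sat_ndvi, sat_map = sat_map)
  }
  out
}

#' Sample vines and extract the per-vine database
#'
#' Applies the SUR design once (sampling vines are fixed across stages),
#' extracts UAV and satellite features per stage, flags edge points, and
#' assembles the vine records.
#'
#' @param sim output of [simulate_study()].
#' @param maps output of [map_vigour_study()].
#' @param config the `run_config` used.
#' @return list with `design` (`sur_design`), `polygons` (named list) and
#'   `records` (data.frame).
#' @export
extract_study <- function(sim, maps, config = default_config()) {
  design <- sur_sample(sim$layout, config$sampling$row_period,
                       config$sampling$vine_period,
                       seed = op_seed(config$seed, 0L, "design"))
  sel <- design$selected
  field <- sim$field
  polys <- lapply(sel, function(id) {
    vine <- sim$layout[sim$layout$vine_id == id, ]
    vine_polygon(vine, field$row_spacing, field$row_azimuth)
  })
  names(polys) <- sel
  edge <- vapply(polys, classify_edge, logical(1),
                 plot_boundary = field$boundary,
                 buffer = config$analysis$edge_buffer)
  manual_all <- list(); uav_all <- list(); sat_all <- list()
  for (st in names(sim$truths)) {
    mp <- maps[[st]]
    uav_feats <- lapply(polys, extract_uav_features, ndvi = mp$uav$ndvi,
                        mask = mp$uav$mask, vmap = mp$uav$map)
    sat_feats <- lapply(polys, extract_sat_features, ndvi_s = mp$sat_ndvi,
                        vmap_s = mp$sat_map)
    uav_all[[st]] <- data.frame(
      vine_id = sel, stage = st,
      NDVI_D = vapply(uav_feats, `[[`, numeric(1), "ndvi_d"),
      Prj_area_D = vapply(uav_feats, `[[`, numeric(1), "prj_area_d"),
      C_vigour_D = vapply(uav_feats, `[[`, character(1), "c_vigour_d"),
      stringsAsFactors = FALSE)
    sat_all[[st]] <- data.frame(
      vine_id = sel, stage = st,
      NDVI_S = vapply(sat_feats, `[[`, numeric(1), "ndvi_s"),
      C_vigour_S = vapply(sat_feats, `[[`, character(1), "c_vigour_s"),
      Edge_pnt = unname(edge), stringsAsFactors = FALSE)
    man <- sim$manual[[st]]
    manual_all[[st]] <- summarise_manual(man[man$vine_id %in% sel, ],
                                         field$row_spacing)[, c("vine_id",
                                                                "stage",
                                                                "H_M", "W_M")]
  }
  manual_summary <- do.call(rbind, manual_all)
  uav <- do.call(rbind, uav_all)
  sat <- do.call(rbind, sat_all)
  records <- assemble_records(manual_summary, uav, sat,
                              list(plot = field$plot_id,
                                   variety = field$variety,
                                   year = config$plot$year,
                                   row_spacing = field$row_spacing))
  records <- records[order(records$BBCH, records$Vine_id), ]
  rownames(records) <- NULL
  list(design = design, polygons = polys, records = records)
}

#' Run the statistical analyses over a vine-record database
#'
#' UAV-platform Spearman matrix, SPD and AD gated regressions against
#' `NDVI_D x Prj_area_D`; satellite edge-point sensitivity, then SPD and AD
#' regressions against `NDVI_S` (on edge-rejected records by default).
#'
#' @param records vine-record data.frame.
#' @param config the `run_config` used.
#' @return list of class `study_analysis`.
#' @export
analyse_study <- function(records, config = default_config()) {
  a <- config$analysis
  uav_vars <- c("NDVI_D", "Prj_area_D", "NDVI_D_x_Prj_area_D",
                "H_M", "W_M", "LWA_M", "TRV_M")
  rho_uav <- spearman_matrix(records, uav_vars)
  spd_uav <- spd_analysis(records, "NDVI_D_x_Prj_area_D",
                          alpha = a$alpha, gate = a$gate)
  ad_uav <- ad_analysis(records, "NDVI_D_x_Prj_area_D",
                        alpha = a$alpha, gate = a$gate)
  edges <- edge_sensitivity(records)
  sat_rec <- if (a$sat_edge_rejected) records[!records$Edge_pnt, ] else records
  spd_sat <- spd_analysis(sat_rec, "NDVI_S", alpha = a$alpha, gate = a$gate)
  ad_sat <- ad_analysis(sat_rec, "NDVI_S", alpha = a$alpha, gate = a$gate)
  structure(list(rho_uav = rho_uav, spd_uav = spd_uav, ad_uav = ad_uav,
                 edge = edges, spd_sat = spd_sat, ad_sat = ad_sat),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("== UAV Spearman matrix ==\n"); print(x$rho_uav)
  cat("\n== UAV regressions (SPD / AD) ==\n")
  print(rbind(as.data.frame(x$spd_uav), as.data.frame(x$ad_uav)))
  cat("\n== Satellite edge sensitivity ==\n"); print(x$edge)
  cat("\n== Satellite regressions (SPD / AD, edge-rejected) ==\n")
  print(rbind(as.data.frame(x$spd_sat), as.data.frame(x$ad_sat)))
  invisible(x)
}

regression_table <- function(analysis) {
  tab <- rbind(cbind(platform = "UAV", as.data.frame(analysis$spd_uav)),
               cbind(platform = "UAV", as.data.frame(analysis$ad_uav)),
               cbind(platform = "SAT", as.data.frame(analysis$spd_sat)),
               cbind(platform = "SAT", as.data.frame(analysis$ad_sat)))
  rownames(tab) <- NULL
  tab[c("mode", "platform", "response", "predictor", "slope", "intercept",
        "r_squared", "ks_p", "verdict", "n")]
}

#' Run the full pipeline and write its artefact set
#'
#' `simulate -> map vigour -> extract -> analyse`, writing into `outdir`:
#' the ground-truth and vine-record CSVs, scene and NDVI/vigour rasters with
#' georeferencing sidecars, layout and polygon GeoJSON, the regression
#' results CSV, a JSON report (quintile thresholds, Spearman matrices,
#' regression table) and a run-metadata sidecar (config, seeds, versions).
#' Reruns with the same config produce byte-identical CSV outputs.
#'
#' @param config a `run_config`.
#' @param outdir output directory (created if needed).
#' @param write_rasters write TIFF rasters (default TRUE; turning it off
#'   speeds up purely numerical reruns).
#' @return (invisibly) list with `sim`, `maps`, `extraction`, `analysis`,
#'   `paths`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("vcrun"),
                         write_rasters = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config)
  maps <- map_vigour_study(sim, config)
  ext <- extract_study(sim, maps, config)
  analysis <- analyse_study(ext$records, config)

  paths <- list()
  for (st in names(sim$truths)) {
    p <- file.path(outdir, paste0("truth_", st, ".csv"))
    write_truth(sim$truths[[st]], p, plot_id = config$plot$plot_id)
    paths[[paste0("truth_", st)]] <- p
    if (write_rasters) {
      ps <- file.path(outdir, paste0("scene_uav_", st, ".tif"))
      write_scene(sim$scenes[[st]], ps)
      write_scene(sim$sat_scenes[[st]],
                  file.path(outdir, paste0("scene_sat_", st, ".tif")))
      write_ndvi(maps[[st]]$uav$continuous,
                 file.path(outdir, paste0("ndvi_continuous_", st, ".tif")))
      paths[[paste0("scene_uav_", st)]] <- ps
    }
  }
  paths$layout <- write_layout_geojson(sim$layout,
                                       file.path(outdir, "layout.geojson"))
  paths$polygons <- write_polygons_geojson(
    c(list(boundary = sim$field$boundary), ext$polygons),
    file.path(outdir, "polygons.geojson"))
  paths$records <- write_records_csv(ext$records,
                                     file.path(outdir, "vine_records.csv"))
  tab <- regression_table(analysis)
  paths$regressions <- file.path(outdir, "regressions.csv")
  write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
            paths$regressions, row.names = FALSE, quote = FALSE)

  report <- list(
    quintile_thresholds = lapply(maps, function(m)
      list(uav = as.list(m$uav$map$thresholds),
           sat = as.list(m$sat_map$thresholds))),
    spearman_uav = as.data.frame(analysis$rho_uav$rho),
    spearman_sat_with_edges = as.data.frame(analysis$edge$with_edges$rho),
    spearman_sat_without_edges =
      if (!is.null(analysis$edge$without_edges))
        as.data.frame(analysis$edge$without_edges$rho) else NULL,
    regressions = tab)
  paths$report <- file.path(outdir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  meta <- list(config = unclass(config), seed = config$seed,
               package = "vinecanopy",
               package_version = as.character(utils::packageVersion("vinecanopy")),
               r_version = R.version.string)
  paths$metadata <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA)

  invisible(list(sim = sim, maps = maps, extraction = ext,
                 analysis = analysis, paths = paths))
}
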