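# Manual-measurement processing and the officially recognised dose-expression
# parameters for vertically trained hedgerow vineyards: leaf wall area (LWA,
# m2 of two-sided leaf wall per ground hectare) and tree row volume (TRV, m3
# of canopy cross-section per ground hectare).

#' Average replicate manual measurements
#'
#' Field protocol: each vine's canopy height and width are measured three
#' times by each of two surveyors; the per-vine value is the arithmetic mean
#' of the six replicates.
#'
#' @param obs numeric vector of replicate measurements (m), typically 6.
#' @return arithmetic mean (m).
#' @export
mean_measurement <- function(obs) {
  if (!length(obs)) stop("no measurements supplied (missing data)", call. = FALSE)
  if (any(!is.finite(obs)) || any(obs < 0))
    stop("measurements must be finite and non-negative", call. = FALSE)
  mean(obs)
}

#' Leaf wall area
#'
#' `LWA = 2 * height * 10000 / row_spacing` (m2 ha-1): both sides of the
#' vertical canopy wall, scaled by the row length packed into one hectare.
#'
#' @param height canopy height (m).
#' @param row_spacing distance between rows (m).
#' @return LWA in m2 ha-1.
#' @examples
#' lwa(0.78, 2.2) # 7090.909...
#' @export
lwa <- function(height, row_spacing) {
  if (any(row_spacing <= 0)) stop("row_spacing must be > 0", call. = FALSE)
  if (any(height < 0)) stop("height must be >= 0", call. = FALSE)
  2 * height * 10000 / row_spacing
}

#' Tree row volume
#'
#' `TRV = height * width * 10000 / row_spacing` (m3 ha-1): the canopy
#' cross-section extruded along the row length per hectare.
#'
#' @param height canopy height (m).
#' @param width canopy width (m).
#' @param row_spacing distance between rows (m).
#' @return TRV in m3 ha-1.
#' @examples
#' trv(0.78, 0.33, 2.2) # 1170
#' @export
trv <- function(height, width, row_spacing) {
  if (any(row_spacing <= 0)) stop("row_spacing must be > 0", call. = FALSE)
  if (any(height < 0) || any(width < 0))
    stop("height and width must be >= 0", call. = FALSE)
  height * width * 10000 / row_spacing
}

#' Read / write manual-measurement tables
#'
#' Long CSV schema: `vine_id, stage, dimension ("height"|"width"),
#' replicate (1..6), value_m`. `summarise_manual()` averages the six
#' replicates per vine/stage/dimension and derives LWA and TRV.
#'
#' @param path CSV path.
#' @export
read_manual_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("vine_id", "stage", "dimension", "replicate", "value_m")
  if (!all(need %in% names(df)))
    stop("manual CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_manual_csv
#' @param manual long-format measurement data.frame.
#' @export
write_manual_csv <- function(manual, path) {
  write.csv(manual, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_manual_csv
#' @param row_spacing plot row spacing (m) used for LWA / TRV.
#' @return `summarise_manual()`: data.frame with one row per vine/stage and
#'   columns `H_M`, `W_M`, `LWA_M`, `TRV_M` (full precision; round only at
#'   report boundaries).
#' @export
summarise_manual <- function(manual, row_spacing) {
  key <- interaction(manual$vine_id, manual$stage, drop = TRUE)
  rows <- lapply(split(manual, key), function(d) {
    h <- d$value_m[d$dimension == "height"]
    w <- d$value_m[d$dimension == "width"]
    data.frame(vine_id = d$vine_id[1], stage = d$stage[1],
               H_M = mean_measurement(h), W_M = mean_measurement(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$LWA_M <- lwa(out$H_M, row_spacing)
  out$TRV_M <- trv(out$H_M, out$W_M, row_spacing)
  out
}

#' Simulate the manual measurement campaign on synthetic truth
#'
#' Generates the six replicate tape measurements per vine and dimension as
#' truth plus iid Gaussian surveyor error.
#'
#' @param truths output of [assign_truth()].
#' @param error_sd measurement error standard deviation (m); 0.03 m reflects
#'   tape measurement of a loosely defined canopy envelope.
#' @param n_replicates replicates per dimension (3 measurements x 2
#'   surveyors = 6).
#' @param seed integer RNG seed.
#' @return long-format data.frame, see [read_manual_csv()].
#' @export
simulate_manual <- function(truths, error_sd = 0.03, n_replicates = 6L,
                            seed = 1L) {
  n <- nrow(truths)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        dimension = c("height", "width"),
                        idx = seq_len(n), stringsAsFactors = FALSE)
    truth_val <- ifelse(grid$dimension == "height",
                        truths$height_true[grid$idx],
                        truths$width_true[grid$idx])
    data.frame(vine_id = truths$vine_id[grid$idx],
               stage = truths$stage[grid$idx],
               dimension = grid$dimension, replicate = grid$replicate,
               value_m = pmax(0, truth_val + rnorm(nrow(grid), 0, error_sd)),
               stringsAsFactors = FALSE)
  })
}
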