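# Statistical core: Spearman correlation matrices, log-linear regression
# gated on residual normality (Kolmogorov-Smirnov), single-point (SPD) and
# vigour-class-aggregated (AD) analyses, and edge-point sensitivity.

#' Natural-log transform with domain checking
#'
#' @param values numeric vector, strictly positive.
#' @return `log(values)`. Non-positive entries raise an error naming the
#'   offending indices (records are never silently dropped).
#' @export
ln_transform <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("ln_transform: non-positive or non-finite values at indices ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  log(values)
}

#' Spearman rank correlation matrix
#'
#' Pairwise-complete Spearman correlations (average ranks for ties).
#'
#' @param records data.frame.
#' @param variables column names to correlate (numeric).
#' @return Object of class `spearman_matrix`: `rho` (symmetric matrix,
#'   diagonal 1, `NA` where a variable is constant) and `n` (complete cases
#'   per pair).
#' @export
spearman_matrix <- function(records, variables) {
  x <- as.matrix(records[variables])
  storage.mode(x) <- "double"
  const <- apply(x, 2, function(v) {
    v <- v[is.finite(v)]; length(v) > 0 && min(v) == max(v)
  })
  rho <- suppressWarnings(cor(x, method = "spearman",
                              use = "pairwise.complete.obs"))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho)[!const] <- 1
  n <- crossprod(!is.na(x))
  if (any(n[upper.tri(n)] < 3))
    warning("some variable pairs have fewer than 3 complete cases")
  structure(list(rho = rho, n = n, constant = names(const)[const]),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("Spearman rank correlation matrix\n")
  print(round(x$rho, digits))
  if (length(x$constant))
    cat("constant (undefined) variables:", paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

#' Log-linear regression gated on residual normality
#'
#' Fits `y = intercept + slope * x` by ordinary least squares on
#' already-log-transformed inputs, then tests the residuals for normality.
#' If the test rejects at level `alpha` the model's verdict is `"rejected"`;
#' otherwise `"accepted"`. The default gate is a one-sample
#' Kolmogorov-Smirnov test against a normal with mean and sd estimated from
#' the residuals; since estimating parameters makes plain KS conservative,
#' the Lilliefors-corrected variant is available with `gate = "lilliefors"`.
#'
#' @param x,y numeric vectors (log scale); `n >= 3` after removing
#'   incomplete pairs.
#' @param alpha gate significance level, default 0.05.
#' @param gate `"ks"` (default) or `"lilliefors"`.
#' @param mode `"SPD"` (each vine-date one point) or `"AD"` (vigour-class
#'   means), a label carried into reports.
#' @param response,predictor variable labels for reporting.
#' @return Object of class `gated_lm`: the underlying [stats::lm()] fit plus
#'   `slope`, `intercept`, `r_squared`, `ks_p`, `verdict`, `n`, `mode`.
#' @export
gated_lm <- function(x, y, alpha = 0.05, gate = c("ks", "lilliefors"),
                     mode = "SPD", response = "y", predictor = "x") {
  gate <- match.arg(gate)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (max(x) == min(x)) stop("zero variance in the predictor", call. = FALSE)
  df <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = df)
  res <- residuals(fit)
  ks_p <- if (sd(res) == 0) 1 else if (gate == "ks") {
    suppressWarnings(ks.test(res, "pnorm", mean(res), sd(res)))$p.value
  } else {
    nortest::lillie.test(res)$p.value
  }
  structure(list(fit = fit, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 ks_p = ks_p, alpha = alpha, gate = gate,
                 verdict = if (ks_p > alpha) "accepted" else "rejected",
                 n = length(x), mode = mode,
                 response = response, predictor = predictor),
            class = "gated_lm")
}

#' @export
print.gated_lm <- function(x, ...) {
  cat(sprintf("%s model [%s]: Ln %s ~ Ln %s\n", x$mode, x$verdict,
              x$response, x$predictor))
  cat(sprintf("  slope %.4f, intercept %.4f, R2 %.3f, KS p %.3g, n %d\n",
              x$slope, x$intercept, x$r_squared, x$ks_p, x$n))
  invisible(x)
}

#' @export
summary.gated_lm <- function(object, ...) {
  s <- summary(object$fit)
  cat(sprintf("Gated log-linear model (%s, gate %s at alpha %.2f): %s\n",
              object$mode, object$gate, object$alpha, object$verdict))
  cat(sprintf("residual normality p = %.4g; R2 = %.4f; n = %d\n\n",
              object$ks_p, object$r_squared, object$n))
  print(s$coefficients)
  invisible(s)
}

#' @export
coef.gated_lm <- function(object, ...) coef(object$fit)

#' @export
residuals.gated_lm <- function(object, ...) residuals(object$fit)

#' Predict from a gated log-linear model
#'
#' @param object a `gated_lm`.
#' @param newdata optional data.frame with column `x` (log scale).
#' @param interval `"none"` or `"confidence"` (95% band, as drawn in the
#'   model plots).
#' @param ... passed to [stats::predict.lm()].
#' @export
predict.gated_lm <- function(object, newdata = NULL,
                             interval = c("none", "confidence"), ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) predict(object$fit, interval = interval, ...)
  else predict(object$fit, newdata = newdata, interval = interval, ...)
}

#' Scatter, fitted line and 95% confidence band of a gated model
#'
#' @param x a `gated_lm`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gated_lm <- function(x, ...) {
  d <- x$fit$model
  xs <- seq(min(d$x), max(d$x), length.out = 100)
  pr <- predict(x$fit, data.frame(x = xs), interval = "confidence")
  plot(d$x, d$y, pch = 19, col = "grey30",
       xlab = paste("Ln", x$predictor), ylab = paste("Ln", x$response), ...)
  polygon(c(xs, rev(xs)), c(pr[, "lwr"], rev(pr[, "upr"])),
          col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  lines(xs, pr[, "fit"], lwd = 2)
  legend("topleft", bty = "n",
         legend = sprintf("R2 = %.2f, KS p = %.3f (%s)",
                          x$r_squared, x$ks_p, x$verdict))
  invisible(x)
}

fit_one_response <- function(records, predictor, response, alpha, gate, mode) {
  ok <- is.finite(records[[predictor]]) & is.finite(records[[response]])
  if (any(!ok))
    warning(sum(!ok), " incomplete record(s) dropped for ", response)
  records <- records[ok, , drop = FALSE]
  gated_lm(ln_transform(records[[predictor]]),
           ln_transform(records[[response]]),
           alpha = alpha, gate = gate, mode = mode,
           response = response, predictor = predictor)
}

#' Single-point-data (SPD) regression analysis
#'
#' One gated log-linear fit per manual response against the remote-sensing
#' predictor, every vine-date record one point. Plots, years and stages are
#' pooled into a single model per response.
#'
#' @param records vine-record data.frame (see [assemble_records()]).
#' @param predictor predictor column, `"NDVI_D_x_Prj_area_D"` for the UAV
#'   platform or `"NDVI_S"` for the satellite platform.
#' @param responses response columns, default the four canopy parameters.
#' @param alpha,gate see [gated_lm()].
#' @return Object of class `vigour_regressions` (a list of `gated_lm` with a
#'   tabular summary method).
#' @export
spd_analysis <- function(records, predictor = "NDVI_D_x_Prj_area_D",
                         responses = c("H_M", "W_M", "LWA_M", "TRV_M"),
                         alpha = 0.05, gate = "ks") {
  fits <- lapply(responses, function(r)
    fit_one_response(records, predictor, r, alpha, gate, "SPD"))
  names(fits) <- responses
  structure(fits, class = "vigour_regressions")
}

#' Aggregated-data (AD) regression analysis
#'
#' Records are averaged within (plot, year, stage, vigour class) cells --
#' three zone means per plot and date -- and the gated fits run on the cell
#' means. Empty class cells are dropped with a warning.
#'
#' @inheritParams spd_analysis
#' @param class_var vigour-class column matching the predictor platform
#'   (`"C_vigour_D"` for UAV, `"C_vigour_S"` for satellite).
#' @export
ad_analysis <- function(records, predictor = "NDVI_D_x_Prj_area_D",
                        responses = c("H_M", "W_M", "LWA_M", "TRV_M"),
                        class_var = if (predictor == "NDVI_S") "C_vigour_S"
                                    else "C_vigour_D",
                        alpha = 0.05, gate = "ks") {
  agg <- aggregate_by_class(records, c(predictor, responses), class_var)
  fits <- lapply(responses, function(r)
    fit_one_response(agg, predictor, r, alpha, gate, "AD"))
  names(fits) <- responses
  out <- structure(fits, class = "vigour_regressions")
  attr(out, "aggregated") <- agg
  out
}

#' Average records within (plot, year, stage, vigour class) cells
#'
#' @param records vine-record data.frame.
#' @param value_vars numeric columns to average.
#' @param class_var vigour-class column.
#' @return data.frame of cell means, one row per non-empty cell.
#' @export
aggregate_by_class <- function(records, value_vars, class_var) {
  cls <- records[[class_var]]
  keep <- !is.na(cls)
  if (any(!keep))
    warning(sum(!keep), " record(s) without a vigour class dropped")
  rec <- records[keep, , drop = FALSE]
  by <- list(Plot = rec$Plot, Year = rec$Year, BBCH = rec$BBCH,
             class = rec[[class_var]])
  agg <- aggregate(rec[value_vars], by = by, FUN = mean, na.rm = TRUE)
  n_cells_expected <- nrow(unique(data.frame(by$Plot, by$Year, by$BBCH))) * 3
  if (nrow(agg) < n_cells_expected)
    warning("empty vigour-class cells dropped: ",
            n_cells_expected - nrow(agg), " of ", n_cells_expected)
  agg
}

#' @export
print.vigour_regressions <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.vigour_regressions <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(f)
    data.frame(mode = f$mode, response = f$response, predictor = f$predictor,
               slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, ks_p = f$ks_p, verdict = f$verdict,
               n = f$n, stringsAsFactors = FALSE)))
}

#' Edge-point sensitivity of satellite correlations
#'
#' Spearman matrices computed twice: over all records and over the subset
#' with `Edge_pnt == FALSE`, mirroring the with/without-edge comparison used
#' to justify rejecting border vines from satellite analyses.
#'
#' @param records vine-record data.frame carrying `Edge_pnt`.
#' @param variables columns to correlate, default `NDVI_S` against the four
#'   manual parameters.
#' @return list of class `edge_sensitivity` with elements `with_edges`,
#'   `without_edges` (both `spearman_matrix`) and `n_edge`.
#' @export
edge_sensitivity <- function(records,
                             variables = c("NDVI_S", "H_M", "W_M",
                                           "LWA_M", "TRV_M")) {
  if (!"Edge_pnt" %in% names(records))
    stop("records lack the Edge_pnt flag", call. = FALSE)
  keep <- !records$Edge_pnt
  without <- if (any(keep)) spearman_matrix(records[keep, ], variables) else {
    warning("all records are edge points; edge-rejected matrix undefined")
    NULL
  }
  structure(list(with_edges = spearman_matrix(records, variables),
                 without_edges = without,
                 n_edge = sum(records$Edge_pnt)),
            class = "edge_sensitivity")
}

#' @export
print.edge_sensitivity <- function(x, ...) {
  cat("Considering edge points (n_edge =", x$n_edge, "):\n")
  print(x$with_edges)
  cat("\nRejecting edge points:\n")
  if (is.null(x$without_edges)) cat("  (undefined: all records are edge points)\n")
  else print(x$without_edges)
  invisible(x)
}
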