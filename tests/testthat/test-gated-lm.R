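test_that("ln transform guards its domain and lists offenders", {
  expect_equal(ln_transform(1), 0)
  expect_equal(ln_transform(exp(1)), 1)
  expect_error(ln_transform(c(1, 0, 2)), "indices 2")
  expect_error(ln_transform(c(-1, NA)), "indices 1, 2")
})

test_that("Spearman matrix handles ties like the hand-ranked oracle", {
  df <- data.frame(x = c(1, 2, 2, 4), y = c(3, 1, 4, 4))
  m <- spearman_matrix(df, c("x", "y"))
  # hand ranks: x -> (1, 2.5, 2.5, 4); y -> (2, 1, 3.5, 3.5);
  # Pearson of those ranks = 2.25 / sqrt(4.5 * 4.5) = 0.5
  expect_equal(m$rho["x", "y"], 0.5)
  expect_equal(diag(m$rho), c(x = 1, y = 1))
  # monotone invariance: x vs exp(x) is a perfect rank correlation
  df2 <- data.frame(a = c(0.3, 1.2, 2, 5), b = exp(c(0.3, 1.2, 2, 5)))
  expect_equal(spearman_matrix(df2, c("a", "b"))$rho["a", "b"], 1)
  # constant variable flagged undefined
  df3 <- data.frame(a = 1:4, c = rep(2, 4))
  m3 <- suppressWarnings(spearman_matrix(df3, c("a", "c")))
  expect_true(is.na(m3$rho["a", "c"]))
  expect_identical(m3$constant, "c")
})

test_that("Spearman is invariant to strictly monotone transforms", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(30); y <- x + rnorm(30)
    r1 <- spearman_matrix(data.frame(x = x, y = y), c("x", "y"))$rho[1, 2]
    r2 <- spearman_matrix(data.frame(x = exp(x), y = y^3), c("x", "y"))$rho[1, 2]
    expect_equal(r1, r2)
  }
})

test_that("gated OLS recovers exact lines and matches the normal-equations oracle", {
  x <- seq_len(10)
  # a perfect line triggers base lm's "essentially perfect fit" warning
  fit <- suppressWarnings(gated_lm(x, 2 * x + 1))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$verdict, "accepted")
  # 5 hand-listed points vs closed-form normal equations
  xs <- c(0.1, 0.5, 1.1, 1.8, 2.4); ys <- c(0.3, 0.9, 1.2, 2.4, 2.6)
  f2 <- gated_lm(xs, ys)
  sxx <- sum((xs - mean(xs))^2); sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  b <- sxy / sxx; a <- mean(ys) - b * mean(xs)
  expect_equal(f2$slope, b, tolerance = 1e-10)
  expect_equal(f2$intercept, a, tolerance = 1e-10)
  ssr <- sum((ys - a - b * xs)^2); sst <- sum((ys - mean(ys))^2)
  expect_equal(f2$r_squared, 1 - ssr / sst, tolerance = 1e-10)
  expect_error(gated_lm(rep(1, 5), 1:5), "variance")
  expect_error(gated_lm(1:2, 1:2), "3 complete")
})

test_that("the normality gate rejects exponential residuals and is pure in ks_p", {
  # strongly skewed residuals: the gate should reject nearly always
  rejected <- vapply(1:100, function(s) {
    set.seed(s)
    x <- runif(300)
    y <- x + rexp(300)
    gated_lm(x, y)$verdict == "rejected"
  }, logical(1))
  expect_gte(mean(rejected), 0.90)
  # verdict is a pure function of ks_p and alpha
  set.seed(1)
  f <- gated_lm(runif(50), rnorm(50))
  expect_identical(f$verdict, if (f$ks_p > f$alpha) "accepted" else "rejected")
  f2 <- gated_lm(runif(50), rnorm(50), alpha = 1)
  expect_identical(f2$verdict, "rejected")   # ks_p <= 1 always
})

test_that("gated_lm methods expose the fit", {
  set.seed(2)
  x <- runif(40); y <- 1 + 0.5 * x + rnorm(40, 0, 0.05)
  f <- gated_lm(x, y, response = "TRV_M", predictor = "NDVI")
  expect_equal(unname(coef(f)), c(f$intercept, f$slope))
  expect_length(residuals(f), 40)
  pr <- predict(f, data.frame(x = c(0, 1)), interval = "confidence")
  expect_equal(unname(pr[, "fit"]), c(f$intercept, f$intercept + f$slope))
  expect_true(all(pr[, "lwr"] < pr[, "fit"] & pr[, "fit"] < pr[, "upr"]))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
  expect_output(print(f), "TRV_M")
})

test_that("SPD analysis is exact for a noiseless generating process", {
  rec <- synthetic_records(100, a = 2, b = 1.5, sigma = 0, seed = 1)
  out <- suppressWarnings(spd_analysis(rec, "NDVI_D_x_Prj_area_D", "TRV_M"))
  f <- out$TRV_M
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 1.5, tolerance = 1e-9)
  expect_equal(f$intercept, 2, tolerance = 1e-9)
  expect_identical(f$mode, "SPD")
})

test_that("duplicated records give the same fit as a weighted oracle", {
  rec <- synthetic_records(30, a = 1, b = 0.8, sigma = 0.1, seed = 9)
  dup <- rbind(rec, rec)
  f1 <- spd_analysis(rec, "NDVI_D_x_Prj_area_D", "TRV_M")$TRV_M
  f2 <- spd_analysis(dup, "NDVI_D_x_Prj_area_D", "TRV_M")$TRV_M
  # duplicating every point leaves the OLS solution unchanged
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-12)
  # and equals explicit weighted least squares with weight 2
  w <- lm(log(TRV_M) ~ log(NDVI_D_x_Prj_area_D), data = rec, weights = rep(2, 30))
  expect_equal(f2$slope, unname(coef(w)[2]), tolerance = 1e-12)
})

test_that("AD aggregation equals a group-by-mean oracle and yields 3 points per cell-group", {
  set.seed(6)
  rec <- data.frame(
    Plot = "A", Year = 2018,
    BBCH = rep(c("59", "75"), each = 30),
    C_vigour_D = rep(rep(c("low", "medium", "high"), each = 10), 2),
    NDVI_D_x_Prj_area_D = runif(60, 0.05, 0.4),
    TRV_M = runif(60, 500, 2000),
    H_M = runif(60, 0.4, 1.4), W_M = runif(60, 0.2, 0.6),
    LWA_M = runif(60, 3000, 12000))
  agg <- aggregate_by_class(rec, c("NDVI_D_x_Prj_area_D", "TRV_M"), "C_vigour_D")
  expect_equal(nrow(agg), 6)   # 2 stages x 3 classes
  # oracle: explicit split + colMeans
  for (i in seq_len(nrow(agg))) {
    sub <- rec[rec$BBCH == agg$BBCH[i] & rec$C_vigour_D == agg$class[i], ]
    expect_equal(agg$TRV_M[i], mean(sub$TRV_M), tolerance = 1e-12)
    expect_equal(agg$NDVI_D_x_Prj_area_D[i], mean(sub$NDVI_D_x_Prj_area_D),
                 tolerance = 1e-12)
  }
  # degenerate aggregation: all vines identical within a class
  rec2 <- rec
  for (cl in c("low", "medium", "high")) for (st in c("59", "75")) {
    sel <- rec2$C_vigour_D == cl & rec2$BBCH == st
    rec2$NDVI_D_x_Prj_area_D[sel] <- rec2$NDVI_D_x_Prj_area_D[sel][1]
    rec2$TRV_M[sel] <- rec2$TRV_M[sel][1]
  }
  f_ad <- ad_analysis(rec2, "NDVI_D_x_Prj_area_D", "TRV_M")$TRV_M
  reps <- rec2[!duplicated(paste(rec2$BBCH, rec2$C_vigour_D)), ]
  f_spd <- spd_analysis(reps, "NDVI_D_x_Prj_area_D", "TRV_M")$TRV_M
  expect_equal(f_ad$slope, f_spd$slope, tolerance = 1e-12)
  expect_equal(f_ad$r_squared, f_spd$r_squared, tolerance = 1e-12)
  # empty class cell is dropped with a warning
  rec3 <- rec[!(rec$BBCH == "59" & rec$C_vigour_D == "low"), ]
  expect_warning(aggregate_by_class(rec3, "TRV_M", "C_vigour_D"), "empty")
})

test_that("edge sensitivity compares with/without edge records", {
  rec <- synthetic_records(40, a = 1, b = 1, sigma = 0.1, seed = 4)
  rec$NDVI_S <- rec$NDVI_D_x_Prj_area_D
  rec$H_M <- rec$TRV_M; rec$W_M <- rec$TRV_M; rec$LWA_M <- rec$TRV_M
  rec$Edge_pnt <- FALSE
  es <- edge_sensitivity(rec)
  expect_equal(es$with_edges$rho, es$without_edges$rho)
  expect_equal(es$n_edge, 0)
  # toy 6-record set vs hand computation: attenuating the edge NDVI_S
  # weakens the pooled correlation
  toy <- data.frame(NDVI_S = c(0.2, 0.3, 0.4, 0.5, 0.05, 0.06),
                    TRV_M = c(500, 800, 1100, 1400, 1600, 1800),
                    H_M = 1, W_M = 1, LWA_M = 1,
                    Edge_pnt = c(rep(FALSE, 4), TRUE, TRUE))
  es2 <- suppressWarnings(edge_sensitivity(toy))
  # without edges: NDVI_S and TRV_M are both increasing -> rho = 1
  expect_equal(es2$without_edges$rho["NDVI_S", "TRV_M"], 1)
  # with the two attenuated edge vines rho drops below 1 (hand ranks:
  # NDVI ranks 3,4,5,6,1,2 vs TRV ranks 1..6)
  expect_lt(es2$with_edges$rho["NDVI_S", "TRV_M"], 0.2)
  noflag <- rec; noflag$Edge_pnt <- NULL
  expect_error(edge_sensitivity(noflag), "Edge_pnt")
  all_edge <- toy; all_edge$Edge_pnt <- TRUE
  expect_warning(es3 <- edge_sensitivity(all_edge), "all records")
  expect_null(es3$without_edges)
})
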