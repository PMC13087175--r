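test_that("DOC to DOM conversion applies the fixed factor", {
  expect_equal(dom_from_doc(0), 0)
  expect_equal(dom_from_doc(1e6), 0.0408) # 1 mol/L
  expect_equal(dom_from_doc(50), 2.04e-6)
})

test_that("TPP to POM conversion and the station override", {
  out <- pom_from_tpp(10)
  expect_equal(out$poc_umol, 0.8)
  expect_equal(out$pom_kg, 1.92176e-8, tolerance = 1e-6)
  expect_equal(pom_from_tpp(0)$pom_kg, 0)
  ov <- pom_from_tpp(c(30, 30, 30), station = c("22", "22", "07"),
                     depth = c(2200, 1500, 2200))
  expect_equal(ov$pom_kg[1], 2e-9) # inside the override window
  expect_equal(ov$pom_kg[2], ov$pom_kg[3]) # outside: depth or station
  expect_gt(ov$pom_kg[2], 2e-9)
})

test_that("DOC outliers are dropped from support, samples retained", {
  d <- tibble::tibble(doc = c(60, 45, 53, NA), depth = c(400, 400, 200, 400))
  out <- filter_doc_outliers(d)
  expect_equal(out$doc_support, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(nrow(out), 4)
  all_low <- filter_doc_outliers(tibble::tibble(doc = c(40, 45), depth = c(400, 500)))
  expect_true(all(all_low$doc_support))
})

test_that("gridding reproduces support values, interpolates linearly, no extrapolation", {
  d <- tibble::tibble(
    station = rep(c("a", "b", "c"), each = 3),
    lon = rep(c(0, 0.5, 1.0), each = 3), lat = 0,
    depth = rep(c(100, 200, 300), 3),
    val = c(1, 2, 3, 2, 4, 6, 3, 6, 9)
  )
  g <- interpolate_transect(d, "val", dx_km = 5, dz_m = 10)
  db <- unname(g$station_dist["b"])
  expect_equal(grid_lookup(g, db, 200), 4)        # support point
  expect_equal(grid_lookup(g, db, 150), 3)        # vertical midpoint mean
  expect_true(is.na(grid_lookup(g, db, 5000)))    # outside the envelope
  expect_true(is.na(grid_lookup(g, -50, 200)))
  expect_error(interpolate_transect(d[1:2, ], "val"), "insufficient")
  expect_error(interpolate_transect(d, "nope"), "not found")
})

test_that("residual classes are assigned by the documented thresholds", {
  d <- tibble::tibble(
    residual_dfe = c(0, -0.5, 1.0, 0.1, 0.2),
    residual_lpfe = c(0, 0, 0, -0.5, 0.3)
  )
  out <- classify_residuals(d, preset = "text")
  expect_equal(as.character(out$class),
               c("equilibrium_inlier", "enhanced_negative", "enhanced_positive",
                 "enhanced_negative", "intermediate"))
  # data-derived band: zero residual sits inside any IQR containing the median
  set.seed(1)
  d2 <- tibble::tibble(residual_dfe = rnorm(101, 0, 0.05),
                       residual_lpfe = rnorm(101, 0, 0.02))
  d2$residual_dfe[1] <- 0
  d2$residual_lpfe[1] <- 0
  out2 <- classify_residuals(d2, preset = "data")
  expect_equal(as.character(out2$class[1]), "equilibrium_inlier")
})

test_that("classification is an exhaustive, exclusive partition", {
  set.seed(3)
  d <- tibble::tibble(residual_dfe = rnorm(500, 0, 0.6),
                      residual_lpfe = rnorm(500, 0, 0.4))
  for (preset in c("data", "text", "figure")) {
    out <- classify_residuals(d, preset = preset)
    expect_false(anyNA(out$class))
  }
  # both printed presets are available and differ
  b1 <- attr(classify_residuals(d, "text"), "inlier_band")
  b2 <- attr(classify_residuals(d, "figure"), "inlier_band")
  expect_equal(b1, c(-0.034, 0.135))
  expect_equal(b2, c(-0.032, 0.157))
})

test_that("ferromanganese diagnostic gates on class, depth and Fe:Mn ratio", {
  d <- tibble::tibble(
    class = factor(c("enhanced_negative", "enhanced_negative",
                     "enhanced_negative", "equilibrium_inlier"),
                   levels = levels(classify_residuals(
                     tibble::tibble(residual_dfe = 0, residual_lpfe = 0))$class)),
    depth = c(3500, 1000, 3500, 3500),
    lpfe_obs = c(0.44, 0.44, 10, 0.44),   # nmol/L
    lpmn = c(400, 400, 200, 400)          # pmol/L -> ratios 1.1, 1.1, 50, 1.1
  )
  out <- flag_ferromanganese(d)
  expect_equal(out$ferromanganese, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("summary statistics match closed forms on constructed data", {
  x <- c(1, 2, 3, 4, 5)
  s <- summary_stats(x, x)
  expect_equal(s$median_obs, 3)
  expect_equal(s$iqr_obs, 2)
  expect_equal(s$r, 1)
  expect_equal(s$slope, 1)
  expect_equal(s$intercept, 0, tolerance = 1e-12)
  s2 <- summary_stats(x, 2 * x)
  expect_equal(s2$slope, 2)
  expect_equal(s2$r2, 1)
  expect_error(summary_stats(c(1, 2), c(1, 2)), "at least 3")
  s3 <- summary_stats(c(x, NA), c(2 * x, 1)) # missing pair dropped
  expect_equal(s3$n, 5)
})

test_that("the pipeline is deterministic and classifies a small transect", {
  tr <- synth_transect(seed = 21, n_stations = 6,
                       depths = c(300, 600, 1200, 2500, 4000), noise_fe = 0.03)
  out1 <- run_transect(tr$samples, preset = "text")
  out2 <- run_transect(tr$samples, preset = "text")
  expect_identical(out1$samples, out2$samples)
  expect_s3_class(out1, "fe_transect")
  expect_false(anyNA(out1$samples$class))
  gl <- glance(out1)
  expect_true(gl$inlier_fraction > 0.5)
  td <- tidy(out1)
  expect_identical(nrow(td), nrow(tr$samples))
  # depth filter: samples at/above 250 m are excluded
  shallow <- dplyr::mutate(tr$samples[1, ], depth = 200)
  out3 <- run_transect(dplyr::bind_rows(shallow, tr$samples), preset = "text")
  expect_identical(nrow(out3$samples), nrow(tr$samples))
})
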