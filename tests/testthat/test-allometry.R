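test_that("the three built-in predictive equations are shipped verbatim", {
  bm <- builtin_models()
  expect_length(bm, 3)
  expect_equal(bm$A60$slope, 100.72)
  expect_equal(bm$A60$intercept, 436.24)
  expect_equal(bm$A65$slope, 105.98)
  expect_equal(bm$A65$intercept, 390)
  expect_equal(bm$C$form, "LOG10LOG10")
  expect_equal(bm$C$slope, 1.0739)
  expect_equal(bm$C$intercept, 1.9842)
  expect_equal(bm$C$predictor, "prW")
  expect_true(all(vapply(bm, `[[`, "", "provenance") == "BUILTIN"))
})

test_that("predict_tbl reproduces the published giant-snake maximum", {
  # largest recorded prezygapophyseal width, log-log equation -> 15.2 m
  est <- predict_tbl(builtin_models()$C, 111.4)
  expect_equal(tbl_m(est), 15.2)
  expect_equal(unclass(est),
               10^(1.0739 * log10(111.4) + 1.9842), tolerance = 1e-12)
})

test_that("linear prediction matches direct evaluation and converts to metres", {
  est <- predict_tbl(builtin_models()$A60, 110.84)
  expect_equal(unclass(est), 100.72 * 110.84 + 436.24, tolerance = 1e-12)
  expect_equal(tbl_m(est), 11.6)
  expect_error(predict_tbl(builtin_models()$A60, 0), "width")
  expect_error(predict_tbl(builtin_models()$C, -5), "width")
})

test_that("prediction is strictly increasing and power-law scaling holds", {
  w <- seq(10, 200, by = 5)
  for (m in builtin_models()) {
    y <- unclass(predict_tbl(m, w))
    expect_true(all(diff(y) > 0), info = m$model_id)
  }
  cm <- builtin_models()$C
  for (c0 in c(1.5, 2, 7)) {
    ratio <- unclass(predict_tbl(cm, c0 * 50)) / unclass(predict_tbl(cm, 50))
    expect_equal(ratio, c0^cm$slope, tolerance = 1e-12)
  }
})

test_that("inverse_width is the exact algebraic inverse", {
  bm <- builtin_models()
  expect_equal(inverse_width(bm$A60, 436.24 + 100.72), 1.0, tolerance = 1e-12)
  expect_equal(inverse_width(bm$C, 15222), 111.4, tolerance = 0.5)
  expect_error(inverse_width(bm$A65, 390), "intercept")
  for (m in bm) {
    for (y in c(1500, 5000, 15000)) {
      w <- inverse_width(m, y)
      expect_equal(unclass(predict_tbl(m, w)), y, tolerance = 1e-9 * y)
    }
  }
})

test_that("OLS fitting recovers exact and noisy generating models", {
  exact <- comparative_dataset(c("a", "b", "c"), c(10, 20, 30),
                               c(1000, 2000, 3000))
  # exact collinearity: lm warns about the perfect fit, which is the point
  m <- suppressWarnings(fit_allometry(exact, "LINEAR"))
  expect_equal(m$slope, 100, tolerance = 1e-9)
  expect_equal(m$intercept, 0, tolerance = 1e-6)
  expect_equal(m$r2, 1, tolerance = 1e-12)

  ds <- sim_allometric(n = 21, slope = 1.0739, intercept = 1.9842,
                       noise_sd = 0.02, seed = 421)
  fm <- fit_allometry(ds, "LOG10LOG10", "prW")
  expect_lt(abs(fm$slope - 1.0739), 0.05)
  expect_lt(fm$p_slope, 0.05)
  expect_gt(fm$r2, 0.95)

  degen <- comparative_dataset(c("a", "b", "c"), c(10, 10, 10),
                               c(1000, 2000, 3000))
  expect_error(fit_allometry(degen, "LINEAR"), "degenerate")
  expect_error(fit_allometry(exact[1:2, ], "LINEAR"), "n >= 3")
})

test_that("prediction intervals degenerate on collinear data and cover ~95%", {
  exact <- sim_allometric(n = 10, noise_sd = 0, seed = 3)
  fm0 <- suppressWarnings(fit_allometry(exact, "LOG10LOG10", "prW"))
  pi0 <- prediction_interval(fm0, 50, 0.95)
  expect_lt(pi0["upper"] / pi0["lower"] - 1, 1e-6)

  # coverage: fresh points from the generating model vs the fitted interval
  set.seed(99)
  ds <- sim_allometric(n = 21, noise_sd = 0.05, seed = 17)
  fm <- fit_allometry(ds, "LOG10LOG10", "prW")
  n_rep <- 1000
  w <- 10^runif(n_rep, log10(10), log10(110))
  y <- 10^(1.0739 * log10(w) + 1.9842 + rnorm(n_rep, 0, 0.05))
  inside <- vapply(seq_len(n_rep), function(i) {
    pi <- prediction_interval(fm, w[i], 0.95)
    y[i] >= pi["lower"] && y[i] <= pi["upper"]
  }, TRUE)
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.99)

  expect_error(prediction_interval(fm, 50, 1.2), "level")
  expect_error(prediction_interval(builtin_models()$C, 50, 0.95), "FITTED")
})

test_that("models and comparative data serialize and read back", {
  p <- tempfile(fileext = ".json")
  write_model_json(builtin_models()$C, p)
  j <- jsonlite::fromJSON(p)
  expect_equal(j$slope, 1.0739)
  expect_equal(j$form, "LOG10LOG10")

  ds <- sim_allometric(n = 5, seed = 2)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(ds)[c("taxon", "width_mm", "tbl_mm")],
                   csv, row.names = FALSE)
  back <- read_comparative_csv(csv)
  expect_equal(back$width_mm, ds$width_mm, tolerance = 1e-9)
})
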