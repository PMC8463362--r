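test_that("cta_index matches hand arithmetic and rejects bad pairs", {
  expect_equal(cta_index(100, 100), 0)
  expect_equal(cta_index(60, 180), -0.5)
  expect_equal(cta_index(90, 310), -0.55)
  expect_error(cta_index(-10, 5), class = "perv_metric_error")
  expect_error(cta_index(5, -5), class = "perv_metric_error")
})

test_that("delta_attenuation and void_fraction match their definitions", {
  expect_equal(delta_attenuation(120, 50), 70)
  expect_equal(delta_attenuation(50, 50), 0)
  expect_equal(delta_attenuation(45, 50), -5)
  expect_equal(void_fraction(70, 280), 0.25)
  expect_equal(void_fraction(0, 280), 0)
  expect_error(void_fraction(10, 0), class = "perv_metric_error")
  expect_error(void_fraction(10, -5), class = "perv_metric_error")
})

test_that("compute_result fills every field and flags negative uptake", {
  r <- compute_result(list(cta_t = 112.5, cta_c = 300, ncct_t = 55,
                           ncct_c = 45))
  expect_equal(r$delta_t, 57.5)
  expect_equal(r$delta_c, 255)
  expect_equal(r$void_fraction, 57.5 / 255)
  expect_equal(r$cta_index, (112.5 - 300) / (112.5 + 300))
  expect_length(r$flags, 0)

  r2 <- compute_result(list(cta_t = 50, cta_c = 300, ncct_t = 55,
                            ncct_c = 45))
  expect_true("negative_uptake" %in% r2$flags)

  # degenerate: all four equal -> delta_c = 0 error path
  expect_error(compute_result(list(cta_t = 80, cta_c = 80, ncct_t = 80,
                                   ncct_c = 80)),
               class = "perv_metric_error")
  # missing sample named in the error
  expect_error(compute_result(list(cta_t = 1, cta_c = 2, ncct_t = 3)),
               "NCCT, C", class = "perv_metric_error")
})

test_that("metric chain agrees with the independent arithmetic oracle", {
  set.seed(41)
  for (i in seq_len(1000)) {
    hu <- runif(4, 10, 400)
    o <- oracle_metrics(hu[1], hu[2], hu[3], hu[4])
    if (o$delta_c <= 0) next
    r <- compute_result(list(cta_t = hu[1], cta_c = hu[2],
                             ncct_t = hu[3], ncct_c = hu[4]))
    expect_equal(r$delta_t, o$delta_t, tolerance = 1e-12)
    expect_equal(r$void_fraction, o$void_fraction, tolerance = 1e-12)
    expect_equal(r$cta_index, o$cta_index, tolerance = 1e-12)
  }
})

test_that("cta_index properties: antisymmetry, scale invariance, bounds", {
  set.seed(42)
  a <- runif(1000, 1, 500)
  b <- runif(1000, 1, 500)
  k <- runif(1000, 0.1, 10)
  for (i in seq_len(1000)) {
    v <- cta_index(a[i], b[i])
    expect_equal(v, -cta_index(b[i], a[i]), tolerance = 1e-12)
    expect_equal(v, cta_index(k[i] * a[i], k[i] * b[i]), tolerance = 1e-12)
    expect_lt(abs(v), 1)
  }
})

test_that("void fraction is invariant to a constant HU offset at one site", {
  set.seed(43)
  for (i in seq_len(50)) {
    hu <- c(runif(2, 100, 300), runif(2, 40, 90))
    off <- runif(1, -30, 30)
    r1 <- compute_result(list(cta_t = hu[1], cta_c = hu[2] + 100,
                              ncct_t = hu[3], ncct_c = hu[4]))
    r2 <- compute_result(list(cta_t = hu[1] + off, cta_c = hu[2] + 100,
                              ncct_t = hu[3] + off, ncct_c = hu[4]))
    expect_equal(r1$void_fraction, r2$void_fraction, tolerance = 1e-12)
  }
})
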