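test_that("ordinary kriging is exact at data points with zero nugget", {
  m <- variogram_model("exp", 1, 8)
  set.seed(4)
  co <- matrix(runif(15) * 20, 5, 3)
  v <- rnorm(5)
  k <- ordinary_kriging(co, v, m, co[3, ])
  expect_equal(k$prediction, v[3], tolerance = 1e-8)
  expect_lt(abs(k$variance), 1e-8)
  expect_equal(sum(k$weights), 1, tolerance = 1e-10)
})

test_that("single observation: unit weight, variance 2*gamma(d)", {
  m <- variogram_model("sph", 2, 10)
  k <- ordinary_kriging(matrix(c(0, 0, 0), 1), 7, m, c(3, 4, 0))
  expect_equal(k$weights, 1)
  expect_equal(k$prediction, 7)
  # the 1-point system forces mu = gamma(d); the prediction error variance is
  # E[(Z0 - Z1)^2] = 2 gamma(d) by the definition of the variogram
  expect_equal(k$lagrange, model_semivariance(m, 5))
  expect_equal(k$variance, 2 * model_semivariance(m, 5))
})

test_that("symmetric configurations give equal weights", {
  m <- variogram_model("exp", 1, 5)
  sq <- cbind(c(0, 0, 10, 10), c(0, 10, 0, 10))
  k <- ordinary_kriging(sq, c(1, 2, 3, 4), m, c(5, 5))
  expect_equal(k$weights, rep(0.25, 4), tolerance = 1e-10)
  expect_equal(k$prediction, 2.5, tolerance = 1e-10)
})

test_that("pure nugget kriging returns the mean with variance c0(1 + 1/N)", {
  c0 <- 1.7
  m <- variogram_model("exp", 1e-12, 1, nugget = c0)
  set.seed(5)
  for (n in c(2, 6, 10)) {
    co <- matrix(runif(3 * n) * 30, n, 3)
    v <- rnorm(n)
    k <- ordinary_kriging(co, v, m, c(15, 15, 15))
    expect_equal(k$prediction, mean(v), tolerance = 1e-6)
    expect_equal(k$variance, c0 * (1 + 1 / n), tolerance = 1e-5)
  }
})

test_that("solver matches the brute-force constrained-minimization oracle", {
  set.seed(6)
  models <- list(
    variogram_model("exp", 1, 8),
    variogram_model("sph", 0.6, 15, nugget = 0.3),
    variogram_model(c("exp", "sph"), c(0.4, 0.8), c(3, 18))
  )
  for (m in models) for (n in c(4, 8, 12)) {
    co <- matrix(runif(3 * n) * 25, n, 3)
    v <- rnorm(n)
    tgt <- runif(3) * 25
    k <- ordinary_kriging(co, v, m, tgt)
    o <- ok_bruteforce(co, v, m, tgt)
    expect_equal(k$prediction, o$prediction, tolerance = 1e-6)
    expect_equal(k$variance, o$variance, tolerance = 1e-6)
    expect_equal(sum(k$weights), 1, tolerance = 1e-10)
    expect_gte(k$variance, -1e-9)
  }
})

test_that("duplicate observations are refused with advice", {
  m <- variogram_model("exp", 1, 8)
  co <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(ordinary_kriging(co, 1:3, m, c(2, 2, 2)), "deduplicate")
})

test_that("two-layer grids enumerate, centre and shift correctly", {
  g1 <- two_layer_grid(c(10, 10, 32), n = 1, spacing = 8, layer_z = c(0, 65))
  expect_equal(nrow(g1$points), 2)
  expect_equal(g1$points[, "z"], c(0, 65), ignore_attr = TRUE)
  expect_equal(g1$points[, "row"], c(10, 10), ignore_attr = TRUE)

  g3 <- two_layer_grid(c(10, 10, 32), n = 3, spacing = 2, layer_z = c(0, 65))
  expect_equal(nrow(g3$points), 18)
  expect_setequal(unique(g3$points[, "row"]), c(8, 10, 12))
  expect_setequal(unique(g3$points[, "col"]), c(8, 10, 12))
  expect_false(g3$shifted)

  # corner target: grid shifted inside the extent and flagged
  gs <- two_layer_grid(c(1, 1, 32), n = 9, spacing = 8, layer_z = c(0, 65),
                       extent = c(100, 100))
  expect_true(gs$shifted)
  expect_true(all(gs$points[, 1:2] >= 1 & gs$points[, 1:2] <= 100))
  expect_error(two_layer_grid(c(1, 1, 32), n = 9, spacing = 20,
                              layer_z = c(0, 65), extent = c(100, 100)),
               "larger than the layer")
  expect_error(two_layer_grid(c(1, 1, 32), n = 4, spacing = 2,
                              layer_z = c(0, 65)), "odd")
})

test_that("variance profile is flat for pure nugget and U-shaped for structure", {
  c0 <- 0.9
  nug <- variogram_model("exp", 1e-12, 1, nugget = c0)
  prof <- kriging_variance_profile(nug, n = 9, spacings = 1:20)
  expect_equal(prof$variance, rep(c0 * (1 + 1 / 162), 20), tolerance = 1e-4)
  expect_equal(optimize_grid_spacing(prof), 1L)  # flat ties to smallest

  ex <- kriging_variance_profile(variogram_model("exp", 1, 25), spacings = 1:20)
  expect_lt(min(ex$variance), ex$variance[1])
  expect_lt(min(ex$variance), ex$variance[20])

  one <- kriging_variance_profile(variogram_model("exp", 1, 25), spacings = 7L)
  expect_equal(nrow(one), 1L)
  expect_error(kriging_variance_profile(variogram_model("exp", 1, 25),
                                        target_offset = 0), "strictly between")
})

test_that("optimizer returns the argmin with deterministic tie-break", {
  prof <- tibble::tibble(spacing = 1:5, variance = c(5, 3, 1, 3, 5))
  expect_equal(optimize_grid_spacing(prof), 3L)
  flat <- tibble::tibble(spacing = 2:6, variance = rep(1, 5))
  expect_equal(optimize_grid_spacing(flat), 2L)
  expect_error(optimize_grid_spacing(flat[0, ]), "empty")
})
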