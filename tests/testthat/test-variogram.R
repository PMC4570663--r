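test_that("Matheron estimator matches hand computation", {
  # two points at distance 1 with values 0 and 2: gamma = (2-0)^2 / (2*1) = 2
  ev <- empirical_variogram(rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 2))
  expect_equal(ev$gamma, 2)
  expect_equal(ev$lag, 0.5)
  expect_equal(ev$n_pairs, 1L)

  # constant values: zero semivariance in every bin
  set.seed(1)
  co <- matrix(runif(30) * 20, 10, 3)
  ev0 <- empirical_variogram(co, rep(3, 10), bin_width = 5, max_lag = 40)
  expect_true(all(ev0$gamma == 0))

  # three collinear points, hand-binned
  ev3 <- empirical_variogram(cbind(c(0, 1, 2), 0, 0), c(0, 1, 3), bin_width = 1)
  # pairs: d=1 (0,1):1; d=1 (1,3):4; d=2 (0,3):9
  expect_equal(ev3$gamma, c((1 + 4) / (2 * 2), 9 / 2))
  expect_equal(ev3$n_pairs, c(2L, 1L))
})

test_that("white noise has a flat variogram at its variance", {
  set.seed(3)
  v <- rnorm(64 * 64)
  co <- as.matrix(expand.grid(1:64, 1:64))
  ev <- empirical_variogram(co, v, bin_width = 1, max_lag = 10,
                            subsample = c(3000, 1))
  expect_true(all(abs(ev$gamma - 1) < 0.1))
})

test_that("model semivariance matches closed forms and is monotone bounded", {
  sph <- variogram_model("spherical", 0.8, 10, nugget = 0.2)
  expect_equal(model_semivariance(sph, 0), 0)
  expect_equal(model_semivariance(sph, 10), 1)      # total sill at the range
  expect_equal(model_semivariance(sph, 5), 0.2 + 0.8 * (0.75 - 0.0625))
  expect_equal(model_semivariance(sph, 50), 1)

  ex <- variogram_model("exp", 1, 8)
  expect_equal(model_semivariance(ex, 8), 1 - exp(-1))
  expect_error(model_semivariance(ex, -1), "non-negative")

  # nested model: non-decreasing, bounded by total sill
  nest <- variogram_model(c("exp", "sph"), c(0.5, 0.7), c(4, 20), nugget = 0.1)
  h <- seq(0, 60, by = 0.25)
  g <- model_semivariance(nest, h)
  expect_true(all(diff(g) >= -1e-12))
  expect_true(all(g <= nest$total_sill + 1e-12))
})

test_that("WLS fit recovers noiseless parameters and beats a grid-search oracle", {
  truth <- variogram_model("exp", 1, 8)
  lags <- seq(0.5, 40.5, by = 1)
  emp <- tibble::tibble(lag = lags, gamma = model_semivariance(truth, lags),
                        n_pairs = rep(100L, length(lags)))
  class(emp) <- c("empirical_variogram", class(emp))
  fit <- fit_variogram(emp, "exp", nugget = FALSE)
  expect_equal(fit$model$components$sill, 1, tolerance = 1e-4)
  expect_equal(fit$model$components$range, 8, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)

  # noisy case: never worse than a dense parameter grid search
  set.seed(8)
  empn <- emp
  empn$gamma <- pmax(empn$gamma + rnorm(nrow(emp), 0, 0.05), 0)
  fitn <- fit_variogram(empn, "exp", nugget = FALSE)
  grid <- expand.grid(sill = seq(0.5, 1.6, by = 0.02),
                      range = seq(2, 20, by = 0.2))
  rss_grid <- mapply(function(s, r) {
    sum(empn$n_pairs * (empn$gamma - s * (1 - exp(-empn$lag / r)))^2)
  }, grid$sill, grid$range)
  expect_lte(fitn$rss, min(rss_grid) + 1e-8)
})

test_that("under-determined fits are refused", {
  emp <- tibble::tibble(lag = c(0.5, 1.5, 2.5), gamma = c(0.2, 0.5, 0.9),
                        n_pairs = c(5L, 5L, 5L))
  expect_error(fit_variogram(emp, c("sph", "sph"), nugget = FALSE),
               "under-determined")
})

test_that("AIC selection penalizes parameters and returns a full table", {
  truth <- variogram_model("sph", 1, 12)
  lags <- seq(0.5, 30.5, by = 1)
  emp <- tibble::tibble(lag = lags, gamma = model_semivariance(truth, lags),
                        n_pairs = rep(50L, length(lags)))
  class(emp) <- c("empirical_variogram", class(emp))

  sel <- aic_select(emp, list(one = list(families = "sph", nugget = FALSE)))
  expect_equal(sel$selected, "one")

  # equal fit, different p: fewer parameters must win
  n <- length(lags)
  aic2 <- n * log(0.5 / n) + 2 * 2
  aic4 <- n * log(0.5 / n) + 2 * 4
  expect_lt(aic2, aic4)

  sel_full <- aic_select(emp)
  expect_s3_class(sel_full$table, "tbl_df")
  expect_true(all(c("candidate", "p", "rss", "aic") %in% names(sel_full$table)))
  # noiseless spherical data: a spherical-family candidate must win
  expect_match(sel_full$selected, "sph")
})

test_that("tidy/glance methods expose model structure", {
  m <- variogram_model(c("exp", "sph"), c(0.5, 0.7), c(4, 20), nugget = 0.1)
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_equal(td$family, c("nugget", "exp", "sph"))
  expect_equal(sum(td$sill), m$total_sill)
})
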