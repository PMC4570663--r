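test_that("field simulation is deterministic and degenerates correctly", {
  m <- variogram_model("exp", 1, 8)
  f1 <- simulate_gaussian_field(m, c(32, 32), seed = 2)
  f2 <- simulate_gaussian_field(m, c(32, 32), seed = 2)
  expect_identical(f1, f2)
  expect_false(identical(f1, simulate_gaussian_field(m, c(32, 32), seed = 3)))

  z <- simulate_gaussian_field(variogram_model("exp", 1e-300, 1), c(8, 8), 1)
  expect_true(all(abs(z) < 1e-100))  # zero total sill: constant zero field

  f3 <- simulate_gaussian_field(m, c(8, 8, 8), seed = 4)
  expect_equal(dim(f3), c(8, 8, 8))
})

test_that("simulated fields reproduce their generating variogram", {
  m <- variogram_model("exp", 1, 8)
  co <- as.matrix(expand.grid(1:128, 1:128))
  devs <- matrix(NA_real_, 8, 10)
  for (s in 1:8) {
    f <- simulate_gaussian_field(m, c(128, 128), seed = 100 + s)
    ev <- empirical_variogram(co, as.vector(f), bin_width = 2, max_lag = 20,
                              subsample = c(2500, s))
    devs[s, ] <- ev$gamma - model_semivariance(m, ev$lag)
  }
  # average over 8 seeds within +/-0.15 of the model curve at lags 2..20
  expect_true(all(abs(colMeans(devs)) < 0.15))
})

test_that("layered fields carry genuine between-layer correlation", {
  m <- variogram_model("exp", 1, 20)
  cors <- sapply(1:6, function(s) {
    lf <- simulate_layered_field(m, 72, 72, c(0, 15, 65), seed = 200 + s)
    c(c12 = cov(as.vector(lf[, , 1]), as.vector(lf[, , 2])),
      c13 = cov(as.vector(lf[, , 1]), as.vector(lf[, , 3])))
  })
  model_c12 <- 1 - model_semivariance(m, 15)
  expect_equal(mean(cors["c12", ]), model_c12, tolerance = 0.35)
  # nearby layers much more correlated than distant ones
  expect_gt(mean(cors["c12", ]), mean(cors["c13", ]) + 0.1)
  # determinism
  expect_identical(simulate_layered_field(m, 16, 16, c(0, 5), seed = 1),
                   simulate_layered_field(m, 16, 16, c(0, 5), seed = 1))
})

test_that("soil volume realizes requested phase fractions", {
  ph <- data.frame(proportion = c(0.3, 0.6, 0.1), mean = c(60, 140, 230),
                   sd = c(5, 5, 5))
  vol <- simulate_soil_volume(c(64, 64, 64), phases = ph,
                              correlation_range = 3, seed = 6)
  fr <- tabulate(attr(vol, "phase"), 3) / length(attr(vol, "phase"))
  expect_true(all(abs(fr - c(0.3, 0.6, 0.1)) < 0.02))
  expect_true(all(unclass(vol) >= 0 & unclass(vol) <= 255))
  expect_identical(unclass(simulate_soil_volume(c(16, 16, 16), seed = 7))[, , ],
                   unclass(simulate_soil_volume(c(16, 16, 16), seed = 7))[, , ])
  ph_bad <- ph; ph_bad$proportion <- c(0.5, 0.6, 0.1)
  expect_error(simulate_soil_volume(c(8, 8, 8), phases = ph_bad), "sum to 1")

  one <- simulate_soil_volume(c(8, 8, 8),
                              phases = data.frame(proportion = 1, mean = 99,
                                                  sd = 0), seed = 8)
  expect_true(all(unclass(one) == 99))
})

test_that("trend_law is a faithful step lookup", {
  expect_equal(trend_law(c(10, 200), numeric(0), 4), c(4, 4))
  expect_equal(trend_law(c(99, 100), 100, c(1, 5)), c(1, 5))
  set.seed(9)
  g <- sample(0:255, 500, replace = TRUE)
  th <- c(50, 120, 210); lv <- c(1, 3, 2, 7)
  loop <- vapply(g, function(x) lv[sum(x >= th) + 1], 0)
  expect_equal(trend_law(g, th, lv), loop)
  expect_error(trend_law(1, c(5, 2), c(1, 2, 3)), "increasing")
  expect_error(trend_law(1, 5, c(1, 2, 3)), "one longer")
})

test_that("element maps equal the trend exactly when residual and noise vanish", {
  vol <- make_test_volume(c(24, 24, 40))
  truth <- list(C = list(thresholds = c(100, 200), levels = c(8, 3.5, 1),
                         residual = variogram_model("exp", 1e-13, 5),
                         noise_sd = 0))
  ls <- simulate_element_maps(vol, c(5, 20), truth, seed = 10)
  g <- unclass(vol)[, , 5]
  expect_equal(unclass(ls$faces[[1]]$maps$C)[, ],
               trend_law(g, c(100, 200), c(8, 3.5, 1)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(simulate_element_maps(vol, c(0, 5), truth, seed = 1), "outside")
})

test_that("full study generation is seed-stable and carries its truth", {
  s1 <- synthetic_study(dim = c(32, 32, 80), z_faces = c(3, 18, 68),
                        seed = 11)
  s2 <- synthetic_study(dim = c(32, 32, 80), z_faces = c(3, 18, 68),
                        seed = 11)
  expect_identical(unclass(s1$volume)[, , ], unclass(s2$volume)[, , ])
  expect_identical(lapply(s1$layers$faces, function(f) unclass(f$maps$C)[, ]),
                   lapply(s2$layers$faces, function(f) unclass(f$maps$C)[, ]))
  expect_named(s1$truth, c("C", "Si", "Fe", "O"))
  # default geometry: 10 faces, every outer pair of a triple 65 apart
  z <- default_face_geometry()
  expect_length(z, 10)
  expect_true(all(z[seq(3, 10)] - z[seq(1, 8)] == 65))
})

test_that("study round-trips to disk as plain text + image formats", {
  st <- synthetic_study(dim = c(16, 16, 40), z_faces = c(2, 10, 30),
                        truth = default_truth()["Fe"], seed = 12)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  vol <- read_volume(file.path(dir, "volume", "*.tif"))
  expect_identical(unclass(vol)[, , ], unclass(st$volume)[, , ])
  m <- read_element_map(file.path(dir, "face01_Fe.csv"), "Fe")
  expect_equal(unclass(m)[, ], unclass(st$layers$faces[[1]]$maps$Fe)[, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 12)
})

test_that("extract_tilted_slices returns planes with their ground truth", {
  vol <- make_test_volume(c(32, 32, 32))
  os <- list(plane_orientation(0, 0, 10, c(16, 16)),
             plane_orientation(0.02, 0.01, 16, c(16, 16)))
  ext <- extract_tilted_slices(vol, os)
  expect_identical(ext$planes[[1]], unclass(vol)[, , 10])
  expect_identical(ext$orientations, os)
  bad <- list(plane_orientation(0.5, 0, 1, c(16, 16)))
  expect_error(extract_tilted_slices(vol, bad), "admissible")
})
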