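test_that("reconstruct_plane recovers the flat slice and matches a per-pixel oracle", {
  vol <- make_test_volume(c(32, 32, 40))
  # a = b = 0: the un-rotated plane is the slice itself, bit-exact
  expect_identical(reconstruct_plane(vol, 0, 0, 17), unclass(vol)[, , 17])

  # tilted plane against a direct per-pixel loop
  a <- 0.05; b <- -0.02; k0 <- 20; center <- c(16, 16); shape <- c(32L, 32L)
  got <- reconstruct_plane(vol, a, b, k0, center, shape)
  manual <- matrix(0L, 32, 32)
  for (j in 1:32) for (i in 1:32) {
    z <- a * (i - center[2]) + b * (j - center[1])
    k <- sign(z) * floor(abs(z) + 0.5) + k0
    manual[j, i] <- unclass(vol)[j, i, k]
  }
  expect_identical(got, manual)
  # max |dz| over a window spanning +/-16 columns at a = 0.05
  expect_equal(max(abs(soilrtk:::plane_k_offsets(0.05, 0, shape, center))), 1)
  expect_equal(max(abs(soilrtk:::plane_k_offsets(0.05, 0, c(32L, 801L), c(16, 401)))),
               round(0.05 * 400))
})

test_that("reconstruct_plane reports the admissible k0 range on violation", {
  vol <- make_test_volume(c(32, 32, 10))
  expect_error(reconstruct_plane(vol, 0.2, 0, 1, c(16, 16)), "admissible k0 range")
  expect_error(reconstruct_plane(vol, 0, 0, 11), "admissible k0 range")
})

test_that("pearson_r matches hand computation and rejects constants", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 2, 5)), 3 / sqrt(12))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(pearson_r(1:2, 1:3), "equal length")
  mask <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(pearson_r(c(1, 2, 3, 99), c(2, 2, 5, -99), mask), 3 / sqrt(12))
})

test_that("cumulative correlation sums absolute per-element correlations", {
  plane <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3)
  m1 <- element_map(plane, "A")            # r = 1
  m2 <- element_map(max(plane) - plane, "B")  # r = -1
  cc <- cumulative_correlation(plane, list(m1, m2))
  expect_equal(cc$cumulative, 2)
  expect_equal(unname(cc$per_element), c(1, -1))
  # invariant to negating any map (absolute values)
  m2b <- element_map(2 * mean(plane) - (max(plane) - plane) + 20, "B")
  expect_equal(cumulative_correlation(plane, list(m1, m2b))$cumulative, 2)
})

test_that("FFT offset scoring equals direct correlation at every offset", {
  set.seed(7)
  plane <- matrix(rnorm(26 * 24), 26, 24)
  mp <- matrix(abs(rnorm(18 * 16)), 18, 16)
  mp[3, 4] <- NA  # masked pixel
  m <- element_map(mp, "C")
  kern <- soilrtk:::offset_kernels(list(C = m), c(18L, 16L), c(27L, 25L))
  sc <- soilrtk:::score_all_offsets(plane, kern, c(18L, 16L), c(27L, 25L))
  msk <- !is.na(mp)
  for (or in c(1, 4, 9)) for (oc in c(1, 5, 9)) {
    win <- plane[or + 0:17, oc + 0:15]
    expect_equal(sc[or, oc], abs(cor(win[msk], mp[msk])), tolerance = 1e-10)
  }
})

test_that("align_face recovers known extractions exactly (noise-free)", {
  vol <- make_test_volume(c(48, 48, 48), seed = 5)
  truth <- plane_orientation(0.02, -0.015, 25, c(24, 24))
  ext <- extract_tilted_slices(vol, list(truth), shape = c(48, 48))
  win <- crop_region(ext$planes[[1]], c(6, 9), c(36, 36))
  maps <- identity_maps(win)
  srch <- align_search(a_range = c(-0.03, 0.03), b_range = c(-0.03, 0.03),
                       step = 0.005, k0_range = c(21, 29),
                       plane_shape = c(48, 48), crop_shape = c(36, 36))
  res <- align_face(vol, maps, srch)
  expect_equal(res$orientation$a, 0.02)
  expect_equal(res$orientation$b, -0.015)
  expect_equal(res$orientation$k0, 25)
  expect_equal(res$orientation$crop_offset, c(6L, 9L))
  expect_equal(res$cumulative_corr, 1)

  # flat extraction at k = 27, offset (1,1)
  maps2 <- identity_maps(crop_region(unclass(vol)[, , 27], c(1, 1), c(36, 36)))
  res2 <- align_face(vol, maps2, srch)
  expect_equal(c(res2$orientation$a, res2$orientation$b), c(0, 0))
  expect_equal(res2$orientation$k0, 27)
  expect_equal(res2$orientation$crop_offset, c(1L, 1L))
})

test_that("coarse-to-fine search equals the plain exhaustive loop oracle", {
  vol <- make_test_volume(c(40, 40, 40), seed = 9)
  truth <- plane_orientation(0.01, 0.02, 20, c(16, 16))
  pl <- reconstruct_plane(vol, truth$a, truth$b, truth$k0, c(16, 16), c(32, 32))
  win <- crop_region(pl, c(3, 5), c(24, 24))
  maps <- identity_maps(win, noise_sd = 3, seed = 11)  # mild noise
  a_vals <- seq(-0.02, 0.02, by = 0.005)
  srch <- align_search(a_range = c(-0.02, 0.02), b_range = c(-0.02, 0.02),
                       step = 0.005, k0_range = c(18, 22),
                       plane_shape = c(32, 32), crop_shape = c(24, 24))
  res_c2f <- align_face(vol, maps, srch)
  srch$exhaustive <- TRUE
  res_exh <- align_face(vol, maps, srch)
  oracle <- align_oracle(vol, maps, a_vals, a_vals, 18:22, c(32L, 32L), c(24L, 24L))

  for (res in list(res_c2f, res_exh)) {
    expect_equal(res$orientation$a, oracle$a)
    expect_equal(res$orientation$b, oracle$b)
    expect_equal(res$orientation$k0, oracle$k0)
    expect_equal(res$orientation$crop_offset, oracle$off)
  }
  # reported per-element correlations re-computed independently match closely
  win_best <- res_exh$reconstructed_plane
  r_indep <- cor(as.vector(win_best), as.vector(unclass(maps$G)))
  expect_equal(unname(res_exh$per_element_corr["G"]), r_indep, tolerance = 1e-12)
})

test_that("alignment ties break to smaller |a|+|b| then smaller k0", {
  # constant-z volume: every plane is identical, all scores tie exactly
  slice <- matrix(rep(0:15, 16), 16, 16)
  vol <- grayscale_volume(array(slice, dim = c(16, 16, 8)))
  maps <- identity_maps(crop_region(slice, c(1, 1), c(12, 12)))
  srch <- align_search(a_range = c(-0.01, 0.01), b_range = c(-0.01, 0.01),
                       step = 0.01, k0_range = c(2, 6),
                       plane_shape = c(16, 16), crop_shape = c(12, 12),
                       exhaustive = TRUE)
  res <- align_face(vol, maps, srch)
  expect_equal(c(res$orientation$a, res$orientation$b), c(0, 0))
  expect_equal(res$orientation$k0, 2)
  expect_equal(res$orientation$crop_offset, c(1L, 1L))
})
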