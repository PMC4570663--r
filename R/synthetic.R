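# ---- Gaussian random field simulation ---------------------------------------

# covariance of the continuous (non-nugget) part of a variogram model
model_covariance <- function(model, h) {
  cont_sill <- sum(model$components$sill)
  cont_gamma <- model_semivariance(
    variogram_model(model$components$family, model$components$sill,
                    model$components$range, nugget = 0), h)
  cont_sill - cont_gamma
}

embed_dims <- function(n, ranges, pad_mult = 1) {
  pad <- pmin(ceiling(6 * max(ranges) * pad_mult), n)
  vapply(n + pad, function(m) stats::nextn(m, c(2, 3, 5)), 0L)
}

# torus minimal-image distances along one embedded axis
torus_d <- function(m) {
  l <- 0:(m - 1)
  pmin(l, m - l)
}

#' Simulate a Gaussian random field with a given variogram
#'
#' Generates a zero-mean stationary Gaussian field on a regular 2D or 3D grid
#' (unit spacing) whose theoretical variogram equals the supplied model.
#' The continuous part is simulated by circulant embedding (FFT); the nugget,
#' if any, is added as independent noise.  For very small problems
#' (`<= 4096` points) an exact covariance-factorization fallback is used when
#' the embedding is not positive semi-definite.
#'
#' @param model A [variogram_model()].
#' @param dim Grid dimensions, length 2 or 3.
#' @param seed Integer seed; identical seeds give identical fields.
#' @return Numeric array of shape `dim`.
#' @export
simulate_gaussian_field <- function(model, dim, seed) {
  dim <- as.integer(dim)
  stopifnot(length(dim) %in% 2:3, all(dim >= 1))
  if (model$total_sill <= 0) return(array(0, dim = dim))
  if (sum(model$components$sill) <= 1e-15) {
    # pure nugget: i.i.d. noise
    return(withr::with_seed(as.integer(seed),
      array(rnorm(prod(dim), 0, sqrt(model$nugget)), dim = dim)))
  }
  withr::with_seed(as.integer(seed), {
    field <- tryCatch(
      circulant_field(model, dim),
      error = function(e) {
        if (prod(dim) <= 4096L) exact_field(model, dim) else stop(e)
      }
    )
    if (model$nugget > 0) {
      field <- field + array(rnorm(prod(dim), 0, sqrt(model$nugget)), dim = dim)
    }
    field
  })
}

circulant_field <- function(model, dim, pad_mult = 1) {
  m <- embed_dims(dim, model$components$range, pad_mult)
  ds <- lapply(m, torus_d)
  h2 <- ds[[1]]^2
  for (ax in 2:length(m)) {
    h2 <- outer(h2, ds[[ax]]^2, `+`)
  }
  K <- array(model_covariance(model, sqrt(h2)), dim = m)
  lam <- Re(fft(K))
  neg <- min(lam)
  if (neg < -1e-6 * max(lam)) {
    if (pad_mult < 4) return(circulant_field(model, dim, pad_mult * 2))
    stop("circulant embedding is not positive semi-definite", call. = FALSE)
  }
  lam[lam < 0] <- 0
  M <- prod(m)
  xi <- array(complex(real = rnorm(M), imaginary = rnorm(M)), dim = m)
  y <- fft(sqrt(lam) * xi, inverse = TRUE) / sqrt(M)
  idx <- lapply(dim, seq_len)
  do.call(`[`, c(list(Re(y)), idx, list(drop = FALSE)))
}

exact_field <- function(model, dim) {
  grids <- lapply(dim, seq_len)
  coords <- as.matrix(expand.grid(grids))
  C <- model_covariance(model, as.matrix(stats::dist(coords)))
  diag(C) <- diag(C) + 1e-10 * model$total_sill
  L <- chol(C)
  array(as.vector(t(L) %*% rnorm(nrow(coords))), dim = dim)
}

#' Simulate one 3D Gaussian field sampled on a set of parallel planes
#'
#' Generates the restriction of a single 3D stationary Gaussian field (with
#' the given variogram) to a set of z-slices, without simulating the full 3D
#' block: a multivariate circulant embedding in-plane carries the exact
#' between-slice cross-covariance, so residual fields on different faces are
#' physically consistent (values on nearby faces are correlated according to
#' the 3D model).
#'
#' @param model A [variogram_model()].
#' @param nrow,ncol In-plane grid size.
#' @param z_levels Numeric vector of slice positions (voxel units).
#' @param seed Integer seed.
#' @return A 3D array `nrow x ncol x length(z_levels)`.
#' @export
simulate_layered_field <- function(model, nrow, ncol, z_levels, seed) {
  q <- length(z_levels)
  stopifnot(q >= 1L)
  if (q == 1L) {
    f <- simulate_gaussian_field(model, c(nrow, ncol), seed)
    return(array(f, dim = c(nrow, ncol, 1L)))
  }
  if (sum(model$components$sill) <= 1e-15) {
    out <- withr::with_seed(as.integer(seed),
      array(rnorm(nrow * ncol * q, 0, sqrt(model$nugget)),
            dim = c(nrow, ncol, q)))
    return(out)
  }
  m <- embed_dims(c(nrow, ncol), model$components$range)
  M <- prod(m)
  h2 <- outer(torus_d(m[1])^2, torus_d(m[2])^2, `+`)
  dz <- abs(outer(z_levels, z_levels, `-`))
  udz <- sort(unique(as.vector(dz)))
  lam <- matrix(0, M, length(udz))  # spectra of each inter-layer kernel
  for (i in seq_along(udz)) {
    K <- matrix(model_covariance(model, sqrt(h2 + udz[i]^2)), m[1], m[2])
    lam[, i] <- as.vector(Re(fft(K)))
  }
  dz_idx <- matrix(match(dz, udz), q, q)
  withr::with_seed(as.integer(seed), {
    xi_re <- matrix(rnorm(q * M), q, M)
    xi_im <- matrix(rnorm(q * M), q, M)
    w <- matrix(0i, q, M)
    for (f in seq_len(M)) {
      S <- matrix(lam[f, dz_idx], q, q)
      ev <- eigen(S, symmetric = TRUE)
      A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
      w[, f] <- A %*% complex(real = xi_re[, f], imaginary = xi_im[, f])
    }
    out <- array(0, dim = c(nrow, ncol, q))
    for (p in seq_len(q)) {
      y <- fft(matrix(w[p, ], m[1], m[2]), inverse = TRUE) / sqrt(M)
      out[, , p] <- Re(y)[seq_len(nrow), seq_len(ncol)]
    }
    if (model$nugget > 0) {
      out <- out + array(rnorm(length(out), 0, sqrt(model$nugget)), dim = dim(out))
    }
    out
  })
}

# ---- synthetic soil volume --------------------------------------------------

# separable circular Gaussian smoothing of white noise along every axis
smooth_noise <- function(dim, range, seed) {
  withr::with_seed(as.integer(seed), {
    x <- array(rnorm(prod(dim)), dim = dim)
    if (range <= 0) return(x)
    nd <- length(dim)
    for (ax in seq_len(nd)) {
      # kernel must fit the axis (circular convolution)
      half <- min(max(1L, ceiling(2 * range)), (dim[ax] - 1L) %/% 2L)
      kern <- stats::dnorm(seq(-half, half), sd = range)
      kern <- kern / sum(kern)
      perm <- c(ax, setdiff(seq_len(nd), ax))
      xp <- aperm(x, perm)
      d <- dim(xp)
      mat <- matrix(xp, d[1])
      sm <- stats::filter(mat, kern, method = "convolution",
                          sides = 2, circular = TRUE)
      x <- aperm(array(as.numeric(sm), d), order(perm))
    }
    x
  })
}

#' Simulate a phase-structured grayscale soil volume
#'
#' Thresholds a spatially correlated Gaussian field into material phases with
#' prescribed volume fractions (pore/resin, mineral matrix, Fe-rich grains in
#' the default), then draws voxel intensities from each phase's normal
#' distribution, clipped to 8-bit.
#'
#' @param dim Volume dimensions `(rows, cols, slices)`.
#' @param phases Data frame (or list coercible to one) with columns
#'   `proportion`, `mean`, `sd`; proportions must sum to 1.
#' @param correlation_range Smoothing length of the phase field in voxels.
#' @param seed Integer seed.
#' @param voxel_size_um Voxel size of the result.
#' @return A [grayscale_volume()] with attribute `phase` (integer array of
#'   phase labels).
#' @export
simulate_soil_volume <- function(dim, phases = default_phases(),
                                 correlation_range = 6, seed = 1,
                                 voxel_size_um = DEFAULT_VOXEL_UM) {
  phases <- as.data.frame(phases)
  stopifnot(all(c("proportion", "mean", "sd") %in% names(phases)))
  if (abs(sum(phases$proportion) - 1) > 1e-8) {
    stop("phase proportions must sum to 1", call. = FALSE)
  }
  field <- smooth_noise(dim, correlation_range, seed)
  cuts <- stats::quantile(field, cumsum(phases$proportion)[-nrow(phases)])
  phase <- array(findInterval(field, cuts) + 1L, dim = dim)
  gray <- withr::with_seed(as.integer(seed) + 1L, {
    g <- rnorm(prod(dim), mean = phases$mean[phase], sd = phases$sd[phase])
    pmin(pmax(round(g), 0), 255)
  })
  vol <- grayscale_volume(array(as.integer(gray), dim = dim), voxel_size_um)
  attr(vol, "phase") <- phase
  vol
}

#' Default material phases of the synthetic soil volume
#'
#' Dark resin-filled pore space, mid-gray mineral matrix and sparse bright
#' Fe-rich grains.
#'
#' @return Data frame with columns `phase`, `proportion`, `mean`, `sd`.
#' @export
default_phases <- function() {
  data.frame(
    phase = c("pore_resin", "mineral", "fe_rich"),
    proportion = c(0.35, 0.60, 0.05),
    mean = c(60, 140, 230),
    sd = c(12, 18, 10)
  )
}

#' Piecewise-constant trend of concentration on grayscale
#'
#' The step-function law linking material density (CT grayscale) to element
#' concentration; the same boundary convention as the regression tree: a
#' value equal to a threshold belongs to the right-hand level.
#'
#' @param gray Numeric vector/matrix of intensities.
#' @param thresholds Strictly increasing threshold vector (possibly empty).
#' @param levels Concentration levels, one more than `thresholds`.
#' @return Concentrations with the shape of `gray`.
#' @export
trend_law <- function(gray, thresholds, levels) {
  if (length(levels) != length(thresholds) + 1L) {
    stop("`levels` must be one longer than `thresholds`", call. = FALSE)
  }
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  out <- levels[findInterval(as.vector(gray), thresholds) + 1L]
  if (!is.null(dim(gray))) dim(out) <- dim(gray)
  out
}

#' Default ground-truth generating laws per element
#'
#' Step trends on grayscale plus an exponential residual model per element,
#' chosen to emulate the observed regimes: carbon concentrated in the
#' resin-filled pores, silicon and oxygen on the mineral matrix, iron sparse
#' and tied to the brightest voxels.
#'
#' @return Named list per element: `thresholds`, `levels`,
#'   `residual` ([variogram_model()]), `noise_sd`.
#' @export
default_truth <- function() {
  list(
    C = list(thresholds = c(100, 200), levels = c(8, 3.5, 1),
             residual = variogram_model("exp", 1.5, 20), noise_sd = 0.2),
    Si = list(thresholds = c(100, 200), levels = c(2, 14, 6),
              residual = variogram_model("exp", 5, 20), noise_sd = 0.35),
    Fe = list(thresholds = 200, levels = c(0.05, 5),
              residual = variogram_model("exp", 0.3, 20), noise_sd = 0.08),
    O = list(thresholds = c(100, 200), levels = c(2, 4.5, 3.5),
             residual = variogram_model("exp", 0.8, 20), noise_sd = 0.15)
  )
}

#' Simulate elemental maps on a set of faces
#'
#' For each element: concentration = step trend of the face's grayscale plus
#' one shared 3D correlated residual field sampled at the face planes (so
#' residuals on nearby faces are genuinely correlated — the signal kriging
#' exploits) plus i.i.d. measurement noise.  Optionally masks out a random
#' pixel fraction to mimic broken-slice regions.
#'
#' @param volume A [grayscale_volume()].
#' @param z_faces Slice indices of the (axis-aligned) faces.
#' @param truth Generating laws as in [default_truth()].
#' @param seed Integer seed.
#' @param mask_fraction Fraction of pixels masked out per face (default 0).
#' @return A [layer_set()] of [aligned_face()]s.
#' @export
simulate_element_maps <- function(volume, z_faces, truth = default_truth(),
                                  seed = 1, mask_fraction = 0) {
  d <- dim(volume)
  if (any(z_faces < 1L | z_faces > d[3])) {
    stop("face slice indices outside the volume", call. = FALSE)
  }
  els <- names(truth)
  resid <- list()
  for (i in seq_along(els)) {
    resid[[els[i]]] <- simulate_layered_field(
      truth[[els[i]]]$residual, d[1], d[2], z_faces,
      seed = as.integer(seed) + 100L * i
    )
  }
  faces <- vector("list", length(z_faces))
  for (fi in seq_along(z_faces)) {
    gray <- unclass(volume)[, , z_faces[fi]]
    mask <- NULL
    if (mask_fraction > 0) {
      mask <- withr::with_seed(as.integer(seed) + 7000L + fi, {
        matrix(runif(length(gray)) >= mask_fraction, d[1], d[2])
      })
    }
    maps <- list()
    for (i in seq_along(els)) {
      el <- els[i]
      tr <- truth[[el]]
      conc <- trend_law(gray, tr$thresholds, tr$levels) + resid[[el]][, , fi]
      if (tr$noise_sd > 0) {
        conc <- conc + withr::with_seed(
          as.integer(seed) + 100L * i + fi,
          matrix(rnorm(length(gray), 0, tr$noise_sd), d[1], d[2])
        )
      }
      conc <- pmax(conc, 0)  # X-ray counts are non-negative
      maps[[el]] <- element_map(conc, element = el,
                                pixel_size_um = attr(volume, "voxel_size_um"),
                                mask = mask)
    }
    faces[[fi]] <- aligned_face(gray, maps, z = z_faces[fi],
                                id = sprintf("face%02d", fi))
  }
  layer_set(faces)
}

#' Extract tilted staircase slices with known ground truth
#'
#' Test harness for the registration step: reconstructs planes at the given
#' orientations and returns them together with the orientations, so recovery
#' can be verified.
#'
#' @param volume A [grayscale_volume()].
#' @param orientations List of [plane_orientation()]s.
#' @param shape `(rows, cols)` of the planes.
#' @return List with `planes` (list of matrices) and `orientations`.
#' @export
extract_tilted_slices <- function(volume, orientations, shape = NULL) {
  planes <- lapply(orientations, function(o) {
    reconstruct_plane(volume, o$a, o$b, o$k0,
                      center = if (length(o$center)) o$center else NULL,
                      shape = shape)
  })
  list(planes = planes, orientations = orientations)
}

#' Default face geometry of the reference study design
#'
#' Ten faces (two per slice, five slices): slice thickness 15 CT layers, kerf
#' 50 layers, so consecutive outer faces of any leave-middle-out triple are
#' 65 slices apart.
#'
#' @param z0 Slice index of the first face (default 6).
#' @return Integer vector of 10 face slice positions.
#' @export
default_face_geometry <- function(z0 = 6L) {
  z0 + cumsum(c(0L, rep(c(15L, 50L), 5L)[1:9]))
}

#' Generate a complete synthetic study with known ground truth
#'
#' Bundles a phase-structured grayscale volume, a face set with elemental
#' maps generated by step trends plus shared 3D residual fields, and the full
#' generating truth.  Regenerating with the same seed is bit-identical.
#'
#' @param dim Volume dimensions (default `c(256, 256, 300)`).
#' @param truth Generating laws per element ([default_truth()]).
#' @param phases Material phases ([default_phases()]).
#' @param z_faces Face slice indices ([default_face_geometry()]).
#' @param mask_fraction Broken-slice mask fraction per face (default 0).
#' @param seed Integer seed (default 1).
#' @return List of class `synthetic_study`: `volume`, `layers`, `truth`,
#'   `phases`, `seed`.
#' @export
synthetic_study <- function(dim = c(256L, 256L, 300L), truth = default_truth(),
                            phases = default_phases(),
                            z_faces = default_face_geometry(),
                            mask_fraction = 0, seed = 1) {
  volume <- simulate_soil_volume(dim, phases = phases, seed = seed)
  layers <- simulate_element_maps(volume, z_faces, truth = truth, seed = seed,
                                  mask_fraction = mask_fraction)
  structure(list(volume = volume, layers = layers, truth = truth,
                 phases = phases, z_faces = z_faces, seed = seed),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Writes the volume as an 8-bit TIFF stack, each face's element maps as CSV
#' matrices named `<faceid>_<element>.csv`, and the generating truth as
#' `truth.json`.
#'
#' @param study A [synthetic_study()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(study$volume, file.path(dir, "volume"))
  for (f in study$layers$faces) {
    for (el in names(f$maps)) {
      write_element_map(f$maps[[el]],
                        file.path(dir, sprintf("%s_%s.csv", f$id, el)))
    }
  }
  truth_rec <- lapply(study$truth, function(tr) {
    list(thresholds = tr$thresholds, levels = tr$levels,
         residual = list(c0 = tr$residual$nugget,
                         components = tr$residual$components),
         noise_sd = tr$noise_sd)
  })
  jsonlite::write_json(list(truth = truth_rec, z_faces = study$z_faces,
                            seed = study$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
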