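#' Ordinary kriging at a target point
#'
#' Solves the standard ordinary-kriging system: semivariance matrix of the
#' observations augmented with the unbiasedness (weights-sum-to-one)
#' constraint via a Lagrange multiplier.  The prediction is the weighted sum
#' of the observations; the kriging variance is
#' `sum_i lambda_i gamma(x_i, x0) + mu`.  With a zero nugget the predictor
#' interpolates exactly at data locations.
#'
#' @param coords Numeric matrix of observation coordinates (one row each,
#'   2 or 3 columns, voxel units).
#' @param values Numeric vector of observed values.
#' @param model A [variogram_model()].
#' @param target Coordinate vector of the prediction point.
#' @return A list of class `kriging_result`: `prediction`, `variance`,
#'   `weights`, `lagrange`.
#' @export
ordinary_kriging <- function(coords, values, model, target) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(values), length(target) == ncol(coords))
  sys <- ok_system(coords, model)
  rhs <- ok_rhs(coords, model, target)
  sol <- solve(sys$A, rhs)
  n <- nrow(coords)
  lambda <- sol[seq_len(n)]
  mu <- sol[n + 1L]
  structure(
    list(prediction = sum(lambda * values),
         variance = sum(lambda * rhs[seq_len(n)]) + mu,
         weights = lambda, lagrange = mu),
    class = "kriging_result"
  )
}

# build (n+1) x (n+1) OK matrix with duplicate/conditioning guards
ok_system <- function(coords, model) {
  n <- nrow(coords)
  if (n == 1L) {
    A <- matrix(c(0, 1, 1, 0), 2, 2)
    return(list(A = A, n = 1L))
  }
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate observation coordinates: kriging system is singular; deduplicate the observations",
         call. = FALSE)
  }
  G <- matrix(model_semivariance(model, as.vector(d)), n, n)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  # conditioning guard: tiny diagonal jitter on the semivariance block
  if (!is.finite(rcond_est(A)) || rcond_est(A) < 1e-12) {
    jit <- 1e-10 * max(model$total_sill, 1)
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + jit
    if (rcond_est(A) < 1e-15) {
      stop("kriging system is too ill-conditioned to solve", call. = FALSE)
    }
  }
  list(A = A, n = n)
}

rcond_est <- function(A) tryCatch(rcond(A), error = function(e) NA_real_)

ok_rhs <- function(coords, model, target) {
  d0 <- sqrt(colSums((t(coords) - target)^2))
  c(model_semivariance(model, d0), 1)
}

# reusable factorization for many right-hand sides with fixed geometry
ok_factor <- function(coords, model) {
  sys <- ok_system(coords, model)
  list(qr = qr(sys$A), n = sys$n, coords = as.matrix(coords), model = model)
}

ok_solve_target <- function(fac, target) {
  rhs <- ok_rhs(fac$coords, fac$model, target)
  sol <- solve(fac$qr, rhs)
  list(weights = sol[seq_len(fac$n)], lagrange = sol[fac$n + 1L],
       variance = sum(sol[seq_len(fac$n)] * rhs[seq_len(fac$n)]) + sol[fac$n + 1L])
}

#' Two-layer sampling grid around a target point
#'
#' Builds the kriging observation set used throughout the package: an
#' `n x n` square grid on each of the two measurement layers, centred at the
#' projection of the target point onto the layers.  Grids that would fall
#' outside the layer extent are shifted minimally to fit (and flagged).
#'
#' @param target `(row, col, z)` of the prediction point, voxel units.
#' @param n Odd grid side (default 9, i.e. `2 * 81 = 162` points).
#' @param spacing Grid spacing in voxels.
#' @param layer_z Slice indices of the two layers.
#' @param extent Optional `(rows, cols)` extent of the layers; `NULL` means
#'   unbounded (used for data-free variance profiles).
#' @return List: `points` (a `2 n^2 x 3` matrix, layer 1 rows first,
#'   row-major within a layer), `shifted` flag, `shift` `(rows, cols)`.
#' @export
two_layer_grid <- function(target, n = 9L, spacing = 8L, layer_z, extent = NULL) {
  n <- as.integer(n)
  if (n %% 2L == 0L) stop("grid side `n` must be odd", call. = FALSE)
  stopifnot(length(layer_z) == 2L, spacing > 0)
  half <- (n - 1L) %/% 2L
  off <- spacing * (-half:half)
  shift <- c(0, 0)
  if (!is.null(extent)) {
    for (ax in 1:2) {
      lo <- target[ax] + off[1]; hi <- target[ax] + off[n]
      if (hi - lo + 1 > extent[ax]) {
        stop("sampling grid larger than the layer extent", call. = FALSE)
      }
      if (lo < 1) shift[ax] <- 1 - lo else if (hi > extent[ax]) shift[ax] <- extent[ax] - hi
    }
  }
  rows <- rep(target[1] + shift[1] + off, each = n)
  cols <- rep(target[2] + shift[2] + off, times = n)
  pts <- rbind(cbind(rows, cols, layer_z[1]), cbind(rows, cols, layer_z[2]))
  dimnames(pts) <- list(NULL, c("row", "col", "z"))
  list(points = pts, shifted = any(shift != 0), shift = shift)
}

#' Kriging variance as a function of grid spacing
#'
#' Computes, for each candidate spacing, the ordinary-kriging variance of a
#' target point lying between two measurement layers when the observations
#' are a centred two-layer `n x n` grid.  The variance depends only on the
#' observation geometry and the variogram model, not on observed values,
#' which is what makes the sampling grid optimizable before any prediction.
#'
#' @param model A [variogram_model()].
#' @param n Odd grid side (default 9).
#' @param spacings Integer vector of candidate spacings (default `1:20`).
#' @param layer_gap Separation of the layers in slices (default 65).
#' @param target_offset Distance from the upper layer to the target
#'   (default 32, the mid-gap point); must lie strictly inside `(0, layer_gap)`.
#' @return A tibble of class `kriging_profile` with columns `spacing`,
#'   `variance`.
#' @export
kriging_variance_profile <- function(model, n = 9L, spacings = 1:20,
                                     layer_gap = 65L, target_offset = 32L) {
  if (target_offset <= 0 || target_offset >= layer_gap) {
    stop("`target_offset` must lie strictly between the layers", call. = FALSE)
  }
  target <- c(0, 0, target_offset)
  variance <- vapply(spacings, function(s) {
    g <- two_layer_grid(target, n = n, spacing = s, layer_z = c(0, layer_gap))
    fac <- ok_factor(g$points, model)
    ok_solve_target(fac, target)$variance
  }, 0)
  out <- tibble::tibble(spacing = as.integer(spacings), variance = variance)
  class(out) <- c("kriging_profile", class(out))
  attr(out, "n") <- as.integer(n)
  attr(out, "layer_gap") <- as.integer(layer_gap)
  attr(out, "target_offset") <- as.integer(target_offset)
  out
}

#' Pick the grid spacing minimizing the kriging variance
#'
#' @param profile A [kriging_variance_profile()] (any tibble with `spacing`
#'   and `variance` columns).
#' @return The argmin spacing (ties break to the smallest spacing).
#' @export
optimize_grid_spacing <- function(profile) {
  if (nrow(profile) == 0L) stop("empty variance profile", call. = FALSE)
  vmin <- min(profile$variance)
  # variances within solver noise of the minimum count as tied
  tol <- max(1e-12, 1e-9 * abs(vmin))
  min(profile$spacing[profile$variance <= vmin + tol])
}
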