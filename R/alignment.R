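#' Plane orientation of a registered face
#'
#' Locates a (possibly tilted) cut face inside the CT volume.  The staircase
#' plane through the stack is
#' `k(row, col) = round(a * (col - c_col) + b * (row - c_row)) + k0`,
#' with rounding to the nearest integer, halves away from zero.  `a` and `b`
#' are tangents of the two tilt angles (`a = tan(psi)` for the in-column
#' direction, `b = tan(phi)/cos(psi)` for the in-row direction) and the
#' rotation centre defaults to the geometric centre of the plane window.
#'
#' @param a,b Unitless slopes (tilt tangents).
#' @param k0 Base slice index at the rotation centre (1-based).
#' @param center `(row, col)` rotation centre in voxels.
#' @param crop_offset `(row, col)` of the best-correlating crop window inside
#'   the reconstructed plane (1-based).
#' @return An object of class `plane_orientation`.
#' @export
plane_orientation <- function(a, b, k0, center, crop_offset = c(1L, 1L)) {
  structure(
    list(a = a, b = b, k0 = as.integer(k0), center = as.numeric(center),
         crop_offset = as.integer(crop_offset)),
    class = "plane_orientation"
  )
}

#' @export
print.plane_orientation <- function(x, ...) {
  cat(sprintf(
    "<plane_orientation> a = %.4g, b = %.4g (psi = %.3f deg, phi = %.3f deg), k0 = %d, centre (%g, %g), crop offset (%d, %d)\n",
    x$a, x$b, atan(x$a) * 180 / pi, atan(x$b * cos(atan(x$a))) * 180 / pi,
    x$k0, x$center[1], x$center[2], x$crop_offset[1], x$crop_offset[2]
  ))
  invisible(x)
}

# round to nearest integer, halves away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Reconstruct a tilted staircase plane from the volume
#'
#' Extracts the 2D grayscale plane `out[row, col] =
#' volume[row, col, round(a*(col - c_col) + b*(row - c_row)) + k0]`.  With
#' `a = b = 0` the un-rotated slice `k0` is recovered exactly.
#'
#' @param volume A [grayscale_volume()].
#' @param a,b Tilt slopes.
#' @param k0 Base slice index (1-based).
#' @param center `(row, col)` rotation centre; default: geometric centre of
#'   the plane window, `shape %/% 2`.
#' @param shape `(rows, cols)` of the plane window (rows/cols `1..shape`);
#'   default: the full in-plane extent of the volume.
#' @return Numeric matrix `shape[1] x shape[2]` of grayscale values.
#' @export
reconstruct_plane <- function(volume, a, b, k0, center = NULL, shape = NULL) {
  d <- dim(volume)
  if (is.null(shape)) shape <- d[1:2]
  shape <- as.integer(shape)
  if (shape[1] > d[1] || shape[2] > d[2]) {
    stop("plane shape exceeds the in-plane extent of the volume", call. = FALSE)
  }
  if (is.null(center)) center <- shape %/% 2L
  koff <- plane_k_offsets(a, b, shape, center)
  k <- koff + as.integer(k0)
  if (any(k < 1L) || any(k > d[3])) {
    lo <- 1L - min(koff); hi <- d[3] - max(koff)
    stop(sprintf(
      "plane maps outside the volume (slices %d..%d requested, stack has %d); admissible k0 range is [%d, %d]",
      min(k), max(k), d[3], lo, hi
    ), call. = FALSE)
  }
  rows <- rep.int(seq_len(shape[1]), shape[2])
  cols <- rep(seq_len(shape[2]), each = shape[1])
  matrix(unclass(volume)[cbind(rows, cols, as.vector(k))], shape[1], shape[2])
}

# integer slice offsets of the staircase plane relative to k0
plane_k_offsets <- function(a, b, shape, center) {
  off <- outer(b * (seq_len(shape[1]) - center[1]),
               a * (seq_len(shape[2]) - center[2]), `+`)
  matrix(as.integer(round_half_away(off)), shape[1], shape[2])
}

# admissible k0 interval for a tilt, or NULL if empty
feasible_k0 <- function(a, b, shape, center, depth) {
  koff <- range(plane_k_offsets(a, b, shape, center))
  lo <- 1L - koff[1]; hi <- depth - koff[2]
  if (lo > hi) NULL else c(lo, hi)
}

#' Product-moment correlation with explicit degeneracy handling
#'
#' Pearson correlation over masked-in pairs.  Unlike [stats::cor()], constant
#' input raises an explicit error rather than returning `NA` silently.
#'
#' @param x,y Numeric vectors of equal length (matrices are flattened).
#' @param mask Optional logical vector selecting valid pairs; pairs with `NA`
#'   in either input are dropped as well.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y, mask = NULL) {
  x <- as.vector(x); y <- as.vector(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("fewer than 2 valid pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: constant input on the mask", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Cumulative absolute correlation between a plane and element maps
#'
#' The registration objective: the sum over elements of the absolute Pearson
#' correlation between the reconstructed grayscale plane and each element
#' map, computed over the intersection of all map masks.
#'
#' @param plane Numeric grayscale matrix.
#' @param maps Named list of [element_map()]s with `plane`'s shape.
#' @return List with `cumulative` (scalar) and `per_element` (named vector).
#' @export
cumulative_correlation <- function(plane, maps) {
  if (is.null(names(maps))) names(maps) <- vapply(maps, attr, "", "element")
  joint <- Reduce(`&`, lapply(maps, map_mask))
  per <- vapply(maps, function(m) pearson_r(plane, unclass(m), mask = joint), 0)
  list(cumulative = sum(abs(per)), per_element = per)
}

#' Alignment search settings
#'
#' @param a_range,b_range Tilt search intervals (default the instrument's
#'   `[-0.05, 0.05]`, about +/- 3 degrees).
#' @param step Tilt grid step (default 0.001).
#' @param k0_range Integer range of base slices searched; `NULL` means the
#'   full admissible range for each tilt.
#' @param plane_shape `(rows, cols)` of the reconstructed plane window.
#' @param crop_shape `(rows, cols)` of the crop window matched to the maps.
#' @param exhaustive If `TRUE`, evaluate every tilt on the fine grid;
#'   otherwise a coarse-to-fine refinement is used (identical optimum on
#'   smooth objectives, far fewer plane evaluations).
#' @param ab_stride Coarse-stage stride over tilt steps (default 5).
#' @param keep Number of coarse candidates refined (default 25).
#' @return A list of class `align_search`.
#' @export
align_search <- function(a_range = c(-0.05, 0.05), b_range = c(-0.05, 0.05),
                         step = 0.001, k0_range = NULL,
                         plane_shape = c(830L, 880L), crop_shape = c(750L, 800L),
                         exhaustive = FALSE, ab_stride = 5L, keep = 25L) {
  structure(list(a_range = a_range, b_range = b_range, step = step,
                 k0_range = k0_range, plane_shape = as.integer(plane_shape),
                 crop_shape = as.integer(crop_shape), exhaustive = exhaustive,
                 ab_stride = as.integer(ab_stride), keep = as.integer(keep)),
            class = "align_search")
}

# ---- fast correlation over all crop offsets ---------------------------------

fft2 <- function(x, dims) {
  pad <- matrix(0, dims[1], dims[2])
  pad[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  fft(pad)
}

# cross-correlation sums for all offsets via FFT: out[or, oc] =
# sum_u A[or+u1-1, oc+u2-1] * K[u1, u2], valid offsets only
cross_sums <- function(fa, fk_conj, dims, n_valid) {
  d <- Re(fft(fa * fk_conj, inverse = TRUE)) / prod(dims)
  d[seq_len(n_valid[1]), seq_len(n_valid[2]), drop = FALSE]
}

# kernel FFTs for a fixed set of maps (reused across all planes in a search)
offset_kernels <- function(maps, crop_shape, fft_dims) {
  joint <- Reduce(`&`, lapply(maps, map_mask))
  if (!any(joint)) stop("all pixels masked out across the element maps", call. = FALSE)
  n <- sum(joint)
  ys <- lapply(maps, function(m) {
    y <- unclass(m); y[!joint] <- 0; y[is.na(y)] <- 0
    y
  })
  list(
    joint = joint, n = n,
    fk_mask = Conj(fft2(joint * 1, fft_dims)),
    fk_y = lapply(ys, function(y) Conj(fft2(y, fft_dims))),
    s_y = vapply(ys, sum, 0),
    s_yy = vapply(ys, function(y) sum(y^2), 0)
  )
}

# cumulative |r| for every crop offset of `plane`; NA where undefined
score_all_offsets <- function(plane, kern, crop_shape, fft_dims) {
  nv <- c(nrow(plane) - crop_shape[1] + 1L, ncol(plane) - crop_shape[2] + 1L)
  fa <- fft2(plane, fft_dims)
  fa2 <- fft2(plane^2, fft_dims)
  s_x <- cross_sums(fa, kern$fk_mask, fft_dims, nv)
  s_xx <- cross_sums(fa2, kern$fk_mask, fft_dims, nv)
  n <- kern$n
  ss_x <- s_xx - s_x^2 / n
  ss_x[ss_x < 1e-9] <- NA  # constant plane window: correlation undefined
  cum <- matrix(0, nv[1], nv[2])
  for (el in names(kern$fk_y)) {
    s_xy <- cross_sums(fa, kern$fk_y[[el]], fft_dims, nv)
    ss_y <- kern$s_yy[[el]] - kern$s_y[[el]]^2 / n
    if (ss_y < 1e-12) stop("element map '", el, "' is constant on the joint mask",
                           call. = FALSE)
    r <- (s_xy - s_x * kern$s_y[[el]] / n) / sqrt(ss_x * ss_y)
    cum <- cum + pmin(abs(r), 1)
  }
  cum
}

# deterministic candidate comparison: higher score, then smaller |a|+|b|,
# then smaller k0, then row-major first offset.  Scores within 1e-9 are
# treated as tied so that FFT rounding jitter cannot break determinism.
SCORE_TOL <- 1e-9

better_candidate <- function(x, y) {
  if (is.null(y)) return(TRUE)
  if (abs(x$score - y$score) > SCORE_TOL) return(x$score > y$score)
  sx <- abs(x$a) + abs(x$b); sy <- abs(y$a) + abs(y$b)
  if (sx != sy) return(sx < sy)
  if (x$k0 != y$k0) return(x$k0 < y$k0)
  if (x$off[1] != y$off[1]) return(x$off[1] < y$off[1])
  x$off[2] < y$off[2]
}

# best offset of a score matrix under the row-major tie-break
best_offset <- function(cum) {
  if (all(is.na(cum))) return(NULL)
  m <- max(cum, na.rm = TRUE)
  hit <- which(!is.na(cum) & cum >= m - SCORE_TOL)  # ties within tolerance
  rows <- (hit - 1L) %% nrow(cum) + 1L
  cols <- (hit - 1L) %/% nrow(cum) + 1L
  ord <- order(rows, cols)[1]
  list(score = m, off = c(rows[ord], cols[ord]))
}

#' Register a face inside the volume
#'
#' Systematically searches tilt slopes `(a, b)`, base slice `k0` and crop
#' offset for the combination maximizing the cumulative absolute correlation
#' between the reconstructed staircase plane and the face's element maps.
#' Ties are broken deterministically: smallest `|a| + |b|`, then smallest
#' `k0`, then the row-major first offset.
#'
#' @param volume A [grayscale_volume()].
#' @param maps Named list of [element_map()]s, all of `crop_shape`.
#' @param search An [align_search()] configuration.
#' @return A list of class `alignment_result`: `orientation`
#'   ([plane_orientation()]), `cumulative_corr`, `per_element_corr`,
#'   `reconstructed_plane` (the best crop window), `n_evaluated`.
#' @export
align_face <- function(volume, maps, search = align_search()) {
  d <- dim(volume)
  ps <- search$plane_shape; cs <- search$crop_shape
  if (any(cs > ps)) stop("crop_shape must not exceed plane_shape", call. = FALSE)
  if (any(ps > d[1:2])) stop("plane_shape exceeds the volume's in-plane extent", call. = FALSE)
  for (m in maps) {
    if (!identical(dim(unclass(m)), cs)) {
      stop("all element maps must have crop_shape ", cs[1], " x ", cs[2], call. = FALSE)
    }
  }
  center <- ps %/% 2L
  a_vals <- grid_vals(search$a_range, search$step)
  b_vals <- grid_vals(search$b_range, search$step)
  fft_dims <- c(stats::nextn(ps[1], c(2, 3, 5)), stats::nextn(ps[2], c(2, 3, 5)))
  kern <- offset_kernels(maps, cs, fft_dims)

  eval_combo <- function(a, b) {
    f <- feasible_k0(a, b, ps, center, d[3])
    if (is.null(f)) return(list())
    k0s <- if (is.null(search$k0_range)) f[1]:f[2] else {
      ks <- max(f[1], search$k0_range[1]):min(f[2], search$k0_range[2])
      if (length(ks) == 0L || ks[1] > ks[length(ks)]) return(list())
      ks
    }
    out <- vector("list", length(k0s))
    for (idx in seq_along(k0s)) {
      k0 <- k0s[idx]
      plane <- reconstruct_plane(volume, a, b, k0, center, ps)
      bo <- best_offset(score_all_offsets(plane, kern, cs, fft_dims))
      if (!is.null(bo)) out[[idx]] <- c(bo, list(a = a, b = b, k0 = k0))
    }
    out[!vapply(out, is.null, TRUE)]
  }

  best <- NULL
  n_eval <- 0L
  consider <- function(cands) {
    for (cnd in cands) if (better_candidate(cnd, best)) best <<- cnd
    n_eval <<- n_eval + length(cands)
  }

  if (search$exhaustive || search$ab_stride <= 1L) {
    for (a in a_vals) for (b in b_vals) consider(eval_combo(a, b))
  } else {
    ai <- unique(c(seq(1L, length(a_vals), by = search$ab_stride), length(a_vals)))
    bi <- unique(c(seq(1L, length(b_vals), by = search$ab_stride), length(b_vals)))
    coarse <- list()
    for (a in a_vals[ai]) for (b in b_vals[bi]) {
      cands <- eval_combo(a, b)
      n_eval <- n_eval + length(cands)
      coarse <- c(coarse, cands)
    }
    if (length(coarse) == 0L) stop("empty feasible search space", call. = FALSE)
    scores <- vapply(coarse, function(cn) cn$score, 0)
    top <- coarse[order(-scores)[seq_len(min(search$keep, length(coarse)))]]
    seen <- character()
    for (cnd in top) {
      ia <- which.min(abs(a_vals - cnd$a)); ib <- which.min(abs(b_vals - cnd$b))
      ra <- max(1L, ia - search$ab_stride + 1L):min(length(a_vals), ia + search$ab_stride - 1L)
      rb <- max(1L, ib - search$ab_stride + 1L):min(length(b_vals), ib + search$ab_stride - 1L)
      for (a in a_vals[ra]) for (b in b_vals[rb]) {
        key <- paste(a, b)
        if (key %in% seen) next
        seen <- c(seen, key)
        consider(eval_combo(a, b))
      }
    }
  }
  if (is.null(best)) stop("empty feasible search space", call. = FALSE)

  # re-score the optimum with the exact (non-FFT) correlation path
  plane <- reconstruct_plane(volume, best$a, best$b, best$k0, center, ps)
  window <- crop_region(plane, best$off, cs)
  cc <- cumulative_correlation(window, maps)
  structure(
    list(
      orientation = plane_orientation(best$a, best$b, best$k0, center, best$off),
      cumulative_corr = cc$cumulative,
      per_element_corr = cc$per_element,
      reconstructed_plane = window,
      n_evaluated = n_eval
    ),
    class = "alignment_result"
  )
}

grid_vals <- function(range, step) {
  n <- round((range[2] - range[1]) / step)
  round(range[1] + step * (0:n), 12)
}

#' @export
print.alignment_result <- function(x, ...) {
  print(x$orientation)
  cat(sprintf("  cumulative |r| = %.4f (%s)\n", x$cumulative_corr,
              paste(sprintf("%s: %.3f", names(x$per_element_corr),
                            x$per_element_corr), collapse = ", ")))
  invisible(x)
}

#' Write an alignment result as JSON
#'
#' @param result An `alignment_result` from [align_face()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(result, path) {
  o <- result$orientation
  jsonlite::write_json(
    list(a = o$a, b = o$b, k0 = o$k0, center = o$center,
         crop_offset = o$crop_offset,
         cumulative_corr = result$cumulative_corr,
         per_element_corr = as.list(result$per_element_corr)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
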