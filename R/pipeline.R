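#' Control parameters for regression-tree kriging
#'
#' @param min_leaf,prune,cv_folds,seed Tree-fitting controls ([fit_tree()]).
#' @param grid_n Odd side of the two-layer kriging grid (default 9).
#' @param spacing Fixed grid spacing; `NULL` (default) selects it by
#'   minimizing the kriging variance over `spacings`.
#' @param spacings Candidate spacings for the optimizer (default `1:20`).
#' @param bin_width,max_lag Empirical-variogram binning (voxels).
#' @param subsample_per_layer Seeded number of pixels sampled per layer for
#'   variogram estimation (default 5000).
#' @param candidates Variogram model candidates
#'   ([default_variogram_candidates()]).
#' @param clamp_nonnegative Clamp negative predictions to zero
#'   (default `FALSE`; element counts cannot be negative, but clamping alters
#'   error measures, so it is opt-in).
#' @return A list of class `rtk_control`.
#' @export
rtk_control <- function(min_leaf = 50L, prune = TRUE, cv_folds = 5L, seed = 1L,
                        grid_n = 9L, spacing = NULL, spacings = 1:20,
                        bin_width = 1, max_lag = 64,
                        subsample_per_layer = 5000L,
                        candidates = default_variogram_candidates(),
                        clamp_nonnegative = FALSE) {
  structure(list(min_leaf = min_leaf, prune = prune, cv_folds = cv_folds,
                 seed = seed, grid_n = grid_n, spacing = spacing,
                 spacings = spacings, bin_width = bin_width, max_lag = max_lag,
                 subsample_per_layer = subsample_per_layer,
                 candidates = candidates,
                 clamp_nonnegative = clamp_nonnegative),
            class = "rtk_control")
}

face_pixels <- function(face, element) {
  m <- face$maps[[element]]
  if (is.null(m)) {
    stop(sprintf("face '%s' has no map for element '%s'", face$id, element),
         call. = FALSE)
  }
  mask <- map_mask(m)
  list(gray = face$gray[mask], conc = unclass(m)[mask], mask = mask)
}

#' Fit a regression-tree-kriging model for one element
#'
#' Pools the pixels of the two training faces, fits the grayscale regression
#' tree, computes per-face residual maps, estimates and AIC-selects the
#' residual variogram on a seeded pixel subsample (3D distances, both layers
#' pooled, inter-layer pairs included under isotropy), and sets the kriging
#' grid spacing by minimizing the kriging variance (unless fixed in `cfg`).
#' When the residuals are numerically degenerate (the trend explains the data
#' exactly) the model is flagged trend-only and kriging is skipped.
#'
#' @param upper,lower Training [aligned_face()]s, `upper$z < lower$z`.
#' @param element Element label present on both faces.
#' @param cfg An [rtk_control()].
#' @return An object of class `rtk_model`.
#' @export
fit_rtk <- function(upper, lower, element, cfg = rtk_control()) {
  if (upper$z >= lower$z) stop("`upper` must lie above `lower` (smaller z)", call. = FALSE)
  pu <- face_pixels(upper, element)
  pl <- face_pixels(lower, element)
  tree <- fit_tree(c(pu$gray, pl$gray), c(pu$conc, pl$conc),
                   min_leaf = cfg$min_leaf, prune = cfg$prune,
                   cv_folds = cfg$cv_folds, seed = cfg$seed)
  resid_u <- unclass(upper$maps[[element]]) - predict(tree, upper$gray)
  resid_l <- unclass(lower$maps[[element]]) - predict(tree, lower$gray)
  rvals <- c(resid_u[pu$mask], resid_l[pl$mask])
  cvals <- c(pu$conc, pl$conc)
  trend_only <- stats::var(rvals) < max(1e-12, 1e-8 * stats::var(cvals))
  variogram <- NULL; vfit <- NULL; emp <- NULL; spacing <- cfg$spacing
  if (!trend_only) {
    coords_u <- sample_face_coords(pu$mask, upper$z, cfg$subsample_per_layer,
                                   cfg$seed)
    coords_l <- sample_face_coords(pl$mask, lower$z, cfg$subsample_per_layer,
                                   cfg$seed + 1L)
    coords <- rbind(coords_u, coords_l)
    vals <- c(resid_u[coords_u[, 1:2]], resid_l[coords_l[, 1:2]])
    emp <- empirical_variogram(coords, vals, bin_width = cfg$bin_width,
                               max_lag = cfg$max_lag)
    sel <- aic_select(emp, cfg$candidates)
    variogram <- sel$model; vfit <- sel
    if (is.null(spacing)) {
      gap <- lower$z - upper$z
      # only spacings whose grid footprint fits the layer are admissible
      max_s <- (min(dim(resid_u)) - 1L) %/% (cfg$grid_n - 1L)
      spacings <- cfg$spacings[cfg$spacings <= max_s]
      if (length(spacings) == 0L) {
        stop("no candidate grid spacing fits the layer extent", call. = FALSE)
      }
      prof <- kriging_variance_profile(variogram, n = cfg$grid_n,
                                       spacings = spacings,
                                       layer_gap = gap,
                                       target_offset = round(gap / 2))
      spacing <- optimize_grid_spacing(prof)
    }
  }
  structure(
    list(element = element, tree = tree, variogram = variogram,
         variogram_selection = if (is.null(vfit)) NULL else vfit$table,
         empirical = emp, spacing = spacing, grid_n = cfg$grid_n,
         upper_z = upper$z, lower_z = lower$z,
         resid_upper = resid_u, resid_lower = resid_l,
         trend_only = trend_only, cfg = cfg),
    class = "rtk_model"
  )
}

# seeded sample of masked-in pixel coordinates on a face, as (row, col, z)
sample_face_coords <- function(mask, z, size, seed) {
  idx <- which(mask)
  if (length(idx) > size) {
    idx <- withr::with_seed(as.integer(seed), sample(idx, size))
  }
  nr <- nrow(mask)
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L, z = z)
}

#' @export
print.rtk_model <- function(x, ...) {
  cat(sprintf("<rtk_model> %s: layers z = %g and %g, %d-leaf tree%s\n",
              x$element, x$upper_z, x$lower_z, length(x$tree$leaf_means),
              if (x$trend_only) ", trend-only (degenerate residuals)" else ""))
  if (!is.null(x$variogram)) {
    print(x$variogram)
    cat(sprintf("  grid: %d x %d per layer, spacing %d voxels\n",
                x$grid_n, x$grid_n, x$spacing))
  }
  invisible(x)
}

# ---- residual kriging over a pixel grid -------------------------------------

# Ordinary kriging of the residual field at every (row, col) of one z-slice,
# using the two-layer grid centred on each target's in-plane projection.
# Weights are solved once per distinct boundary shift (the grid-grid
# semivariance matrix does not depend on the target, so a single
# factorization serves every target at this z).
krige_residual_slice <- function(model, z, rows, cols) {
  n <- model$grid_n; s <- model$spacing
  half <- (n - 1L) %/% 2L
  ext <- dim(model$resid_upper)
  span <- 2L * half * s + 1L
  if (span > ext[1] || span > ext[2]) {
    stop("sampling grid larger than the layer extent", call. = FALSE)
  }
  off <- as.integer(s * (-half:half))
  g_row <- rep(off, each = n); g_col <- rep(off, times = n)
  gpts <- rbind(cbind(g_row, g_col, model$upper_z),
                cbind(g_row, g_col, model$lower_z))
  fac <- ok_factor(gpts, model$variogram)
  nobs <- nrow(gpts)

  # clamped centre shift per target pixel
  clamp <- function(p, lim) pmin(pmax(p, 1L + half * s), lim - half * s)
  sr <- clamp(rows, ext[1]) - rows
  sc <- clamp(cols, ext[2]) - cols
  tgt <- expand.grid(r = seq_along(rows), c = seq_along(cols))
  tgt$sr <- sr[tgt$r]; tgt$sc <- sc[tgt$c]
  out <- matrix(NA_real_, length(rows), length(cols))
  ru <- model$resid_upper; rl <- model$resid_lower
  nr_ext <- ext[1]

  lin_off <- (g_col) * nr_ext + g_row  # linear index offset of each grid point
  groups <- split(seq_len(nrow(tgt)), paste(tgt$sr, tgt$sc))
  for (g in groups) {
    g1 <- g[1]
    shift <- c(tgt$sr[g1], tgt$sc[g1])
    sol <- ok_solve_target(fac, c(-shift[1], -shift[2], z))
    lam <- sol$weights
    prow <- rows[tgt$r[g]] + shift[1]
    pcol <- cols[tgt$c[g]] + shift[2]
    # gather residuals at the 2 n^2 grid points of every target in the group
    idx <- outer((pcol - 1L) * nr_ext + prow, lin_off, `+`)
    vu <- ru[idx]; vl <- rl[idx]
    dim(vu) <- dim(vl) <- dim(idx)
    nas <- is.na(vu) | is.na(vl)
    acc <- if (any(nas)) {
      vu0 <- vu; vl0 <- vl; vu0[is.na(vu0)] <- 0; vl0[is.na(vl0)] <- 0
      as.vector(vu0 %*% lam[seq_len(n * n)] + vl0 %*% lam[n * n + seq_len(n * n)])
    } else {
      as.vector(vu %*% lam[seq_len(n * n)] + vl %*% lam[n * n + seq_len(n * n)])
    }
    # targets whose grid hits masked pixels: re-solve on the complete subset
    bad <- which(rowSums(nas) > 0L)
    for (j in bad) {
      vals <- c(vu[j, ], vl[j, ])
      ok <- !is.na(vals)
      if (!any(ok)) { acc[j] <- 0; next }
      pts <- gpts[ok, , drop = FALSE]
      pts[, 1] <- pts[, 1] + shift[1]; pts[, 2] <- pts[, 2] + shift[2]
      kr <- ordinary_kriging(pts, vals[ok], model$variogram, c(0, 0, z))
      acc[j] <- kr$prediction
    }
    out[cbind(tgt$r[g], tgt$c[g])] <- acc
  }
  out
}

#' Predict a 3D concentration block
#'
#' Predicts element concentration at every voxel of a region lying between
#' the two training layers, by the regression tree alone (`method = "rt"`:
#' a pure grayscale lookup) or by regression-tree kriging (`method = "rtk"`:
#' the tree prediction plus ordinary kriging of the training residuals on the
#' centred two-layer grid).
#'
#' @param model An [fit_rtk()] model.
#' @param volume The [grayscale_volume()].
#' @param region List with `rows`, `cols`, `z`: integer index vectors; `z`
#'   must lie within `[upper_z, lower_z]`.
#' @param method `"rtk"` (default) or `"rt"`.
#' @return 3D array `length(rows) x length(cols) x length(z)`.
#' @export
predict_block <- function(model, volume, region, method = c("rtk", "rt")) {
  method <- match.arg(method)
  rows <- as.integer(region$rows); cols <- as.integer(region$cols)
  zs <- as.integer(region$z)
  if (any(zs < model$upper_z) || any(zs > model$lower_z)) {
    stop("region z outside the training layers", call. = FALSE)
  }
  out <- array(NA_real_, dim = c(length(rows), length(cols), length(zs)))
  for (zi in seq_along(zs)) {
    gray <- unclass(volume)[rows, cols, zs[zi], drop = FALSE]
    pred <- predict(model$tree, matrix(gray, length(rows), length(cols)))
    if (method == "rtk" && !model$trend_only) {
      pred <- pred + krige_residual_slice(model, zs[zi], rows, cols)
    }
    if (isTRUE(model$cfg$clamp_nonnegative)) pred <- pmax(pred, 0)
    out[, , zi] <- pred
  }
  out
}

#' Predict one face (a single z-slice)
#'
#' @param model An [fit_rtk()] model.
#' @param gray Grayscale matrix of the face (the registered CT plane).
#' @param z Slice position of the face.
#' @param method `"rtk"` or `"rt"`.
#' @return Prediction matrix of `gray`'s shape.
#' @export
predict_face <- function(model, gray, z, method = c("rtk", "rt")) {
  method <- match.arg(method)
  pred <- predict(model$tree, gray)
  if (method == "rtk" && !model$trend_only) {
    pred <- pred + krige_residual_slice(model, z, seq_len(nrow(gray)),
                                        seq_len(ncol(gray)))
  }
  if (isTRUE(model$cfg$clamp_nonnegative)) pred <- pmax(pred, 0)
  pred
}

#' Prediction error measures on a validation face
#'
#' `rmse = sqrt(sum((P - O)^2) / N)` and
#' `r2 = 1 - sum((O - P)^2) / sum((O - mean(O))^2)`, over masked-in pixels.
#'
#' @param predicted Numeric prediction matrix.
#' @param observed An [element_map()] of the same shape.
#' @return List: `rmse`, `r2`, `n`.
#' @export
evaluate <- function(predicted, observed) {
  stopifnot(identical(dim(predicted), dim(unclass(observed))))
  mask <- map_mask(observed) & !is.na(predicted)
  o <- unclass(observed)[mask]; p <- predicted[mask]
  if (length(o) < 2L) stop("fewer than 2 valid pixels", call. = FALSE)
  if (stats::var(o) == 0) {
    stop("observed values are constant: R^2 undefined", call. = FALSE)
  }
  list(rmse = sqrt(sum((p - o)^2) / length(o)),
       r2 = 1 - sum((o - p)^2) / sum((o - mean(o))^2),
       n = length(o))
}

#' Leave-middle-layer-out folds
#'
#' Every triple of consecutive faces whose outer faces are `outer_gap` slices
#' apart, with the middle face strictly between them (generally nearer one of
#' the two, since slice thickness and kerf differ).  In the reference
#' geometry of 10 faces (slice 15, kerf 50) this yields exactly 8 folds.
#'
#' @param layers A [layer_set()].
#' @param outer_gap Required separation of the outer faces (default 65).
#' @return List of folds: `list(upper, middle, lower)` face indices.
#' @export
make_folds <- function(layers, outer_gap = 65) {
  z <- layers$z
  if (length(z) < 3L) stop("need at least 3 faces", call. = FALSE)
  folds <- list()
  for (i in seq_len(length(z) - 2L)) {
    if (z[i + 2L] - z[i] == outer_gap && z[i + 1L] > z[i] && z[i + 1L] < z[i + 2L]) {
      folds[[length(folds) + 1L]] <- list(upper = i, middle = i + 1L,
                                          lower = i + 2L)
    }
  }
  if (length(folds) == 0L) {
    stop(sprintf("no consecutive face triples with outer gap %g (z = %s)",
                 outer_gap, paste(z, collapse = ", ")), call. = FALSE)
  }
  folds
}

#' Paired-samples t-test with explicit degeneracy handling
#'
#' Two-sided paired t-test on the difference `x - y`.  Zero-variance
#' differences yield an explicit undefined result (never `p = 0`).
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return A one-row tibble: `t`, `df`, `p`, `note`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(tibble::tibble(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                          note = "undefined: zero-variance differences"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, note = NA_character_)
}

#' Leave-middle-layer-out cross-validation of RT vs RTK
#'
#' For every fold and element: fit the regression-tree-kriging model on the
#' outer face pair, predict the middle face by the tree alone and by tree +
#' residual kriging, and score both against the measured map.  Summaries are
#' fold means with standard errors (`SD / sqrt(n_folds)`), and paired t-tests
#' compare the two methods on RMSE and R^2 and each method's predicted
#' mean/SD against the observed ones.
#'
#' @param layers A [layer_set()] of registered faces.
#' @param elements Elements to validate (default: all on the faces).
#' @param cfg An [rtk_control()].
#' @param outer_gap Fold geometry (see [make_folds()]).
#' @return An object of class `rtk_cv`: tibbles `metrics` (fold x element x
#'   method), `summary`, `comparisons`, plus `folds` and `cfg`.
#' @export
cross_validate <- function(layers, elements = layers$elements,
                           cfg = rtk_control(), outer_gap = 65) {
  folds <- make_folds(layers, outer_gap)
  rows <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    up <- layers$faces[[fold$upper]]
    mid <- layers$faces[[fold$middle]]
    lo <- layers$faces[[fold$lower]]
    for (el in elements) {
      model <- fit_rtk(up, lo, el, cfg)
      obs <- mid$maps[[el]]
      for (method in c("rt", "rtk")) {
        pred <- predict_face(model, mid$gray, mid$z, method = method)
        ev <- evaluate(pred, obs)
        mask <- map_mask(obs) & !is.na(pred)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fold = fi, element = el, method = method,
          rmse = ev$rmse, r2 = ev$r2, n = ev$n,
          pred_mean = mean(pred[mask]), pred_sd = stats::sd(pred[mask]),
          obs_mean = mean(unclass(obs)[mask]),
          obs_sd = stats::sd(unclass(obs)[mask]),
          spacing = if (is.null(model$spacing)) NA_integer_ else as.integer(model$spacing),
          variogram = if (is.null(model$variogram_selection)) NA_character_
                      else model$variogram_selection$candidate[1],
          trend_only = model$trend_only
        )
      }
    }
  }
  metrics <- dplyr::bind_rows(rows)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- metrics |>
    dplyr::group_by(.data$element, .data$method) |>
    dplyr::summarise(
      folds = dplyr::n(),
      rmse_mean = mean(.data$rmse), rmse_se = se(.data$rmse),
      r2_mean = mean(.data$r2), r2_se = se(.data$r2),
      pred_mean = mean(.data$pred_mean), pred_mean_se = se(.data$pred_mean),
      pred_sd = mean(.data$pred_sd), pred_sd_se = se(.data$pred_sd),
      obs_mean = mean(.data$obs_mean), obs_sd = mean(.data$obs_sd),
      .groups = "drop"
    )
  comparisons <- cv_comparisons(metrics)
  structure(list(metrics = metrics, summary = summary,
                 comparisons = comparisons, folds = folds, cfg = cfg),
            class = "rtk_cv")
}

cv_comparisons <- function(metrics) {
  out <- list()
  for (el in unique(metrics$element)) {
    rt <- metrics[metrics$element == el & metrics$method == "rt", ]
    rtk <- metrics[metrics$element == el & metrics$method == "rtk", ]
    add <- function(label, x, y) {
      tt <- if (length(x) < 2L) {
        tibble::tibble(t = NA_real_, df = NA_integer_, p = NA_real_,
                       note = "undefined: fewer than 2 folds")
      } else {
        paired_ttest(x, y)
      }
      out[[length(out) + 1L]] <<- dplyr::bind_cols(
        tibble::tibble(element = el, comparison = label), tt)
    }
    add("rmse: rt vs rtk", rt$rmse, rtk$rmse)
    add("r2: rt vs rtk", rt$r2, rtk$r2)
    add("mean: rt vs observed", rt$pred_mean, rt$obs_mean)
    add("mean: rtk vs observed", rtk$pred_mean, rtk$obs_mean)
    add("sd: rt vs observed", rt$pred_sd, rt$obs_sd)
    add("sd: rtk vs observed", rtk$pred_sd, rtk$obs_sd)
  }
  dplyr::bind_rows(out)
}

#' @export
print.rtk_cv <- function(x, ...) {
  cat(sprintf("<rtk_cv> %d folds x %d elements\n", length(x$folds),
              length(unique(x$metrics$element))))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Export cross-validation metrics as CSV
#'
#' @param cv An `rtk_cv` result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cv_metrics <- function(cv, path) {
  utils::write.csv(cv$metrics, path, row.names = FALSE)
  invisible(path)
}
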