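#' Empirical (experimental) variogram
#'
#' Matheron method-of-moments estimator of the isotropic semivariance:
#' for each lag bin, half the mean squared difference between all pairs of
#' values whose Euclidean separation falls in the bin.  Distances are in
#' voxel units (coordinates are voxel indices; multiply by the voxel size for
#' physical lags).
#'
#' @param coords Numeric matrix of point coordinates, one row per point
#'   (2 or 3 columns).
#' @param values Numeric vector, one value per point.
#' @param bin_width Lag bin width in voxel units (default 1).
#' @param max_lag Largest lag retained (default 64).
#' @param subsample Optional `c(size, seed)`: a seeded random subset of
#'   points used to keep the pair count tractable on full imaging layers.
#' @return A tibble of class `empirical_variogram` with columns `lag`
#'   (bin centre), `gamma`, `n_pairs`; attributes `bin_width`, `max_lag`,
#'   `n_points`.
#' @export
empirical_variogram <- function(coords, values, bin_width = 1, max_lag = 64,
                                subsample = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(values), bin_width > 0, max_lag > 0)
  keep <- !is.na(values) & stats::complete.cases(coords)
  coords <- coords[keep, , drop = FALSE]; values <- values[keep]
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (!is.null(subsample) && n > subsample[[1]]) {
    idx <- withr::with_seed(as.integer(subsample[[2]]),
                            sample.int(n, as.integer(subsample[[1]])))
    coords <- coords[idx, , drop = FALSE]; values <- values[idx]
    n <- nrow(coords)
  }
  d <- as.vector(stats::dist(coords))
  dv <- as.vector(stats::dist(values))^2
  sel <- d > 0 & d <= max_lag
  if (!any(sel)) stop("no point pairs within max_lag", call. = FALSE)
  bin <- as.integer(ceiling(d[sel] / bin_width))
  nb <- max(bin)
  cnt <- tabulate(bin, nbins = nb)
  ssq <- as.vector(rowsum(dv[sel], bin, reorder = TRUE))
  bins <- sort(unique(bin))
  out <- tibble::tibble(
    lag = (bins - 0.5) * bin_width,
    gamma = ssq / (2 * cnt[bins]),
    n_pairs = cnt[bins]
  )
  out <- out[order(out$lag), ]
  attr(out, "bin_width") <- bin_width
  attr(out, "max_lag") <- max_lag
  attr(out, "n_points") <- n
  class(out) <- c("empirical_variogram", class(out))
  out
}

normalize_family <- function(f) {
  f <- match.arg(tolower(f), c("exp", "exponential", "sph", "spherical"))
  if (f %in% c("exp", "exponential")) "exp" else "sph"
}

#' Nested isotropic variogram model
#'
#' A nugget plus one or two bounded components.  The exponential component
#' uses the distance-parameter convention `gamma(h) = c (1 - exp(-h/r))`
#' (effective range about `3r`); the spherical component reaches its sill
#' exactly at `h = r`.
#'
#' @param families Character vector (length 1 or 2) of `"exp"` /`"sph"`
#'   (long names accepted).
#' @param sills Positive partial sills, one per component.
#' @param ranges Positive distance parameters, one per component.
#' @param nugget Non-negative nugget variance `c0`.
#' @return An object of class `variogram_model`.
#' @export
#' @examples
#' m <- variogram_model("exp", sills = 1, ranges = 8)
#' model_semivariance(m, c(0, 8, 24))
variogram_model <- function(families, sills, ranges, nugget = 0) {
  families <- vapply(families, normalize_family, "")
  stopifnot(length(families) %in% 1:2,
            length(sills) == length(families),
            length(ranges) == length(families))
  if (nugget < 0 || any(sills <= 0) || any(ranges <= 0)) {
    stop("nugget must be >= 0, sills and ranges > 0", call. = FALSE)
  }
  structure(
    list(nugget = as.numeric(nugget),
         components = data.frame(family = unname(families),
                                 sill = as.numeric(sills),
                                 range = as.numeric(ranges)),
         total_sill = nugget + sum(sills)),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  comps <- paste(sprintf("%s(sill %.4g, range %.4g)", x$components$family,
                         x$components$sill, x$components$range), collapse = " + ")
  cat(sprintf("<variogram_model> nugget %.4g + %s (total sill %.4g)\n",
              x$nugget, comps, x$total_sill))
  invisible(x)
}

#' Model semivariance at lag h
#'
#' `gamma(0) = 0` exactly (including with a nugget); for `h > 0`,
#' `gamma(h) = c0 + sum_i c_i g_i(h / r_i)` with `g(u) = 1 - exp(-u)` for the
#' exponential family and `g(u) = 1.5 u - 0.5 u^3` for `u <= 1`, else 1, for
#' the spherical family.
#'
#' @param model A [variogram_model()].
#' @param h Non-negative lag(s).
#' @return Semivariance(s), same length as `h`.
#' @export
model_semivariance <- function(model, h) {
  if (any(h < 0)) stop("lags must be non-negative", call. = FALSE)
  g <- numeric(length(h))
  dim(g) <- dim(h)
  pos <- h > 0
  if (any(pos)) {
    acc <- rep(model$nugget, sum(pos))
    hp <- h[pos]
    for (ci in seq_len(nrow(model$components))) {
      u <- hp / model$components$range[ci]
      gi <- if (model$components$family[ci] == "exp") {
        1 - exp(-u)
      } else {
        ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3)
      }
      acc <- acc + model$components$sill[ci] * gi
    }
    g[pos] <- acc
  }
  g
}

# semivariance on raw parameters (hot path of the WLS objective: avoids
# constructing a variogram_model per evaluation)
semivar_raw <- function(h, c0, families, sills, ranges) {
  g <- rep(c0, length(h))
  for (ci in seq_along(families)) {
    u <- h / ranges[ci]
    g <- g + sills[ci] *
      (if (families[ci] == "exp") {
        1 - exp(-u)
      } else {
        um <- pmin(u, 1)
        1.5 * um - 0.5 * um^3
      })
  }
  g[h == 0] <- 0
  g
}

# parameter packing for WLS fitting
unpack_model <- function(theta, families, nugget) {
  off <- 0L
  c0 <- 0
  if (nugget) { c0 <- theta[1]; off <- 1L }
  k <- length(families)
  sills <- theta[off + seq_len(k)]
  ranges <- theta[off + k + seq_len(k)]
  variogram_model(families, pmax(sills, 1e-12), pmax(ranges, 1e-9),
                  nugget = max(c0, 0))
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes `sum_b w_b (gamma_emp - gamma_model)^2` over the model
#' parameters with weights `w_b` equal to the pair counts, by multistart
#' Levenberg-Marquardt.
#'
#' @param emp An [empirical_variogram()].
#' @param families Component families, e.g. `"exp"` or `c("exp", "sph")`.
#' @param nugget Fit a nugget parameter?
#' @param n_starts Number of deterministic starting points per range scale.
#' @return A list of class `variogram_fit`: `model`, `rss` (weighted), `p`
#'   (free parameters), `n_bins`, `converged`.
#' @export
fit_variogram <- function(emp, families = "exp", nugget = FALSE, n_starts = 4L) {
  families <- vapply(families, normalize_family, "")
  k <- length(families)
  p <- 2L * k + as.integer(nugget)
  nb <- nrow(emp)
  if (nb <= p) {
    stop(sprintf("under-determined fit: %d lag bins for %d parameters", nb, p),
         call. = FALSE)
  }
  w <- sqrt(emp$n_pairs)
  resid_fn <- function(theta) {
    off <- as.integer(nugget)
    w * (emp$gamma - semivar_raw(emp$lag, if (nugget) max(theta[1], 0) else 0,
                                 families,
                                 pmax(theta[off + seq_len(k)], 1e-12),
                                 pmax(theta[off + k + seq_len(k)], 1e-9)))
  }
  s_tot <- max(emp$gamma)
  if (s_tot <= 0) {
    # constant field: all semivariances zero; degenerate flat model
    m <- variogram_model(families, rep(1e-12, k), rep(1, k), nugget = 0)
    return(structure(list(model = m, rss = 0, p = p, n_bins = nb, converged = TRUE),
                     class = "variogram_fit"))
  }
  max_lag <- max(emp$lag)
  range_scales <- max_lag * c(0.05, 0.15, 0.35, 0.7)[seq_len(min(n_starts, 4L))]
  starts <- list()
  for (r1 in range_scales) {
    if (k == 1L) {
      starts <- c(starts, list(c(if (nugget) 0.1 * s_tot, s_tot, r1)))
    } else {
      for (r2 in range_scales[range_scales > r1]) {
        starts <- c(starts, list(c(if (nugget) 0.1 * s_tot,
                                   rep(s_tot / 2, 2), r1, r2)))
      }
      starts <- c(starts, list(c(if (nugget) 0.1 * s_tot, rep(s_tot / 2, 2),
                                 r1, r1 * 2)))
    }
  }
  lower <- c(if (nugget) 0, rep(1e-12, k), rep(1e-6, k))
  upper <- c(if (nugget) 2 * s_tot, rep(5 * s_tot, k), rep(20 * max_lag, k))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("variogram fit failed to converge from all starts", call. = FALSE)
  structure(
    list(model = unpack_model(best$fit$par, families, nugget),
         rss = best$rss, p = p, n_bins = nb,
         converged = best$fit$info %in% 1:4),
    class = "variogram_fit"
  )
}

#' @export
print.variogram_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  weighted RSS %.6g over %d bins (%d parameters)\n",
              x$rss, x$n_bins, x$p))
  invisible(x)
}

#' Default candidate set for variogram model selection
#'
#' Single and nested exponential/spherical structures, each with and without
#' a nugget.
#'
#' @return A named list of candidate specifications
#'   (`list(families, nugget)`).
#' @export
default_variogram_candidates <- function() {
  fams <- list(exp = "exp", sph = "sph",
               `exp+exp` = c("exp", "exp"), `sph+sph` = c("sph", "sph"),
               `exp+sph` = c("exp", "sph"))
  out <- list()
  for (nm in names(fams)) {
    out[[nm]] <- list(families = fams[[nm]], nugget = FALSE)
    out[[paste0(nm, "+nug")]] <- list(families = fams[[nm]], nugget = TRUE)
  }
  out
}

#' Select a variogram model by AIC
#'
#' Fits every candidate by [fit_variogram()] and ranks them by
#' `AIC = n ln(rss / n) + 2 p` (`n` lag bins, `p` free parameters; constant
#' terms dropped).  Candidates that fail to fit are skipped with a warning.
#'
#' @param emp An [empirical_variogram()].
#' @param candidates Named list of `list(families, nugget)` specifications;
#'   defaults to [default_variogram_candidates()].
#' @return List with `model` (the winner), `fit` (its `variogram_fit`), and
#'   `table` (a tibble with one row per candidate: `candidate`, `p`, `rss`,
#'   `aic`, `converged`).
#' @export
aic_select <- function(emp, candidates = default_variogram_candidates()) {
  stopifnot(length(candidates) >= 1L)
  rows <- list(); fits <- list()
  for (nm in names(candidates)) {
    spec <- candidates[[nm]]
    fit <- tryCatch(
      fit_variogram(emp, families = spec$families, nugget = isTRUE(spec$nugget)),
      error = function(e) {
        warning("candidate '", nm, "' skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(fit)) next
    n <- fit$n_bins
    aic <- n * log(max(fit$rss, 1e-300) / n) + 2 * fit$p
    rows[[nm]] <- tibble::tibble(candidate = nm, p = fit$p, rss = fit$rss,
                                 aic = aic, converged = fit$converged)
    fits[[nm]] <- fit
  }
  if (length(fits) == 0L) stop("all variogram candidates failed to fit", call. = FALSE)
  tab <- dplyr::bind_rows(rows)
  ord <- order(tab$aic, tab$p)
  winner <- tab$candidate[ord[1]]
  list(model = fits[[winner]]$model, fit = fits[[winner]],
       table = tab[ord, ], selected = winner)
}

#' Export fitted variogram model(s) as JSON
#'
#' @param model A [variogram_model()] or named list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variogram_json <- function(model, path) {
  as_rec <- function(m) list(
    c0 = m$nugget,
    components = lapply(seq_len(nrow(m$components)), function(i) {
      list(family = m$components$family[i], sill = m$components$sill[i],
           range = m$components$range[i])
    })
  )
  rec <- if (inherits(model, "variogram_model")) as_rec(model) else lapply(model, as_rec)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
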