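#' Tidy a fitted variogram model
#'
#' One row per structure (nugget included when positive).
#'
#' @param x A [variogram_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `family`, `sill`, `range`.
#' @method tidy variogram_model
#' @export
tidy.variogram_model <- function(x, ...) {
  rows <- tibble::tibble(
    term = paste0("comp", seq_len(nrow(x$components))),
    family = x$components$family,
    sill = x$components$sill,
    range = x$components$range
  )
  if (x$nugget > 0) {
    rows <- dplyr::bind_rows(
      tibble::tibble(term = "nugget", family = "nugget", sill = x$nugget,
                     range = NA_real_), rows)
  }
  rows
}

#' @rdname tidy.variogram_model
#' @method tidy variogram_fit
#' @export
tidy.variogram_fit <- function(x, ...) tidy(x$model)

#' One-line fit summary of a variogram fit
#'
#' @param x A `variogram_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `rss`, `p`, `n_bins`, `total_sill`, `converged`.
#' @method glance variogram_fit
#' @export
glance.variogram_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, p = x$p, n_bins = x$n_bins,
                 total_sill = x$model$total_sill, converged = x$converged)
}

#' Tidy a fitted regression tree
#'
#' One row per leaf with its intensity interval and mean.
#'
#' @param x An `rtk_tree`.
#' @param ... Unused.
#' @return A tibble: `leaf`, `gray_from`, `gray_to`, `mean`, `n`.
#' @method tidy rtk_tree
#' @export
tidy.rtk_tree <- function(x, ...) {
  edges <- c(-Inf, x$thresholds, Inf)
  tibble::tibble(
    leaf = seq_along(x$leaf_means),
    gray_from = edges[-length(edges)],
    gray_to = edges[-1],
    mean = x$leaf_means,
    n = x$leaf_counts
  )
}

#' @rdname tidy.rtk_tree
#' @method glance rtk_tree
#' @export
glance.rtk_tree <- function(x, ...) {
  tibble::tibble(leaves = length(x$leaf_means), n = x$n,
                 pruned = isTRUE(x$cfg$prune))
}

#' Tidy an RTK model
#'
#' @param x An `rtk_model` from [fit_rtk()].
#' @param ... Unused.
#' @return A one-row tibble summarising trend and residual structure.
#' @method glance rtk_model
#' @export
glance.rtk_model <- function(x, ...) {
  tibble::tibble(
    element = x$element, leaves = length(x$tree$leaf_means),
    trend_only = x$trend_only,
    variogram = if (is.null(x$variogram_selection)) NA_character_
                else x$variogram_selection$candidate[1],
    total_sill = if (is.null(x$variogram)) NA_real_ else x$variogram$total_sill,
    spacing = if (is.null(x$spacing)) NA_integer_ else as.integer(x$spacing),
    layer_gap = x$lower_z - x$upper_z
  )
}

#' Tidy cross-validation results
#'
#' @param x An `rtk_cv` from [cross_validate()].
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @method tidy rtk_cv
#' @export
tidy.rtk_cv <- function(x, ...) x$metrics

#' @rdname tidy.rtk_cv
#' @method glance rtk_cv
#' @export
glance.rtk_cv <- function(x, ...) x$summary
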