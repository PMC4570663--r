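#' Plot an empirical variogram, optionally with fitted models
#'
#' @param object An [empirical_variogram()].
#' @param models Optional named list of [variogram_model()]s to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot empirical_variogram
#' @export
autoplot.empirical_variogram <- function(object, models = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "lag h (voxels)", y = expression(gamma(h)),
                  title = "Empirical semivariance") +
    ggplot2::theme_minimal()
  if (!is.null(models)) {
    if (inherits(models, "variogram_model")) models <- list(fitted = models)
    hh <- seq(0, max(object$lag), length.out = 200)
    curves <- purrr::imap_dfr(models, function(m, nm) {
      tibble::tibble(model = nm, lag = hh, gamma = model_semivariance(m, hh))
    })
    p <- p + ggplot2::geom_line(
      data = curves, ggplot2::aes(colour = .data$model), linewidth = 0.7)
  }
  p
}

#' Plot a kriging-variance profile against grid spacing
#'
#' The characteristic U-shape: very dense grids are redundant, very coarse
#' grids are distant from the target.
#'
#' @param object A [kriging_variance_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kriging_profile
#' @export
autoplot.kriging_profile <- function(object, ...) {
  best <- optimize_grid_spacing(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$spacing, y = .data$variance)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "grid spacing (voxels)", y = "kriging variance",
                  title = sprintf("Two-layer grid: minimum at spacing %d", best)) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation error measures by method
#'
#' @param object An `rtk_cv` from [cross_validate()].
#' @param measure `"rmse"` or `"r2"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rtk_cv
#' @export
autoplot.rtk_cv <- function(object, measure = c("rmse", "r2"), ...) {
  measure <- match.arg(measure)
  df <- object$metrics
  df$value <- df[[measure]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$fold), alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = NULL, y = toupper(measure),
                  title = "Leave-middle-layer-out validation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
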