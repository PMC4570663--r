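#' Fit a regression tree of concentration on CT grayscale
#'
#' The deterministic trend of the regression-kriging decomposition: a CART
#' regression tree with the single grayscale covariate, i.e. a
#' piecewise-constant step function of intensity.  Splitting minimizes the
#' within-leaf sum of squares; with pruning enabled, the subtree is chosen by
#' seeded k-fold cross-validated cost-complexity pruning with the 1-SE rule.
#' The fitted tree is reduced to its canonical form for a single covariate:
#' strictly increasing split thresholds and one mean per intensity interval
#' (values at a threshold go to the right leaf, i.e. the split is
#' `gray < t` vs `gray >= t`).
#'
#' @param gray Numeric vector of grayscale intensities.
#' @param conc Numeric vector of concentrations, same length.
#' @param min_leaf Minimum training points per leaf (default 50).
#' @param max_leaves Optional cap on the number of leaves.
#' @param prune Apply cost-complexity pruning (default `TRUE`).
#' @param cv_folds Cross-validation folds for pruning (default 5).
#' @param seed Seed controlling the CV fold assignment (default 1).
#' @return An object of class `rtk_tree`: `thresholds`, `leaf_means`,
#'   `leaf_counts`, `n`, `cp_table` (pruning record), `cfg`.
#' @export
fit_tree <- function(gray, conc, min_leaf = 50L, max_leaves = NULL,
                     prune = TRUE, cv_folds = 5L, seed = 1L) {
  stopifnot(length(gray) == length(conc))
  keep <- !(is.na(gray) | is.na(conc))
  gray <- gray[keep]; conc <- conc[keep]
  n <- length(gray)
  if (n < 2L * min_leaf) {
    stop(sprintf("too few training points (%d) for min_leaf = %d", n, min_leaf),
         call. = FALSE)
  }
  if (stats::var(gray) == 0 && stats::var(conc) > 0) {
    warning("grayscale is constant: fitting a single-leaf tree", call. = FALSE)
  }
  df <- data.frame(gray = gray, conc = conc)
  ctrl <- rpart::rpart.control(
    minbucket = as.integer(min_leaf),
    minsplit = 2L * as.integer(min_leaf),
    cp = 0, xval = if (prune) as.integer(cv_folds) else 0L,
    maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L
  )
  fit <- withr::with_seed(as.integer(seed),
                          rpart::rpart(conc ~ gray, data = df, method = "anova",
                                       control = ctrl))
  cp_table <- fit$cptable
  if (prune && !is.null(cp_table) && nrow(cp_table) > 1L) {
    xerr <- cp_table[, "xerror"]
    best <- which.min(xerr)
    thr <- xerr[best] + cp_table[best, "xstd"]
    chosen <- which(xerr <= thr)[1]  # simplest subtree within one SE
    fit <- rpart::prune(fit, cp = cp_table[chosen, "CP"] * 1.0000001)
  }
  thresholds <- sort(tree_split_points(fit))
  if (!is.null(max_leaves) && length(thresholds) + 1L > max_leaves) {
    # tighten cp until the leaf budget is met
    for (i in rev(seq_len(nrow(cp_table)))) {
      if (cp_table[i, "nsplit"] + 1 <= max_leaves) {
        fit <- rpart::prune(fit, cp = cp_table[i, "CP"] * 1.0000001)
        thresholds <- sort(tree_split_points(fit))
        break
      }
    }
  }
  leaf <- findInterval(gray, thresholds) + 1L
  leaf_means <- vapply(seq_len(length(thresholds) + 1L),
                       function(l) mean(conc[leaf == l]), 0)
  leaf_counts <- tabulate(leaf, nbins = length(thresholds) + 1L)
  structure(
    list(thresholds = thresholds, leaf_means = leaf_means,
         leaf_counts = leaf_counts, n = n, cp_table = cp_table,
         cfg = list(min_leaf = min_leaf, max_leaves = max_leaves,
                    prune = prune, cv_folds = cv_folds, seed = seed)),
    class = "rtk_tree"
  )
}

# primary split values of an rpart tree grown on a single covariate
tree_split_points <- function(fit) {
  if (is.null(fit$splits) || nrow(fit$splits) == 0L) return(numeric(0))
  unname(fit$splits[, "index"])
}

#' @export
print.rtk_tree <- function(x, ...) {
  cat(sprintf("<rtk_tree> %d leaves on %d points\n", length(x$leaf_means), x$n))
  if (length(x$thresholds)) {
    edges <- c(-Inf, x$thresholds, Inf)
    for (l in seq_along(x$leaf_means)) {
      cat(sprintf("  gray in [%s, %s): mean %.4g  (n = %d)\n",
                  format(edges[l]), format(edges[l + 1]), x$leaf_means[l],
                  x$leaf_counts[l]))
    }
  } else {
    cat(sprintf("  constant %.4g\n", x$leaf_means[1]))
  }
  invisible(x)
}

#' Predict concentrations from a fitted tree
#'
#' Each grayscale value maps to the mean of its intensity interval; values at
#' a threshold go right, values beyond the extreme thresholds map to the
#' extreme leaves.
#'
#' @param object An `rtk_tree`.
#' @param gray Numeric vector (or matrix/array) of intensities.
#' @param ... Unused.
#' @return Predictions with the shape of `gray`.
#' @export
predict.rtk_tree <- function(object, gray, ...) {
  out <- object$leaf_means[findInterval(as.vector(gray), object$thresholds) + 1L]
  if (!is.null(dim(gray))) dim(out) <- dim(gray)
  out
}

#' Trend residuals of a fitted tree
#'
#' @param object An `rtk_tree`.
#' @param gray,conc Evaluation data.
#' @param ... Unused.
#' @return `conc - predict(object, gray)`.
#' @export
residuals.rtk_tree <- function(object, gray, conc, ...) {
  conc - predict(object, gray)
}

#' Serialize a fitted tree as JSON
#'
#' @param tree An `rtk_tree`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(
    list(thresholds = tree$thresholds, leaf_means = tree$leaf_means,
         cfg = tree$cfg),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
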