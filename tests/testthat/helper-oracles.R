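# Independent oracles used across the suite.  Each deliberately avoids the
# package's production code path for the quantity it checks.

# Brute-force ordinary kriging: numerically minimize the unbiased prediction
# error variance  2 sum_i w_i g(x_i, x0) - sum_ij w_i w_j g(x_i, x_j)  over
# weights summing to 1 (last weight substituted out), by Nelder-Mead/BFGS.
ok_bruteforce <- function(coords, values, model, target) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G[i, j] <- model_semivariance(model, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  }
  g0 <- vapply(seq_len(n), function(i) {
    model_semivariance(model, sqrt(sum((coords[i, ] - target)^2)))
  }, 0)
  obj <- function(wfree) {
    w <- c(wfree, 1 - sum(wfree))
    2 * sum(w * g0) - as.numeric(t(w) %*% G %*% w)
  }
  if (n == 1L) {
    w <- 1
  } else {
    fit <- stats::optim(rep(1 / n, n - 1L), obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    w <- c(fit$par, 1 - sum(fit$par))
  }
  list(prediction = sum(w * values), variance = obj(w[-n]), weights = w)
}

# Exhaustive-split greedy regression tree on a single covariate: at every
# node, try all midpoints between adjacent distinct covariate values and
# take the SSE-minimizing admissible split.  Returns sorted thresholds.
tree_oracle <- function(gray, conc, min_leaf = 1L) {
  splits <- c()
  recurse <- function(idx) {
    g <- gray[idx]; v <- conc[idx]
    ug <- sort(unique(g))
    if (length(ug) < 2L || length(idx) < 2L * min_leaf) return()
    cand <- (head(ug, -1) + tail(ug, -1)) / 2
    base <- sum((v - mean(v))^2)
    best <- NULL
    for (t in cand) {
      l <- g < t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      sse <- sum((v[l] - mean(v[l]))^2) + sum((v[!l] - mean(v[!l]))^2)
      if (is.null(best) || sse < best$sse) best <- list(t = t, sse = sse)
    }
    if (is.null(best) || best$sse >= base - 1e-12) return()
    splits <<- c(splits, best$t)
    recurse(idx[g < best$t])
    recurse(idx[g >= best$t])
  }
  recurse(seq_along(gray))
  sort(splits)
}

oracle_tree_predict <- function(thresholds, gray_train, conc_train, gray_new) {
  leaf_tr <- findInterval(gray_train, thresholds) + 1L
  means <- vapply(seq_len(length(thresholds) + 1L),
                  function(l) mean(conc_train[leaf_tr == l]), 0)
  means[findInterval(gray_new, thresholds) + 1L]
}

# Direct (non-FFT) alignment search over the full discrete grid.
align_oracle <- function(volume, maps, a_vals, b_vals, k0_vals, plane_shape,
                         crop_shape) {
  center <- plane_shape %/% 2L
  joint <- Reduce(`&`, lapply(maps, function(m) !is.na(unclass(m))))
  best <- NULL
  n_or <- plane_shape[1] - crop_shape[1] + 1L
  n_oc <- plane_shape[2] - crop_shape[2] + 1L
  for (a in a_vals) for (b in b_vals) for (k0 in k0_vals) {
    plane <- tryCatch(
      reconstruct_plane(volume, a, b, k0, center, plane_shape),
      error = function(e) NULL
    )
    if (is.null(plane)) next
    for (or in seq_len(n_or)) for (oc in seq_len(n_oc)) {
      win <- plane[or + seq_len(crop_shape[1]) - 1L,
                   oc + seq_len(crop_shape[2]) - 1L]
      sc <- 0
      ok <- TRUE
      for (m in maps) {
        x <- win[joint]; y <- unclass(m)[joint]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) { ok <- FALSE; break }
        sc <- sc + abs(stats::cor(x, y))
      }
      if (!ok) next
      cand <- list(score = sc, a = a, b = b, k0 = k0, off = c(or, oc))
      if (is.null(best) ||
          sc > best$score ||
          (sc == best$score && abs(a) + abs(b) < abs(best$a) + abs(best$b)) ||
          (sc == best$score && abs(a) + abs(b) == abs(best$a) + abs(best$b) &&
           k0 < best$k0)) {
        best <- cand
      }
    }
  }
  best
}

# small deterministic test volume with visible structure
make_test_volume <- function(dim = c(48, 48, 48), seed = 42) {
  simulate_soil_volume(dim, correlation_range = 4, seed = seed)
}

# identity-trend maps from a plane window (the extracted slice itself as map)
identity_maps <- function(window, noise_sd = 0, seed = 1) {
  w <- window
  if (noise_sd > 0) {
    w <- w + withr::with_seed(seed, matrix(rnorm(length(w), 0, noise_sd),
                                           nrow(w), ncol(w)))
  }
  list(G = element_map(pmax(w, 0), "G"))
}
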