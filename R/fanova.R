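#' Smoothing specification for rating curves
#'
#' Individual rating trajectories are smoothed by local polynomial
#' regression before group mean functions are formed. Local linear fits
#' (degree 1) are the default: they reproduce linear trends exactly and
#' behave well at the curve ends.
#'
#' @param degree Local polynomial degree, 0, 1 or 2.
#' @param kernel Weight kernel, `"epanechnikov"` (compact support) or
#'   `"gaussian"`.
#' @param bandwidth Bandwidth in seconds, or `"auto"` for leave-one-out
#'   cross-validation via [select_bandwidth()].
#' @return A `smoothing_spec` list.
#' @export
smoothing_spec <- function(degree = 1, kernel = c("epanechnikov", "gaussian"),
                           bandwidth = "auto") {
  kernel <- match.arg(kernel)
  if (!degree %in% 0:2) {
    stopf("config_error", "degree must be 0, 1 or 2")
  }
  if (is.numeric(bandwidth) && bandwidth <= 0) {
    stopf("config_error", "bandwidth must be positive")
  }
  structure(list(degree = degree, kernel = kernel, bandwidth = bandwidth),
            class = "smoothing_spec")
}

#' Bootstrap specification for the functional ANOVA
#'
#' @param B Number of bootstrap resamples (at least 99; default 1000).
#' @param seed Optional RNG seed; with a seed the test is fully
#'   deterministic.
#' @param scheme Resampling scheme. Only within-group residual-curve
#'   resampling is provided: whole residual curves are drawn with
#'   replacement within each group, which preserves each curve's
#'   autocorrelation and each group's dispersion (the heteroscedasticity
#'   contract).
#' @return A `bootstrap_spec` list.
#' @export
bootstrap_spec <- function(B = 1000, seed = NULL,
                           scheme = "within_group_residual") {
  scheme <- match.arg(scheme)
  if (B < 99) {
    stopf("config_error", "B must be >= 99 (got %d)", B)
  }
  structure(list(B = as.integer(B), seed = seed, scheme = scheme),
            class = "bootstrap_spec")
}

kernel_weights <- function(u, kernel) {
  switch(kernel,
         epanechnikov = ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0),
         gaussian = exp(-u^2 / 2))
}

# Linear smoother matrix for local polynomial regression evaluated on the
# design grid itself. Cached: the battery smooths thousands of curve sets on
# a handful of (grid, bandwidth) combinations.
smoother_cache <- new.env(parent = emptyenv())

locpoly_smoother <- function(t, h, degree, kernel) {
  key <- paste(length(t), t[1], t[length(t)], h, degree, kernel, sep = "|")
  hit <- smoother_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(t)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    u <- (t - t[i]) / h
    w <- kernel_weights(u, kernel)
    active <- w > 0
    if (sum(active) < degree + 1) {
      stopf("bandwidth_too_small_error",
            "bandwidth %.3g leaves %d point(s) in the window at t=%g; need %d",
            h, sum(active), t[i], degree + 1)
    }
    X <- outer(t - t[i], 0:degree, `^`)
    XtW <- t(X * w)
    # first row of (X'WX)^{-1} X'W is the local fit's value at t[i]
    S[i, ] <- solve(XtW %*% X, XtW)[1, ]
  }
  smoother_cache[[key]] <- S
  S
}

resolve_bandwidth <- function(curves, t, spec) {
  if (identical(spec$bandwidth, "auto")) select_bandwidth(curves, t, spec)
  else spec$bandwidth
}

#' Smooth a rating series by local polynomial regression
#'
#' Weighted local least-squares fit of the configured degree, evaluated at
#' each grid point. Exact on globally polynomial inputs of the same degree
#' (a linear series passes through unchanged under the default local linear
#' fit).
#'
#' @param values Numeric series (or a T x k matrix of series in columns).
#' @param time_s Time grid in seconds.
#' @param spec A [smoothing_spec()].
#' @return Smoothed values, same shape as `values`.
#' @export
smooth_local_poly <- function(values, time_s, spec = smoothing_spec()) {
  m <- as.matrix(values)
  if (nrow(m) < 5) {
    stopf("structural_error", "need >= 5 grid points to smooth")
  }
  step <- min(diff(time_s))
  h <- resolve_bandwidth(m, time_s, spec)
  if (h < step) {
    stopf("bandwidth_too_small_error",
          "bandwidth %.3g below the grid step %.3g", h, step)
  }
  S <- locpoly_smoother(time_s, h, spec$degree, spec$kernel)
  out <- S %*% m
  if (is.matrix(values)) out else drop(out)
}

# Log-spaced candidates from just above the grid step to one-eighth of the
# observation window. The cap matters: on curves whose mean is featureless
# the CV criterion decreases in h indefinitely, so whatever cap exists is
# selected, and smoothing beyond ~T/8 visibly flattens the localized
# (seconds-scale) group differences the test is meant to detect. Estimation-
# optimal smoothing is not test-optimal; the bootstrap calibration absorbs
# the variance that mild undersmoothing leaves in.
default_bandwidth_candidates <- function(t, n = 10) {
  step <- min(diff(t))
  lo <- 1.5 * step
  hi <- max(diff(range(t)) / 8, lo * 2)
  exp(seq(log(lo), log(hi), length.out = n))
}

# Cross-validation predictor matrix: row i predicts the value at t[i] from
# a local polynomial fit that excludes every observation within `block`
# seconds of t[i]. block = 0 is classical leave-one-out; a positive block
# is leave-block-out CV, the standard guard against undersmoothing when
# errors are serially correlated (neighbouring seconds would otherwise
# "predict" the held-out noise, driving the bandwidth toward zero).
locpoly_cv_predictor <- function(t, h, degree, kernel, block) {
  key <- paste("cv", length(t), t[1], t[length(t)], h, degree, kernel,
               block, sep = "|")
  hit <- smoother_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(t)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    u <- (t - t[i]) / h
    w <- kernel_weights(u, kernel)
    w[abs(t - t[i]) <= block] <- 0
    if (sum(w > 0) < degree + 1) {
      stopf("bandwidth_too_small_error",
            "bandwidth %.3g leaves %d point(s) outside the held-out block at t=%g",
            h, sum(w > 0), t[i])
    }
    X <- outer(t - t[i], 0:degree, `^`)
    XtW <- t(X * w)
    S[i, ] <- solve(XtW %*% X, XtW)[1, ]
  }
  smoother_cache[[key]] <- S
  S
}

#' Select a shared smoothing bandwidth by cross-validation
#'
#' Each curve's squared prediction error is evaluated over a log-spaced
#' candidate grid by leave-block-out cross-validation: the local fit
#' predicting second `t` omits all observations within `block` seconds of
#' `t` (with `block = 0` this is classical leave-one-out). Rating noise is
#' serially correlated over a few seconds, and plain LOO then selects
#' near-interpolating bandwidths; excluding the correlated neighbourhood
#' restores a sensible bias-variance trade-off. Each curve votes for its
#' optimal candidate (ties broken toward the smallest), and the lower
#' median of the per-curve optima is returned so that all curves of one
#' stimulus x dimension share a bandwidth and their smoothed means are
#' comparable. Candidates too small to leave enough points outside the
#' held-out block are infeasible and skipped.
#'
#' @param curves T x k matrix of curves (columns) or a single series.
#' @param time_s Time grid in seconds.
#' @param spec A [smoothing_spec()] (degree and kernel are honoured).
#' @param candidates Optional bandwidth candidates in seconds.
#' @param block Half-width in seconds of the held-out neighbourhood
#'   (default 3).
#' @return Selected bandwidth in seconds.
#' @export
select_bandwidth <- function(curves, time_s, spec = smoothing_spec(),
                             candidates = NULL, block = 3) {
  m <- as.matrix(curves)
  candidates <- sort(candidates %||% default_bandwidth_candidates(time_s))
  cv <- matrix(NA_real_, length(candidates), ncol(m))
  for (j in seq_along(candidates)) {
    h <- candidates[j]
    S <- tryCatch(
      locpoly_cv_predictor(time_s, h, spec$degree, spec$kernel, block),
      affectfanova_error = function(e) NULL)
    if (is.null(S)) next
    resid <- m - S %*% m
    cv[j, ] <- colMeans(resid^2)
  }
  if (all(is.na(cv))) {
    stopf("config_error", "no bandwidth candidate satisfies the fit preconditions")
  }
  # per-curve optimum with an absolute tolerance so exact ties (e.g. all
  # candidates perfect on a linear curve) resolve to the smallest bandwidth
  opt <- apply(cv, 2, function(x) {
    candidates[which(x <= min(x, na.rm = TRUE) + 1e-12)[1]]
  })
  sort(opt)[ceiling(length(opt) / 2)]
}

# quadrature weights for the trapezoid rule on a fixed grid
trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  dt <- diff(t)
  w[-n] <- w[-n] + dt / 2
  w[-1] <- w[-1] + dt / 2
  w
}

check_groups <- function(groups) {
  if (length(groups) < 2) {
    stopf("structural_error", "need at least 2 groups")
  }
  Ts <- vapply(groups, nrow, integer(1))
  if (length(unique(Ts)) > 1) {
    stopf("structural_error", "groups are on different grids (lengths %s)",
          paste(unique(Ts), collapse = ", "))
  }
  ns <- vapply(groups, ncol, integer(1))
  if (any(ns < 2)) {
    stopf("structural_error", "every group needs >= 2 curves")
  }
  invisible(ns)
}

cvm_from_means <- function(means, ns, w) {
  k <- length(means)
  C <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- means[[i]] - means[[j]]
      C <- C + ns[i] * ns[j] / (ns[i] + ns[j]) * sum(w * d^2)
    }
  }
  C
}

#' Cramér-von Mises statistic between group mean curves
#'
#' Each group's curves are smoothed and averaged into an estimated mean
#' function; the statistic is the sample-size-weighted integrated squared
#' difference between group means, summed over group pairs:
#' `C = sum_{i<j} n_i n_j / (n_i + n_j) * int (m_i(t) - m_j(t))^2 dt`,
#' with the integral taken by the trapezoid rule on the observation grid.
#' With two groups this is the familiar two-sample form. The statistic is
#' nonnegative and symmetric in the groups.
#'
#' @param groups List of two or more T x n_g matrices of curves on a shared
#'   grid (columns are participants).
#' @param time_s Time grid in seconds.
#' @param smoothing A [smoothing_spec()]; pass `smooth = FALSE` to use the
#'   curves as-is.
#' @param smooth Smooth the curves before averaging (default `TRUE`).
#' @return Scalar statistic `C >= 0`.
#' @export
cvm_statistic <- function(groups, time_s, smoothing = smoothing_spec(),
                          smooth = TRUE) {
  ns <- check_groups(groups)
  if (smooth) {
    h <- resolve_bandwidth(do.call(cbind, groups), time_s, smoothing)
    spec <- smoothing_spec(smoothing$degree, smoothing$kernel, h)
    groups <- lapply(groups, smooth_local_poly, time_s = time_s, spec = spec)
  }
  w <- trapz_weights(time_s)
  cvm_from_means(lapply(groups, rowMeans), ns, w)
}

#' Functional ANOVA by Cramér-von Mises statistic and functional bootstrap
#'
#' Tests equality of the group mean functions. The observed statistic is
#' computed by [cvm_statistic()]. Its null distribution is approximated by
#' functional bootstrap: each curve's residual (raw curve minus its own
#' group's smoothed mean) is a zero-mean-function curve; resampling whole
#' residual curves with replacement within each group, re-smoothing at the
#' originally selected bandwidth and recomputing the statistic yields
#' resamples `C*` whose distribution mimics the null. Resampling within
#' groups preserves group-specific dispersion, so the test remains valid
#' under heteroscedasticity. The p-value is
#' `(1 + #\{C* >= C\}) / (B + 1)`, so it is always at least `1/(B+1)`.
#'
#' @param groups List (optionally named) of two or more T x n_g curve
#'   matrices on a shared grid.
#' @param time_s Time grid in seconds.
#' @param smoothing A [smoothing_spec()].
#' @param bootstrap A [bootstrap_spec()].
#' @return A `fanova_test` object: list with `statistic`, `p_value`,
#'   `n_bootstrap`, `bandwidth`, `seed`, `group_sizes` and the bootstrap
#'   replicates `boot_stats`.
#' @export
functional_bootstrap_test <- function(groups, time_s,
                                      smoothing = smoothing_spec(),
                                      bootstrap = bootstrap_spec()) {
  ns <- check_groups(groups)
  h <- resolve_bandwidth(do.call(cbind, groups), time_s, smoothing)
  spec <- smoothing_spec(smoothing$degree, smoothing$kernel, h)
  S <- locpoly_smoother(time_s, h, spec$degree, spec$kernel)
  w <- trapz_weights(time_s)

  smoothed <- lapply(groups, function(g) S %*% g)
  means <- lapply(smoothed, rowMeans)
  C_obs <- cvm_from_means(means, ns, w)

  # smoothed residual curves: smoothing is linear, so re-smoothing the
  # resampled raw residuals equals resampling these precomputed columns.
  # Residuals are re-centered within group: subtracting the *smoothed* mean
  # leaves the rough part of the group mean in every residual, and that
  # common offset would inflate all bootstrap replicates alike.
  # the sqrt(n/(n-1)) factor undoes the variance deflation of centred
  # residuals, the usual finite-sample correction in residual bootstraps
  sm_resid <- mapply(function(g, m) {
    E <- S %*% (g - m)
    (E - rowMeans(E)) * sqrt(ncol(E) / (ncol(E) - 1))
  }, groups, means, SIMPLIFY = FALSE)

  run <- function() {
    vapply(seq_len(bootstrap$B), function(b) {
      m_star <- mapply(function(E, n) rowMeans(E[, sample.int(n, replace = TRUE),
                                                 drop = FALSE]),
                       sm_resid, ns, SIMPLIFY = FALSE)
      cvm_from_means(m_star, ns, w)
    }, numeric(1))
  }
  boot_stats <- if (is.null(bootstrap$seed)) run() else
    with_seed(bootstrap$seed, run())

  structure(
    list(statistic = C_obs,
         p_value = (1 + sum(boot_stats >= C_obs)) / (bootstrap$B + 1),
         n_bootstrap = bootstrap$B,
         bandwidth = h,
         seed = bootstrap$seed,
         group_sizes = ns,
         boot_stats = boot_stats),
    class = "fanova_test")
}

#' @export
print.fanova_test <- function(x, ...) {
  cat("Functional ANOVA (Cramér-von Mises statistic, functional bootstrap)\n")
  cat(sprintf("  groups: %s\n", paste(x$group_sizes, collapse = " / ")))
  cat(sprintf("  C = %.4g, bandwidth = %.3g s, B = %d\n",
              x$statistic, x$bandwidth, x$n_bootstrap))
  cat(sprintf("  p = %.4g (minimum attainable %.4g)\n",
              x$p_value, 1 / (x$n_bootstrap + 1)))
  invisible(x)
}
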