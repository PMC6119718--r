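#' Normalize raw ratings to the [-1, 1] emotion-space scale
#'
#' Raw 2D rating devices report screen or slider coordinates; analysis uses
#' a continuous scale from -1 to 1 with 0 as the neutral point. The map is
#' affine: `v' = 2 (v - raw_min) / (raw_max - raw_min) - 1`.
#'
#' @param values Numeric vector within `[raw_min, raw_max]`.
#' @param raw_min,raw_max The device's coordinate range.
#' @return Values rescaled to `[-1, 1]`.
#' @export
normalize_ratings <- function(values, raw_min, raw_max) {
  if (raw_max <= raw_min) {
    stopf("degenerate_range_error",
          "degenerate raw range [%s, %s]", raw_min, raw_max)
  }
  if (any(values < raw_min | values > raw_max, na.rm = TRUE)) {
    stopf("range_error", "values outside the declared raw range [%s, %s]",
          raw_min, raw_max)
  }
  2 * (values - raw_min) / (raw_max - raw_min) - 1
}

#' Invert [normalize_ratings()]
#' @inheritParams normalize_ratings
#' @export
denormalize_ratings <- function(values, raw_min, raw_max) {
  (values + 1) / 2 * (raw_max - raw_min) + raw_min
}

#' Pointwise mean curve across participants
#'
#' The central tendency of the individual valence/arousal trajectories is the
#' arithmetic mean across participants at each second.
#'
#' @param curves A T x k matrix (one column per participant) as returned by
#'   [rating_curves()], or a list of equal-length numeric vectors.
#' @return Numeric vector of length T.
#' @export
mean_curve <- function(curves) {
  if (is.list(curves)) {
    len <- lengths(curves)
    if (length(unique(len)) > 1) {
      stopf("structural_error", "series lengths differ: %s",
            paste(unique(len), collapse = ", "))
    }
    curves <- do.call(cbind, curves)
  }
  rowMeans(curves)
}

#' Classify a valence/arousal point into an emotion-space quadrant
#'
#' The two-dimensional emotion space is partitioned by sign: Q1 is positive
#' valence and positive arousal, Q2 negative valence / positive arousal, Q3
#' negative/negative, Q4 positive valence / negative arousal. Points with
#' either coordinate exactly 0 sit on an axis and are labelled `"neutral"`
#' rather than silently assigned to a quadrant.
#'
#' @param valence,arousal Numeric vectors in `[-1, 1]`, recycled to a common
#'   length.
#' @return Character vector of `"Q1"`, `"Q2"`, `"Q3"`, `"Q4"` or
#'   `"neutral"`.
#' @export
classify_quadrant <- function(valence, arousal) {
  if (any(abs(valence) > 1, na.rm = TRUE) || any(abs(arousal) > 1, na.rm = TRUE)) {
    stopf("range_error", "coordinates must lie in [-1, 1]")
  }
  n <- max(length(valence), length(arousal))
  valence <- rep_len(valence, n)
  arousal <- rep_len(arousal, n)
  out <- rep("neutral", n)
  out[valence > 0 & arousal > 0] <- "Q1"
  out[valence < 0 & arousal > 0] <- "Q2"
  out[valence < 0 & arousal < 0] <- "Q3"
  out[valence > 0 & arousal < 0] <- "Q4"
  out
}

#' Cronbach's alpha for a panel of rating time series
#'
#' Internal consistency of the participants' trajectories for one stimulus
#' and dimension, treating participants as "items" and time points as cases:
#' `alpha = k/(k-1) * (1 - sum_i Var(column_i) / Var(rowsums))`, with sample
#' variances (denominator T - 1). Alpha is at most 1 but can be negative
#' when raters move in opposite directions; negative values are reported
#' as-is.
#'
#' @param rating_matrix T x k numeric matrix, k >= 2 participants (columns),
#'   T >= 3 time points (rows), no missing values.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(rating_matrix) {
  m <- as.matrix(rating_matrix)
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) {
    stopf("undefined_reliability_error",
          "need >= 2 raters and >= 3 time points, got %d x %d", nrow(m), k)
  }
  if (anyNA(m)) {
    stopf("undefined_reliability_error", "matrix contains missing values")
  }
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    stopf("undefined_reliability_error", "zero total variance across raters")
  }
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Compute the reliability table for a study
#'
#' One Cronbach's alpha per stimulus x dimension, from the individual rating
#' time series.
#'
#' @param study A `study_dataset`.
#' @param threshold Retention threshold on alpha (default 0.75); pairs below
#'   it are screened out of downstream testing.
#' @return A `reliability_table` tibble with columns `stimulus`, `dimension`,
#'   `alpha`, `retained`.
#' @export
reliability_table <- function(study, threshold = 0.75) {
  cells <- study$ratings |>
    dplyr::distinct(.data$stimulus, .data$dimension)
  alpha <- mapply(function(s, d) cronbach_alpha(rating_curves(study, s, d)),
                  cells$stimulus, cells$dimension)
  out <- tibble::tibble(stimulus = cells$stimulus,
                        dimension = cells$dimension,
                        alpha = as.numeric(alpha))
  apply_reliability_filter(out, threshold)
}

#' Mark unreliable stimulus x dimension cells for exclusion
#'
#' Cells whose panel alpha falls below the threshold are flagged; the test
#' battery enumerates them but skips their execution.
#'
#' @param reliability Tibble with columns `stimulus`, `dimension`, `alpha`.
#' @param threshold Retention threshold (retain iff `alpha >= threshold`).
#' @return The table with a logical `retained` column, classed
#'   `reliability_table`; the excluded rows are also attached as attribute
#'   `"excluded"`.
#' @export
apply_reliability_filter <- function(reliability, threshold = 0.75) {
  out <- tibble::as_tibble(reliability) |>
    dplyr::mutate(retained = .data$alpha >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "excluded") <- dplyr::filter(out, !.data$retained) |>
    dplyr::select("stimulus", "dimension")
  class(out) <- c("reliability_table", class(out))
  out
}

#' Apply participant-level exclusion rules
#'
#' Participants flagged for measurement error are unusable; participants
#' whose native language differs from the study language are removed to
#' limit variability in responses to the speech samples.
#'
#' @param participants Roster tibble; logical columns `measurement_error`
#'   and `non_native` are honoured when present.
#' @return The retained roster rows.
#' @export
exclude_participants <- function(participants) {
  out <- tibble::as_tibble(participants)
  for (flag in c("measurement_error", "non_native")) {
    if (flag %in% names(out)) {
      out <- dplyr::filter(out, !.data[[flag]])
    }
  }
  out
}
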