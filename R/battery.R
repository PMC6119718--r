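#' Enumerate the full test battery
#'
#' The battery crosses every stimulus with every rating dimension and every
#' grouping factor. Cells screened out by the reliability filter stay in
#' the enumeration (they count toward the battery size) but are flagged so
#' execution skips them.
#'
#' @param stimuli Stimulus metadata tibble (columns `stimulus`, `modality`)
#'   or a character vector of stimulus ids.
#' @param dimensions Character vector, default both rating dimensions.
#' @param factors Character vector of factor names, or a list of
#'   [grouping_factor()]s.
#' @param reliability Optional `reliability_table`; its non-retained cells
#'   set `excluded_for_reliability`.
#' @return Tibble of tests ordered by (modality, stimulus, dimension,
#'   factor), with a stable `test_index`.
#' @export
enumerate_tests <- function(stimuli, dimensions = c("arousal", "valence"),
                            factors, reliability = NULL) {
  if (is.character(stimuli)) {
    stimuli <- tibble::tibble(stimulus = stimuli, modality = NA_character_)
  }
  if (!nrow(stimuli) || !length(dimensions) || !length(factors)) {
    stopf("validation_error", "stimuli, dimensions and factors must be non-empty")
  }
  factor_names <- if (is.list(factors)) {
    vapply(factors, attr, character(1), "name")
  } else factors
  grid <- tidyr::expand_grid(
    stimuli[c("stimulus", "modality")],
    dimension = dimensions,
    factor = factor_names
  ) |>
    dplyr::arrange(.data$modality, .data$stimulus, .data$dimension,
                   .data$factor) |>
    dplyr::mutate(test_index = dplyr::row_number(), .before = 1)
  grid$excluded_for_reliability <- FALSE
  if (!is.null(reliability)) {
    excl <- dplyr::filter(reliability, !.data$retained)
    grid$excluded_for_reliability <-
      paste(grid$stimulus, grid$dimension) %in%
      paste(excl$stimulus, excl$dimension)
  }
  grid
}

check_pvalues <- function(p) {
  p_ok <- p[!is.na(p)]
  if (any(p_ok <= 0 | p_ok > 1)) {
    stopf("validation_error", "p-values must lie in (0, 1]")
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are `p_(i) = min_{j >= i} min(1, m p_(j) / j)` over the
#' ordered raw p-values; rejecting adjusted values at level `q` reproduces
#' the classical largest-k step-up rule and controls the false discovery
#' rate at `q`.
#'
#' @param p Raw p-values in (0, 1] (NAs pass through).
#' @param q FDR level in (0, 1).
#' @return List with `p_adjusted` (input order) and logical `rejected`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  check_pvalues(p)
  if (q <= 0 || q >= 1) stopf("validation_error", "q must lie in (0, 1)")
  adj <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m) {
    o <- order(p[idx])
    scaled <- pmin(1, m * p[idx][o] / seq_len(m))
    adj[idx[o]] <- rev(cummin(rev(scaled)))
  }
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Bonferroni adjustment (comparison baseline)
#'
#' Controls the family-wise error rate; far more conservative than
#' [bh_adjust()] — its rejections are always a subset of the BH rejections
#' at the same level.
#'
#' @param p Raw p-values in (0, 1].
#' @return Adjusted p-values `min(1, m p)`.
#' @export
bonferroni_adjust <- function(p) {
  check_pvalues(p)
  m <- sum(!is.na(p))
  pmin(1, m * p)
}

#' Run the full functional-ANOVA battery
#'
#' Executes one functional bootstrap test per enumerated stimulus x
#' dimension x factor cell (skipping reliability-excluded cells), derives a
#' deterministic child seed per test from the master seed and the test's
#' ordinal index (so results do not depend on execution order), and applies
#' BH correction within the configured family.
#'
#' @param study A `study_dataset`.
#' @param factors List of [grouping_factor()]s; default: the nine
#'   individual-difference factors built from the retained roster.
#' @param reliability A `reliability_table`; default: computed from the
#'   study at threshold 0.75.
#' @param smoothing A [smoothing_spec()].
#' @param bootstrap A [bootstrap_spec()] (its seed field is ignored; child
#'   seeds come from `master_seed`).
#' @param q FDR level.
#' @param family BH family definition. `"per_factor"` (default) adjusts
#'   across the stimuli of one modality for each dimension x factor (8
#'   music or 9 speech tests per family); `"per_stimulus"` adjusts within
#'   each stimulus's tests; `"global"` over the whole battery. Note that
#'   with `B` bootstrap resamples the smallest attainable raw p-value is
#'   `1/(B+1)`, so a family of m tests can only ever reject when
#'   `m/(B+1) <= q`.
#' @param master_seed Integer master seed.
#' @return A `battery_result` tibble: one row per enumerated test with the
#'   statistic, raw and adjusted p-values, significance and exclusion
#'   flags, group sizes and any per-test error message.
#' @export
run_battery <- function(study, factors = NULL, reliability = NULL,
                        smoothing = smoothing_spec(),
                        bootstrap = bootstrap_spec(B = 199),
                        q = 0.05,
                        family = c("per_factor", "per_stimulus", "global"),
                        master_seed = 1L) {
  family <- match.arg(family)
  if (is.null(factors)) {
    factors <- build_grouping_factors(exclude_participants(study$participants))
  }
  if (is.null(reliability)) reliability <- reliability_table(study)
  tests <- enumerate_tests(study$stimuli, factors = factors,
                           reliability = reliability)
  fnames <- vapply(factors, attr, character(1), "name")

  run_one <- function(row) {
    fac <- factors[[match(row$factor, fnames)]]
    lv <- attr(fac, "levels")
    curves <- rating_curves(study, row$stimulus, row$dimension)
    grp <- lapply(lv, function(l) {
      ids <- intersect(fac$participant[fac$level == l], colnames(curves))
      curves[, ids, drop = FALSE]
    })
    res <- functional_bootstrap_test(
      grp, attr(curves, "time_s"), smoothing,
      bootstrap_spec(bootstrap$B, seed = derive_seed(master_seed,
                                                     row$test_index)))
    tibble::tibble(statistic = res$statistic, p_raw = res$p_value,
                   bandwidth = res$bandwidth,
                   n_a = res$group_sizes[1], n_b = res$group_sizes[2],
                   error = NA_character_)
  }

  rows <- lapply(seq_len(nrow(tests)), function(i) {
    row <- tests[i, ]
    if (row$excluded_for_reliability) {
      return(tibble::tibble(statistic = NA_real_, p_raw = NA_real_,
                            bandwidth = NA_real_, n_a = NA_integer_,
                            n_b = NA_integer_, error = NA_character_))
    }
    tryCatch(run_one(row), error = function(e) {
      tibble::tibble(statistic = NA_real_, p_raw = NA_real_,
                     bandwidth = NA_real_, n_a = NA_integer_,
                     n_b = NA_integer_, error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_cols(tests, dplyr::bind_rows(rows))

  executed <- !out$excluded_for_reliability
  failed <- executed & !is.na(out$error)
  if (sum(failed) > 0.1 * sum(executed)) {
    stopf("battery_error", "%d of %d tests failed; first error: %s",
          sum(failed), sum(executed), out$error[which(failed)[1]])
  }

  out$p_adjusted <- NA_real_
  fam <- switch(family,
                per_factor = paste(out$modality, out$dimension, out$factor),
                per_stimulus = out$stimulus,
                global = "all")
  for (f in unique(fam)) {
    sel <- fam == f
    out$p_adjusted[sel] <- bh_adjust(out$p_raw[sel], q)$p_adjusted
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= q &
    !out$excluded_for_reliability

  attr(out, "q") <- q
  attr(out, "family") <- family
  attr(out, "master_seed") <- master_seed
  attr(out, "n_bootstrap") <- bootstrap$B
  class(out) <- c("battery_result", class(out))
  out
}

#' @export
print.battery_result <- function(x, ...) {
  cat(sprintf(
    "<battery_result> %d tests (%d excluded for reliability, %d failed)\n",
    nrow(x), sum(x$excluded_for_reliability), sum(!is.na(x$error))))
  cat(sprintf("  significant at BH q = %s (%s families): %d (%.1f%%)\n",
              format(attr(x, "q")), attr(x, "family"), sum(x$significant),
              100 * mean(x$significant)))
  invisible(x)
}

#' Render the battery significance matrix
#'
#' A factor-by-(stimulus, dimension) grid in the style of a multi-test
#' summary figure: a filled marker where the BH-adjusted p-value clears the
#' threshold, an open marker where it does not, and a blank where the cell
#' was excluded for unreliable ratings. A TSV twin of the grid is written
#' next to the figure.
#'
#' @param result A `battery_result`.
#' @param path Output stem: the figure is written to `<path>.png` and the
#'   table to `<path>.tsv`.
#' @return The ggplot object, invisibly.
#' @export
render_significance_matrix <- function(result, path) {
  df <- tibble::as_tibble(result) |>
    dplyr::mutate(
      cell = paste(.data$stimulus, .data$dimension, sep = "\n"),
      status = dplyr::case_when(
        .data$excluded_for_reliability ~ "excluded",
        .data$significant ~ "significant",
        TRUE ~ "n.s."
      )
    )
  readr::write_tsv(
    dplyr::select(df, "modality", "stimulus", "dimension", "factor",
                  "p_raw", "p_adjusted", "status"),
    paste0(path, ".tsv"))
  plot_df <- dplyr::filter(df, .data$status != "excluded")
  p <- ggplot2::ggplot(plot_df,
                       ggplot2::aes(x = .data$cell, y = .data$factor)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$status), size = 3,
                        colour = "grey40") +
    ggplot2::scale_alpha_manual(
      values = c(significant = 1, n.s. = 0.15), drop = FALSE) +
    ggplot2::facet_grid(. ~ modality, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, alpha = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  ggplot2::ggsave(paste0(path, ".png"), p, width = 9, height = 4, dpi = 150)
  invisible(p)
}
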