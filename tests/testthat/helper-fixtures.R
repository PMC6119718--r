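# Small deterministic fixtures shared across test files.

# A two-stimulus, 12-participant study: fast enough for I/O and battery
# plumbing tests while exercising both modalities.
tiny_config <- function(seed = 101, ...) {
  simulation_config(
    stimuli = default_stimuli()[c(1, 9), ],
    n_recruited = 14, n_measurement_error = 1, n_non_native = 1,
    seed = seed, ...
  )
}

tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(tiny_config())
    cache
  }
})

# Hoyt's method: Cronbach's alpha from the two-way ANOVA decomposition with
# time points as cases and raters as items. Independent of the variance
# formula used by the implementation.
alpha_anova_oracle <- function(m) {
  df <- data.frame(
    v = as.vector(m),
    time = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  ms <- summary(stats::aov(v ~ time + rater, df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / ms[1]
}

# Brute-force BH: find the largest k with p_(k) <= k q / m and reject the k
# smallest p-values.
bh_bruteforce_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(ks)) rejected[o[seq_len(max(ks))]] <- TRUE
  rejected
}

# Panel reliability values printed for a comparable 17-stimulus study
# (8 music pieces, 9 speech samples), used to exercise the keep/drop rule.
reference_panel_alphas <- function() {
  tibble::tibble(
    stimulus = c(sprintf("music_%02d", 1:8), sprintf("speech_%02d", 1:9)),
    arousal = c(0.98, 0.94, 0.99, 0.98, 0.99, 0.93, 0.99, 0.99,
                0.99, 0.96, 0.99, 0.99, 0.96, 0.97, 0.96, 0.65, 0.95),
    valence = c(0.94, 0.97, 0.89, 0.98, 0.95, 0.96, 0.98, 0.97,
                0.97, 0.95, 0.99, 0.99, 0.97, 0.73, 0.78, 0.89, 0.15)
  ) |>
    tidyr::pivot_longer(c("arousal", "valence"), names_to = "dimension",
                        values_to = "alpha")
}
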