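test_that("test enumeration is the full ordered cross product", {
  expect_equal(nrow(enumerate_tests("s1", "valence", "Age")), 1)
  expect_equal(nrow(enumerate_tests(c("a", "b", "c"),
                                    c("arousal", "valence"),
                                    c("F1", "F2"))), 12)
  tests <- enumerate_tests(default_stimuli(),
                           factors = sprintf("F%d", 1:9))
  expect_equal(tests$test_index, seq_len(nrow(tests)))
  # music tests come first, ordered within modality
  expect_equal(unique(tests$modality), c("music", "speech"))
  expect_error(enumerate_tests(character(0), "valence", "Age"),
               class = "validation_error")
})

test_that("reliability-excluded cells stay enumerated but flagged", {
  rel <- apply_reliability_filter(
    tibble::tibble(stimulus = c("a", "a", "b", "b"),
                   dimension = rep(c("arousal", "valence"), 2),
                   alpha = c(0.9, 0.5, 0.9, 0.9)))
  tests <- enumerate_tests(c("a", "b"), factors = c("F1", "F2"),
                           reliability = rel)
  expect_equal(nrow(tests), 8)
  expect_equal(sum(tests$excluded_for_reliability), 2)
  expect_true(all(tests$dimension[tests$excluded_for_reliability] ==
                    "valence"))
})

test_that("BH adjustment matches the brute-force step-up rule and p.adjust", {
  # all five clear the largest-k rule at q = 0.05
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  res <- bh_adjust(p, 0.05)
  expect_true(all(res$rejected))
  expect_equal(bh_adjust(0.04, 0.05)$p_adjusted, 0.04)
  expect_true(bh_adjust(0.04, 0.05)$rejected)
  expect_false(any(bh_adjust(c(1, 1), 0.2)$rejected))

  for (s in 1:100) {
    p <- withr::with_seed(s, runif(sample(3:40, 1)))
    q <- withr::with_seed(s + 1000, runif(1, 0.01, 0.3))
    res <- bh_adjust(p, q)
    expect_equal(res$rejected, bh_bruteforce_reject(p, q))
    expect_equal(res$p_adjusted, stats::p.adjust(p, "BH"))
    # adjusted values are monotone in the raw p-values
    expect_true(all(diff(res$p_adjusted[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "validation_error")
  expect_error(bh_adjust(0.5, q = 1), class = "validation_error")
})

test_that("Bonferroni is more conservative than BH on every input", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.005, 0.2)), c(0.01, 0.4))
  for (s in 1:100) {
    p <- withr::with_seed(s + 5000, runif(sample(3:30, 1)))
    bh <- bh_adjust(p, 0.05)
    bonf_rej <- bonferroni_adjust(p) <= 0.05
    expect_true(all(bh$rejected[bonf_rej]))
    expect_true(all(bonferroni_adjust(p) >= bh$p_adjusted - 1e-12))
  }
})

test_that("run_battery is deterministic and carries per-test child seeds", {
  study <- tiny_study()
  bs <- bootstrap_spec(B = 99)
  r1 <- run_battery(study, bootstrap = bs, master_seed = 7)
  r2 <- run_battery(study, bootstrap = bs, master_seed = 7)
  expect_identical(r1$p_raw, r2$p_raw)
  expect_identical(r1$p_adjusted, r2$p_adjusted)
  expect_equal(nrow(r1), 2 * 2 * 9)
  expect_true(all(r1$p_adjusted >= r1$p_raw - 1e-12, na.rm = TRUE))
  expect_false(any(r1$significant & r1$excluded_for_reliability))

  # a single test replayed with its derived child seed reproduces its row
  row <- r1[which(!is.na(r1$p_raw))[5], ]
  fac <- build_grouping_factors(
    exclude_participants(study$participants))[[row$factor]]
  curves <- rating_curves(study, row$stimulus, row$dimension)
  grp <- lapply(attr(fac, "levels"), function(l) {
    curves[, intersect(fac$participant[fac$level == l], colnames(curves)),
           drop = FALSE]
  })
  replay <- functional_bootstrap_test(
    grp, attr(curves, "time_s"),
    bootstrap = bootstrap_spec(99, seed = affectfanova:::derive_seed(
      7, row$test_index)))
  expect_equal(replay$p_value, row$p_raw)
  expect_equal(replay$statistic, row$statistic)
})

test_that("a null battery rarely declares significance", {
  study <- tiny_study()
  res <- run_battery(study, bootstrap = bootstrap_spec(B = 199),
                     master_seed = 31)
  # no effects were injected: BH at q = 0.05 should reject (almost) nothing
  expect_lte(mean(res$significant), 0.1)
})

test_that("the significance matrix renders a figure and a complete TSV twin", {
  study <- tiny_study()
  res <- run_battery(study, bootstrap = bootstrap_spec(B = 99),
                     master_seed = 7)
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "matrix")
  p <- render_significance_matrix(res, stem)
  expect_s3_class(p, "ggplot")
  expect_true(file.exists(paste0(stem, ".tsv")))
  twin <- readr::read_tsv(paste0(stem, ".tsv"), show_col_types = FALSE)
  expect_equal(nrow(twin), nrow(res))
})
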