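test_that("mean functions interpolate their waypoints and traverse quadrants", {
  wp <- tibble::tibble(time_frac = c(0, 0.4, 1),
                       valence = c(0.5, -0.6, -0.2),
                       arousal = c(0.5, 0.6, -0.7))
  mu <- make_mean_function(wp, 100)
  expect_equal(mu$time_s, 0:99)
  fns <- attr(mu, "interpolants")
  wt <- attr(mu, "waypoint_times")
  expect_equal(fns$valence(wt), wp$valence, tolerance = 1e-9)
  expect_equal(fns$arousal(wt), wp$arousal, tolerance = 1e-9)
  expect_true(all(abs(mu$valence) <= 1 & abs(mu$arousal) <= 1))
  # journey visits Q1 then Q2 in order
  q <- classify_quadrant(mu$valence, mu$arousal)
  expect_lt(min(which(q == "Q1")), min(which(q == "Q2")))

  # two identical coordinates give constant curves
  flat <- make_mean_function(
    tibble::tibble(time_frac = c(0, 1), valence = 0.3, arousal = -0.2), 50)
  expect_equal(flat$valence, rep(0.3, 50))
  expect_equal(flat$arousal, rep(-0.2, 50))

  expect_error(make_mean_function(wp[1, ], 60), class = "validation_error")
  expect_error(
    make_mean_function(tibble::tibble(time_frac = c(0.5, 0.2),
                                      valence = 0, arousal = 0), 60),
    class = "validation_error")
})

test_that("group-effect bumps are Gaussian with the right mass", {
  tt <- 0:119
  base <- rep(0, 120)
  expect_equal(inject_group_effect(base, tt, 60, 10, 0), base)
  bumped <- inject_group_effect(base, tt, 60, 10, 0.3)
  expect_equal(bumped[61], 0.3)  # peak value at t0 (pre-clip scale)
  for (w in c(3, 5, 10)) {
    b <- inject_group_effect(base, tt, 60, w, 0.2)
    mass <- sum(b)  # unit-spaced grid
    expect_equal(mass, 0.2 * w * sqrt(2 * pi), tolerance = 0.02)
  }
  # clipping keeps the result in range
  high <- inject_group_effect(rep(0.9, 120), tt, 60, 10, 0.5)
  expect_true(all(high <= 1))
})

test_that("participant simulation is deterministic and respects its parameters", {
  mu <- make_mean_function(default_waypoints("Q1,Q3"), 80)
  s1 <- simulate_participant(mu, a = 1.2, b = 0.05, seed = 9)
  s2 <- simulate_participant(mu, a = 1.2, b = 0.05, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(abs(s1$value) <= 1))
  # sigma = 0 reproduces a * mu + b exactly (within clipping)
  clean <- simulate_participant(mu, a = 1, b = 0, sigma = 0, seed = 1)
  expect_equal(clean$value[clean$dimension == "valence"], mu$valence)
  expect_equal(clean$value[clean$dimension == "arousal"], mu$arousal)
})

test_that("the AR(1) noise has the configured lag-1 autocorrelation", {
  long <- simulate_rating_curves(1, 0:9999, 0, rho = 0.5, sigma = 0.1,
                                 seed = 4, clip = FALSE)
  r1 <- stats::cor(long[-1, 1], long[-10000, 1])
  expect_equal(r1, 0.5, tolerance = 0.03)
  white <- simulate_rating_curves(1, 0:9999, 0, rho = 0, sigma = 0.1,
                                  seed = 5, clip = FALSE)
  expect_lt(abs(stats::cor(white[-1, 1], white[-10000, 1])), 0.03)
  # stationary start: early values have the same spread as late ones
  expect_equal(sd(long[1:2000, 1]), sd(long[8001:10000, 1]),
               tolerance = 0.1)
})

test_that("simulated studies have valid grids, ranges and reproducibility", {
  study <- tiny_study()
  expect_s3_class(study, "study_dataset")
  expect_true(all(abs(study$ratings$value) <= 1))
  grids <- study$ratings |>
    dplyr::group_by(participant, stimulus, dimension) |>
    dplyr::summarise(ok = all(diff(time_s) == 1) && min(time_s) == 0,
                     .groups = "drop")
  expect_true(all(grids$ok))
  again <- simulate_study(tiny_config())
  expect_equal(study$ratings, again$ratings)
  expect_equal(study$participants, again$participants)
})

test_that("the truth manifest records injected effects and they are recoverable", {
  cfg <- tiny_config(seed = 77, effects = list(
    list(factor = "Gender", stimulus = "music_01", dimension = "valence",
         A = 0.4, w = 10)))
  study <- simulate_study(cfg)
  man <- attr(study, "manifest")
  expect_equal(length(man$effects), 1)
  expect_equal(man$effects[[1]]$level, "male")
  expect_equal(man$effects[[1]]$A, 0.4)

  # the injected gender gap is visible in the raw group means
  fac <- build_grouping_factors(
    exclude_participants(study$participants))$Gender
  curves <- rating_curves(study, "music_01", "valence")
  males <- intersect(fac$participant[fac$level == "male"], colnames(curves))
  females <- intersect(fac$participant[fac$level == "female"],
                       colnames(curves))
  tt <- attr(curves, "time_s")
  mid <- abs(tt - max(tt) / 2) <= 10
  gap <- mean(curves[mid, males]) - mean(curves[mid, females])
  expect_gt(gap, 0.15)
})

test_that("panel reliability rises as rating noise falls", {
  alphas <- vapply(c(0.4, 0.2, 0.05), function(sg) {
    study <- simulate_study(tiny_config(seed = 500, sigma = sg))
    mean(reliability_table(study)$alpha)
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
})

test_that("heteroscedastic configurations produce group-specific dispersion", {
  cfg <- tiny_config(seed = 31, sigma_by_level = list(
    factor = "Gender", sigma = c(female = 0.05, male = 0.4)))
  study <- simulate_study(cfg)
  fac <- build_grouping_factors(
    exclude_participants(study$participants))$Gender
  curves <- rating_curves(study, "music_01", "arousal")
  sds <- apply(curves, 2, function(x) sd(diff(x)))
  m_sd <- mean(sds[intersect(fac$participant[fac$level == "male"],
                             colnames(curves))])
  f_sd <- mean(sds[intersect(fac$participant[fac$level == "female"],
                             colnames(curves))])
  expect_gt(m_sd / f_sd, 3)
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(rho = 1), class = "config_error")
  expect_error(simulation_config(n_recruited = 5), class = "config_error")
  expect_error(simulation_config(effects = list(list(factor = "Age"))),
               class = "config_error")
  expect_error(
    simulation_config(effects = list(list(factor = "Age", stimulus = "zz",
                                          dimension = "valence", A = 1))),
    class = "config_error")
})
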