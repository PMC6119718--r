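#' Stimulus set with the shape of a two-modality continuous-rating study
#'
#' Eight music excerpts and nine speech samples, 45-156 s long at 1 Hz,
#' each annotated with the emotion-space quadrants its mean trajectory is
#' expected to visit. These are the generator's default stimuli.
#'
#' @return Stimulus metadata tibble (`stimulus`, `modality`, `duration_s`,
#'   `expected_quadrants`).
#' @export
default_stimuli <- function() {
  tibble::tibble(
    stimulus = c(sprintf("music_%02d", 1:8), sprintf("speech_%02d", 1:9)),
    modality = rep(c("music", "speech"), c(8, 9)),
    duration_s = c(120, 84, 114, 110, 130, 108, 108, 89,
                   45, 156, 99, 58, 76, 100, 63, 88, 106),
    expected_quadrants = c(
      "Q2", "Q1,Q2,Q3,Q4", "Q1,Q3", "Q2,Q3", "Q1,Q4", "Q1,Q4", "Q2,Q3",
      "Q1,Q2,Q4",
      "Q1", "Q1,Q4", "Q2", "Q2", "Q2,Q3", "Q3,Q4", "Q3", "Q1,Q4", "Q3,Q4")
  )
}

quadrant_center <- function(q) {
  centers <- list(Q1 = c(0.6, 0.6), Q2 = c(-0.6, 0.6),
                  Q3 = c(-0.6, -0.6), Q4 = c(0.6, -0.6))
  centers[[q]]
}

#' Default waypoint journey through a stimulus's expected quadrants
#'
#' Builds a waypoint list whose spline interpolant starts from a muted
#' version of the first quadrant's emotion and then visits each expected
#' quadrant's centre in turn.
#'
#' @param expected_quadrants Comma-separated quadrant labels, e.g.
#'   `"Q1,Q3"`.
#' @return Waypoint tibble (`time_frac`, `valence`, `arousal`) for
#'   [make_mean_function()].
#' @export
default_waypoints <- function(expected_quadrants) {
  qs <- strsplit(expected_quadrants, ",")[[1]]
  centers <- t(vapply(qs, quadrant_center, numeric(2)))
  if (length(qs) == 1) {
    coords <- rbind(0.3 * centers[1, ], centers[1, ], 0.8 * centers[1, ])
  } else {
    coords <- rbind(0.3 * centers[1, ], centers)
  }
  tibble::tibble(
    time_frac = seq(0, 1, length.out = nrow(coords)),
    valence = coords[, 1],
    arousal = coords[, 2]
  )
}

#' Smooth mean valence/arousal curves through waypoints
#'
#' Natural cubic spline through the waypoints, evaluated on the 1 Hz grid
#' `0:(duration - 1)` (waypoint time fractions are mapped onto
#' `[0, duration - 1]`) and clipped to `[-1, 1]`. The interpolant passes
#' through every waypoint exactly; the un-clipped interpolating functions
#' are attached as attribute `"interpolants"`.
#'
#' @param waypoints Tibble with strictly increasing `time_frac` in
#'   `[0, 1]` and coordinates `valence`, `arousal` in `[-1, 1]`; at least
#'   two rows.
#' @param duration_s Stimulus duration in seconds.
#' @return Tibble (`time_s`, `valence`, `arousal`).
#' @export
make_mean_function <- function(waypoints, duration_s) {
  wp <- tibble::as_tibble(waypoints)
  if (nrow(wp) < 2) {
    stopf("validation_error", "need at least 2 waypoints")
  }
  if (any(diff(wp$time_frac) <= 0) || any(wp$time_frac < 0 | wp$time_frac > 1)) {
    stopf("validation_error",
          "waypoint time fractions must be strictly increasing within [0, 1]")
  }
  if (any(abs(wp$valence) > 1) || any(abs(wp$arousal) > 1)) {
    stopf("validation_error", "waypoint coordinates must lie in [-1, 1]")
  }
  grid <- 0:(duration_s - 1)
  times <- wp$time_frac * (duration_s - 1)
  fns <- list(
    valence = stats::splinefun(times, wp$valence, method = "natural"),
    arousal = stats::splinefun(times, wp$arousal, method = "natural")
  )
  out <- tibble::tibble(
    time_s = grid,
    valence = clip01(fns$valence(grid)),
    arousal = clip01(fns$arousal(grid))
  )
  attr(out, "interpolants") <- fns
  attr(out, "waypoint_times") <- times
  out
}

#' Add a localized Gaussian bump to a mean curve
#'
#' Group effects are modelled as localized deviations: the affected group's
#' mean curve gains `A * exp(-(t - t0)^2 / (2 w^2))`, clipped back into
#' `[-1, 1]`. Individual differences are expected to matter most during
#' specific regions of a stimulus, which this shape emulates.
#'
#' @param values Mean curve values on the grid.
#' @param time_s Time grid in seconds.
#' @param t0 Bump centre in seconds (within the grid).
#' @param w Bump width (Gaussian sd) in seconds, > 0.
#' @param A Bump amplitude.
#' @return Modified curve values.
#' @export
inject_group_effect <- function(values, time_s, t0, w, A) {
  stopifnot(w > 0)
  clip01(values + A * exp(-(time_s - t0)^2 / (2 * w^2)))
}

# stationary AR(1): lag-1 correlation rho, innovation sd sigma
ar1_noise <- function(n, rho, sigma) {
  z <- rnorm(n, 0, sigma)
  if (rho == 0 || sigma == 0) return(z)
  init <- rnorm(1, 0, sigma / sqrt(1 - rho^2))
  as.numeric(stats::filter(z, rho, method = "recursive", init = init))
}

#' Simulate one participant's rating curves for one stimulus
#'
#' `X(t) = clip(a * mu(t) + b + e(t))` per dimension, where `a` is the
#' participant's multiplicative amplitude, `b` their additive offset and
#' `e` stationary AR(1) noise with lag-1 coefficient `rho` and innovation
#' sd `sigma`.
#'
#' @param mean_curves Output of [make_mean_function()] (possibly with
#'   injected effects).
#' @param a,b Participant amplitude and offset.
#' @param rho,sigma AR(1) noise parameters.
#' @param seed Optional seed for a deterministic draw.
#' @return Long tibble (`dimension`, `time_s`, `value`).
#' @export
simulate_participant <- function(mean_curves, a = 1, b = 0, rho = 0.5,
                                 sigma = 0.15, seed = NULL) {
  draw <- function() {
    n <- nrow(mean_curves)
    dplyr::bind_rows(lapply(c("valence", "arousal"), function(d) {
      tibble::tibble(
        dimension = d,
        time_s = mean_curves$time_s,
        value = clip01(a * mean_curves[[d]] + b + ar1_noise(n, rho, sigma))
      )
    }))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a matrix of rating curves around a common mean
#'
#' Convenience generator for calibration studies: `n` curves sharing a mean
#' function, each perturbed by independent stationary AR(1) noise.
#'
#' @param n Number of curves.
#' @param time_s Time grid.
#' @param mean_values Common mean curve (scalar or vector on the grid).
#' @param rho,sigma AR(1) parameters.
#' @param seed Optional seed.
#' @param clip Clip to `[-1, 1]` (default `TRUE`).
#' @return T x n matrix.
#' @export
simulate_rating_curves <- function(n, time_s, mean_values = 0, rho = 0.5,
                                   sigma = 0.15, seed = NULL, clip = TRUE) {
  mu <- rep_len(mean_values, length(time_s))
  draw <- function() {
    m <- vapply(seq_len(n),
                function(i) mu + ar1_noise(length(time_s), rho, sigma),
                numeric(length(time_s)))
    if (clip) clip01(m) else m
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  colnames(out) <- sprintf("P%03d", seq_len(n))
  attr(out, "time_s") <- time_s
  out
}

#' Configuration for a synthetic rating study
#'
#' The defaults reproduce the shape of a 60-recruited / 52-retained
#' two-modality study: 8 music + 9 speech stimuli of 45-156 s at 1 Hz,
#' smooth mean trajectories through the expected emotion-space quadrants,
#' participant amplitude/offset effects, and heteroscedastic-capable AR(1)
#' rating noise.
#'
#' @param stimuli Stimulus metadata tibble, see [default_stimuli()].
#' @param waypoints Optional named list (by stimulus id) of waypoint
#'   tibbles; defaults are derived from `expected_quadrants`.
#' @param n_recruited Recruited sample size.
#' @param n_measurement_error,n_non_native Participants flagged for
#'   exclusion (measurement errors; non-native speakers of the study
#'   language).
#' @param amplitude_sdlog sdlog of the lognormal participant amplitude
#'   `a_i` (mean 1 on the log scale).
#' @param offset_sd sd of the normal participant offset `b_i`.
#' @param rho AR(1) lag-1 coefficient of the rating noise, in `[0, 1)`.
#' @param sigma AR(1) innovation sd.
#' @param sigma_by_level Optional heteroscedastic noise: a list
#'   `list(factor = <name>, sigma = c(<level_a> = .., <level_b> = ..))`
#'   giving group-specific innovation sds.
#' @param effects List of localized group effects, each a list with
#'   elements `factor`, `stimulus`, `dimension`, `t0_frac` (bump centre as
#'   a fraction of duration, default 0.5), `w` (seconds, default 10),
#'   `A` (amplitude) and optionally `level` (affected level; default the
#'   factor's second level).
#' @param seed RNG seed for [simulate_study()].
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(stimuli = default_stimuli(), waypoints = NULL,
                              n_recruited = 60, n_measurement_error = 2,
                              n_non_native = 6, amplitude_sdlog = 0.15,
                              offset_sd = 0.1, rho = 0.5, sigma = 0.15,
                              sigma_by_level = NULL, effects = list(),
                              seed = NULL) {
  if (rho < 0 || rho >= 1) {
    stopf("config_error", "rho must lie in [0, 1)")
  }
  if (n_measurement_error + n_non_native >= n_recruited) {
    stopf("config_error", "exclusions exceed the recruited sample")
  }
  if (any(stimuli$duration_s < 45 | stimuli$duration_s > 156)) {
    warn("stimulus durations outside the typical 45-156 s range")
  }
  for (ef in effects) {
    need <- setdiff(c("factor", "stimulus", "dimension", "A"), names(ef))
    if (length(need)) {
      stopf("config_error", "effect is missing field(s): %s",
            paste(need, collapse = ", "))
    }
    if (!ef$stimulus %in% stimuli$stimulus) {
      stopf("config_error", "effect targets unknown stimulus %s", ef$stimulus)
    }
  }
  structure(
    list(stimuli = tibble::as_tibble(stimuli), waypoints = waypoints,
         n_recruited = n_recruited,
         n_measurement_error = n_measurement_error,
         n_non_native = n_non_native, amplitude_sdlog = amplitude_sdlog,
         offset_sd = offset_sd, rho = rho, sigma = sigma,
         sigma_by_level = sigma_by_level, effects = effects, seed = seed),
    class = "simulation_config")
}

simulate_roster <- function(config) {
  n <- config$n_recruited
  ids <- sprintf("P%02d", seq_len(n))
  excl <- sample.int(n, config$n_measurement_error + config$n_non_native)
  measurement_error <- seq_len(n) %in% excl[seq_len(config$n_measurement_error)]
  non_native <- seq_len(n) %in%
    setdiff(excl, excl[seq_len(config$n_measurement_error)])
  retained <- !(measurement_error | non_native)

  gender <- character(n)
  gender[retained] <- rep_len(c("female", "male"), sum(retained))
  gender[!retained] <- sample(c("female", "male"), sum(!retained),
                              replace = TRUE)
  age <- round(clip01(rnorm(n, 32, 13), 18, 62))

  bands <- c("<1 yr", "1-10 yr", ">10 yr")
  k <- sum(retained)
  counts <- round(k * c(15, 20, 17) / 52)
  counts[2] <- k - counts[1] - counts[3]
  training <- character(n)
  training[retained] <- sample(rep(bands, counts))
  training[!retained] <- sample(bands, sum(!retained), replace = TRUE)

  roster <- tibble::tibble(
    participant = ids, age = age, gender = gender,
    training_category = training,
    measurement_error = measurement_error, non_native = non_native)

  # questionnaire items are back-filled from latent dimension scores so
  # that scoring the items approximately recovers the latent draw
  key <- tipi_key()
  tipi <- matrix(NA_real_, n, 10)
  for (dim_items in key$pairs) {
    d <- clip01(rnorm(n, 4.4, 1.1), 1, 7)
    k1 <- clip01(round(d + rnorm(n, 0, 0.7)), 1, 7)
    k2 <- clip01(round(2 * d - k1), 1, 7)
    keyed <- cbind(k1, k2)
    for (j in 1:2) {
      item <- dim_items[j]
      tipi[, item] <- if (item %in% key$reversed) 8 - keyed[, j] else keyed[, j]
    }
  }
  colnames(tipi) <- paste0("tipi_", 1:10)

  ei <- clip01(rnorm(n, 4.8, 0.7), 1, 7)
  teique <- vapply(1:30, function(i) clip01(round(ei + rnorm(n, 0, 1)), 1, 7),
                   numeric(n))
  teique[, teique_reverse_key()] <- 8 - teique[, teique_reverse_key()]
  colnames(teique) <- paste0("teique_", 1:30)

  mood_pre <- matrix(sample(-2:2, n * 6, replace = TRUE), n, 6)
  mood_post <- clip01(mood_pre + matrix(sample(-1:1, n * 6, replace = TRUE),
                                        n, 6), -3, 3)
  colnames(mood_pre) <- paste0("mood_pre_", 1:6)
  colnames(mood_post) <- paste0("mood_post_", 1:6)

  dplyr::bind_cols(roster, tibble::as_tibble(tipi),
                   tibble::as_tibble(teique), tibble::as_tibble(mood_pre),
                   tibble::as_tibble(mood_post))
}

#' Simulate a complete synthetic rating study
#'
#' Generates a participant roster (with exclusion flags and questionnaire
#' responses back-filled from latent trait scores), builds each stimulus's
#' mean valence/arousal trajectory from its waypoints, injects any
#' configured localized group effects into the affected group's mean
#' curves, and draws each retained participant's rating curves with
#' participant amplitude/offset effects and AR(1) noise. A truth manifest
#' (attribute `"manifest"`) records the seed and every injected effect for
#' parameter-recovery studies.
#'
#' @param config A [simulation_config()].
#' @return A `study_dataset` whose `participants` table is the full
#'   recruited roster (ratings exist only for retained participants).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed %||% sample.int(2147483646L, 1)
  with_seed(seed, {
    roster <- simulate_roster(config)
    retained <- exclude_participants(roster)
    factors <- build_grouping_factors(retained)
    fnames <- vapply(factors, attr, character(1), "name")
    n_ret <- nrow(retained)

    a_i <- exp(rnorm(n_ret, 0, config$amplitude_sdlog))
    b_i <- rnorm(n_ret, 0, config$offset_sd)

    sigma_i <- rep(config$sigma, n_ret)
    if (!is.null(config$sigma_by_level)) {
      fac <- factors[[match(config$sigma_by_level$factor, fnames)]]
      lv <- fac$level[match(retained$participant, fac$participant)]
      hit <- lv %in% names(config$sigma_by_level$sigma)
      sigma_i[hit] <- config$sigma_by_level$sigma[lv[hit]]
    }

    effects <- lapply(config$effects, function(ef) {
      fac <- factors[[match(ef$factor, fnames)]]
      ef$level <- ef$level %||% attr(fac, "levels")[2]
      ef$t0_frac <- ef$t0_frac %||% 0.5
      ef$w <- ef$w %||% 10
      ef$participants <- fac$participant[fac$level == ef$level]
      ef
    })

    ratings <- lapply(seq_len(nrow(config$stimuli)), function(si) {
      st <- config$stimuli[si, ]
      wp <- config$waypoints[[st$stimulus]] %||%
        default_waypoints(st$expected_quadrants)
      mu <- make_mean_function(wp, st$duration_s)
      tt <- mu$time_s
      per_dim <- lapply(c("valence", "arousal"), function(d) {
        base <- mu[[d]]
        efs <- Filter(function(e) e$stimulus == st$stimulus &&
                        e$dimension == d, effects)
        vals <- lapply(seq_len(n_ret), function(i) {
          m <- base
          for (ef in efs) {
            if (retained$participant[i] %in% ef$participants) {
              m <- inject_group_effect(m, tt, ef$t0_frac * max(tt), ef$w,
                                       ef$A)
            }
          }
          clip01(a_i[i] * m + b_i[i] +
                   ar1_noise(length(tt), config$rho, sigma_i[i]))
        })
        tibble::tibble(
          participant = rep(retained$participant, each = length(tt)),
          stimulus = st$stimulus, dimension = d,
          time_s = rep(tt, n_ret), value = unlist(vals))
      })
      dplyr::bind_rows(per_dim)
    })

    study <- study_dataset(dplyr::bind_rows(ratings), roster,
                           config$stimuli)
    attr(study, "manifest") <- list(
      seed = seed, rho = config$rho, sigma = config$sigma,
      sigma_by_level = config$sigma_by_level,
      amplitude_sdlog = config$amplitude_sdlog,
      offset_sd = config$offset_sd,
      effects = lapply(effects, function(ef)
        ef[c("factor", "level", "stimulus", "dimension", "t0_frac", "w", "A")])
    )
    study
  })
}
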