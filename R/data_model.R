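#' Assemble a study dataset
#'
#' A study dataset bundles the three tables the analysis pipeline works on:
#' long-format continuous ratings, the participant roster with questionnaire
#' responses and exclusion flags, and stimulus metadata.
#'
#' @param ratings Tibble with columns `participant`, `stimulus`, `dimension`
#'   (`"valence"` or `"arousal"`), `time_s` (0-based seconds on a 1 Hz grid)
#'   and `value` (normalized rating in `[-1, 1]`). The value at time `t` is
#'   the rating prevailing during the second `[t, t + 1)`.
#' @param participants Tibble keyed by `participant`; any further columns
#'   (age, gender, questionnaire items, exclusion flags) are carried along.
#' @param stimuli Tibble with columns `stimulus`, `modality` (`"music"` or
#'   `"speech"`), `duration_s` and optionally `expected_quadrants`
#'   (comma-separated subset of `Q1`–`Q4`).
#' @param validate Run structural validation (default `TRUE`).
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `ratings`, `participants`, `stimuli`.
#' @export
study_dataset <- function(ratings, participants, stimuli, validate = TRUE) {
  out <- structure(
    list(
      ratings = tibble::as_tibble(ratings),
      participants = tibble::as_tibble(participants),
      stimuli = tibble::as_tibble(stimuli)
    ),
    class = "study_dataset"
  )
  if (validate) validate_study_dataset(out)
  out
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat(sprintf("  participants: %d (%d with ratings)\n",
              nrow(x$participants),
              dplyr::n_distinct(x$ratings$participant)))
  cat(sprintf("  stimuli:      %d (%s)\n", nrow(x$stimuli),
              paste(sprintf("%d %s", table(x$stimuli$modality),
                            names(table(x$stimuli$modality))),
                    collapse = ", ")))
  cat(sprintf("  rating rows:  %d\n", nrow(x$ratings)))
  invisible(x)
}

rating_cols <- c("participant", "stimulus", "dimension", "time_s", "value")

validate_study_dataset <- function(x) {
  missing <- setdiff(rating_cols, names(x$ratings))
  if (length(missing)) {
    stopf("schema_error", "ratings table lacks required column(s): %s",
          paste(missing, collapse = ", "))
  }
  bad_dim <- setdiff(unique(x$ratings$dimension), c("valence", "arousal"))
  if (length(bad_dim)) {
    stopf("schema_error", "unknown rating dimension(s): %s",
          paste(bad_dim, collapse = ", "))
  }
  dup <- x$ratings |>
    dplyr::count(.data$participant, .data$stimulus, .data$dimension,
                 .data$time_s) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stopf("duplicate_key_error",
          "duplicated (participant, stimulus, dimension, time) rows, e.g. %s/%s/%s t=%s",
          dup$participant[1], dup$stimulus[1], dup$dimension[1], dup$time_s[1])
  }
  na_rows <- sum(is.na(x$ratings$value))
  if (na_rows > 0) {
    warn(sprintf("%d rating rows have missing values", na_rows))
  }
  oor <- !is.na(x$ratings$value) & abs(x$ratings$value) > 1
  if (any(oor)) {
    stopf("range_error", "%d rating values outside [-1, 1]; normalize first",
          sum(oor))
  }
  check_uniform_grids(x$ratings)
  invisible(x)
}

check_uniform_grids <- function(ratings) {
  grids <- ratings |>
    dplyr::group_by(.data$participant, .data$stimulus, .data$dimension) |>
    dplyr::summarise(
      ok = all(diff(sort(.data$time_s)) == 1) && min(.data$time_s) == 0,
      len = dplyr::n(),
      .groups = "drop"
    )
  bad <- dplyr::filter(grids, !.data$ok)
  if (nrow(bad)) {
    stopf("grid_error",
          "non-uniform 1 Hz grid for participant/stimulus: %s",
          paste(utils::head(paste(bad$participant, bad$stimulus, sep = "/"), 5),
                collapse = ", "))
  }
  odd <- dplyr::filter(grids, .data$len < 45 | .data$len > 156)
  if (nrow(odd)) {
    warn(sprintf(
      "%d series have grid lengths outside the typical 45-156 s range",
      nrow(odd)))
  }
  invisible(grids)
}

#' Column-name schema for ratings and covariate CSV files
#'
#' File dialects differ; the schema maps the on-disk column names onto the
#' canonical names used internally.
#'
#' @param participant,stimulus,dimension,time,value On-disk column names.
#' @return A named list of class `ratings_schema`.
#' @export
ratings_schema <- function(participant = "participant", stimulus = "stimulus",
                           dimension = "dimension", time = "time_s",
                           value = "value") {
  structure(list(participant = participant, stimulus = stimulus,
                 dimension = dimension, time = time, value = value),
            class = "ratings_schema")
}

#' Read a column-name schema from a YAML file
#'
#' Convenience for pipelines whose file dialects are configured rather than
#' hard-coded: the YAML file maps the canonical names (`participant`,
#' `stimulus`, `dimension`, `time`, `value`) onto the file's column names;
#' omitted entries keep their defaults.
#'
#' @param path YAML file path.
#' @return A [ratings_schema()].
#' @export
ratings_schema_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(ratings_schema))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stopf("config_error", "unknown schema field(s): %s",
          paste(bad, collapse = ", "))
  }
  do.call(ratings_schema, cfg)
}

#' Read a study from long-format CSV files
#'
#' Reads the canonical long ratings table (one row per participant, stimulus,
#' dimension and second) plus optional companion CSVs for participant
#' covariates and stimulus metadata, validates grids and value ranges, and
#' returns a [study_dataset()].
#'
#' @param path Ratings CSV path.
#' @param covariates_path Optional participant covariates CSV.
#' @param stimuli_path Optional stimulus metadata CSV; when absent, stimulus
#'   metadata (duration, unknown modality) is inferred from the ratings.
#' @param schema A [ratings_schema()] describing the file's column names.
#' @return A `study_dataset`.
#' @export
read_ratings_csv <- function(path, covariates_path = NULL,
                             stimuli_path = NULL,
                             schema = ratings_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(unlist(schema), names(raw))
  if (length(missing)) {
    stopf("schema_error", "ratings file %s lacks column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  ratings <- tibble::tibble(
    participant = as.character(raw[[schema$participant]]),
    stimulus = as.character(raw[[schema$stimulus]]),
    dimension = as.character(raw[[schema$dimension]]),
    time_s = as.numeric(raw[[schema$time]]),
    value = as.numeric(raw[[schema$value]])
  ) |>
    dplyr::arrange(.data$participant, .data$stimulus, .data$dimension,
                   .data$time_s)

  participants <- if (!is.null(covariates_path)) {
    readr::read_csv(covariates_path, show_col_types = FALSE) |>
      dplyr::mutate(participant = as.character(.data$participant))
  } else {
    tibble::tibble(participant = sort(unique(ratings$participant)))
  }

  stimuli <- if (!is.null(stimuli_path)) {
    readr::read_csv(stimuli_path, show_col_types = FALSE) |>
      dplyr::mutate(stimulus = as.character(.data$stimulus))
  } else {
    ratings |>
      dplyr::group_by(.data$stimulus) |>
      dplyr::summarise(modality = NA_character_,
                       duration_s = max(.data$time_s) + 1, .groups = "drop")
  }
  study_dataset(ratings, participants, stimuli)
}

#' Write a study back to long-format CSV files
#'
#' Inverse of [read_ratings_csv()]; `read_ratings_csv(write_ratings_csv(x))`
#' reproduces the input tables.
#'
#' @param study A `study_dataset`.
#' @param path Ratings CSV path.
#' @param covariates_path,stimuli_path Optional companion CSV paths.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(study, path, covariates_path = NULL,
                              stimuli_path = NULL) {
  stopifnot(inherits(study, "study_dataset"))
  readr::write_csv(study$ratings, path)
  if (!is.null(covariates_path)) {
    readr::write_csv(study$participants, covariates_path)
  }
  if (!is.null(stimuli_path)) {
    readr::write_csv(study$stimuli, stimuli_path)
  }
  invisible(path)
}

#' Fill gaps in a rating series by carrying the last observation forward
#'
#' The rating device records mouse position, which persists between
#' movements: a missing second means "unchanged", so interior gaps are filled
#' with the last observed value and a leading gap with 0 (the neutral start
#' position).
#'
#' @param time_s Observed (possibly gappy) integer seconds, 0-based.
#' @param value Observed values.
#' @param duration_s Target grid length in seconds.
#' @return Tibble with a complete `time_s` grid `0:(duration_s - 1)` and
#'   filled `value`.
#' @export
fill_rating_gaps <- function(time_s, value, duration_s) {
  grid <- 0:(duration_s - 1)
  out <- rep(NA_real_, length(grid))
  out[match(time_s, grid)] <- value
  last <- 0 # neutral until the first observation
  for (i in seq_along(out)) {
    if (is.na(out[i])) out[i] <- last else last <- out[i]
  }
  tibble::tibble(time_s = grid, value = out)
}

#' Extract the curve matrix for one stimulus and dimension
#'
#' @param study A `study_dataset`.
#' @param stimulus,dimension Which cell to extract.
#' @param participants Optional subset of participant ids (default: everyone
#'   with ratings for the cell).
#' @return A numeric T x k matrix, one column per participant, with the time
#'   grid in `rownames`-free attribute `time_s`.
#' @export
rating_curves <- function(study, stimulus, dimension, participants = NULL) {
  sub <- study$ratings |>
    dplyr::filter(.data$stimulus == !!stimulus,
                  .data$dimension == !!dimension)
  if (!is.null(participants)) {
    sub <- dplyr::filter(sub, .data$participant %in% !!participants)
  }
  if (!nrow(sub)) {
    stopf("structural_error", "no ratings for stimulus %s / %s",
          stimulus, dimension)
  }
  wide <- sub |>
    dplyr::arrange(.data$time_s) |>
    tidyr::pivot_wider(id_cols = "time_s", names_from = "participant",
                       values_from = "value")
  if (anyNA(wide)) {
    stopf("structural_error",
          "participants rated stimulus %s / %s on mismatched grids",
          stimulus, dimension)
  }
  m <- as.matrix(wide[, -1, drop = FALSE])
  attr(m, "time_s") <- wide$time_s
  m
}

#' Write battery results to TSV with a JSON sidecar
#'
#' The TSV holds one row per enumerated test; the sidecar records the run
#' configuration (seed, bootstrap size, FDR settings, package version) so a
#' result file is self-describing and re-readable.
#'
#' @param result A `battery_result` from [run_battery()] (or any tibble of
#'   battery rows).
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_battery_results <- function(result, path) {
  readr::write_tsv(tibble::as_tibble(result), path)
  meta <- attributes(result)
  sidecar <- list(
    package = "affectfanova",
    version = as.character(utils::packageVersion("affectfanova")),
    n_tests = nrow(result),
    q = meta$q, family = meta$family,
    master_seed = meta$master_seed, n_bootstrap = meta$n_bootstrap
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read battery results written by [write_battery_results()]
#'
#' @param path TSV path.
#' @return A tibble with the sidecar metadata attached as attributes where
#'   present.
#' @export
read_battery_results <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "q") <- meta$q
    attr(out, "family") <- meta$family
    attr(out, "master_seed") <- meta$master_seed
    attr(out, "n_bootstrap") <- meta$n_bootstrap
  }
  out
}
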