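#' Standard scoring key for the Ten-Item Personality Inventory
#'
#' Each Big-Five dimension is measured by one direct and one reverse-keyed
#' item; reverse-keyed responses are recoded as `8 - x` before averaging.
#' The shipped default is the instrument's published key; studies using a
#' rearranged form can supply their own.
#'
#' @return A list with `pairs` (named list of the two item indices per
#'   dimension) and `reversed` (indices of reverse-keyed items).
#' @export
tipi_key <- function() {
  list(
    pairs = list(
      Extroversion = c(1L, 6L),
      Agreeableness = c(2L, 7L),
      Conscientiousness = c(3L, 8L),
      EmotionalStability = c(4L, 9L),
      Openness = c(5L, 10L)
    ),
    reversed = c(2L, 4L, 6L, 8L, 10L)
  )
}

#' Reverse-keyed items of the TEIQue short form
#'
#' The instrument's published 30-item key; configurable because forms vary.
#' @return Integer vector of reverse-keyed item indices.
#' @export
teique_reverse_key <- function() {
  c(2L, 4L, 5L, 7L, 8L, 10L, 12L, 13L, 14L, 16L, 18L, 22L, 25L, 26L, 28L)
}

check_items <- function(items, n, lo, hi, what) {
  if (length(items) != n) {
    stopf("config_error", "%s expects %d responses, got %d",
          what, n, length(items))
  }
  bad <- which(is.na(items) | items < lo | items > hi)
  if (length(bad)) {
    stopf("validation_error", "%s response out of range at item %d",
          what, bad[1])
  }
  invisible(items)
}

#' Score the Ten-Item Personality Inventory
#'
#' @param items_10 Ten responses on the 1-7 scale, in instrument order.
#' @param key Scoring key, see [tipi_key()].
#' @return Named numeric vector of the five dimension scores
#'   (Extroversion, Agreeableness, Conscientiousness, EmotionalStability,
#'   Openness), each the mean of its item pair after reverse-keying and
#'   therefore within `[1, 7]`.
#' @export
score_tipi <- function(items_10, key = tipi_key()) {
  check_items(items_10, 10L, 1, 7, "TIPI")
  keyed <- items_10
  keyed[key$reversed] <- 8 - keyed[key$reversed]
  vapply(key$pairs, function(idx) mean(keyed[idx]), numeric(1))
}

#' Score the TEIQue short form to a global trait emotional intelligence score
#'
#' @param items_30 Thirty responses on the 1-7 scale.
#' @param reverse_key Indices of reverse-keyed items (recoded `8 - x`);
#'   defaults to [teique_reverse_key()].
#' @return Scalar global EI score in `[1, 7]`.
#' @export
score_teique <- function(items_30, reverse_key = teique_reverse_key()) {
  check_items(items_30, 30L, 1, 7, "TEIQue-SF")
  if (any(reverse_key < 1 | reverse_key > 30)) {
    stopf("config_error", "reverse key indices must be within 1..30")
  }
  keyed <- items_30
  keyed[reverse_key] <- 8 - keyed[reverse_key]
  mean(keyed)
}

#' Score the six mood semantic-differential items
#'
#' Three items measure valence and three arousal, each on a -3..3 scale; the
#' mood measure for a dimension is the mean of its three items.
#'
#' @param items_6 Six responses in -3..3.
#' @param valence_items,arousal_items Index mapping (defaults: first three
#'   valence, last three arousal).
#' @return Named numeric vector `c(valence, arousal)`.
#' @export
mood_scores <- function(items_6, valence_items = 1:3, arousal_items = 4:6) {
  check_items(items_6, 6L, -3, 3, "mood scale")
  c(valence = mean(items_6[valence_items]),
    arousal = mean(items_6[arousal_items]))
}

#' Mood change from pre- to post-session ratings
#'
#' @param pre,post Six-item mood responses (see [mood_scores()]).
#' @param ... Passed on to [mood_scores()].
#' @return Named numeric vector of post - pre differences per mood measure.
#' @export
mood_change <- function(pre, post, ...) {
  mood_scores(post, ...) - mood_scores(pre, ...)
}

#' A named two-level participant grouping
#'
#' @param name Factor name (e.g. `"Age"`).
#' @param participant Participant ids.
#' @param level Level label per participant; `"excluded"` removes a
#'   participant from this factor only.
#' @param levels The two level labels, low/reference level first.
#' @return A `grouping_factor` tibble.
#' @export
grouping_factor <- function(name, participant, level, levels) {
  stopifnot(length(participant) == length(level), length(levels) == 2)
  bad <- setdiff(unique(level), c(levels, "excluded"))
  if (length(bad)) {
    stopf("validation_error", "unknown level label(s) for %s: %s",
          name, paste(bad, collapse = ", "))
  }
  out <- tibble::tibble(participant = as.character(participant),
                        level = level)
  attr(out, "name") <- name
  attr(out, "levels") <- levels
  class(out) <- c("grouping_factor", class(out))
  out
}

#' Split participants at the sample mean of a trait score
#'
#' Participants are assigned to the high or low group by the sign of their
#' within-sample z-score. A score exactly at the mean (z = 0) goes to the
#' tie level ("low" by default) so the assignment is deterministic.
#'
#' @param scores Numeric trait scores.
#' @param participant Participant ids, same length.
#' @param name Factor name.
#' @param levels Level labels, low first.
#' @param tie Which side receives scores exactly at the mean.
#' @return A [grouping_factor()].
#' @export
dichotomize_by_mean <- function(scores, participant, name = "trait",
                                levels = c("low", "high"),
                                tie = c("low", "high")) {
  tie <- match.arg(tie)
  if (sum(is.finite(scores)) < 3) {
    stopf("validation_error", "need >= 3 finite scores to mean-split")
  }
  if (sd(scores) == 0) {
    stopf("degenerate_factor_error",
          "all %s scores identical; mean split undefined", name)
  }
  z <- (scores - mean(scores)) / sd(scores)
  lvl <- ifelse(z > 0, levels[2], levels[1])
  lvl[z == 0] <- if (tie == "low") levels[1] else levels[2]
  grouping_factor(name, participant, lvl, levels)
}

#' Categorize musical training into trained / untrained
#'
#' Only extensive training is expected to matter: ten or more years counts
#' as trained, under one year as untrained, and the middle band is excluded
#' from the musical-training factor (only).
#'
#' @param training_category Character vector of ordinal band labels:
#'   `"<1 yr"`, `"1-10 yr"`, `">10 yr"`.
#' @return Character vector of `"untrained"`, `"excluded"`, `"trained"`.
#' @export
categorize_training <- function(training_category) {
  map <- c("<1 yr" = "untrained", "1-10 yr" = "excluded",
           ">10 yr" = "trained")
  bad <- setdiff(unique(training_category), names(map))
  if (length(bad)) {
    stopf("validation_error", "unknown training category label(s): %s",
          paste(bad, collapse = ", "))
  }
  unname(map[training_category])
}

#' Categorize age with a split at 40 years
#'
#' Strictly greater than 40 counts as "old" (decline in emotional-prosody
#' perception has been located from this age); 40 and under is "young".
#'
#' @param age Age in years.
#' @return Character vector of `"young"` / `"old"`.
#' @export
categorize_age <- function(age) {
  if (any(age < 0, na.rm = TRUE)) {
    stopf("validation_error", "negative age")
  }
  ifelse(age > 40, "old", "young")
}

#' Score all questionnaires for a participant roster
#'
#' Expects item columns `tipi_1`..`tipi_10` and `teique_1`..`teique_30`.
#'
#' @param participants Roster tibble.
#' @param key,reverse_key Instrument keys.
#' @return Tibble of participant ids and the six trait scores.
#' @export
trait_scores <- function(participants, key = tipi_key(),
                         reverse_key = teique_reverse_key()) {
  tipi_m <- as.matrix(participants[paste0("tipi_", 1:10)])
  teique_m <- as.matrix(participants[paste0("teique_", 1:30)])
  tipi <- t(apply(tipi_m, 1, score_tipi, key = key))
  ei <- apply(teique_m, 1, score_teique, reverse_key = reverse_key)
  tibble::tibble(participant = as.character(participants$participant),
                 tibble::as_tibble(tipi), EI = ei)
}

#' Build the nine individual-difference grouping factors
#'
#' Five Big-Five mean splits, the EI mean split, gender as recorded,
#' musical training (trained vs untrained, middle band excluded) and the
#' age split at 40.
#'
#' @param participants Roster tibble with questionnaire item columns plus
#'   `age`, `gender` and `training_category`.
#' @param tie Tie rule for the mean splits, see [dichotomize_by_mean()].
#' @return Named list of nine [grouping_factor()] objects.
#' @export
build_grouping_factors <- function(participants, tie = "low") {
  ts <- trait_scores(participants)
  ids <- ts$participant
  traits <- c("Extroversion", "Agreeableness", "Conscientiousness",
              "EmotionalStability", "Openness", "EI")
  out <- lapply(traits, function(tr) {
    dichotomize_by_mean(ts[[tr]], ids, name = tr, tie = tie)
  })
  names(out) <- traits
  out$Gender <- grouping_factor("Gender", ids,
                                as.character(participants$gender),
                                levels = c("female", "male"))
  out$MusicalTraining <- grouping_factor(
    "MusicalTraining", ids,
    categorize_training(participants$training_category),
    levels = c("untrained", "trained"))
  out$Age <- grouping_factor("Age", ids,
                             categorize_age(participants$age),
                             levels = c("young", "old"))
  out[c(traits[1:5], "Gender", "EI", "MusicalTraining", "Age")]
}
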