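#' The seven-condition affective-face paradigm
#'
#' Condition labels and their valence classes for the passive-viewing
#' paradigm: five facial-expression categories (angry, fearful, happy, sad,
#' neutral), phase-scrambled faces, and a fixation baseline. Angry, fearful
#' and sad faces are the negative (avoidance) class; happy faces the
#' positive (approach) class; neutral faces are neutral; scrambled and
#' fixation are non-face baselines.
#'
#' @return A tibble with columns `condition`, `valence_class` and `is_face`.
#' @examples
#' face_conditions()
#' @export
face_conditions <- function() {
  tibble::tibble(
    condition = c("angry", "fearful", "happy", "sad", "neutral",
                  "scrambled", "fixation"),
    valence_class = c("negative", "negative", "positive", "negative",
                      "neutral", "baseline", "baseline"),
    is_face = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Map condition labels to valence classes
#'
#' @param condition Character vector of condition labels.
#' @return Character vector of valence classes (`negative`, `positive`,
#'   `neutral`, `baseline`); unknown labels give `NA`.
#' @examples
#' condition_valence(c("angry", "happy", "fixation"))
#' @export
condition_valence <- function(condition) {
  map <- face_conditions()
  map$valence_class[match(condition, map$condition)]
}

negative_conditions <- function() c("angry", "fearful", "sad")
positive_conditions <- function() "happy"
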