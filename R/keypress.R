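#' Viewing time implied by keypress counts
#'
#' In the keypress task a picture stays on screen for a default time unless
#' the subject works to lengthen (approach keys) or shorten (avoid keys)
#' it. Viewing time is modeled as a linear increment per net keypress,
#' clamped to bounds: `clamp(default + delta * (n_approach - n_avoid))`.
#' The effort-to-seconds exchange rate of the original task is not
#' published; `delta` and `bounds` are fully configurable.
#'
#' @param n_approach,n_avoid Non-negative keypress counts (vectorized).
#' @param default Default viewing time in seconds (default 6).
#' @param delta Seconds added per net approach keypress (default 0.1);
#'   must be positive.
#' @param bounds Length-2 numeric clamp in seconds (default `c(0, 14)`).
#' @return Viewing times in seconds.
#' @examples
#' compute_viewtime(0, 0)      # 6 s default
#' compute_viewtime(10, 0)     # 7 s
#' compute_viewtime(0, 100)    # clamped at 0
#' @export
compute_viewtime <- function(n_approach, n_avoid, default = 6.0,
                             delta = 0.1, bounds = c(0, 14)) {
  if (delta <= 0) abort("delta must be positive")
  if (any(n_approach < 0) || any(n_avoid < 0)) abort("counts must be non-negative")
  pmin(pmax(default + delta * (n_approach - n_avoid), bounds[1]), bounds[2])
}

#' Map button ids to approach/avoid key classes
#'
#' Buttons 1 and 2 lengthen viewing (approach); buttons 3 and 4 shorten it
#' (avoid). The map is configurable for other button boxes.
#'
#' @param key_id Integer or character vector of button ids.
#' @param key_map Named character vector mapping button id to class.
#' @return Character vector in `{approach, avoid}`.
#' @export
classify_keys <- function(key_id,
                          key_map = c(`1` = "approach", `2` = "approach",
                                      `3` = "avoid", `4` = "avoid")) {
  cls <- unname(key_map[as.character(key_id)])
  if (anyNA(cls)) {
    bad <- unique(key_id[is.na(cls)])
    abort(paste0("unknown key id(s): ", paste(bad, collapse = ", ")),
          class = "lapref_error_keys")
  }
  cls
}

#' Reduce keypress events to per-trial records
#'
#' Tallies approach and avoid keypresses per trial and computes the implied
#' viewing time. Trials present in `trials` (or implied by the events) with
#' no keypresses get counts of zero and the default viewing time.
#'
#' @param events Tibble of keypress events with columns `subject_id`,
#'   `trial_index`, `picture_id`, `category`, and either `key_class`
#'   (`approach`/`avoid`) or `key_id` (mapped via [classify_keys()]);
#'   `timestamp_s` is carried if present but order does not matter.
#' @param trials Optional tibble of trial stubs (`subject_id`,
#'   `trial_index`, `picture_id`, `category`) so that zero-keypress trials
#'   appear in the output; defaults to the trials observed in `events`.
#' @param key_map Passed to [classify_keys()] when `key_class` is absent.
#' @param default,delta,bounds Passed to [compute_viewtime()].
#' @return A tibble with one row per trial: `subject_id`, `trial_index`,
#'   `picture_id`, `category`, `n_approach`, `n_avoid`, `net`, `viewtime`.
#' @export
tally_trials <- function(events, trials = NULL,
                         key_map = c(`1` = "approach", `2` = "approach",
                                     `3` = "avoid", `4` = "avoid"),
                         default = 6.0, delta = 0.1, bounds = c(0, 14)) {
  if (!"key_class" %in% names(events)) {
    if (!"key_id" %in% names(events)) abort("events need key_class or key_id")
    events$key_class <- classify_keys(events$key_id, key_map)
  }
  bad <- setdiff(unique(events$key_class), c("approach", "avoid"))
  if (length(bad)) {
    abort(paste0("malformed key_class value(s): ", paste(bad, collapse = ", ")),
          class = "lapref_error_keys")
  }
  counts <- events |>
    dplyr::count(.data$subject_id, .data$trial_index, .data$picture_id,
                 .data$category, .data$key_class) |>
    tidyr::pivot_wider(names_from = "key_class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("approach", "avoid")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  if (is.null(trials)) {
    trials <- dplyr::distinct(events, .data$subject_id, .data$trial_index,
                              .data$picture_id, .data$category)
  }
  trials |>
    dplyr::left_join(counts,
                     by = c("subject_id", "trial_index", "picture_id", "category")) |>
    dplyr::mutate(
      n_approach = dplyr::coalesce(.data$approach, 0L),
      n_avoid = dplyr::coalesce(.data$avoid, 0L),
      net = .data$n_approach - .data$n_avoid,
      viewtime = compute_viewtime(.data$n_approach, .data$n_avoid,
                                  default = default, delta = delta,
                                  bounds = bounds),
      approach = NULL, avoid = NULL
    ) |>
    dplyr::arrange(.data$subject_id, .data$trial_index)
}

#' Shannon entropy of a count vector, in bits
#'
#' `H = -sum(p_j log2 p_j)` with `p_j = c_j / sum(c)`; zero counts
#' contribute nothing. An all-zero vector is degenerate and returns 0 with
#' a warning.
#'
#' @param counts Non-negative numeric vector.
#' @return Entropy in bits, between 0 (point mass) and `log2(length(counts))`
#'   (uniform).
#' @examples
#' shannon_entropy(c(5, 5, 5, 5)) # 2 bits
#' shannon_entropy(c(3, 1))       # 0.811 bits
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) {
    warn("all-zero counts: entropy of a degenerate category set to 0")
    return(0)
  }
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Per-category relative-preference coordinates (K, H)
#'
#' For each stimulus category, K is the mean over pictures of signed net
#' keypresses (approach minus avoid; positive K = approach limb, negative
#' K = avoidance limb), or the mean deviation of viewing time from the
#' default when `measure = "viewtime"`. H is the Shannon entropy in bits of
#' the per-picture total keypress counts within the category — the
#' uncertainty of how effort was distributed over that category's
#' pictures.
#'
#' Categories whose |K| falls inside the dead band (typically neutral or
#' scrambled stimuli) are labeled `limb = "neutral"` and excluded from
#' value-curve fitting downstream.
#'
#' @param trials Per-trial records from [tally_trials()] (columns
#'   `subject_id`, `picture_id`, `category`, `n_approach`, `n_avoid`,
#'   `viewtime`), one or more subjects.
#' @param measure `"keypresses"` (default) or `"viewtime"`.
#' @param default Default viewing time used for the viewtime deviation.
#' @param dead_band |K| below which a category is labeled neutral
#'   (default 0.05).
#' @return A tibble with one row per subject x category: `subject_id`,
#'   `category`, `valence_class`, `K`, `H`, `limb`, `n_pictures`,
#'   `mean_approach`, `mean_avoid`.
#' @examples
#' ses <- simulate_keypress_session(subject_spec("s1", true_lambda = 2), seed = 1)
#' category_valuation(ses$trials)
#' @export
category_valuation <- function(trials, measure = c("keypresses", "viewtime"),
                               default = 6.0, dead_band = 0.05) {
  measure <- match.arg(measure)
  per_picture <- trials |>
    dplyr::group_by(.data$subject_id, .data$category, .data$picture_id) |>
    dplyr::summarise(
      net = sum(.data$n_approach) - sum(.data$n_avoid),
      total = sum(.data$n_approach) + sum(.data$n_avoid),
      n_approach = sum(.data$n_approach),
      n_avoid = sum(.data$n_avoid),
      viewtime = mean(.data$viewtime),
      .groups = "drop"
    )
  per_picture |>
    dplyr::group_by(.data$subject_id, .data$category) |>
    dplyr::summarise(
      K = if (measure == "keypresses") mean(.data$net) else
        mean(.data$viewtime - .env$default),
      H = shannon_entropy(.data$total),
      n_pictures = dplyr::n(),
      mean_approach = mean(.data$n_approach),
      mean_avoid = mean(.data$n_avoid),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      valence_class = condition_valence(.data$category),
      limb = dplyr::case_when(
        abs(.data$K) <= dead_band ~ "neutral",
        .data$K > 0 ~ "approach",
        TRUE ~ "avoidance"
      )
    ) |>
    dplyr::select("subject_id", "category", "valence_class", "K", "H",
                  "limb", "n_pictures", "mean_approach", "mean_avoid")
}

#' Read or write keypress event logs as CSV
#'
#' Columns: `subject_id`, `trial_index`, `picture_id`, `category`,
#' `key_id`, `timestamp_s` (seconds from trial onset).
#'
#' @param events Keypress events tibble.
#' @param path File path.
#' @return `write_keypress_csv()` returns `path` invisibly;
#'   `read_keypress_csv()` a tibble of events.
#' @export
write_keypress_csv <- function(events, path) {
  cols <- intersect(
    c("subject_id", "trial_index", "picture_id", "category", "key_id", "timestamp_s"),
    names(events)
  )
  readr::write_csv(dplyr::select(events, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_keypress_csv
#' @export
read_keypress_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      trial_index = readr::col_integer(),
      picture_id = readr::col_character(),
      category = readr::col_character(),
      key_id = readr::col_integer(),
      timestamp_s = readr::col_double()
    ),
    progress = FALSE
  )
}
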