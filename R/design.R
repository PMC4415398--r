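#' Generate a counterbalanced block sequence
#'
#' Builds an ordered sequence of condition blocks for one run such that no
#' ordered pair of conditions occurs as a transition more than once (no
#' condition follows or precedes another more than once) and per-condition
#' block counts differ by at most one. The search is randomized backtracking
#' over the transition graph with a bounded number of node expansions.
#'
#' A 7-condition, 25-block run uses 24 of the 42 possible ordered pairs, so
#' a valid sequence always exists; the expansion cap guards degenerate
#' requests (e.g. `n_blocks` close to the theoretical maximum
#' `n_conditions * (n_conditions - 1) + 1`).
#'
#' @param n_blocks Number of blocks in the run.
#' @param conditions Character vector of condition labels, or a data frame
#'   with a `condition` column (default [face_conditions()]).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   sequence.
#' @param block_duration Block length in seconds (default 20).
#' @param run_index Run number, stored on the result (default 1).
#' @param prefix Optional condition label prepended as an extra block, the
#'   device used to carry counterbalancing across runs: run 2 starts with a
#'   copy of run 1's final block. The prefix does not count toward
#'   `n_blocks` balance and its outgoing transition is constrained like any
#'   other.
#' @param max_expansions Backtracking node-expansion budget before the
#'   search is declared infeasible (default 10000).
#' @return A `block_sequence` tibble with columns `block`, `condition`,
#'   `valence_class`, and attributes `block_duration` and `run_index`.
#' @examples
#' seq1 <- generate_block_sequence(25, seed = 1)
#' validate_counterbalance(seq1)
#' @export
generate_block_sequence <- function(n_blocks,
                                    conditions = face_conditions(),
                                    seed = NULL,
                                    block_duration = 20,
                                    run_index = 1L,
                                    prefix = NULL,
                                    max_expansions = 10000) {
  if (is.data.frame(conditions)) conditions <- conditions$condition
  conditions <- as.character(conditions)
  n_cond <- length(conditions)
  if (n_cond < 2) abort("need at least 2 conditions", class = "lapref_error_design")
  if (anyDuplicated(conditions)) abort("duplicate condition labels")
  if (n_blocks < 1) abort("n_blocks must be >= 1")
  if (n_blocks - 1 > n_cond * (n_cond - 1)) {
    abort(sprintf(
      "design infeasible: %d blocks need %d distinct transitions but only %d ordered pairs exist",
      n_blocks, n_blocks - 1, n_cond * (n_cond - 1)
    ), class = "lapref_error_infeasible")
  }
  if (!is.null(prefix) && !prefix %in% conditions) {
    abort("prefix must be one of the condition labels")
  }

  search <- function() {
    # used[i, j]: transition i -> j already consumed
    used <- matrix(FALSE, n_cond, n_cond, dimnames = list(conditions, conditions))
    counts <- setNames(integer(n_cond), conditions)
    cap <- ceiling(n_blocks / n_cond) # balance: no condition above ceiling
    path <- character(n_blocks)
    expansions <- 0L

    extend <- function(depth, prev) {
      if (depth > n_blocks) {
        return(max(counts) - min(counts) <= 1L)
      }
      cand <- conditions[counts[conditions] < cap]
      if (!is.null(prev)) cand <- cand[!used[prev, cand] & cand != prev]
      if (!length(cand)) return(FALSE)
      for (cond in sample(cand)) {
        expansions <<- expansions + 1L
        if (expansions > max_expansions) {
          abort("design infeasible: backtracking budget exhausted",
                class = "lapref_error_infeasible")
        }
        counts[cond] <<- counts[cond] + 1L
        if (!is.null(prev)) used[prev, cond] <<- TRUE
        path[depth] <<- cond
        if (extend(depth + 1L, cond)) return(TRUE)
        counts[cond] <<- counts[cond] - 1L
        if (!is.null(prev)) used[prev, cond] <<- FALSE
      }
      FALSE
    }

    prev0 <- NULL
    if (!is.null(prefix)) prev0 <- prefix
    if (!extend(1L, prev0)) {
      abort("design infeasible: no valid sequence found", class = "lapref_error_infeasible")
    }
    path
  }

  path <- if (is.null(seed)) search() else withr::with_seed(seed, search())
  if (!is.null(prefix)) path <- c(prefix, path)

  out <- tibble::tibble(
    block = seq_along(path),
    condition = path,
    valence_class = condition_valence(path)
  )
  attr(out, "block_duration") <- block_duration
  attr(out, "run_index") <- as.integer(run_index)
  class(out) <- c("block_sequence", class(out))
  out
}

#' Tally ordered condition transitions in a block sequence
#'
#' Counts every ordered pair of consecutive conditions and flags pairs that
#' occur more than once, i.e. violations of the counterbalancing rule that
#' no condition follows or precedes another more than once.
#'
#' @param seq A `block_sequence`, or any data frame with a `condition`
#'   column ordered by block.
#' @return A tibble with columns `from`, `to`, `n` and `flagged`
#'   (`n > 1`), one row per observed ordered pair.
#' @examples
#' s <- tibble::tibble(condition = c("A", "B", "A", "B"))
#' validate_counterbalance(s) # AB occurs twice -> flagged
#' @export
validate_counterbalance <- function(seq) {
  cond <- if (is.data.frame(seq)) seq$condition else as.character(seq)
  if (length(cond) < 2) {
    return(tibble::tibble(from = character(), to = character(),
                          n = integer(), flagged = logical()))
  }
  tibble::tibble(from = head(cond, -1), to = tail(cond, -1)) |>
    dplyr::count(.data$from, .data$to, name = "n") |>
    dplyr::mutate(flagged = .data$n > 1L)
}

#' Build a millisecond-resolution stimulus timeline from a block sequence
#'
#' Expands each block into stimulus events. Face blocks present
#' `n_identities` face identities `n_repetitions` times each in a
#' pseudorandom order with no identity shown twice in a row, each face for
#' `face_display` seconds followed by `isi` seconds of fixation cross
#' (defaults 200 ms + 300 ms, i.e. 40 faces filling a 20 s block).
#' Scrambled and fixation blocks are single events spanning the whole
#' block.
#'
#' @param seq A `block_sequence` from [generate_block_sequence()].
#' @param face_display Face presentation time in seconds (default 0.2).
#' @param isi Interstimulus interval in seconds (default 0.3).
#' @param n_identities Distinct face identities per block (default 8).
#' @param n_repetitions Repetitions of each identity per block (default 5).
#' @param seed Optional integer seed for the within-block face order.
#' @param block_duration Block length in seconds; defaults to the
#'   sequence's `block_duration` attribute, else 20.
#' @return A `stimulus_timeline` tibble with columns `onset`, `duration`,
#'   `trial_type`, `stim_id` and `block` (onsets in seconds from run
#'   start), with attribute `total_duration`.
#' @examples
#' tl <- generate_block_sequence(25, seed = 1) |> build_timeline(seed = 1)
#' attr(tl, "total_duration") # 25 blocks x 20 s
#' @export
build_timeline <- function(seq,
                           face_display = 0.200,
                           isi = 0.300,
                           n_identities = 8,
                           n_repetitions = 5,
                           seed = NULL,
                           block_duration = NULL) {
  if (face_display <= 0 || isi < 0) abort("timing parameters must be positive")
  if (n_identities < 1 || n_repetitions < 1) abort("need >= 1 identity and repetition")
  block_duration <- block_duration %||% attr(seq, "block_duration") %||% 20
  soa <- face_display + isi
  n_events <- n_identities * n_repetitions
  if (n_events * soa > block_duration + 1e-9) {
    abort("face events do not fit in the block duration")
  }
  face_set <- face_conditions()
  is_face <- setNames(face_set$is_face, face_set$condition)

  build <- function() {
    purrr::map_dfr(seq_len(nrow(seq)), function(i) {
      cond <- seq$condition[i]
      t0 <- (i - 1) * block_duration
      if (isTRUE(is_face[cond])) {
        ids <- shuffle_no_repeat(n_identities, n_repetitions)
        tibble::tibble(
          onset = t0 + (seq_len(n_events) - 1) * soa,
          duration = face_display,
          trial_type = cond,
          stim_id = sprintf("%s_face%02d", cond, ids),
          block = seq$block[i]
        )
      } else {
        tibble::tibble(onset = t0, duration = block_duration,
                       trial_type = cond, stim_id = cond,
                       block = seq$block[i])
      }
    })
  }
  events <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  attr(events, "total_duration") <- nrow(seq) * block_duration
  attr(events, "tr_hint") <- NULL
  class(events) <- c("stimulus_timeline", class(events))
  events
}

# Random order of n_identities x n_repetitions items with no identity twice
# in a row: sequential draw weighted by remaining counts, restarting on the
# rare dead end (feasible whenever max count <= total remaining / 2 + 1).
shuffle_no_repeat <- function(n_identities, n_repetitions, max_tries = 100) {
  if (n_identities == 1) {
    if (n_repetitions > 1) abort("cannot avoid immediate repeats with one identity")
    return(1L)
  }
  for (try in seq_len(max_tries)) {
    remaining <- rep.int(n_repetitions, n_identities)
    out <- integer(n_identities * n_repetitions)
    prev <- 0L
    ok <- TRUE
    for (k in seq_along(out)) {
      avail <- which(remaining > 0L & seq_len(n_identities) != prev)
      if (!length(avail)) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = remaining[avail])
      out[k] <- pick
      remaining[pick] <- remaining[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  abort("could not order faces without immediate repeats")
}

#' Write or read a stimulus timeline as a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`, `stim_id`;
#' onsets in seconds from run start.
#'
#' @param timeline A `stimulus_timeline` tibble.
#' @param path File path.
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` returns a `stimulus_timeline` tibble.
#' @export
write_events_tsv <- function(timeline, path) {
  readr::write_tsv(
    dplyr::select(as.data.frame(timeline), "onset", "duration", "trial_type", "stim_id"),
    path
  )
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  events <- readr::read_tsv(
    path,
    col_types = readr::cols(
      onset = readr::col_double(),
      duration = readr::col_double(),
      trial_type = readr::col_character(),
      stim_id = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  events <- dplyr::arrange(events, .data$onset)
  attr(events, "total_duration") <- max(events$onset + events$duration)
  class(events) <- c("stimulus_timeline", class(events))
  events
}
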