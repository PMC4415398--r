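# Small builders shared across tests.

# keypress events for one trial from explicit key ids
make_events <- function(key_ids, trial_index = 1L, picture_id = "p1",
                        category = "happy", subject_id = "s1",
                        timestamps = NULL) {
  n <- length(key_ids)
  tibble::tibble(
    subject_id = subject_id, trial_index = trial_index,
    picture_id = picture_id, category = category,
    key_id = as.integer(key_ids),
    timestamp_s = timestamps %||% (0.25 * seq_len(n))
  )
}

# trial table with given per-picture net counts for one category
make_trials <- function(nets, category, subject_id = "s1", offset = 0L) {
  n_app <- pmax(nets, 0L)
  n_avd <- pmax(-nets, 0L)
  tibble::tibble(
    subject_id = subject_id,
    trial_index = offset + seq_along(nets),
    picture_id = sprintf("%s_p%02d", category, seq_along(nets)),
    category = category,
    n_approach = as.integer(n_app),
    n_avoid = as.integer(n_avd),
    net = as.integer(nets),
    viewtime = lapref::compute_viewtime(n_app, n_avd)
  )
}

# two-limb point sets lying exactly on mirrored lines K = +/- slope * H
mirrored_line_points <- function(slope_neg, slope_pos, h = c(1, 2, 3)) {
  list(
    neg = tibble::tibble(H = h, K = -slope_neg * h),
    pos = tibble::tibble(H = h, K = slope_pos * h)
  )
}

# a short timeline with explicit blocks, as a plain tibble
make_block_timeline <- function(conditions, block_duration = 20) {
  tl <- tibble::tibble(
    onset = (seq_along(conditions) - 1) * block_duration,
    duration = block_duration,
    trial_type = conditions,
    stim_id = conditions,
    block = seq_along(conditions)
  )
  attr(tl, "total_duration") <- length(conditions) * block_duration
  tl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
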