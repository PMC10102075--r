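# In-code fixtures shared across test files.

# minimal schedule: one epoch per (eye, stimulus), contiguous, duration_s each
toy_schedule <- function(orientations = c(0, 90), duration_s = 10,
                         n_reps = 1, include_blank = TRUE) {
  stimuli <- c(as.character(orientations), if (include_blank) "BLANK")
  grid <- expand.grid(rep = seq_len(n_reps), stimulus = stimuli,
                      eye = c("contra", "ipsi"), stringsAsFactors = FALSE)
  n <- nrow(grid)
  tibble::tibble(
    epoch_id = seq_len(n),
    eye = grid$eye,
    stimulus = grid$stimulus,
    start_s = (seq_len(n) - 1) * duration_s,
    end_s = seq_len(n) * duration_s
  )
}

# spike table with given per-epoch counts (spikes spread inside each epoch)
spikes_for_epochs <- function(schedule, unit_id, counts) {
  stopifnot(length(counts) == nrow(schedule))
  times <- unlist(lapply(seq_len(nrow(schedule)), function(i) {
    if (counts[i] == 0) return(numeric())
    seq(schedule$start_s[i], schedule$end_s[i] - 1e-3,
        length.out = counts[i])
  }))
  tibble::tibble(unit_id = unit_id, spike_time_s = sort(times))
}

# response-summary rows for one unit (both eyes) from per-eye quantities
summary_rows <- function(unit_id, max_c, max_i, spont,
                         mean_c = max_c, mean_i = max_i) {
  tibble::tibble(
    unit_id = unit_id,
    eye = c("contra", "ipsi"),
    max_evoked_hz = c(max_c, max_i),
    preferred_deg = 0,
    mean_evoked_hz = c(mean_c, mean_i),
    spontaneous_hz = spont
  )
}

# unit metadata skeleton for dedup tests
unit_row <- function(unit_id, shank, electrode_index) {
  tibble::tibble(unit_id = unit_id, shank = shank,
                 electrode_index = electrode_index)
}
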