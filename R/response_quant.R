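# Response quantification: epoch firing rates, per-eye response summaries,
# the responsiveness filter, and adjacent-electrode duplicate removal.

#' Per-stimulus mean firing rates from spike times and a schedule
#'
#' For every unit and every (eye, stimulus) pair in the schedule, computes the
#' mean firing rate as total spikes falling in that stimulus's epochs divided
#' by the total epoch time (with the default 8 presentations of 10 s, 80 s
#' per stimulus). Epochs are half-open `[start_s, end_s)`: a spike at exactly
#' `end_s` belongs to the next epoch, or to none. Units present in `unit_ids`
#' but absent from the spike table get rate rows of 0.
#'
#' @param spikes Spike table (`unit_id`, `spike_time_s`).
#' @param schedule Stimulus schedule from [build_schedule()].
#' @param unit_ids Units to tabulate; defaults to those present in `spikes`.
#'
#' @return A tibble with one row per (unit, eye, stimulus): `unit_id`, `eye`,
#'   `stimulus`, `n_spikes`, `total_s`, `rate_hz`.
#' @export
epoch_rate_table <- function(spikes, schedule, unit_ids = NULL) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0) {
    stop("`schedule` must be a non-empty epoch table", call. = FALSE)
  }
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(spikes)))
  if (is.null(unit_ids)) unit_ids <- unique(spikes$unit_id)
  unit_ids <- as.character(unit_ids)
  n_units <- length(unit_ids)
  if (n_units == 0) stop("no units to tabulate", call. = FALSE)

  sched <- schedule[order(schedule$start_s), , drop = FALSE]
  n_ep <- nrow(sched)
  # half-open assignment: spike t lands in epoch i iff start_i <= t < end_i
  ep_of <- findInterval(spikes$spike_time_s, sched$start_s)
  inside <- ep_of >= 1L & spikes$spike_time_s < sched$end_s[pmax(ep_of, 1L)]
  unit_of <- match(spikes$unit_id, unit_ids)
  keep <- inside & !is.na(unit_of)
  key <- (unit_of[keep] - 1L) * n_ep + ep_of[keep]
  counts <- tabulate(key, nbins = n_units * n_ep)  # unit-major

  # aggregate epochs into (eye, stimulus) groups
  grp <- paste(sched$eye, sched$stimulus, sep = "\r")
  grp_levels <- unique(grp)
  gi <- match(grp, grp_levels)
  n_grp <- length(grp_levels)
  agg <- matrix(0, nrow = n_ep, ncol = n_grp)
  agg[cbind(seq_len(n_ep), gi)] <- 1
  count_mat <- matrix(counts, nrow = n_units, ncol = n_ep, byrow = TRUE) %*% agg
  total_s <- as.numeric((sched$end_s - sched$start_s) %*% agg)

  parts <- do.call(rbind, strsplit(grp_levels, "\r", fixed = TRUE))
  n_spikes <- as.vector(t(count_mat))
  denom <- rep(total_s, times = n_units)
  tibble::tibble(
    unit_id = rep(unit_ids, each = n_grp),
    eye = rep(parts[, 1], times = n_units),
    stimulus = rep(parts[, 2], times = n_units),
    n_spikes = n_spikes,
    total_s = denom,
    rate_hz = n_spikes / denom
  )
}

#' Per-unit, per-eye response summaries
#'
#' Reduces the rate table to the quantities the ocular-dominance analysis
#' consumes: for each unit and eye, the preferred orientation (argmax of the
#' orientation rates; ties broken toward the lowest orientation), the maximal
#' evoked rate at that orientation (C for the contralateral eye, I for the
#' ipsilateral eye), and the mean evoked rate across all orientations. The
#' spontaneous rate is the blank-screen rate pooled across both eyes' blank
#' presentations (a blank carries no eye-specific content).
#'
#' @param rates Rate table from [epoch_rate_table()]; must contain `BLANK`
#'   rows and a complete orientation set per (unit, eye).
#'
#' @return A tibble with one row per (unit, eye): `unit_id`, `eye`,
#'   `max_evoked_hz`, `preferred_deg`, `mean_evoked_hz`, `spontaneous_hz`.
#' @export
response_summary <- function(rates) {
  stopifnot(all(c("unit_id", "eye", "stimulus", "rate_hz") %in% names(rates)))
  blank <- rates[rates$stimulus == BLANK, , drop = FALSE]
  if (nrow(blank) == 0) {
    stop("rate table has no BLANK rows; spontaneous rate undefined",
         call. = FALSE)
  }
  evoked <- rates[rates$stimulus != BLANK, , drop = FALSE]
  evoked$orientation <- as.numeric(evoked$stimulus)

  n_ori <- length(unique(evoked$orientation))
  per_cell <- dplyr::count(evoked, .data$unit_id, .data$eye)
  if (any(per_cell$n != n_ori)) {
    bad <- per_cell[per_cell$n != n_ori, ]
    stop(sprintf(
      "incomplete orientation set for %d (unit, eye) pairs, e.g. unit %s / %s eye (%d of %d orientations)",
      nrow(bad), bad$unit_id[1], bad$eye[1], bad$n[1], n_ori), call. = FALSE)
  }

  if (!("n_spikes" %in% names(blank))) {
    blank$n_spikes <- blank$rate_hz * blank$total_s
  }
  spont <- dplyr::summarise(
    dplyr::group_by(blank, .data$unit_id),
    spontaneous_hz = sum(.data$n_spikes) / sum(.data$total_s),
    .groups = "drop"
  )

  summ <- dplyr::summarise(
    dplyr::group_by(evoked, .data$unit_id, .data$eye),
    max_evoked_hz = max(.data$rate_hz),
    preferred_deg = min(.data$orientation[.data$rate_hz == max(.data$rate_hz)]),
    mean_evoked_hz = mean(.data$rate_hz),
    .groups = "drop"
  )
  dplyr::left_join(summ, spont, by = "unit_id")
}

#' Percentage of units passing the responsiveness filter
#'
#' @param n_responsive Number of visually responsive units.
#' @param n_total Total units assessed.
#'
#' @return The percentage `100 * n_responsive / n_total`.
#' @export
#' @examples
#' percent_responsive(222, 263)  # 84.4 (to one decimal)
percent_responsive <- function(n_responsive, n_total) {
  stopifnot(n_total > 0, n_responsive >= 0, n_responsive <= n_total)
  100 * n_responsive / n_total
}

#' Apply the visual-responsiveness filter
#'
#' A unit is non-visually-responsive, and excluded, when its spontaneous
#' (blank-screen) firing rate exceeds its maximum evoked rate over both eyes;
#' a tie is retained since the criterion is strictly "higher than". Units
#' whose maximal evoked rates are zero for both eyes are additionally
#' excluded, with a distinct reason, because their ocular dominance index is
#' undefined.
#'
#' @param summaries Response summaries from [response_summary()], complete
#'   for both eyes.
#'
#' @return A list with `responsive` (the retained summary rows), `exclusions`
#'   (tibble `unit_id`, `reason`), and `summary` (tibble `n_total`,
#'   `n_responsive`, `percent_responsive`).
#' @export
filter_responsive <- function(summaries) {
  per_unit <- dplyr::summarise(
    dplyr::group_by(summaries, .data$unit_id),
    best_evoked = max(.data$max_evoked_hz),
    sum_max = sum(.data$max_evoked_hz),
    spont = .data$spontaneous_hz[1],
    n_eyes = dplyr::n(),
    .groups = "drop"
  )
  if (any(per_unit$n_eyes != 2L)) {
    stop("summaries must contain both eyes for every unit", call. = FALSE)
  }
  reason <- ifelse(per_unit$spont > per_unit$best_evoked,
                   "spontaneous exceeds evoked",
                   ifelse(per_unit$sum_max == 0, "zero evoked", NA_character_))
  excl <- tibble::tibble(unit_id = per_unit$unit_id, reason = reason)
  excl <- excl[!is.na(excl$reason), , drop = FALSE]
  keep <- setdiff(per_unit$unit_id, excl$unit_id)
  list(
    responsive = summaries[summaries$unit_id %in% keep, , drop = FALSE],
    exclusions = excl,
    summary = tibble::tibble(
      n_total = nrow(per_unit),
      n_responsive = length(keep),
      percent_responsive = percent_responsive(length(keep), nrow(per_unit))
    )
  )
}

#' Remove duplicate units detected on adjacent electrodes
#'
#' The inter-electrode spacing of a linear silicon probe allows one neuron's
#' waveform to be picked up on neighbouring contacts, producing sorted units
#' with identical spike timing. Any two units on the same shank whose
#' electrode indices differ by at most 1 and whose spike trains match
#' one-to-one within `tol_s` are treated as one neuron: the unit with the
#' lower electrode index survives (ties broken by unit id), and transitive
#' chains collapse to a single survivor.
#'
#' @param spikes Spike table.
#' @param units Unit metadata with `shank` and `electrode_index`.
#' @param tol_s Per-spike matching tolerance in seconds (default 0.1 ms,
#'   the scale of sampling-clock jitter).
#'
#' @return A list with filtered `spikes` and `units`, plus `removed`, a
#'   tibble (`unit_id`, `kept_as`) logging each removed duplicate and its
#'   surviving partner.
#' @export
dedup_units <- function(spikes, units, tol_s = 1e-4) {
  stopifnot(all(c("unit_id", "shank", "electrode_index") %in% names(units)))
  trains <- split(spikes$spike_time_s, spikes$unit_id)
  trains <- lapply(trains, sort)
  n <- nrow(units)
  comp <- seq_len(n)  # union-find over unit rows
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  same_train <- function(a, b) {
    !is.null(a) && !is.null(b) && length(a) == length(b) &&
      length(a) > 0 && max(abs(a - b)) <= tol_s
  }
  for (sh in unique(units$shank)) {
    rows <- which(units$shank == sh)
    rows <- rows[order(units$electrode_index[rows])]
    for (ii in seq_along(rows)) {
      for (jj in seq_along(rows)) {
        if (jj <= ii) next
        i <- rows[ii]; j <- rows[jj]
        if (abs(units$electrode_index[i] - units$electrode_index[j]) > 1) next
        if (same_train(trains[[units$unit_id[i]]],
                       trains[[units$unit_id[j]]])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  removed <- tibble::tibble(unit_id = character(), kept_as = character())
  drop_ids <- character()
  for (r in unique(root[duplicated(root) | duplicated(root, fromLast = TRUE)])) {
    members <- which(root == r)
    ord <- members[order(units$electrode_index[members],
                         units$unit_id[members])]
    survivor <- ord[1]
    losers <- ord[-1]
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      unit_id = units$unit_id[losers],
      kept_as = units$unit_id[survivor]
    ))
    drop_ids <- c(drop_ids, units$unit_id[losers])
  }
  list(
    spikes = spikes[!(spikes$unit_id %in% drop_ids), , drop = FALSE],
    units = units[!(units$unit_id %in% drop_ids), , drop = FALSE],
    removed = removed
  )
}
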