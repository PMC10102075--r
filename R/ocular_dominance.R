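# Ocular dominance quantification: per-unit ODI and 7-point class,
# per-animal class histograms and contralateral bias index, and empirical
# cumulative distributions for group comparison.

#' Ocular dominance index
#'
#' `(C - I) / (C + I)`, where C is the maximal visually evoked firing rate
#' for preferred-orientation stimuli presented to the contralateral eye and I
#' the maximal rate for the ipsilateral eye. Ranges from -1 (driven
#' exclusively by the ipsilateral eye) through 0 (balanced binocular) to +1
#' (exclusively contralateral). Vectorized.
#'
#' @param C Maximal contralateral-eye evoked rate(s), Hz, non-negative.
#' @param I Maximal ipsilateral-eye evoked rate(s), Hz, non-negative.
#'
#' @return Numeric ODI in `[-1, 1]`.
#' @export
#' @examples
#' odi(10, 0)  # +1: monocular, contralateral
#' odi(6, 2)   # 0.5
odi <- function(C, I) {
  if (any(C < 0) || any(I < 0)) {
    stop("evoked rates must be non-negative", call. = FALSE)
  }
  if (any(C + I == 0)) {
    stop("ODI undefined when C + I = 0 (filter such units upstream)",
         call. = FALSE)
  }
  (C - I) / (C + I)
}

OD_BREAKS <- c(-1, -0.75, -0.45, -0.15, 0.15, 0.45, 0.75, 1)

#' 7-point ocular dominance class from an ODI value
#'
#' Bins ODI onto the classical 7-point ocular dominance scale: class 1 for
#' ODI in `[0.75, 1]` (contralateral-exclusive) down to class 7 for ODI in
#' `[-1, -0.75)` (ipsilateral-exclusive), class 4 (`[-0.15, 0.15)`) being
#' binocular. Intervals are left-closed/right-open in ascending ODI, with the
#' top interval closed, so the seven classes partition `[-1, 1]` exactly and
#' every boundary value maps to exactly one class.
#'
#' @param odi Numeric ODI value(s) in `[-1, 1]`.
#'
#' @return Integer class(es) in `1:7`, non-increasing in ODI.
#' @export
#' @examples
#' od_class(c(0.8, 0, -0.9))  # 1, 4, 7
od_class <- function(odi) {
  if (any(!is.finite(odi)) || any(odi < -1) || any(odi > 1)) {
    stop("`odi` must lie in [-1, 1]", call. = FALSE)
  }
  8L - findInterval(odi, OD_BREAKS, rightmost.closed = TRUE)
}

#' Contralateral bias index from 7-class counts
#'
#' Per-animal weighted summary of the ocular dominance histogram:
#' `CBI = ((n1 - n7) + 2/3 (n2 - n6) + 1/3 (n3 - n5) + N) / (2 N)` with
#' `N = sum(n)`. Equals 1 when every neuron is contralateral-exclusive
#' (class 1), 0 when every neuron is ipsilateral-exclusive (class 7), and 0.5
#' for any class-symmetric population.
#'
#' @param counts Numeric vector of length 7: neurons per OD class 1..7.
#'
#' @return CBI in `[0, 1]`.
#' @export
#' @examples
#' cbi(c(20, 0, 0, 0, 0, 0, 0))  # 1
#' cbi(c(5, 3, 2, 8, 2, 3, 5))   # 0.5
cbi <- function(counts) {
  if (length(counts) != 7 || any(counts < 0) || any(!is.finite(counts))) {
    stop("`counts` must be 7 non-negative class counts", call. = FALSE)
  }
  N <- sum(counts)
  if (N == 0) stop("CBI undefined for N = 0", call. = FALSE)
  ((counts[1] - counts[7]) + 2 / 3 * (counts[2] - counts[6]) +
     1 / 3 * (counts[3] - counts[5]) + N) / (2 * N)
}

#' Per-unit ocular dominance records from response summaries
#'
#' Extracts C and I (the per-eye maximal evoked rates) for each responsive
#' unit and computes its ODI and 7-point class. The contralateral eye is
#' defined relative to the recorded hemisphere (contralateral to the
#' originally deprived eye); the eye labels in the summaries already encode
#' that mapping.
#'
#' @param responses Responsive summary rows, e.g.
#'   `filter_responsive(...)$responsive`.
#'
#' @return A tibble `unit_id`, `C`, `I`, `odi`, `od_class`.
#' @export
od_records <- function(responses) {
  wide <- tidyr::pivot_wider(
    responses[, c("unit_id", "eye", "max_evoked_hz")],
    names_from = "eye", values_from = "max_evoked_hz"
  )
  if (!all(EYES %in% names(wide))) {
    stop("responses must contain both contra and ipsi eyes", call. = FALSE)
  }
  if (any(is.na(wide$contra)) || any(is.na(wide$ipsi))) {
    stop("missing per-eye maximal rates for some units", call. = FALSE)
  }
  v <- odi(wide$contra, wide$ipsi)
  tibble::tibble(
    unit_id = wide$unit_id,
    C = wide$contra,
    I = wide$ipsi,
    odi = v,
    od_class = od_class(v)
  )
}

#' Per-animal OD class counts and contralateral bias index
#'
#' @param records OD records from [od_records()].
#' @param units Unit metadata supplying `animal_id` (and `condition`, if
#'   present, which is carried through).
#'
#' @return A tibble with one row per animal: `animal_id` (and `condition`),
#'   class counts `n1`..`n7`, `N`, and `cbi`.
#' @export
animal_summaries <- function(records, units) {
  stopifnot(all(c("unit_id", "animal_id") %in% names(units)))
  joined <- dplyr::inner_join(
    records, units[, intersect(names(units),
                               c("unit_id", "animal_id", "condition"))],
    by = "unit_id"
  )
  if (nrow(joined) == 0) stop("no records match the unit table", call. = FALSE)
  keys <- intersect(names(joined), c("animal_id", "condition"))
  out <- dplyr::reframe(
    dplyr::group_by(joined, dplyr::across(dplyr::all_of(keys))),
    {
      n <- tabulate(.data$od_class, nbins = 7)
      tibble::tibble(
        n1 = n[1], n2 = n[2], n3 = n[3], n4 = n[4],
        n5 = n[5], n6 = n[6], n7 = n[7],
        N = sum(n), cbi = cbi(n)
      )
    }
  )
  tibble::as_tibble(out)
}

#' 7-bin ocular dominance histogram per group
#'
#' @param records OD records from [od_records()], optionally joined with
#'   grouping metadata.
#' @param group_key Column name(s) to group by; `NULL` for one pooled
#'   histogram.
#'
#' @return A tibble with the grouping columns, `od_class` (1..7, all classes
#'   present) and `n`; the counts in each group sum to the group's record
#'   count.
#' @export
od_histogram <- function(records, group_key = NULL) {
  if (nrow(records) == 0) stop("no records to histogram", call. = FALSE)
  if (is.null(group_key)) {
    records$.all <- "all"
    group_key <- ".all"
  }
  out <- dplyr::reframe(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(group_key))),
    {
      counts <- tabulate(.data$od_class, nbins = 7)
      tibble::tibble(od_class = 1:7, n = counts)
    }
  )
  out$.all <- NULL
  tibble::as_tibble(out)
}

#' Empirical cumulative distribution function as sorted pairs
#'
#' Right-continuous ECDF, returned as the sorted unique values and the
#' cumulative proportion at each, so that `cum_prop` at the largest value
#' is 1. Used to plot and compare group-level ODI distributions.
#'
#' @param values Non-empty numeric vector.
#'
#' @return A tibble `value` (sorted, unique), `cum_prop`.
#' @export
#' @examples
#' od_ecdf(c(1, 2, 3))  # F(2) = 2/3
od_ecdf <- function(values) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  x <- sort(unique(values))
  counts <- tabulate(match(values, x), nbins = length(x))
  tibble::tibble(value = x, cum_prop = cumsum(counts) / length(values))
}

#' Run the ocular dominance pipeline on one dataset
#'
#' Convenience driver chaining the full analysis: adjacent-electrode
#' duplicate removal, per-stimulus rate tables, response summaries, the
#' responsiveness filter, per-unit OD records, and per-animal summaries.
#'
#' @param dataset A list with `schedule`, `spikes`, `units` (as produced by
#'   [simulate_experiment()] or [read_experiment()]).
#'
#' @return A list with `rates`, `responses`, `filter` (responsiveness filter
#'   output), `records`, `animals`, and `dedup` (duplicate-removal log).
#' @export
analyze_od_experiment <- function(dataset) {
  stopifnot(all(c("schedule", "spikes", "units") %in% names(dataset)))
  dd <- dedup_units(dataset$spikes, dataset$units)
  rates <- epoch_rate_table(dd$spikes, dataset$schedule,
                            unit_ids = dd$units$unit_id)
  responses <- response_summary(rates)
  filt <- filter_responsive(responses)
  records <- od_records(filt$responsive)
  animals <- animal_summaries(records, dd$units)
  list(rates = rates, responses = responses, filter = filt,
       records = records, animals = animals, dedup = dd$removed)
}
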