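test_that("epoch rates average spikes over total presentation time", {
  # one stimulus, 8 epochs of 10 s, 10 spikes each -> 80 / 80 s = 1 Hz
  sched <- toy_schedule(orientations = 0, include_blank = FALSE, n_reps = 8)
  contra <- sched[sched$eye == "contra", ]
  spk <- spikes_for_epochs(sched, "u1", rep(10, nrow(sched)))
  rates <- epoch_rate_table(spk, sched)
  expect_equal(nrow(rates), 2)
  expect_equal(rates$total_s, c(80, 80))
  expect_equal(rates$rate_hz, c(1, 1))

  # a unit with no spikes gets rate rows of zero, not an error
  empty <- epoch_rate_table(spk, sched, unit_ids = c("u1", "u2"))
  expect_equal(empty$rate_hz[empty$unit_id == "u2"], c(0, 0))

  expect_error(epoch_rate_table(spk, sched[0, ]), "non-empty")
})

test_that("epoch assignment is half-open: a spike at end_s is not in that epoch", {
  sched <- tibble::tibble(epoch_id = 1:2, eye = "contra",
                          stimulus = c("0", "90"),
                          start_s = c(0, 10), end_s = c(10, 20))
  spk <- tibble::tibble(unit_id = "u1", spike_time_s = c(0, 5, 10, 19.999, 20))
  rates <- epoch_rate_table(spk, sched)
  # 0 and 5 in epoch 1; 10 belongs to epoch 2 (closed start); 20 to none
  expect_equal(rates$n_spikes[rates$stimulus == "0"], 2)
  expect_equal(rates$n_spikes[rates$stimulus == "90"], 2)
  expect_equal(sum(rates$n_spikes), 4)
})

test_that("rate table conserves spike mass across disjoint epochs", {
  cfg <- condition_config("NR", n_animals = 1, n_units_per_animal = 25,
                          seed = 8)
  pop <- build_population(cfg)
  sched <- build_schedule(seed = 8)
  spk <- simulate_spikes(pop, sched, seed = 9)
  rates <- epoch_rate_table(spk, sched, unit_ids = pop$unit_id)
  inside <- spk$spike_time_s < max(sched$end_s)
  expect_equal(sum(rates$n_spikes), sum(inside))
})

test_that("estimated rates match the Poisson standard-error oracle", {
  # 5 Hz homogeneous unit under the 8 x 10 s design: SE = sqrt(5 / 80)
  sched <- build_schedule(seed = 3)
  pop <- tibble::tibble(unit_id = sprintf("u%02d", 1:20), pref_deg = 0,
                        baseline_hz = 5, gain_contra_hz = 0,
                        gain_ipsi_hz = 0, kappa = 2)
  spk <- simulate_spikes(pop, sched, seed = 4)
  rates <- epoch_rate_table(spk, sched, unit_ids = pop$unit_id)
  err <- abs(rates$rate_hz - 5)
  expect_gt(mean(err <= 3 * sqrt(5 / 80)), 0.98)
})

test_that("response summaries take per-eye maxima with the stated tie-break", {
  oris <- as.character(seq(0, 157.5, by = 22.5))
  base <- tidyr::crossing(unit_id = "u1", eye = c("contra", "ipsi"),
                          stimulus = c(oris, "BLANK"))
  base$total_s <- 80

  flat <- base
  flat$rate_hz <- ifelse(flat$stimulus == "BLANK", 1, 2)
  flat$n_spikes <- flat$rate_hz * flat$total_s
  s <- response_summary(flat)
  expect_equal(s$max_evoked_hz, c(2, 2))
  expect_equal(s$mean_evoked_hz, c(2, 2))
  expect_equal(unique(s$spontaneous_hz), 1)

  peaked <- base
  peaked$rate_hz <- ifelse(peaked$stimulus == "45", 8, 0)
  peaked$n_spikes <- peaked$rate_hz * peaked$total_s
  s <- response_summary(peaked)
  expect_equal(s$max_evoked_hz, c(8, 8))
  expect_equal(s$mean_evoked_hz, c(1, 1))
  expect_equal(s$preferred_deg, c(45, 45))

  tied <- base
  tied$rate_hz <- ifelse(tied$stimulus %in% c("0", "90"), 5, 0)
  tied$n_spikes <- tied$rate_hz * tied$total_s
  s <- response_summary(tied)
  expect_equal(s$preferred_deg, c(0, 0))  # tie -> lowest orientation

  expect_error(response_summary(flat[flat$stimulus != "BLANK", ]), "BLANK")
  gap <- flat[!(flat$stimulus == "22.5" & flat$eye == "ipsi"), ]
  expect_error(response_summary(gap), "incomplete orientation")
})

test_that("spontaneous rate pools blank presentations across both eyes", {
  oris <- as.character(seq(0, 157.5, by = 22.5))
  tab <- tidyr::crossing(unit_id = "u1", eye = c("contra", "ipsi"),
                         stimulus = c(oris, "BLANK"))
  tab$total_s <- 80
  tab$rate_hz <- ifelse(tab$stimulus == "BLANK",
                        ifelse(tab$eye == "contra", 2, 4), 6)
  tab$n_spikes <- tab$rate_hz * tab$total_s
  s <- response_summary(tab)
  expect_equal(unique(s$spontaneous_hz), 3)  # (160 + 320) / 160 s
})

test_that("responsiveness filter excludes by the strict spontaneous > evoked rule", {
  summaries <- dplyr::bind_rows(
    summary_rows("quiet", max_c = 2, max_i = 1, spont = 5),   # excluded
    summary_rows("driven", max_c = 5, max_i = 2, spont = 2),  # retained
    summary_rows("tied", max_c = 3, max_i = 1, spont = 3),    # tie retained
    summary_rows("dead", max_c = 0, max_i = 0, spont = 0)     # undefined ODI
  )
  out <- filter_responsive(summaries)
  expect_setequal(unique(out$responsive$unit_id), c("driven", "tied"))
  expect_equal(out$exclusions$reason[out$exclusions$unit_id == "quiet"],
               "spontaneous exceeds evoked")
  expect_equal(out$exclusions$reason[out$exclusions$unit_id == "dead"],
               "zero evoked")
  expect_equal(out$summary$n_total, 4)
  expect_equal(out$summary$n_responsive, 2)

  expect_error(filter_responsive(summaries[summaries$eye == "contra", ]),
               "both eyes")
})

test_that("retention under the default NR generator is high", {
  cfg <- condition_config("NR", n_animals = 2, n_units_per_animal = 60,
                          seed = 14)
  ds <- simulate_experiment(cfg)
  res <- analyze_od_experiment(ds)
  expect_gt(res$filter$summary$percent_responsive, 80)
})

test_that("duplicate removal keeps the lower electrode and collapses chains", {
  train <- withr::with_seed(99, sort(runif(200, 0, 100)))
  units <- dplyr::bind_rows(
    unit_row("a", 1, 10), unit_row("a_dup", 1, 11),
    unit_row("far", 1, 15),          # same train, non-adjacent: kept
    unit_row("jit", 1, 9),           # adjacent but jittered 2 ms: kept
    unit_row("c1", 2, 5), unit_row("c2", 2, 6), unit_row("c3", 2, 7)
  )
  spikes <- dplyr::bind_rows(
    tibble::tibble(unit_id = "a", spike_time_s = train),
    tibble::tibble(unit_id = "a_dup", spike_time_s = train),
    tibble::tibble(unit_id = "far", spike_time_s = train),
    tibble::tibble(unit_id = "jit", spike_time_s = train + 2e-3),
    tibble::tibble(unit_id = "c1", spike_time_s = train + 50),
    tibble::tibble(unit_id = "c2", spike_time_s = train + 50),
    tibble::tibble(unit_id = "c3", spike_time_s = train + 50)
  )
  out <- dedup_units(spikes, units)
  expect_setequal(out$units$unit_id, c("a", "far", "jit", "c1"))
  expect_equal(sort(out$removed$unit_id), c("a_dup", "c2", "c3"))
  expect_true(all(out$removed$kept_as[out$removed$unit_id %in%
                                        c("c2", "c3")] == "c1"))
  expect_false("a_dup" %in% out$spikes$unit_id)
})

test_that("the printed responsive-unit percentage follows from its counts", {
  expect_equal(round(percent_responsive(222, 263), 1), 84.4)
  expect_error(percent_responsive(5, 0))
})
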