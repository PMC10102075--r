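test_that("schedule contains every (eye, stimulus) pair the right number of times", {
  sched <- build_schedule(n_orientations = 8, duration_s = 10, n_reps = 8,
                          include_blank = TRUE, seed = 1)
  expect_equal(nrow(sched), 2 * 9 * 8)
  expect_equal(max(sched$end_s), 1440)
  exposure <- aggregate(end_s - start_s ~ eye + stimulus, data = sched, sum)
  expect_true(all(exposure[[3]] == 80))
  tab <- table(sched$eye, sched$stimulus)
  expect_true(all(tab == 8))

  tiny <- build_schedule(1, 1, 1, include_blank = FALSE, seed = 0)
  expect_equal(nrow(tiny), 2)
})

test_that("schedule epochs are sorted, non-overlapping and seed-reproducible", {
  s1 <- build_schedule(seed = 11)
  s2 <- build_schedule(seed = 11)
  s3 <- build_schedule(seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(s1$stimulus, s3$stimulus))
  expect_true(all(diff(s1$start_s) > 0))
  expect_true(all(s1$end_s[-nrow(s1)] <= s1$start_s[-1]))
  expect_error(build_schedule(duration_s = 0), "positive")
  expect_error(build_schedule(n_reps = 0), "positive")
})

test_that("population draws cell types at the configured fast-spiking fraction", {
  f <- 0.18
  n <- 1000
  cfg <- condition_config("NR", n_animals = 1, n_units_per_animal = n,
                          fs_fraction = f, seed = 3)
  pop <- build_population(cfg)
  n_fs <- sum(pop$true_type == "FS")
  # binomial oracle: count within 3 SD of n * f
  expect_lt(abs(n_fs - n * f), 3 * sqrt(n * f * (1 - f)))
  expect_lt(mean(pop$half_width_ms[pop$true_type == "FS"]),
            mean(pop$half_width_ms[pop$true_type == "RS"]))

  all_rs <- build_population(condition_config(fs_fraction = 0,
                                              n_animals = 1,
                                              n_units_per_animal = 50))
  expect_true(all(all_rs$true_type == "RS"))

  expect_identical(build_population(cfg), build_population(cfg))
})

test_that("population units carry valid metadata and condition gains", {
  cfg <- condition_config("MD", n_animals = 2, n_units_per_animal = 30,
                          seed = 5)
  pop <- build_population(cfg)
  expect_equal(nrow(pop), 60)
  expect_true(all(pop$half_width_ms > 0))
  expect_true(all(pop$electrode_index >= 0))
  expect_true(all(pop$layer %in% c("L23", "L4", "L56")))
  g <- default_condition_gains("MD")
  rs <- pop[pop$true_type == "RS", ]
  expect_true(all(rs$gain_contra_hz ==
                    g$peak_gain_contra_hz[g$cell_type == "RS"]))
  expect_true(all(rs$gain_ipsi_hz == g$peak_gain_ipsi_hz[g$cell_type == "RS"]))
})

test_that("blank-epoch spike counts follow the Poisson oracle", {
  # one unit, baseline 5 Hz, 1000 blank epochs of 10 s
  n_ep <- 1000
  sched <- tibble::tibble(
    epoch_id = seq_len(n_ep), eye = "contra", stimulus = "BLANK",
    start_s = (seq_len(n_ep) - 1) * 10, end_s = seq_len(n_ep) * 10
  )
  pop <- tibble::tibble(unit_id = "u1", pref_deg = 0, baseline_hz = 5,
                        gain_contra_hz = 0, gain_ipsi_hz = 0, kappa = 2)
  sched$stimulus[1] <- "0"  # keep the stimulus set non-empty for validation
  spk <- simulate_spikes(pop, sched, seed = 2)
  counts <- tabulate(findInterval(spk$spike_time_s, sched$start_s),
                     nbins = n_ep)
  counts <- counts[-1]  # drop the non-blank epoch
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / length(counts)))
  # Poisson moments: variance ~ mean within Monte-Carlo error
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.2)
})

test_that("tuned units fire more at the preferred orientation, silent units not at all", {
  sched <- build_schedule(n_orientations = 8, duration_s = 10, n_reps = 8,
                          seed = 4)
  pop <- tibble::tibble(unit_id = "u1", pref_deg = 0, baseline_hz = 0,
                        gain_contra_hz = 10, gain_ipsi_hz = 10, kappa = 2)
  spk <- simulate_spikes(pop, sched, seed = 9)
  rates <- epoch_rate_table(spk, sched, unit_ids = "u1")
  pref <- rates$rate_hz[rates$stimulus == "0"]
  orth <- rates$rate_hz[rates$stimulus == "90"]
  expect_true(all(pref > orth))

  silent <- tibble::tibble(unit_id = "u0", pref_deg = 0, baseline_hz = 0,
                           gain_contra_hz = 0, gain_ipsi_hz = 0, kappa = 2)
  expect_equal(nrow(simulate_spikes(silent, sched, seed = 1)), 0)

  bad_pop <- tibble::tibble(unit_id = "u1", pref_deg = 33, baseline_hz = 1,
                            gain_contra_hz = 1, gain_ipsi_hz = 1, kappa = 2)
  expect_error(simulate_spikes(bad_pop, sched), "stimulus set")
})

test_that("duplicate injection clones spike trains onto adjacent electrodes", {
  cfg <- condition_config("NR", n_animals = 1, n_units_per_animal = 100,
                          seed = 21)
  pop <- build_population(cfg)
  sched <- build_schedule(seed = 21)
  spk <- simulate_spikes(pop, sched, seed = 22)

  none <- inject_duplicates(spk, pop, 0, seed = 1)
  expect_identical(none$spikes, spk)
  expect_identical(none$units, pop)

  out <- inject_duplicates(spk, pop, 0.1, seed = 23)
  clones <- out$units[out$units$is_duplicate, ]
  expect_gt(nrow(clones), 0)
  expect_lt(abs(nrow(clones) - 10), 3 * sqrt(100 * 0.1 * 0.9))
  for (i in seq_len(nrow(clones))) {
    src <- out$units[out$units$unit_id == clones$source_unit[i], ]
    expect_equal(abs(clones$electrode_index[i] - src$electrode_index), 1)
    expect_equal(clones$shank[i], src$shank)
    expect_identical(
      out$spikes$spike_time_s[out$spikes$unit_id == clones$unit_id[i]],
      out$spikes$spike_time_s[out$spikes$unit_id == clones$source_unit[i]]
    )
  }
  expect_error(inject_duplicates(spk, pop, 1), "\\[0, 1\\)")
})

test_that("cell-map counts follow the configured Poisson intensities", {
  cfg <- condition_config("NR", n_animals = 20, seed = 31)
  areas <- tibble::tibble(region = "bV1", layer = "L23", area_mm2 = 0.1)
  ints <- tibble::tibble(condition = "NR", region = "bV1", layer = "L23",
                         cfos_per_mm2 = 1000, pv_per_mm2 = 0,
                         coactivation = 0)
  maps <- simulate_cellmaps(cfg, layer_areas = areas, intensities = ints,
                            n_sections = 3, seed = 32)
  counts <- dplyr::count(maps$cells, animal_id, section_id)
  # 60 sections at mean 100 cells each
  expect_equal(nrow(counts), 60)
  expect_lt(abs(mean(counts$n) - 100), 3 * sqrt(100 / 60))
  expect_true(all(maps$cells$y_um >= 100 & maps$cells$y_um <= 300))

  empty <- simulate_cellmaps(cfg, layer_areas = areas,
                             intensities = dplyr::mutate(ints,
                                                         cfos_per_mm2 = 0),
                             n_sections = 3, seed = 33)
  expect_equal(nrow(empty$cells), 0)

  expect_error(
    simulate_cellmaps(cfg, layer_areas = areas,
                      intensities = dplyr::mutate(ints, cfos_per_mm2 = -1)),
    "non-negative"
  )
})

test_that("default intensity table keeps PV and the A1 control condition-invariant", {
  ints <- default_cellmap_intensities()
  expect_equal(length(unique(ints$pv_per_mm2)), 1L)
  a1 <- ints[ints$region == "A1", ]
  per_layer <- split(a1, a1$layer)
  for (tab in per_layer) {
    expect_equal(length(unique(tab$cfos_per_mm2)), 1L)
    expect_equal(length(unique(tab$coactivation)), 1L)
  }
  # bV1 layer 2/3 carries the condition effect: MD depressed below NR
  l23 <- ints[ints$region == "bV1" & ints$layer == "L23", ]
  expect_lt(l23$cfos_per_mm2[l23$condition == "MD"],
            l23$cfos_per_mm2[l23$condition == "NR"])
})

test_that("on-disk experiments validate and reproduce byte-identically", {
  cfg <- condition_config("NR", n_animals = 1, n_units_per_animal = 6,
                          duplicate_fraction = 0.2, seed = 41)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- run_experiment(cfg, d1)
  run_experiment(cfg, d2)
  files <- c("schedule.csv", "spikes.csv", "units.csv", "cellmaps.csv",
             "cellmap_areas.csv", "manifest.yml")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  back <- read_experiment(d1)
  expect_equal(nrow(back$schedule), 144)
  expect_setequal(names(back$units), names(simulate_experiment(cfg)$units))
  expect_equal(back$manifest$seed, 41)
  expect_true(all(c("epoch_id", "eye", "stimulus", "start_s", "end_s")
                  %in% names(back$schedule)))
})
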