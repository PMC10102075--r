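# Synthetic-experiment generator: stimulus schedules, tuned Poisson spiking
# populations under condition-specific eye gains, duplicate-unit injection,
# and cFos/PV cell maps. Every operation is a pure function of (inputs, seed).

HALF_WIDTH_PARAMS <- list(
  FS = c(mean = 0.22, sd = 0.03),
  RS = c(mean = 0.50, sd = 0.07)
)

# depth bands below the pia, in micrometres
LAYER_BANDS <- list(
  L23 = c(100, 300),
  L4  = c(300, 400),
  L56 = c(400, 700)
)

#' Default per-condition eye-gain table
#'
#' Peak evoked gains (Hz above baseline, at the preferred orientation) for the
#' contralateral and ipsilateral eye, per cell type, for one of the six
#' experimental conditions. The normally-reared (NR) values encode the ~2:1
#' contralateral bias of mouse binocular V1; monocular deprivation (MD)
#' depresses the deprived (contra) eye and potentiates the spared (ipsi) eye;
#' binocular recovery (BR, and BR followed by sleep) restores NR gains;
#' reverse occlusion (RO) recovers only partially; BR followed by sleep
#' deprivation (BR_SD) leaves MD-like gains in place. Fast-spiking units fire
#' at roughly three times regular-spiking rates. These magnitudes are
#' generative stand-ins chosen to reproduce the qualitative condition ordering
#' of the recovery design, not measured values.
#'
#' @param condition One of `"NR"`, `"MD"`, `"BR"`, `"RO"`, `"BR_SLEEP"`,
#'   `"BR_SD"`.
#'
#' @return A tibble with columns `cell_type`, `baseline_hz`,
#'   `peak_gain_contra_hz`, `peak_gain_ipsi_hz`.
#' @export
#' @examples
#' default_condition_gains("MD")
default_condition_gains <- function(condition = CONDITIONS) {
  condition <- match.arg(condition)
  mult <- switch(condition,
    NR       = c(contra = 1.0, ipsi = 1.0),
    MD       = c(contra = 0.5, ipsi = 1.8),
    BR       = c(contra = 1.0, ipsi = 1.0),
    RO       = c(contra = 0.8, ipsi = 1.4),
    BR_SLEEP = c(contra = 1.0, ipsi = 1.0),
    BR_SD    = c(contra = 0.5, ipsi = 1.8)
  )
  base <- tibble::tibble(
    cell_type = c("RS", "FS"),
    baseline_hz = c(1, 3),
    peak_gain_contra_hz = c(8, 24) * mult[["contra"]],
    peak_gain_ipsi_hz = c(4, 12) * mult[["ipsi"]]
  )
  base
}

#' Configuration for one synthetic experimental condition
#'
#' Bundles everything the generator needs to emulate one treatment group:
#' the condition label, cohort size, fast-spiking fraction, orientation-tuning
#' concentration, the per-cell-type eye-gain table, the duplicate-unit
#' injection rate, and the master seed.
#'
#' @param condition Treatment group, one of the six experimental conditions.
#' @param n_animals Number of mice in the group.
#' @param n_units_per_animal Stably recorded units per mouse.
#' @param fs_fraction Proportion of fast-spiking interneurons, in (0, 1)
#'   (0 is allowed and yields an all-RS population).
#' @param kappa von Mises concentration of orientation tuning (on the doubled
#'   angle, period 180 degrees).
#' @param n_orientations Number of grating orientations in the stimulus set.
#' @param duplicate_fraction Fraction of units cloned onto an adjacent
#'   electrode, in `[0, 1)`.
#' @param gains Eye-gain table as returned by [default_condition_gains()].
#' @param seed Master seed; all randomness in the generator derives from it.
#'
#' @return A list of class `condition_config`.
#' @export
#' @examples
#' cfg <- condition_config("MD", n_animals = 2, n_units_per_animal = 10)
condition_config <- function(condition = "NR",
                             n_animals = 5,
                             n_units_per_animal = 48,
                             fs_fraction = 0.18,
                             kappa = 2,
                             n_orientations = 8,
                             duplicate_fraction = 0,
                             gains = default_condition_gains(condition),
                             seed = 1L) {
  condition <- match.arg(condition, CONDITIONS)
  assert_scalar_count(n_animals, "n_animals")
  assert_scalar_count(n_units_per_animal, "n_units_per_animal")
  assert_scalar_count(n_orientations, "n_orientations")
  assert_scalar_pos(kappa, "kappa")
  if (!is.numeric(fs_fraction) || fs_fraction < 0 || fs_fraction >= 1) {
    stop("`fs_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(duplicate_fraction) ||
      duplicate_fraction < 0 || duplicate_fraction >= 1) {
    stop("`duplicate_fraction` must lie in [0, 1)", call. = FALSE)
  }
  req <- c("cell_type", "baseline_hz", "peak_gain_contra_hz",
           "peak_gain_ipsi_hz")
  if (!all(req %in% names(gains)) ||
      !all(c("RS", "FS") %in% gains$cell_type)) {
    stop("`gains` must contain RS and FS rows with baseline and eye gains",
         call. = FALSE)
  }
  if (any(gains$baseline_hz < 0) || any(gains$peak_gain_contra_hz < 0) ||
      any(gains$peak_gain_ipsi_hz < 0)) {
    stop("all rates in `gains` must be non-negative", call. = FALSE)
  }
  structure(
    list(condition = condition,
         n_animals = as.integer(n_animals),
         n_units_per_animal = as.integer(n_units_per_animal),
         fs_fraction = fs_fraction,
         kappa = kappa,
         n_orientations = as.integer(n_orientations),
         duplicate_fraction = duplicate_fraction,
         gains = gains,
         seed = as.integer(seed)),
    class = "condition_config"
  )
}

#' Build a randomly interleaved eye-specific stimulus schedule
#'
#' Produces the presentation clock of a recording session: for each eye, every
#' grating orientation (and optionally a blank screen, used for spontaneous
#' rates) is shown `n_reps` times for `duration_s` seconds each, with all
#' epochs randomly interleaved. Epochs are contiguous and non-overlapping
#' under the half-open convention `[start_s, end_s)`.
#'
#' @param n_orientations Number of equally spaced grating orientations
#'   covering 0-180 degrees (8 gives 0, 22.5, ..., 157.5).
#' @param duration_s Duration of each epoch in seconds.
#' @param n_reps Presentations of each (eye, stimulus) pair.
#' @param include_blank Include a blank-screen stimulus per eye?
#' @param seed Seed for the interleaving order.
#'
#' @return A tibble with columns `epoch_id`, `eye`, `stimulus` (orientation in
#'   degrees as character, or `"BLANK"`), `start_s`, `end_s`, sorted by
#'   `start_s`.
#' @export
#' @examples
#' sched <- build_schedule()
#' nrow(sched)  # 2 eyes x 9 stimuli x 8 reps = 144
build_schedule <- function(n_orientations = 8, duration_s = 10, n_reps = 8,
                           include_blank = TRUE, seed = 1L) {
  assert_scalar_count(n_orientations, "n_orientations")
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_count(n_reps, "n_reps")
  orientations <- seq(0, 180, length.out = n_orientations + 1)[-(n_orientations + 1)]
  stimuli <- as.character(orientations)
  if (include_blank) stimuli <- c(stimuli, BLANK)
  grid <- expand.grid(rep = seq_len(n_reps), stimulus = stimuli, eye = EYES,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  ord <- withr::with_seed(seed, sample.int(n))
  grid <- grid[ord, , drop = FALSE]
  tibble::tibble(
    epoch_id = seq_len(n),
    eye = grid$eye,
    stimulus = grid$stimulus,
    start_s = (seq_len(n) - 1) * duration_s,
    end_s = seq_len(n) * duration_s
  )
}

schedule_orientations <- function(schedule) {
  sort(as.numeric(unique(schedule$stimulus[schedule$stimulus != BLANK])))
}

# draw from Normal(mean, sd) truncated at zero (rejection; the tail mass
# below zero is negligible for the half-width defaults)
rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Generate a synthetic unit population for one condition
#'
#' Assigns each unit an animal, shank, electrode, cortical layer, cell type
#' (Bernoulli draw at the configured fast-spiking fraction), a waveform
#' half-width drawn from a type-specific truncated normal (FS narrower), a
#' preferred orientation uniform over the stimulus set, and baseline/per-eye
#' peak gains from the condition's gain table. Ground-truth columns
#' (`true_type`, generating rates, `is_duplicate`) are retained so downstream
#' recovery can be scored.
#'
#' @param config A [condition_config()].
#'
#' @return A tibble of unit metadata, one row per unit.
#' @export
#' @examples
#' pop <- build_population(condition_config(n_animals = 1,
#'                                          n_units_per_animal = 8))
build_population <- function(config) {
  stopifnot(inherits(config, "condition_config"))
  n <- config$n_animals * config$n_units_per_animal
  orientations <- seq(0, 180, length.out = config$n_orientations + 1)[-(config$n_orientations + 1)]
  withr::with_seed(derive_seed(config$seed, 1L), {
    is_fs <- rbinom(n, 1L, config$fs_fraction) == 1L
    type <- ifelse(is_fs, "FS", "RS")
    hw <- numeric(n)
    for (tt in c("RS", "FS")) {
      idx <- which(type == tt)
      p <- HALF_WIDTH_PARAMS[[tt]]
      hw[idx] <- rnorm_pos(length(idx), p[["mean"]], p[["sd"]])
    }
    layer <- sample(LAYERS, n, replace = TRUE, prob = c(0.35, 0.25, 0.40))
    shank <- sample(1:2, n, replace = TRUE)
    electrode_index <- sample(0:31, n, replace = TRUE)
    pref <- sample(orientations, n, replace = TRUE)
  })
  animal <- rep(sprintf("%s_a%02d", config$condition, seq_len(config$n_animals)),
                each = config$n_units_per_animal)
  g <- config$gains[match(type, config$gains$cell_type), ]
  tibble::tibble(
    unit_id = sprintf("%s_u%04d", config$condition, seq_len(n)),
    animal_id = animal,
    condition = config$condition,
    shank = shank,
    electrode_index = electrode_index,
    layer = layer,
    half_width_ms = hw,
    true_type = type,
    pref_deg = pref,
    baseline_hz = g$baseline_hz,
    gain_contra_hz = g$peak_gain_contra_hz,
    gain_ipsi_hz = g$peak_gain_ipsi_hz,
    kappa = config$kappa,
    is_duplicate = FALSE,
    source_unit = NA_character_
  )
}

# orientation tuning on the doubled angle, normalized to 1 at the preferred
# orientation so the configured gain is the peak gain
tuning_factor <- function(theta_deg, pref_deg, kappa) {
  exp(kappa * (cos(2 * (theta_deg - pref_deg) * pi / 180) - 1))
}

#' Simulate Poisson spike trains for a population against a schedule
#'
#' Each unit fires as a homogeneous Poisson process within each epoch, with
#' rate `baseline + eye_gain * tuning(orientation)` where the tuning factor is
#' a von Mises bump on the doubled orientation angle, equal to 1 at the
#' preferred orientation. Blank epochs evoke the baseline rate only. Epoch
#' counts are independent; spike times are uniform within the epoch.
#'
#' @param population Unit table from [build_population()].
#' @param schedule Stimulus schedule from [build_schedule()].
#' @param seed Seed for spike generation.
#'
#' @return A tibble with columns `unit_id`, `spike_time_s`, sorted by unit and
#'   ascending time.
#' @export
simulate_spikes <- function(population, schedule, seed = 1L) {
  stopifnot(is.data.frame(population), is.data.frame(schedule),
            nrow(schedule) > 0)
  sched_ori <- schedule_orientations(schedule)
  if (!all(population$pref_deg %in% sched_ori)) {
    stop("population preferred orientations are not in the schedule's ",
         "stimulus set", call. = FALSE)
  }
  n_units <- nrow(population)
  n_ep <- nrow(schedule)
  dur <- schedule$end_s - schedule$start_s
  is_blank <- schedule$stimulus == BLANK
  theta <- suppressWarnings(as.numeric(schedule$stimulus))
  gain <- ifelse(schedule$eye == "contra",
                 rep(population$gain_contra_hz, each = n_ep),
                 rep(population$gain_ipsi_hz, each = n_ep))
  # unit-major layout: rows of length n_ep per unit
  theta_rep <- rep(theta, times = n_units)
  pref_rep <- rep(population$pref_deg, each = n_ep)
  kappa_rep <- rep(population$kappa, each = n_ep)
  tune <- ifelse(rep(is_blank, times = n_units), 0,
                 tuning_factor(theta_rep, pref_rep, kappa_rep))
  rate <- rep(population$baseline_hz, each = n_ep) + gain * tune
  lam <- rate * rep(dur, times = n_units)
  withr::with_seed(seed, {
    counts <- rpois(length(lam), lam)
    total <- sum(counts)
    u <- runif(total)
  })
  start_rep <- rep(rep(schedule$start_s, times = n_units), times = counts)
  dur_rep <- rep(rep(dur, times = n_units), times = counts)
  unit_rep <- rep(rep(seq_len(n_units), each = n_ep), times = counts)
  times <- start_rep + dur_rep * u
  ord <- order(unit_rep, times, method = "radix")
  tibble::tibble(
    unit_id = population$unit_id[unit_rep[ord]],
    spike_time_s = times[ord]
  )
}

#' Clone a fraction of units onto adjacent electrodes
#'
#' Emulates the situation the duplicate filter must catch: the same neuron's
#' waveform detected on two neighbouring electrode contacts, yielding two
#' "units" with identical spike timing. Each selected unit is cloned with
#' spike times copied verbatim onto electrode index +1 (or -1 at the top of
#' the probe) on the same shank; clones are flagged in ground truth.
#'
#' @param spikes Spike table.
#' @param units Unit metadata table.
#' @param duplicate_fraction Per-unit cloning probability, in `[0, 1)`.
#' @param seed Seed for clone selection.
#'
#' @return A list with elements `spikes` and `units`, each with clones
#'   appended (`is_duplicate = TRUE`, `source_unit` set).
#' @export
inject_duplicates <- function(spikes, units, duplicate_fraction, seed = 1L) {
  if (!is.numeric(duplicate_fraction) ||
      duplicate_fraction < 0 || duplicate_fraction >= 1) {
    stop("`duplicate_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (duplicate_fraction == 0) {
    return(list(spikes = spikes, units = units))
  }
  pick <- withr::with_seed(seed,
    rbinom(nrow(units), 1L, duplicate_fraction) == 1L)
  if (!any(pick)) return(list(spikes = spikes, units = units))
  clones <- units[pick, , drop = FALSE]
  clones$source_unit <- clones$unit_id
  clones$unit_id <- paste0(clones$unit_id, "_dup")
  clones$is_duplicate <- TRUE
  clones$electrode_index <- ifelse(clones$electrode_index < 31,
                                   clones$electrode_index + 1L,
                                   clones$electrode_index - 1L)
  clone_spikes <- spikes[spikes$unit_id %in% clones$source_unit, , drop = FALSE]
  clone_spikes$unit_id <- paste0(clone_spikes$unit_id, "_dup")
  list(
    spikes = dplyr::bind_rows(spikes, clone_spikes),
    units = dplyr::bind_rows(units, clones)
  )
}

#' Default layer areas for cell-map sections
#'
#' Counted area per cortical layer and region, in square millimetres, for one
#' coronal section. Corresponds to a 1 mm-wide field spanning depth bands
#' (micrometres below the pia) of 100-300 for layer 2/3, 300-400 for layer 4,
#' and 400-700 for layers 5/6, in both binocular V1 and the A1 control region.
#'
#' @return A tibble with columns `region`, `layer`, `area_mm2`.
#' @export
default_layer_areas <- function() {
  tidyr::crossing(region = c("bV1", "A1"),
                  tibble::tibble(layer = LAYERS,
                                 area_mm2 = c(0.2, 0.1, 0.3)))
}

#' Default cFos/PV intensity table
#'
#' Expected cell densities (cells per square millimetre) per condition, region
#' and layer, plus the probability that a parvalbumin-positive cell is also
#' cFos-positive. The binocular-V1 layer 2/3 cFos intensity carries the
#' condition effect (depressed after MD and after sleep-deprived recovery,
#' partially recovered after reverse occlusion, fully recovered after
#' binocular recovery with sleep); PV density is condition-invariant
#' everywhere, and the A1 control region is identical across conditions.
#' Magnitudes are generative stand-ins.
#'
#' @return A tibble with columns `condition`, `region`, `layer`,
#'   `cfos_per_mm2`, `pv_per_mm2`, `coactivation`.
#' @export
default_cellmap_intensities <- function() {
  grid <- tidyr::crossing(condition = CONDITIONS,
                          region = c("bV1", "A1"),
                          layer = LAYERS)
  cfos_l23 <- c(NR = 400, MD = 200, BR = 400, RO = 300,
                BR_SLEEP = 400, BR_SD = 200)
  coact_l23 <- c(NR = 0.35, MD = 0.15, BR = 0.35, RO = 0.25,
                 BR_SLEEP = 0.35, BR_SD = 0.15)
  grid$cfos_per_mm2 <- ifelse(grid$region == "A1", 300,
    ifelse(grid$layer == "L23", cfos_l23[grid$condition], 250))
  grid$pv_per_mm2 <- 300
  grid$coactivation <- ifelse(grid$region == "A1", 0.25,
    ifelse(grid$layer == "L23", coact_l23[grid$condition], 0.25))
  grid
}

#' Simulate layered cFos/PV cell maps for one condition
#'
#' Draws, for each animal, section, region and layer, PV+ cell bodies as a
#' homogeneous Poisson point process at the configured PV intensity; each PV
#' cell is cFos+ with the co-activation probability, and additional
#' cFos+/PV- cells are drawn at the residual cFos intensity so the marginal
#' cFos density matches the table. Points are uniform within the layer's depth
#' band. A1 intensities are condition-invariant by construction of the default
#' table, providing the activity-invariant control region.
#'
#' @param config A [condition_config()] (supplies condition, cohort size and
#'   seed).
#' @param layer_areas Counted area per region/layer, as
#'   [default_layer_areas()].
#' @param intensities Intensity table, as [default_cellmap_intensities()].
#' @param n_sections Sections counted per animal.
#' @param seed Seed; defaults to a stream derived from the config seed.
#'
#' @return A list with `cells` (tibble: `animal_id`, `condition`, `region`,
#'   `section_id`, `layer`, `x_um`, `y_um`, `cfos`, `pv`) and `areas`
#'   (the `layer_areas` table).
#' @export
simulate_cellmaps <- function(config,
                              layer_areas = default_layer_areas(),
                              intensities = default_cellmap_intensities(),
                              n_sections = 3,
                              seed = derive_seed(config$seed, 5L)) {
  stopifnot(inherits(config, "condition_config"))
  assert_scalar_count(n_sections, "n_sections")
  if (any(intensities$cfos_per_mm2 < 0) || any(intensities$pv_per_mm2 < 0)) {
    stop("cell-map intensities must be non-negative", call. = FALSE)
  }
  if (any(intensities$coactivation < 0) || any(intensities$coactivation > 1)) {
    stop("`coactivation` probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(layer_areas$area_mm2 <= 0)) {
    stop("layer areas must be positive", call. = FALSE)
  }
  tab <- dplyr::inner_join(
    layer_areas,
    intensities[intensities$condition == config$condition, ],
    by = c("region", "layer")
  )
  animals <- sprintf("%s_a%02d", config$condition, seq_len(config$n_animals))
  draws <- tidyr::crossing(animal_id = animals,
                           section_id = seq_len(n_sections),
                           tab)
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(draws)), function(i) {
      row <- draws[i, ]
      band <- LAYER_BANDS[[row$layer]]
      height_um <- band[2] - band[1]
      width_um <- row$area_mm2 * 1e6 / height_um
      n_pv <- rpois(1L, row$pv_per_mm2 * row$area_mm2)
      pv_cfos <- rbinom(n_pv, 1L, row$coactivation) == 1L
      resid <- max(row$cfos_per_mm2 - row$coactivation * row$pv_per_mm2, 0)
      n_cf <- rpois(1L, resid * row$area_mm2)
      n_tot <- n_pv + n_cf
      if (n_tot == 0L) return(NULL)
      tibble::tibble(
        animal_id = row$animal_id,
        condition = config$condition,
        region = row$region,
        section_id = row$section_id,
        layer = row$layer,
        x_um = runif(n_tot, 0, width_um),
        y_um = runif(n_tot, band[1], band[2]),
        cfos = c(pv_cfos, rep(TRUE, n_cf)),
        pv = c(rep(TRUE, n_pv), rep(FALSE, n_cf))
      )
    })
  })
  list(cells = dplyr::bind_rows(out), areas = layer_areas)
}

#' Simulate a full in-memory experiment for one condition
#'
#' Runs the generator end to end: one stimulus schedule, a unit population,
#' Poisson spike trains, optional duplicate injection, and cFos/PV cell maps,
#' all seeded from the config's master seed.
#'
#' @param config A [condition_config()].
#'
#' @return A list with `schedule`, `spikes`, `units`, `cellmaps` (cells
#'   tibble), `cellmap_areas`, and the `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "condition_config"))
  schedule <- build_schedule(n_orientations = config$n_orientations,
                             seed = derive_seed(config$seed, 2L))
  units <- build_population(config)
  spikes <- simulate_spikes(units, schedule,
                            seed = derive_seed(config$seed, 3L))
  if (config$duplicate_fraction > 0) {
    dup <- inject_duplicates(spikes, units, config$duplicate_fraction,
                             seed = derive_seed(config$seed, 4L))
    spikes <- dup$spikes
    units <- dup$units
  }
  maps <- simulate_cellmaps(config)
  list(schedule = schedule, spikes = spikes, units = units,
       cellmaps = maps$cells, cellmap_areas = maps$areas, config = config)
}

#' Run a synthetic experiment and write it to disk
#'
#' Materializes [simulate_experiment()] as the pipeline's canonical CSV
#' layout: `schedule.csv`, `spikes.csv`, `units.csv`, `cellmaps.csv`,
#' `cellmap_areas.csv`, plus a `manifest.yml` recording the configuration and
#' seed. Rerunning with the same config reproduces byte-identical tables.
#'
#' @param config A [condition_config()].
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, the list of file paths written.
#' @export
run_experiment <- function(config, out_dir) {
  ds <- simulate_experiment(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- list(
    schedule = file.path(out_dir, "schedule.csv"),
    spikes = file.path(out_dir, "spikes.csv"),
    units = file.path(out_dir, "units.csv"),
    cellmaps = file.path(out_dir, "cellmaps.csv"),
    cellmap_areas = file.path(out_dir, "cellmap_areas.csv"),
    manifest = file.path(out_dir, "manifest.yml")
  )
  readr::write_csv(ds$schedule, paths$schedule)
  readr::write_csv(ds$spikes, paths$spikes)
  readr::write_csv(ds$units, paths$units)
  readr::write_csv(ds$cellmaps, paths$cellmaps)
  readr::write_csv(ds$cellmap_areas, paths$cellmap_areas)
  manifest <- unclass(config)
  manifest$gains <- as.list(manifest$gains)
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

#' Read an on-disk experiment back into memory
#'
#' @param dir Directory written by [run_experiment()].
#'
#' @return A list with the same elements as [simulate_experiment()] (without
#'   the config object; the manifest is returned as a plain list).
#' @export
read_experiment <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    p
  }
  spec_cols <- readr::cols(stimulus = readr::col_character(),
                           .default = readr::col_guess())
  list(
    schedule = readr::read_csv(path("schedule.csv"), col_types = spec_cols,
                               progress = FALSE),
    spikes = readr::read_csv(path("spikes.csv"), show_col_types = FALSE,
                             progress = FALSE),
    units = readr::read_csv(path("units.csv"), show_col_types = FALSE,
                            progress = FALSE),
    cellmaps = readr::read_csv(path("cellmaps.csv"), show_col_types = FALSE,
                               progress = FALSE),
    cellmap_areas = readr::read_csv(path("cellmap_areas.csv"),
                                    show_col_types = FALSE, progress = FALSE),
    manifest = yaml::read_yaml(path("manifest.yml"))
  )
}

#' Draw a per-unit ODI sample for one condition at the count level
#'
#' Generates the ocular dominance index distribution the full pipeline would
#' estimate for a population under the given condition, working directly with
#' the per-stimulus Poisson spike counts (the pipeline's sufficient
#' statistic) instead of materializing spike times. For each unit: draw a
#' cell type and preferred orientation, draw per-orientation spike counts for
#' both eyes over the `n_reps x duration_s` presentation design, estimate the
#' per-eye maximal rates, and compute the ODI. Units with zero evoked rates
#' for both eyes are dropped, mirroring the responsiveness pipeline's
#' undefined-ODI exclusion.
#'
#' @param condition Experimental condition.
#' @param n_units Number of units to draw.
#' @param seed Seed.
#' @param config Optional [condition_config()] overriding the defaults.
#' @param duration_s,n_reps Presentation design (defaults 10 s x 8).
#'
#' @return Numeric vector of ODI values (length at most `n_units`).
#' @export
simulate_odi_sample <- function(condition = "NR", n_units = 200, seed = 1L,
                                config = condition_config(condition),
                                duration_s = 10, n_reps = 8) {
  orientations <- seq(0, 180,
                      length.out = config$n_orientations + 1)[-(config$n_orientations + 1)]
  total_s <- duration_s * n_reps
  withr::with_seed(seed, {
    type <- ifelse(rbinom(n_units, 1L, config$fs_fraction) == 1L, "FS", "RS")
    g <- config$gains[match(type, config$gains$cell_type), ]
    pref <- sample(orientations, n_units, replace = TRUE)
    tune <- tuning_factor(
      matrix(orientations, n_units, config$n_orientations, byrow = TRUE),
      pref, config$kappa
    )
    rate_c <- g$baseline_hz + g$peak_gain_contra_hz * tune
    rate_i <- g$baseline_hz + g$peak_gain_ipsi_hz * tune
    C <- apply(matrix(rpois(length(rate_c), rate_c * total_s),
                      nrow = n_units) / total_s, 1, max)
    I <- apply(matrix(rpois(length(rate_i), rate_i * total_s),
                      nrow = n_units) / total_s, 1, max)
  })
  ok <- C + I > 0
  odi(C[ok], I[ok])
}
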