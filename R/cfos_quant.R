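# Layer-resolved cFos/PV density quantification from labeled cell maps,
# per-animal section averaging, and the A1 control-region comparison.

#' Per-layer marker densities from cell maps
#'
#' Counts cFos+, PV+ and double-labeled (cFos+PV+) cell bodies per cortical
#' layer in each section and divides by the layer's counted area, yielding
#' approximate densities in cells per square millimetre. Layers with a
#' configured area but no points get density 0. Densities are computed on
#' 2-D projected point patterns; co-labeling is point coincidence of the two
#' markers on the same cell.
#'
#' @param cells Cell-map point table (`animal_id`, `condition`, `region`,
#'   `section_id`, `layer`, `cfos`, `pv`).
#' @param areas Layer areas (`region`, `layer`, `area_mm2`), all positive.
#'
#' @return A tibble with one row per (animal, region, section, layer):
#'   the identifiers plus `density_cfos`, `density_pv`, `density_colabel`
#'   (cells/mm^2).
#' @export
layer_density <- function(cells, areas) {
  stopifnot(all(c("region", "layer", "area_mm2") %in% names(areas)))
  if (any(!is.finite(areas$area_mm2)) || any(areas$area_mm2 <= 0)) {
    stop("layer areas must be positive", call. = FALSE)
  }
  missing_area <- !paste(cells$region, cells$layer) %in%
    paste(areas$region, areas$layer)
  if (any(missing_area)) {
    stop("no counted area configured for some (region, layer) in the cell map",
         call. = FALSE)
  }
  counts <- dplyr::summarise(
    dplyr::group_by(cells, .data$animal_id, .data$condition, .data$region,
                    .data$section_id, .data$layer),
    n_cfos = sum(.data$cfos),
    n_pv = sum(.data$pv),
    n_colabel = sum(.data$cfos & .data$pv),
    .groups = "drop"
  )
  # a section with no points in some layer still contributes density 0 there
  sections <- dplyr::distinct(cells, .data$animal_id, .data$condition,
                              .data$region, .data$section_id)
  grid <- dplyr::inner_join(sections, areas, by = "region",
                            relationship = "many-to-many")
  out <- dplyr::left_join(grid, counts,
                          by = c("animal_id", "condition", "region",
                                 "section_id", "layer"))
  out[c("n_cfos", "n_pv", "n_colabel")][is.na(out[c("n_cfos", "n_pv",
                                                    "n_colabel")])] <- 0
  out$density_cfos <- out$n_cfos / out$area_mm2
  out$density_pv <- out$n_pv / out$area_mm2
  out$density_colabel <- out$n_colabel / out$area_mm2
  tibble::as_tibble(out[, c("animal_id", "condition", "region", "section_id",
                            "layer", "density_cfos", "density_pv",
                            "density_colabel")])
}

#' Average section densities per animal
#'
#' Values for each mouse are the arithmetic mean of its section densities
#' per (region, layer, marker). Note this is the mean of per-section
#' densities, which equals pooled-count/pooled-area only when all section
#' areas are equal.
#'
#' @param records Section-level densities from [layer_density()].
#'
#' @return A tibble with one row per (animal, region, layer): mean densities
#'   and `n_sections`.
#' @export
animal_average <- function(records) {
  if (nrow(records) == 0) stop("no density records", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(records, .data$animal_id, .data$condition, .data$region,
                    .data$layer),
    density_cfos = mean(.data$density_cfos),
    density_pv = mean(.data$density_pv),
    density_colabel = mean(.data$density_colabel),
    n_sections = dplyr::n(),
    .groups = "drop"
  )
}

#' Compare group densities across conditions for one region
#'
#' Runs [anova_tukey()] per layer and marker on per-animal densities, the
#' comparison used both for the binocular-V1 effects of interest and for the
#' A1 control region.
#'
#' @param records Animal-level densities from [animal_average()].
#' @param region Region to test.
#' @param alpha Significance level for the `significant` flags.
#'
#' @return A tibble with one row per (layer, marker): `F`, `df1`, `df2`, `p`,
#'   `significant`, and the full [stat_result] in a list column `result`.
#' @export
density_group_comparison <- function(records, region, alpha = 0.05) {
  sub <- records[records$region == region, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for region ", region, call. = FALSE)
  if (length(unique(sub$condition)) < 2) {
    stop("need at least 2 conditions to compare", call. = FALSE)
  }
  markers <- c(cfos = "density_cfos", pv = "density_pv",
               colabel = "density_colabel")
  rows <- list()
  for (ly in sort(unique(sub$layer))) {
    for (m in names(markers)) {
      d <- sub[sub$layer == ly, , drop = FALSE]
      groups <- split(d[[markers[[m]]]], d$condition)
      res <- anova_tukey(groups, alpha = alpha)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = ly, marker = m,
        F = unname(res$statistic[["F"]]),
        df1 = res$df[1], df2 = res$df[2],
        p = res$p_value,
        significant = res$p_value < alpha,
        result = list(res)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' A1 control-region invariance check
#'
#' In the study design, cFos and PV expression in primary auditory cortex
#' (A1) should not differ between experimental groups; a significant omnibus
#' difference there flags a generation or acquisition artifact. Runs
#' [density_group_comparison()] on the A1 records and reports whether the
#' control passes (no omnibus p below `alpha`).
#'
#' @param records Animal-level densities from [animal_average()], including
#'   A1 rows for at least 2 conditions.
#' @param alpha Omnibus significance level.
#'
#' @return A list of class `control_check`: `table` (per layer/marker omnibus
#'   results), `pass` (logical), `alpha`.
#' @export
control_region_check <- function(records, alpha = 0.05) {
  if (!any(records$region == "A1")) {
    stop("no A1 records: control region missing", call. = FALSE)
  }
  tab <- density_group_comparison(records, region = "A1", alpha = alpha)
  structure(list(table = tab, pass = !any(tab$significant), alpha = alpha),
            class = "control_check")
}

#' @export
print.control_check <- function(x, ...) {
  cat(sprintf("<A1 control check: %s (alpha = %g)>\n",
              if (x$pass) "PASS" else "FLAGGED", x$alpha))
  print(x$table[, c("layer", "marker", "F", "p", "significant")])
  invisible(x)
}
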