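# RS/FS unit classification from waveform half-width and firing rate, with a
# multivariate cluster-separation check.

#' Assemble classification features for a unit population
#'
#' @param units Unit metadata with `unit_id` and `half_width_ms`.
#' @param rates Rate table from [epoch_rate_table()]; the overall rate is the
#'   duration-weighted mean across all epochs (all stimuli, both eyes).
#'
#' @return A tibble `unit_id`, `half_width_ms`, `overall_rate_hz`.
#' @export
class_features <- function(units, rates) {
  overall <- dplyr::summarise(
    dplyr::group_by(rates, .data$unit_id),
    overall_rate_hz = sum(.data$n_spikes) / sum(.data$total_s),
    .groups = "drop"
  )
  out <- dplyr::inner_join(units[, c("unit_id", "half_width_ms")], overall,
                           by = "unit_id")
  tibble::as_tibble(out)
}

scale_or_zero <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Classify units into regular-spiking and fast-spiking types
#'
#' Fast-spiking (putative parvalbumin-expressing) interneurons have narrower
#' spike waveforms and higher firing rates than regular-spiking principal
#' neurons; plotted on those two axes the populations form two clusters. The
#' classifier formalizes the usual visual cluster cut as a deterministic
#' two-group k-means partition on standardized half-width and standardized
#' `log(1 + rate)` (the log tames the right skew of rate distributions), run
#' with a fixed-seed multi-start. The cluster with the smaller mean
#' half-width is labelled FS; if that cluster does not also have the higher
#' mean firing rate the labels stand but a consistency warning is recorded.
#'
#' @param features Feature table from [class_features()].
#' @param seed Seed for the k-means multi-start (fixed for reproducibility).
#'
#' @return A list of class `class_result`: `labels` (tibble `unit_id`,
#'   `label`), `centroids` (per-label feature means), `separation` (the
#'   [separation_check()] result), `warnings` (character vector).
#' @export
classify_units <- function(features, seed = 101L) {
  stopifnot(all(c("unit_id", "half_width_ms", "overall_rate_hz")
                %in% names(features)))
  if (nrow(features) < 4) {
    stop("at least 4 units are required for classification", call. = FALSE)
  }
  if (!all(is.finite(features$half_width_ms)) ||
      !all(is.finite(features$overall_rate_hz))) {
    stop("classification features must be finite", call. = FALSE)
  }
  x <- cbind(hw = scale_or_zero(features$half_width_ms),
             lr = scale_or_zero(log1p(features$overall_rate_hz)))
  if (all(x == 0)) {
    stop("degenerate input: all units have identical features", call. = FALSE)
  }
  km <- withr::with_seed(seed, stats::kmeans(x, centers = 2, nstart = 25))
  mean_hw <- tapply(features$half_width_ms, km$cluster, mean)
  fs_cluster <- as.integer(names(which.min(mean_hw)))
  label <- ifelse(km$cluster == fs_cluster, "FS", "RS")
  warnings <- character()
  mean_rate <- tapply(features$overall_rate_hz, km$cluster, mean)
  if (which.max(mean_rate) != which.min(mean_hw)) {
    warnings <- c(warnings,
      "narrow-waveform cluster does not have the higher mean firing rate")
  }
  centroids <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(label = label,
                                   half_width_ms = features$half_width_ms,
                                   overall_rate_hz = features$overall_rate_hz),
                    .data$label),
    half_width_ms = mean(.data$half_width_ms),
    overall_rate_hz = mean(.data$overall_rate_hz),
    n = dplyr::n(),
    .groups = "drop"
  )
  sep <- separation_check(features[, c("half_width_ms", "overall_rate_hz")],
                          label)
  structure(
    list(labels = tibble::tibble(unit_id = features$unit_id, label = label),
         centroids = centroids,
         separation = sep,
         warnings = warnings),
    class = "class_result"
  )
}

#' @export
print.class_result <- function(x, ...) {
  cat("<RS/FS classification>\n")
  print(x$centroids)
  cat(sprintf("  separation: Wilks lambda = %.4g, p = %.3g\n",
              x$separation$statistic[["lambda"]], x$separation$p_value))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Multivariate cluster-separation check
#'
#' Verifies that two putative cell-type clusters are statistically separated,
#' via a one-way MANOVA (Wilks' lambda with its F approximation) on the
#' feature matrix. When a wider waveform-feature matrix (more than two
#' columns) is supplied, the test is run on its first three principal
#' components.
#'
#' @param features Numeric matrix or data frame of per-unit features (any
#'   `unit_id` column is dropped).
#' @param labels Two-level grouping vector, one entry per unit.
#'
#' @return A [stat_result] with `statistic = c(lambda, F)`, the numerator and
#'   denominator degrees of freedom, and the p-value.
#' @export
separation_check <- function(features, labels) {
  x <- as.data.frame(features)
  x$unit_id <- NULL
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2 || any(table(labels) == 0)) {
    stop("`labels` must contain exactly two non-empty groups", call. = FALSE)
  }
  if (ncol(x) > 2) {
    pc <- prcomp(x, center = TRUE, scale. = TRUE)
    x <- pc$x[, seq_len(min(3, ncol(pc$x))), drop = FALSE]
  }
  if (any(table(labels) <= ncol(x))) {
    stop("each group needs more observations than features", call. = FALSE)
  }
  fit <- manova(x ~ labels)
  s <- summary(fit, test = "Wilks")$stats
  stat_result(
    test = "manova_wilks",
    statistic = c(lambda = unname(s[1, "Wilks"]),
                  F = unname(s[1, "approx F"])),
    df = c(unname(s[1, "num Df"]), unname(s[1, "den Df"])),
    p_value = unname(s[1, "Pr(>F)"]),
    groups = levels(labels)
  )
}
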