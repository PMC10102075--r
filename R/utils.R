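#' @importFrom stats aov kruskal.test ks.test manova pnorm prcomp rbinom
#' @importFrom stats rnorm rpois runif sd setNames t.test var wilcox.test
#' @importFrom stats TukeyHSD
#' @importFrom utils head
#' @importFrom rlang .data
NULL

EYES <- c("contra", "ipsi")
LAYERS <- c("L23", "L4", "L56")
CONDITIONS <- c("NR", "MD", "BR", "RO", "BR_SLEEP", "BR_SD")
BLANK <- "BLANK"

# strictly-positive scalar check used across generator entry points
assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

assert_scalar_count <- function(x, name) {
  assert_scalar_pos(x, name)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# deterministic per-component seed stream; stays below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + 7919 * k) %% 2147483647)
}

#' Container for a statistical test result
#'
#' Light-weight S3 container returned by every test in the statistical suite.
#' Holds the test name, the statistic, degrees of freedom where they apply,
#' the p-value, and (for omnibus tests) a post-hoc table of pairwise
#' comparisons with adjusted p-values.
#'
#' @param test Character name of the test.
#' @param statistic Named numeric statistic(s).
#' @param p_value P-value in `[0, 1]`.
#' @param df Degrees of freedom (numeric, possibly length 2) or `NULL`.
#' @param posthoc Tibble of pairwise comparisons or `NULL`.
#' @param groups Character vector of group labels compared.
#' @param note Optional character note (e.g. degenerate-input handling).
#'
#' @return An object of class `stat_result`.
#' @keywords internal
stat_result <- function(test, statistic, p_value, df = NULL, posthoc = NULL,
                        groups = NULL, note = NULL) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L,
            p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(test = test, statistic = statistic, df = df,
         p_value = min(p_value, 1), posthoc = posthoc,
         groups = groups, note = note),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s>\n", x$test))
  stat_str <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
                    collapse = ", ")
  cat(" ", stat_str, "\n")
  if (!is.null(x$df)) cat("  df =", paste(x$df, collapse = ", "), "\n")
  cat(sprintf("  p = %.4g\n", x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, n = nrow(x$posthoc))
  }
  invisible(x)
}
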