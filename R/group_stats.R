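# Statistical comparison suite applied to pipeline outputs: two-sample K-S,
# one-way ANOVA with Tukey HSD, Kruskal-Wallis with Dunn post hoc,
# Mann-Whitney, and unpaired t-tests.

check_groups <- function(groups, min_groups = 2, min_n = 1) {
  if (!is.list(groups) || length(groups) < min_groups) {
    stop(sprintf("need at least %d groups", min_groups), call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lens <- vapply(groups, length, integer(1))
  if (any(lens < min_n)) {
    stop(sprintf("every group needs at least %d observations", min_n),
         call. = FALSE)
  }
  groups
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two empirical cumulative distributions via the maximal vertical
#' distance `D = sup |F_a - F_b|`, with the asymptotic two-sided p-value.
#' This is the comparison used for group-level ODI cumulative distributions.
#'
#' @param a,b Non-empty numeric samples.
#'
#' @return A [stat_result] with `statistic = c(D = ...)`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  stat_result("ks_two_sample",
              statistic = c(D = unname(res$statistic)),
              p_value = res$p.value)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus F test across k groups followed by Tukey's honestly-significant-
#' difference pairwise comparisons (studentized-range adjustment). This is
#' the comparison applied to per-animal contralateral bias indices and
#' cFos/PV densities.
#'
#' @param groups Named list of numeric samples, each with at least 2
#'   observations.
#' @param alpha Significance level used only to set the post-hoc
#'   `significant` flag.
#'
#' @return A [stat_result] with `statistic = c(F = ...)`,
#'   `df = c(k - 1, N - k)` and a post-hoc tibble (`comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups, min_groups = 2, min_n = 2)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  within_var <- vapply(groups, var, numeric(1))
  if (all(within_var == 0)) {
    stop("zero within-group variance: F statistic undefined", call. = FALSE)
  }
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  posthoc <- tibble::tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  stat_result("anova_tukey",
              statistic = c(F = s[1, "F value"]),
              df = c(s[1, "Df"], s[2, "Df"]),
              p_value = s[1, "Pr(>F)"],
              posthoc = posthoc,
              groups = names(groups))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected H statistic with its chi-square p-value, followed by Dunn's
#' pairwise z-tests on mean ranks with Bonferroni adjustment (the most common
#' Dunn convention; switchable via `p_adjust`). Used for non-normal firing
#' rate comparisons across three or more groups.
#'
#' @param groups Named list of at least 3 non-empty numeric samples (for two
#'   groups use [mann_whitney_u()]).
#' @param p_adjust Adjustment method for the Dunn p-values (any method of
#'   [stats::p.adjust()]).
#' @param alpha Significance level for the post-hoc `significant` flag.
#'
#' @return A [stat_result] with `statistic = c(H = ...)`, `df = k - 1`, and a
#'   post-hoc tibble (`comparison`, `z`, `p`, `p_adj`, `significant`).
#' @export
kruskal_dunn <- function(groups, p_adjust = "bonferroni", alpha = 0.05) {
  groups <- check_groups(groups, min_groups = 3, min_n = 1)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kw <- kruskal.test(values, g)
  # Dunn: z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)),
  # T = sum(t^3 - t) / (12 (N - 1)) over tied values
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(values)
  T_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  cmp <- character(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt((N * (N + 1) / 12 - T_corr) * (1 / n[i] + 1 / n[j]))
    z[m] <- (rbar[i] - rbar[j]) / se
    p[m] <- 2 * pnorm(-abs(z[m]))
    cmp[m] <- paste(names(groups)[i], names(groups)[j], sep = "-")
  }
  p_adj <- stats::p.adjust(p, method = p_adjust)
  stat_result("kruskal_dunn",
              statistic = c(H = unname(kw$statistic)),
              df = unname(kw$parameter),
              p_value = kw$p.value,
              posthoc = tibble::tibble(comparison = cmp, z = z, p = p,
                                       p_adj = p_adj,
                                       significant = p_adj < alpha),
              groups = names(groups))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples, using the normal
#' approximation with tie and continuity corrections. The reported U counts,
#' over all cross-group pairs, how often an observation of `a` exceeds one of
#' `b` (ties counting one half).
#'
#' @param a,b Non-empty numeric samples.
#'
#' @return A [stat_result] with `statistic = c(U = ...)`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = TRUE)
  )
  stat_result("mann_whitney_u",
              statistic = c(U = unname(res$statistic)),
              p_value = res$p.value)
}

#' Two-tailed unpaired t-test (pooled variance)
#'
#' Classical two-sample t-test with pooled variance and `n1 + n2 - 2` degrees
#' of freedom. If the pooled variance is zero the test is degenerate: equal
#' means return `p = 1` with a note; unequal means raise an error, since the
#' statistic is infinite.
#'
#' @param a,b Numeric samples with at least 2 observations each.
#'
#' @return A [stat_result] with `statistic = c(t = ...)` and
#'   `df = n1 + n2 - 2`.
#' @export
t_test_unpaired <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  s2p <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (s2p == 0) {
    if (mean(a) == mean(b)) {
      return(stat_result("t_test_unpaired", statistic = c(t = 0),
                         df = n1 + n2 - 2, p_value = 1,
                         note = "degenerate: zero pooled variance, equal means"))
    }
    stop("degenerate input: zero pooled variance with unequal means",
         call. = FALSE)
  }
  res <- t.test(a, b, var.equal = TRUE)
  stat_result("t_test_unpaired",
              statistic = c(t = unname(res$statistic)),
              df = unname(res$parameter),
              p_value = res$p.value)
}
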