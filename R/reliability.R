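#' @title Reliability and comparison statistics
#' @description
#' The statistics layer of the study: Shapiro-Wilk-routed paired
#' comparisons (paired t-test or Wilcoxon signed-rank), repeated-measures
#' comparisons across data-collection days (RM-ANOVA or Friedman),
#' Bonferroni correction, route-appropriate descriptive summaries, and
#' Cronbach's alpha for test-retest reliability.
#' @name reliability
NULL

#' Cronbach's alpha across measurement occasions
#'
#' Raw-score (covariance) alpha:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)`, with `k` occasions,
#' `var_i` the per-occasion sample variance and `var_total` the variance
#' of the row sums (all with denominator n-1). Rows with missing cells
#' are dropped with a message.
#'
#' @param m numeric matrix or data frame; rows are subjects (here
#'   horse x side x electrode groups), columns occasions (DCD1-3).
#' @return alpha, a real number <= 1.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    stop("cronbach_alpha: need at least 2 occasions", call. = FALSE)
  complete <- stats::complete.cases(m)
  if (any(!complete))
    message(sprintf("cronbach_alpha: dropping %d incomplete row(s)",
                    sum(!complete)))
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L)
    stop("cronbach_alpha: need at least 2 complete rows", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0)
    stop(errorCondition("cronbach_alpha: zero total variance, alpha undefined",
                        class = c("undefined_alpha_error", "error")))
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

new_comparison_result <- function(test_name, statistic, p_raw, family_size,
                                  normal_route, n, degenerate = FALSE) {
  structure(list(
    test_name = test_name,
    statistic = unname(statistic),
    p_raw = p_raw,
    p_adjusted = min(1, p_raw * family_size),
    n_comparisons_in_family = as.integer(family_size),
    normal_route = normal_route,
    n = n,
    degenerate = degenerate),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4g, p = %.4g (adj. %.4g, family %d)%s>\n",
              x$test_name, x$statistic, x$p_raw, x$p_adjusted,
              x$n_comparisons_in_family,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Normality-routed paired comparison
#'
#' Tests the paired differences for normality with Shapiro-Wilk at
#' `alpha_level`; normal differences route to a paired t-test,
#' non-normal to a Wilcoxon signed-rank test. The raw p-value is
#' Bonferroni-adjusted by `family_size`. Incomplete pairs are removed.
#'
#' @param a,b paired numeric samples of equal length.
#' @param family_size number of comparisons in the Bonferroni family.
#' @param alpha_level significance level used for the normality gate
#'   (study value 0.05).
#' @return a `comparison_result` with fields `test_name`, `statistic`,
#'   `p_raw`, `p_adjusted`, `n_comparisons_in_family`, `normal_route`,
#'   `degenerate`.
#' @export
route_and_compare_paired <- function(a, b, family_size = 1L,
                                     alpha_level = 0.05) {
  if (length(a) != length(b))
    stop("route_and_compare_paired: samples must have equal length",
         call. = FALSE)
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L)
    stop("route_and_compare_paired: need at least 3 complete pairs",
         call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(new_comparison_result("paired_t", 0, 1, family_size,
                                 normal_route = TRUE, n = n,
                                 degenerate = TRUE))
  if (stats::sd(d) == 0)  # identical nonzero shift in every pair
    return(new_comparison_result("paired_t", Inf, 0, family_size,
                                 normal_route = TRUE, n = n,
                                 degenerate = TRUE))
  normal <- stats::shapiro.test(d)$p.value >= alpha_level
  if (normal) {
    tt <- stats::t.test(a, b, paired = TRUE)
    new_comparison_result("paired_t", tt$statistic, tt$p.value,
                          family_size, TRUE, n)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE))
    new_comparison_result("wilcoxon", wt$statistic, wt$p.value,
                          family_size, FALSE, n)
  }
}

#' Normality-routed repeated-measures comparison
#'
#' Compares `k` occasions (the three data-collection days) within
#' subjects. Additive-model residuals are tested with Shapiro-Wilk at
#' `alpha_level`; normal residuals route to a one-way repeated-measures
#' ANOVA (`occasion` within `subject`), non-normal to a Friedman test.
#' Bonferroni adjustment by `family_size`.
#'
#' @param values numeric matrix; rows subjects, columns occasions.
#'   Incomplete rows are dropped.
#' @param family_size Bonferroni family size.
#' @param alpha_level normality-gate level.
#' @return a `comparison_result` (`test_name` `"rm_anova"` or
#'   `"friedman"`).
#' @export
route_and_compare_repeated <- function(values, family_size = 1L,
                                       alpha_level = 0.05) {
  m <- as.matrix(values)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L)
    stop("route_and_compare_repeated: need at least 3 complete rows",
         call. = FALSE)
  if (ncol(m) < 2L)
    stop("route_and_compare_repeated: need at least 2 occasions",
         call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  res <- m - rowMeans(m) - matrix(colMeans(m), n, k, byrow = TRUE) + mean(m)
  if (all(abs(res) < 1e-12) && all(abs(sweep(m, 1, rowMeans(m))) < 1e-12))
    return(new_comparison_result("rm_anova", 0, 1, family_size,
                                 normal_route = TRUE, n = n,
                                 degenerate = TRUE))
  normal <- if (stats::sd(as.numeric(res)) == 0) TRUE else
    stats::shapiro.test(as.numeric(res))$p.value >= alpha_level
  if (normal && stats::sd(as.numeric(res)) > 0) {
    df <- data.frame(y = as.numeric(m),
                     occasion = factor(rep(seq_len(k), each = n)),
                     subject = factor(rep(seq_len(n), times = k)))
    fit <- stats::aov(y ~ occasion + Error(subject), data = df)
    tab <- summary(fit)[["Error: Within"]][[1]]
    new_comparison_result("rm_anova", tab[1, "F value"],
                          tab[1, "Pr(>F)"], family_size, TRUE, n)
  } else if (normal) {
    # zero residual variance but occasion effects present: F unbounded
    new_comparison_result("rm_anova", Inf, 0, family_size, TRUE, n,
                          degenerate = TRUE)
  } else {
    ft <- stats::friedman.test(m)
    new_comparison_result("friedman", ft$statistic, ft$p.value,
                          family_size, FALSE, n)
  }
}

#' Route-appropriate descriptive summary
#'
#' Normal route: mean and SD (denominator n-1), formatted like
#' `"0.29±0.09"`. Non-normal route: median and IQR with
#' linear-interpolation quartiles (type 7).
#'
#' @param x numeric sample, length >= 2.
#' @param normal_route logical; which presentation to use.
#' @param digits digits for the formatted text.
#' @return list with `center`, `spread`, `normal_route`, `text`.
#' @export
descriptive_summary <- function(x, normal_route = TRUE, digits = 2) {
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    stop("descriptive_summary: need at least 2 values", call. = FALSE)
  if (normal_route) {
    center <- mean(x); spread <- stats::sd(x)
    text <- sprintf("%.*f±%.*f", digits, center, digits, spread)
  } else {
    center <- stats::median(x)
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    spread <- q[2] - q[1]
    text <- sprintf("%.*f (IQR %.*f)", digits, center, digits, spread)
  }
  list(center = center, spread = spread, normal_route = normal_route,
       text = text)
}
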