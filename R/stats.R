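#' Group summary: mean, SD, SEM
#'
#' @param values Numeric vector (NA values are dropped).
#' @return A list with `n`, `mean`, `sd`, `sem` (`sd`/`sem` are `NA` for
#'   n = 1).
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("empty group")
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else NA_real_
  list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}

test_result <- function(test_name, statistic, p_value, n1, n2 = NA_integer_) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)\n", x$test_name,
              x$statistic, x$p_value,
              if (is.na(x$n2)) x$n1 else paste(x$n1, x$n2, sep = ", ")))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact two-sided p-value when both samples are small (min n <= 8 by
#' default, as `stats::wilcox.test` computes exact p for untied samples),
#' otherwise the normal approximation with tie correction and continuity
#' correction. The statistic is U for the first sample.
#'
#' @param a,b Numeric samples.
#' @return A `test_result`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result("mann_whitney_u", wt$statistic, wt$p.value, length(a), length(b))
}

#' Welch's two-sided t test (unequal variances)
#'
#' @param a,b Numeric samples with n >= 2 each.
#' @return A `test_result` including `df` (Satterthwaite).
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    stop("zero variance in both groups with equal means: t undefined")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  out <- test_result("welch_t", tt$statistic, tt$p.value, length(a), length(b))
  out$df <- unname(tt$parameter)
  out
}

#' Two-sided Wilcoxon signed-rank test for paired measurements
#'
#' Zero differences are dropped (Wilcoxon's convention). The p-value is
#' exact for up to 12 nonzero untied pairs, otherwise a normal
#' approximation with continuity correction is used.
#'
#' @param before,after Equal-length paired samples.
#' @return A `test_result` with `n1` the number of nonzero pairs.
#' @export
wilcoxon_signed_rank <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 1)
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero")
  exact <- !anyDuplicated(abs(d)) && length(d) <= 12
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result("wilcoxon_signed_rank", wt$statistic, wt$p.value, length(d))
}

#' Shapiro-Wilk normality gate
#'
#' Returns `TRUE` (use a parametric test) when the Shapiro-Wilk p-value is
#' at least `alpha`; samples with fewer than 3 values default to the
#' nonparametric branch.
#'
#' @param values Numeric sample.
#' @param alpha Gate level.
#' @return Logical scalar.
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) return(FALSE)
  if (stats::sd(values) == 0) return(FALSE)
  stats::shapiro.test(values)$p.value >= alpha
}

#' Cohort comparison following the normality-gate policy
#'
#' Runs the Shapiro-Wilk gate on both groups (or on the paired
#' differences) and reports the nonparametric rank test when either is
#' non-normal, Welch's t (or the paired t) otherwise. Both tests are
#' always computed and returned.
#'
#' @param a,b Numeric samples (paired order when `paired = TRUE`).
#' @param paired Paired comparison.
#' @param alpha Gate level for the Shapiro-Wilk test.
#' @return A list with `chosen` (`test_result`), `parametric`,
#'   `nonparametric`, and `normal` (gate outcome).
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (paired) {
    normal <- shapiro_wilk_gate(a - b, alpha)
    nonpar <- wilcoxon_signed_rank(a, b)
    tt <- stats::t.test(a, b, paired = TRUE)
    par <- test_result("paired_t", tt$statistic, tt$p.value, length(a))
  } else {
    normal <- shapiro_wilk_gate(a, alpha) && shapiro_wilk_gate(b, alpha)
    nonpar <- mann_whitney_u(a, b)
    par <- welch_t(a, b)
  }
  list(chosen = if (normal) par else nonpar,
       parametric = par, nonparametric = nonpar, normal = normal)
}
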