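# Inter-rater agreement statistics on per-grade counts.
#
# Two tests, both applied to the five per-grade counts of a pair of raters
# (algorithm vs expert, or expert vs expert):
#   * a goodness-of-fit chi-square in which each grade's expected count is
#     the average of the two raters' observed counts (an equal-split model,
#     summed over both raters' columns), with df = number of grades - 1;
#   * the paired t statistic over the five per-grade count differences,
#     compared against a one-sided critical value by default.

#' Validate a per-grade count vector
#'
#' @param x Numeric vector of five non-negative counts, ordered
#'   Normal ... Severe (names optional).
#' @return Named numeric vector of counts.
#' @export
grade_counts <- function(x) {
  x <- unlist(x)
  if (length(x) != 5L || any(!is.finite(x)) || any(x < 0)) {
    stop_invalid("grade counts must be five non-negative numbers")
  }
  if (sum(x) <= 0) {
    stop_degenerate("grade counts sum to zero")
  }
  stats::setNames(as.numeric(x), kl_grades())
}

new_agreement_test <- function(method, statistic, df, critical_value, alpha,
                               per_class, infinite = FALSE) {
  accept <- if (method == "chi-square") {
    statistic < critical_value
  } else {
    !infinite && abs(statistic) <= critical_value
  }
  structure(
    list(method = method, statistic = statistic, df = df,
         critical_value = critical_value, alpha = alpha,
         decision = if (accept) "accept-H0" else "reject-H0",
         infinite = infinite, per_class = per_class),
    class = "agreement_test"
  )
}

#' Chi-square agreement between two raters' grade counts
#'
#' Goodness-of-fit chi-square on per-grade counts: for each grade the
#' expected count is the average of the two raters' observed counts, and
#' \eqn{\chi^2 = \sum (f_o - f_e)^2 / f_e} is accumulated over both raters'
#' columns. H0 (close consensus between the raters) is accepted when the
#' statistic falls below the chi-square critical value at `alpha` with
#' df = 4.
#'
#' @param algorithm,expert Five per-grade counts per rater
#'   (see [grade_counts()]).
#' @param alpha Significance level (default 0.05).
#' @return An `agreement_test` object: `statistic`, `df`, `critical_value`,
#'   `alpha`, `decision` (`"accept-H0"` / `"reject-H0"`) and a `per_class`
#'   tibble of observed/expected counts and contributions.
#' @export
#' @examples
#' chi_square_agreement(c(649, 530, 279, 260, 282),
#'                      c(651, 528, 279, 260, 282))
chi_square_agreement <- function(algorithm, expert, alpha = 0.05) {
  a <- grade_counts(algorithm)
  b <- grade_counts(expert)
  fe <- (a + b) / 2
  if (any(fe == 0)) {
    stop_degenerate("expected count is zero for at least one grade")
  }
  contrib <- (a - fe)^2 / fe + (b - fe)^2 / fe
  df <- length(fe) - 1L
  per_class <- tibble::tibble(
    grade = kl_grade(kl_grades()),
    observed_1 = unname(a), observed_2 = unname(b),
    expected = unname(fe), contribution = unname(contrib)
  )
  new_agreement_test("chi-square", sum(contrib), df,
                     chi2_critical(df, alpha), alpha, per_class)
}

#' Paired t test between two raters' grade counts
#'
#' The paired t statistic over the per-grade count differences
#' \eqn{D = X - Y}:
#' \deqn{t = \frac{\sum D / N}{\sqrt{(\sum D^2 - (\sum D)^2/N) /
#'   ((N-1) N)}}}
#' with \eqn{N = 5} grades and df = 4, compared to the one-sided critical
#' value by default. If every difference is equal the variance is zero: the
#' result is t = 0 when the common difference is zero, otherwise an
#' infinite-statistic flag (`infinite = TRUE`, decision reject).
#'
#' @param x,y Five per-grade counts per rater.
#' @param alpha Significance level (default 0.05).
#' @param tails `"one"` (default) or `"two"`.
#' @return An `agreement_test` object; `per_class` carries `d` and
#'   `d_squared` per grade, and the object records `sum_d` and
#'   `sum_d_squared`.
#' @export
#' @examples
#' paired_t_agreement(c(651, 528, 279, 260, 282),
#'                    c(628, 551, 279, 260, 282))
paired_t_agreement <- function(x, y, alpha = 0.05,
                               tails = c("one", "two")) {
  tails <- match.arg(tails)
  a <- grade_counts(x)
  b <- grade_counts(y)
  d <- a - b
  n <- length(d)
  sum_d <- sum(d)
  sum_d2 <- sum(d^2)
  ss <- sum_d2 - sum_d^2 / n
  infinite <- FALSE
  if (ss <= .Machine$double.eps * max(1, sum_d2)) {
    statistic <- if (sum_d == 0) 0 else sign(sum_d) * Inf
    infinite <- sum_d != 0
  } else {
    statistic <- (sum_d / n) / sqrt(ss / ((n - 1) * n))
  }
  per_class <- tibble::tibble(
    grade = kl_grade(kl_grades()),
    x = unname(a), y = unname(b),
    d = unname(d), d_squared = unname(d^2)
  )
  out <- new_agreement_test("paired-t", statistic, n - 1L,
                            t_critical(n - 1L, alpha, tails), alpha,
                            per_class, infinite = infinite)
  out$sum_d <- sum_d
  out$sum_d_squared <- sum_d2
  out$tails <- tails
  out
}

#' Chi-square critical value
#'
#' Upper-`alpha` quantile of the chi-square distribution.
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return Critical value, e.g. 9.48773 for df = 4, alpha = 0.05.
#' @export
chi2_critical <- function(df, alpha = 0.05) {
  if (df < 1 || df != round(df)) {
    stop_invalid("`df` must be a positive integer")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_invalid("`alpha` must be in (0, 1)")
  }
  qchisq(1 - alpha, df)
}

#' Student-t critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param tails `"one"` (default; e.g. 2.1318 for df = 4, alpha = 0.05) or
#'   `"two"` (2.7764 for df = 4, alpha = 0.05).
#' @return Critical value.
#' @export
t_critical <- function(df, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (df < 1 || df != round(df)) {
    stop_invalid("`df` must be a positive integer")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_invalid("`alpha` must be in (0, 1)")
  }
  p <- if (tails == "one") 1 - alpha else 1 - alpha / 2
  qt(p, df)
}

#' @export
print.agreement_test <- function(x, ...) {
  cat(sprintf("<agreement_test> %s: statistic = %.6f, df = %d\n",
              x$method, x$statistic, x$df))
  cat(sprintf("  critical = %.5f (alpha = %g) -> %s\n",
              x$critical_value, x$alpha, x$decision))
  invisible(x)
}

#' Tidy an agreement test
#'
#' @param x An `agreement_test`.
#' @param ... Unused.
#' @return The per-grade detail tibble (observed/expected counts or paired
#'   differences).
#' @method tidy agreement_test
#' @export
tidy.agreement_test <- function(x, ...) {
  x$per_class
}

#' One-row summary of an agreement test
#'
#' @inheritParams tidy.agreement_test
#' @return Tibble with `method`, `statistic`, `df`, `critical_value`,
#'   `alpha`, `decision`.
#' @method glance agreement_test
#' @export
glance.agreement_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    df = x$df,
    critical_value = x$critical_value,
    alpha = x$alpha,
    decision = x$decision
  )
}
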