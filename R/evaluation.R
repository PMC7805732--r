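# Confusion-matrix metrics.
#
# Orientation convention used throughout: rows index the algorithm's
# predicted grade, columns the expert's annotated grade. Note that under
# this orientation the bundled reference tables label "precision" with the
# expert-column denominator and "recall" with the algorithm-row denominator
# — the reverse of the standard definitions — so both conventions are
# implemented (`convention = "paper"` vs `"standard"`).

#' Build a 5x5 KL confusion matrix from paired grade vectors
#'
#' @param pred Predicted grades (anything accepted by [kl_grade()]).
#' @param truth Expert-annotated grades, same length.
#' @return Integer matrix of class `kl_confusion`; entry `[i, j]` counts
#'   samples predicted grade `i` and annotated grade `j`.
#' @export
confusion_from_predictions <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_invalid("`pred` and `truth` must have equal length")
  }
  if (length(pred) < 1L) {
    stop_invalid("need at least one prediction")
  }
  tab <- table(predicted = kl_grade(pred), expert = kl_grade(truth))
  as_kl_confusion(unclass(tab))
}

#' Coerce a 5x5 count matrix to a KL confusion matrix
#'
#' @param counts 5x5 matrix of non-negative counts, rows = predicted,
#'   columns = expert grades.
#' @return An object of class `kl_confusion`.
#' @export
as_kl_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(5L, 5L))) {
    stop_invalid("a KL confusion matrix must be 5x5")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("confusion counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(predicted = kl_grades(), expert = kl_grades())
  class(counts) <- c("kl_confusion", "matrix")
  counts
}

#' @export
print.kl_confusion <- function(x, ...) {
  cat("<kl_confusion> rows = predicted, cols = expert\n")
  print(unclass(x))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A [as_kl_confusion()] matrix.
#' @return Proportion correct: trace / grand total.
#' @export
overall_accuracy <- function(cm) {
  cm <- as_kl_confusion(cm)
  total <- sum(cm)
  if (total == 0) {
    stop_degenerate("confusion matrix is empty (grand total 0)")
  }
  sum(diag(cm)) / total
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (0.00005 -> 0.0001),
#' the convention used when comparing metrics against printed tables;
#' base `round()` rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 4) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Per-grade precision and recall of a confusion matrix
#'
#' With rows = predicted and columns = expert, the standard definitions are
#' precision = diagonal / row sum and recall = diagonal / column sum. The
#' `"paper"` convention reproduces the bundled reference tables, which use
#' the swapped denominators (precision over the expert column total, recall
#' over the algorithm row total); it is the default so that the reference
#' tables round-trip exactly.
#'
#' @param cm A [as_kl_confusion()] matrix.
#' @param convention `"paper"` (expert-total precision) or `"standard"`.
#' @return Tibble with columns `grade`, `precision`, `recall` (unrounded)
#'   and `undefined` (`TRUE` where a zero denominator makes the metric
#'   undefined; the value is then `NA`).
#' @export
precision_recall <- function(cm, convention = c("paper", "standard")) {
  cm <- as_kl_confusion(cm)
  convention <- match.arg(convention)
  d <- diag(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  if (convention == "paper") {
    prec_den <- cs
    rec_den <- rs
  } else {
    prec_den <- rs
    rec_den <- cs
  }
  precision <- ifelse(prec_den > 0, d / prec_den, NA_real_)
  recall <- ifelse(rec_den > 0, d / rec_den, NA_real_)
  tibble::tibble(
    grade = kl_grade(kl_grades()),
    precision = unname(precision),
    recall = unname(recall),
    undefined = unname(prec_den == 0 | rec_den == 0)
  )
}
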