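#' Kellgren-Lawrence grade labels
#'
#' The five-level ordinal Kellgren-Lawrence (KL) scale for radiographic knee
#' osteoarthritis: Normal (0), Doubtful (1), Mild (2), Moderate (3),
#' Severe (4). All classifiers and evaluation tables in the package index
#' grades by these labels, in this order.
#'
#' @return Character vector of the five grade labels, from least to most
#'   severe.
#' @export
#' @examples
#' kl_grades()
kl_grades <- function() {
  c("Normal", "Doubtful", "Mild", "Moderate", "Severe")
}

#' Coerce labels or ordinals to a KL grade factor
#'
#' @param x Character labels, a factor, or integer ordinals in 0--4.
#' @return An ordered factor with levels `kl_grades()`.
#' @export
#' @examples
#' kl_grade(c("Severe", "Normal"))
#' kl_grade(0:4)
kl_grade <- function(x) {
  lv <- kl_grades()
  if (is.numeric(x)) {
    if (any(is.na(x)) || any(x < 0 | x > 4) || any(x != round(x))) {
      stop_invalid("numeric KL grades must be integers in 0..4")
    }
    x <- lv[x + 1L]
  }
  x <- as.character(x)
  if (!all(x %in% lv)) {
    stop_invalid(paste0(
      "unknown KL grade label(s): ",
      paste(unique(setdiff(x, lv)), collapse = ", ")
    ))
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Ordinal (0-based) code of a KL grade
#'
#' @param x Anything accepted by [kl_grade()].
#' @return Integer vector in 0--4.
#' @export
kl_ordinal <- function(x) {
  as.integer(kl_grade(x)) - 1L
}
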