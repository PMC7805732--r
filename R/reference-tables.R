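#' Bundled reference evaluation tables
#'
#' The package ships, as plain CSV under `inst/extdata`, the printed
#' evaluation tables of a published automatic KL-grading study of 2,000
#' digital knee radiographs annotated independently by two medical experts:
#' the 5x5 confusion matrices of the K-NN grader against each expert
#' (rows = algorithm prediction, columns = expert annotation) and the
#' per-grade count table for the algorithm and both experts. They are the
#' inputs for the table-reproduction tests and the agreement statistics.
#'
#' @return A list with elements `confusion_expert1` and `confusion_expert2`
#'   ([as_kl_confusion()] matrices) and `grade_counts` (tibble with columns
#'   `grade`, `algorithm_expert1`, `expert1`, `algorithm_expert2`,
#'   `expert2`).
#' @export
#' @examples
#' ref <- kl_reference_tables()
#' overall_accuracy(ref$confusion_expert1)
kl_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "kneemoments",
                                  mustWork = TRUE)
  read_cm <- function(f) {
    df <- read.csv(path(f), check.names = FALSE)
    as_kl_confusion(as.matrix(df[, -1]))
  }
  counts <- tibble::as_tibble(read.csv(path("grade_counts.csv")))
  counts$grade <- kl_grade(counts$grade)
  list(
    confusion_expert1 = read_cm("confusion_expert1.csv"),
    confusion_expert2 = read_cm("confusion_expert2.csv"),
    grade_counts = counts
  )
}

#' Read a 5x5 confusion-matrix CSV
#'
#' Expects a header row and a leading label column, rows = predicted grade,
#' columns = expert grade (the format of the bundled reference tables).
#'
#' @param path CSV path.
#' @return An [as_kl_confusion()] matrix.
#' @export
read_confusion_csv <- function(path) {
  if (!file.exists(path)) {
    stop_io(paste0("confusion CSV not found: ", path))
  }
  df <- read.csv(path, check.names = FALSE)
  as_kl_confusion(as.matrix(df[, -1, drop = FALSE]))
}
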