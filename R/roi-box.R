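#' Rectangular region of interest
#'
#' ROI boxes use 0-based, half-open index ranges `[start, end)`, matching
#' the JSON run reports.
#'
#' @param row_start,row_end,col_start,col_end Integer bounds, 0-based,
#'   half-open.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(row_start, row_end, col_start, col_end) {
  b <- c(row_start, row_end, col_start, col_end)
  if (any(b != round(b))) {
    stop_invalid("ROI bounds must be integers")
  }
  if (row_start < 0 || col_start < 0 ||
      row_start >= row_end || col_start >= col_end) {
    stop_invalid("ROI bounds must satisfy 0 <= start < end")
  }
  structure(
    list(row_start = as.integer(row_start), row_end = as.integer(row_end),
         col_start = as.integer(col_start), col_end = as.integer(col_end)),
    class = "roi_box"
  )
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> rows [%d, %d), cols [%d, %d)\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

#' Crop an image to an ROI box
#'
#' @param image Numeric intensity matrix.
#' @param roi An [roi_box()].
#' @return The cropped sub-matrix.
#' @export
crop_roi <- function(image, roi) {
  check_gray_image(image)
  if (!inherits(roi, "roi_box")) {
    stop_invalid("`roi` must be an roi_box")
  }
  if (roi$row_end > nrow(image) || roi$col_end > ncol(image)) {
    stop_invalid("ROI extends beyond the image")
  }
  image[(roi$row_start + 1):roi$row_end,
        (roi$col_start + 1):roi$col_end, drop = FALSE]
}
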