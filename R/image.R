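# Grayscale images are plain numeric matrices: rows = image rows (y),
# columns = image columns (x), intensities on the 8-bit scale [0, 255].
# Moment coordinates are 0-based: x = column - 1, y = row - 1.

check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_invalid(paste0("`", arg, "` must be a numeric matrix"))
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop_invalid(paste0("`", arg, "` must have at least one row and column"))
  }
  if (any(!is.finite(image))) {
    stop_invalid(paste0("`", arg, "` contains non-finite intensities"))
  }
  if (any(image < 0)) {
    stop_invalid(paste0("`", arg, "` contains negative intensities"))
  }
  invisible(image)
}

clip_intensity <- function(image) {
  image[image < 0] <- 0
  image[image > 255] <- 255
  image
}

#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file and returns a numeric matrix of intensities on
#' the 8-bit scale \[0, 255\]. Colour images are converted to grayscale by
#' averaging channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix (rows x columns) with values in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io(paste0("cannot read image file: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) {
      stop_io(paste0("failed to decode PNG: ", conditionMessage(e)))
    }),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path), error = function(e) {
      stop_io(paste0("failed to decode TIFF: ", conditionMessage(e)))
    }),
    stop_io(paste0("unsupported image extension: .", ext))
  )
  if (length(dim(arr)) == 3L) {
    arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE],
                 c(1L, 2L), mean)
  }
  round(arr * 255)
}

#' Write an 8-bit grayscale image
#'
#' @param image Numeric matrix with intensities in \[0, 255\].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  scaled <- clip_intensity(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, target = path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, where = path, bits.per.sample = 8L),
    stop_io(paste0("unsupported image extension: .", ext))
  )
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_invalid("`mask` must be a logical matrix")
  }
  write_gray_image(matrix(as.numeric(mask) * 255, nrow(mask), ncol(mask)),
                   path)
}
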