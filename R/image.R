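# Images are plain numeric matrices, rows = y (height), cols = x (width),
# intensities on the 8-bit scale [0, 255]. Pixel coordinates are 0-based with
# x = column and y = row, pixel centers at integers, so pixel (x, y)
# corresponds to mat[y + 1, x + 1]. This convention is shared by the conic
# fit, the rasterizer and the edge list; do not mix with 1-based indexing
# outside of matrix subscripts.

#' Validate a grayscale image matrix
#'
#' @param image numeric matrix of intensities in \[0, 255\].
#' @param require_nonconstant error when all pixels share one intensity.
#' @return the image, invisibly.
#' @keywords internal
check_gray_image <- function(image, require_nonconstant = FALSE) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_wbc("`image` must be a numeric matrix", "wbc_validation_error")
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    abort_wbc("`image` must have at least one pixel", "wbc_validation_error")
  }
  if (any(!is.finite(image))) {
    abort_wbc("`image` contains non-finite intensities", "wbc_validation_error")
  }
  if (require_nonconstant && length(unique(as.vector(image))) < 2L) {
    abort_wbc("`image` is constant; no intensity classes are identifiable",
              "wbc_degenerate_input_error")
  }
  invisible(image)
}

#' Convert an RGB array to luminance
#'
#' Collapses an height x width x 3 array to a single gray channel using the
#' Rec. 601 weights (0.299, 0.587, 0.114). Matrices pass through unchanged.
#'
#' @param image matrix or 3-channel array on the \[0, 255\] scale.
#' @return numeric matrix on the \[0, 255\] scale.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  abort_wbc("`image` must be a matrix or an RGB array", "wbc_validation_error")
}

#' Read a grayscale image
#'
#' Reads PNG (via the png package) or plain-text ASCII PGM (P2). RGB PNGs are
#' converted to luminance. The result is on the \[0, 255\] scale.
#'
#' @param path file path ending in .png or .pgm.
#' @return numeric matrix, rows = y, cols = x.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_wbc(paste("no such file:", path), "wbc_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- to_gray(img * 255) else img <- img * 255
    return(round(img))
  }
  if (ext == "pgm") return(read_pgm(path))
  abort_wbc(paste("unsupported image format:", ext), "wbc_io_error")
}

#' Write a grayscale image
#'
#' @param image numeric matrix on the \[0, 255\] scale.
#' @param path destination ending in .png or .pgm (ASCII P2).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  } else if (ext == "pgm") {
    write_pgm(image, path)
  } else {
    abort_wbc(paste("unsupported image format:", ext), "wbc_io_error")
  }
  invisible(path)
}

# ASCII PGM (P2): text-only fixture format, useful because the test corpus
# must remain plain text.
read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2") {
    abort_wbc("not an ASCII PGM (P2) file", "wbc_io_error")
  }
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) abort_wbc("corrupt PGM payload", "wbc_io_error")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  apply_rows <- apply(round(image), 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}
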