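#' Write or read a movie as a multi-page grayscale TIFF
#'
#' Frames are stored as 32-bit float pages. Requires the `tiff` package.
#'
#' @param stack Numeric array `c(rows, cols, frames)`.
#' @param path Output `.tif` path.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   the array.
#' @export
write_movie_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  }
  frames <- purrr::map(seq_len(dim(stack)[3]), ~ stack[, , .x])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import", call. = FALSE)
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}
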