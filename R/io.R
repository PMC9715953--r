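# TIFF I/O for stacks, parameter maps and label masks.
#
# Counts are stored scaled by 1/65535 so that 16-bit unsigned pages keep
# integer counts exactly up to 65535; parameter maps are written as 32-bit
# float pages with the same scaling. NA pixels in float maps are written as
# NaN.

#' Write a polarization stack as a multi-page TIFF
#'
#' Pages are ordered incoming-major: for each incoming state (LCP, RCP,
#' VLP, HLP), the four analyzed states (LCP, RCP, VLP, HLP); frames follow
#' as additional blocks of 16 pages. Intensities are stored as 16-bit
#' unsigned counts (values are clamped to `[0, 65535]` and rounded).
#'
#' @param stack A `"polarization_stack"` array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack)
  if (length(d) == 4) dim(stack) <- c(d, 1)
  d <- dim(stack)
  pages <- list()
  for (f in seq_len(d[5]))
    for (inc in seq_len(4))
      for (ana in seq_len(4))
        pages[[length(pages) + 1]] <-
          pmin(pmax(round(stack[, , inc, ana, f]), 0), 65535) / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Read a polarization stack from a multi-page TIFF
#'
#' Inverse of [write_stack_tiff()]; the page count must be a multiple
#' of 16.
#'
#' @param path TIFF file path.
#' @return A `"polarization_stack"` array
#'   `[height, width, incoming, analyzed, frame]`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 16 != 0)
    stop("expected a multiple of 16 pages (4 incoming x 4 analyzed); got ",
         length(pages))
  n_frames <- length(pages) %/% 16
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(h, w, 4, 4, n_frames),
               dimnames = list(NULL, NULL, incoming = PSHG_STATES,
                               analyzed = PSHG_STATES, NULL))
  k <- 1
  for (f in seq_len(n_frames))
    for (inc in seq_len(4))
      for (ana in seq_len(4)) {
        arr[, , inc, ana, f] <- pages[[k]] * 65535
        k <- k + 1
      }
  structure(arr, class = "polarization_stack")
}

#' Write a numeric map as a two-page 32-bit float TIFF
#'
#' Page 1 holds the values mapped to the unit range via
#' `(map - offset) / scale` (values outside `[offset, offset + scale]` are
#' clamped); page 2 is a validity page marking invalid (`NA`) pixels, which
#' carry 0 on the value page.
#'
#' @param map Numeric matrix.
#' @param path Output path.
#' @param scale Value span mapped to `[0, 1]`; default 65535.
#' @param offset Value mapped to 0; default 0.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path, scale = 65535, offset = 0) {
  u <- (map - offset) / scale
  u <- pmin(pmax(u, 0), 1)
  mask <- 1 - is.na(map)
  u[is.na(u)] <- 0
  tiff::writeTIFF(list(u, mask), path, bits.per.sample = 32,
                  reduce = FALSE)
  invisible(path)
}

#' Read a numeric map written by [write_map_tiff()]
#'
#' @param path TIFF file path.
#' @param scale,offset Transform used at write time.
#' @return Numeric matrix with `NA` at invalid pixels.
#' @export
read_map_tiff <- function(path, scale = 65535, offset = 0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  m <- pages[[1]] * scale + offset
  if (length(pages) > 1) m[pages[[2]] < 0.5] <- NA_real_
  m
}

#' Write an integer label raster as an 8-bit TIFF
#'
#' @param labels Integer matrix with values in `0..255`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8, reduce = FALSE)
  invisible(path)
}

#' Read an 8-bit label raster written by [write_label_tiff()]
#'
#' @param path TIFF file path.
#' @return Integer matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path) * 255
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}
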