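#' Read a microscopy image from a plain TIFF file
#'
#' Reads a single-page TIFF as a 2D intensity matrix or a multi-page TIFF as a
#' 3D stack. Integer sample values are preserved bit-exactly. Pixel/voxel
#' spacing is supplied by the caller, never parsed from vendor metadata.
#'
#' @param path Path to a TIFF file.
#' @param kind `"2d"` (exactly one page) or `"3d"` (two or more pages, stacked
#'   along the third array dimension in page order, i.e. `[y, x, z]`).
#'
#' @return A numeric matrix (`kind = "2d"`) or 3D array (`kind = "3d"`) of
#'   non-negative intensities.
#'
#' @examples
#' path <- tempfile(fileext = ".tif")
#' write_image(matrix(0L, 64, 64), path)
#' img <- read_image(path, "2d")
#' @export
read_image <- function(path, kind = c("2d", "3d")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop_rf("file_not_found", paste0("file does not exist: ", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, drop_alpha)
  if (kind == "2d") {
    if (length(pages) != 1L) {
      stop_rf("format", sprintf(
        "expected a single-page TIFF for kind = '2d', got %d pages", length(pages)))
    }
    return(pages[[1L]])
  }
  if (length(pages) < 2L) {
    stop_rf("format", "expected a multi-page TIFF (>= 2 pages) for kind = '3d'")
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) {
    stop_rf("format", "TIFF pages have inconsistent dimensions")
  }
  array(unlist(pages, use.names = FALSE),
        dim = c(dim(pages[[1L]]), length(pages)))
}

drop_alpha <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  p
}

#' Write an intensity image or stack to a plain TIFF file
#'
#' The inverse of [read_image()]: a matrix becomes a single-page TIFF, a 3D
#' array a multi-page TIFF (one page per `z` slice). Intensities must be
#' integers representable at the chosen bit depth; round trips are lossless.
#'
#' @param img Numeric matrix or 3D array of non-negative integer intensities.
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16.
#'
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop_rf("value", "bits must be 8 or 16")
  maxval <- 2^bits - 1
  if (any(img < 0) || any(img > maxval) || any(img != round(img))) {
    stop_rf("value", sprintf(
      "intensities must be integers in [0, %d] for %d-bit TIFF", maxval, bits))
  }
  nd <- length(dim(img))
  pages <- if (nd == 2L) list(img / maxval)
           else lapply(seq_len(dim(img)[3L]), function(z) img[, , z] / maxval)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) stop_rf("io", conditionMessage(e)))
  invisible(path)
}

#' Write a results table to CSV
#'
#' @param table A non-empty data frame of results.
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_rf("io", "refusing to write an empty results table")
  }
  tryCatch(readr::write_csv(table, path),
           error = function(e) stop_rf("io", conditionMessage(e)))
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_rf("file_not_found", paste0("file does not exist: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
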