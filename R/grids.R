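#' Read / write dense grid rasters
#'
#' A "dense grid" is a whitespace-delimited text matrix (rows x cols of
#' integers), the plain-text raster format used for tests and small
#' examples.  Annual mask stacks are either one grid file per year, or a
#' multi-layer (Geo)TIFF read through the tiff package (one band per year,
#' values >= 0.5 taken as forest).
#'
#' @param path file path.
#' @return `read_grid`: integer matrix.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  as.matrix(utils::read.table(path, header = FALSE,
                              colClasses = "numeric"))
}

#' @rdname read_grid
#' @param x matrix to write.
#' @export
write_grid <- function(x, path) {
  utils::write.table(matrix(as.integer(x), nrow(x), ncol(x)), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an annual forest-mask stack
#'
#' @param paths either a character vector of per-year grid/TIFF files (in
#'   year order) or a single multi-layer TIFF.
#' @return logical array `[rows, cols, years]`.
#' @export
read_mask_stack <- function(paths) {
  is_tiff <- grepl("\\.tiff?$", paths, ignore.case = TRUE)
  layers <- if (length(paths) == 1L && is_tiff[1L]) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF rasters requires the 'tiff' package")
    x <- tiff::readTIFF(paths, all = TRUE)
    if (!is.list(x)) x <- list(x)
    lapply(x, function(m) (if (length(dim(m)) == 3L) m[, , 1L] else m) >= 0.5)
  } else {
    lapply(paths, function(p) {
      if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("reading TIFF rasters requires the 'tiff' package")
        m <- tiff::readTIFF(p)
        (if (length(dim(m)) == 3L) m[, , 1L] else m) >= 0.5
      } else read_grid(p) >= 0.5
    })
  }
  d <- dim(layers[[1L]])
  if (!all(vapply(layers, function(m) all(dim(m) == d), TRUE)))
    stop("mask layers differ in shape")
  array(unlist(layers), dim = c(d, length(layers)))
}

#' Write an annual mask stack as per-year grid files
#'
#' @param stack logical array `[rows, cols, years]`.
#' @param dir output directory (created if needed).
#' @param years calendar years used in the file names.
#' @return character vector of written paths, in year order.
#' @export
write_mask_stack <- function(stack, dir, years = NULL) {
  if (is.null(years)) years <- seq_len(dim(stack)[3])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("mask_%s.txt", years))
  for (i in seq_along(paths)) write_grid(stack[, , i], paths[i])
  invisible(paths)
}
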