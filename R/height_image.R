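#' Construct a height image
#'
#' An AFM-style height map: a single-channel matrix of heights (in physical
#' length units, typically nm) together with the lateral pixel spacing.
#' Coordinates follow the raster convention used throughout the package:
#' row-major, origin at the centre of the top-left pixel,
#' `x = (col - 1) * pixel_size`, `y = (row - 1) * pixel_size`.
#'
#' @param heights Numeric matrix of heights. All values must be finite.
#' @param pixel_size Lateral pixel spacing (length units per pixel). Either a
#'   single value or `c(x, y)`; x and y spacing must agree within 1% (the
#'   scale-space machinery assumes square pixels).
#' @param unit Unit label for heights and pixel size (default `"nm"`).
#'
#' @return An object of class `height_image`: a list with elements `heights`,
#'   `pixel_size`, `unit`.
#' @examples
#' img <- height_image(matrix(0, 16, 16), pixel_size = 1)
#' dim(img$heights)
#' @export
height_image <- function(heights, pixel_size, unit = "nm") {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    stop("`heights` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(heights))) {
    stop("`heights` contains non-finite values", call. = FALSE)
  }
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- c(pixel_size, pixel_size)
  if (length(pixel_size) != 2L || any(!is.finite(pixel_size)) ||
      any(pixel_size <= 0)) {
    stop("`pixel_size` must be one or two strictly positive numbers",
         call. = FALSE)
  }
  if (abs(pixel_size[1] - pixel_size[2]) > 0.01 * mean(pixel_size)) {
    stop("anisotropic pixels: pixel_size_x and pixel_size_y differ by more ",
         "than 1%; resample the image to square pixels first", call. = FALSE)
  }
  structure(
    list(heights = heights, pixel_size = pixel_size[1], unit = unit),
    class = "height_image"
  )
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf("<height_image> %d x %d px, pixel %g %s, range [%.4g, %.4g] %s\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size, x$unit,
              min(x$heights), max(x$heights), x$unit))
  invisible(x)
}

#' @export
dim.height_image <- function(x) dim(x$heights)

#' @export
as_tibble.height_image <- function(x, ...) {
  h <- x$heights
  px <- x$pixel_size
  rows <- rep(seq_len(nrow(h)), times = ncol(h))
  cols <- rep(seq_len(ncol(h)), each = nrow(h))
  tibble::tibble(row = rows, col = cols,
                 x = (cols - 1) * px, y = (rows - 1) * px,
                 height = as.vector(h))
}

#' Read a height image from a text matrix
#'
#' Reads a whitespace-delimited numeric matrix (one image row per line).
#' Pixel size is not stored in the text format, so it must be supplied.
#' TIFF input is not supported in this build; export instrument data to a
#' plain-text matrix instead.
#'
#' @param path Path to a whitespace-delimited text matrix.
#' @param pixel_size Lateral pixel spacing in physical units (required).
#' @param unit Unit label (default `"nm"`).
#' @param scale_factor Multiplier applied to raw values (e.g. to convert
#'   integer instrument counts to physical heights). Default 1.
#' @return A [height_image].
#' @export
read_height_image <- function(path, pixel_size = NULL, unit = "nm",
                              scale_factor = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("TIFF input is not supported in this build; export the image as a ",
         "whitespace-delimited text matrix and pass `pixel_size`",
         call. = FALSE)
  }
  if (is.null(pixel_size)) {
    stop("text matrices carry no pixel-size metadata; supply `pixel_size`",
         call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) {
    stop("ragged text matrix: rows have differing lengths", call. = FALSE)
  }
  m <- do.call(rbind, rows) * scale_factor
  height_image(m, pixel_size = pixel_size, unit = unit)
}

#' Write a height image as a text matrix
#'
#' Inverse of [read_height_image()]: writes the height matrix as
#' whitespace-delimited text with a comment header recording pixel size and
#' units, at full double precision.
#'
#' @param img A [height_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_height_image <- function(img, path) {
  stopifnot(inherits(img, "height_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# height image: pixel_size=%.17g unit=%s rows=%d cols=%d",
                     img$pixel_size, img$unit,
                     nrow(img$heights), ncol(img$heights)), con)
  utils::write.table(format(img$heights, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
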