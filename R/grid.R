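#' Regular grid geometry
#'
#' A minimal description of a regular, axis-aligned grid of square cells.
#' Row 1 of a grid matrix is the northernmost row; `origin` is the (x, y)
#' coordinate of the *top-left corner* of cell \[1, 1\].
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param cell_size cell edge length in metres (square cells).
#' @param origin numeric length-2, (x, y) of the top-left corner in metres.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, cell_size, origin = c(0, 0)) {
  stopifnot(nrow >= 1, ncol >= 1, cell_size > 0, length(origin) == 2)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells @ %g m, top-left (%g, %g)\n",
              x$nrow, x$ncol, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec a [grid_spec()].
#' @return A two-column matrix (x, y), one row per cell in column-major
#'   (R matrix) order.
#' @export
cell_centers <- function(spec) {
  cs <- spec$cell_size
  x <- spec$origin[1] + (seq_len(spec$ncol) - 0.5) * cs
  y <- spec$origin[2] - (seq_len(spec$nrow) - 0.5) * cs
  cbind(x = rep(x, each = spec$nrow), y = rep(y, times = spec$ncol))
}

same_geometry <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' north first. `NA` cells are written as the nodata value.
#'
#' @param values numeric or integer matrix, row 1 = north.
#' @param path output file path.
#' @param spec the [grid_spec()] describing the geometry.
#' @param nodata value standing for missing cells in the file.
#' @export
write_ascii_grid <- function(values, path, spec, nodata = -9999) {
  stopifnot(nrow(values) == spec$nrow, ncol(values) == spec$ncol)
  cs <- spec$cell_size
  hdr <- c(
    sprintf("ncols %d", spec$ncol),
    sprintf("nrows %d", spec$nrow),
    sprintf("xllcorner %.10g", spec$origin[1]),
    sprintf("yllcorner %.10g", spec$origin[2] - spec$nrow * cs),
    sprintf("cellsize %.10g", cs),
    sprintf("NODATA_value %.10g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                               digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any conforming
#'   ESRI ASCII grid).
#' @return A list with `values` (matrix, nodata as `NA`), `spec`
#'   (a [grid_spec()]) and `nodata` (the file's nodata code).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[seq(i, length(lines))]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  spec <- grid_spec(nr, nc, hdr$cellsize,
                    origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize))
  list(values = m, spec = spec, nodata = nodata)
}
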