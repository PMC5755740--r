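#' Simple georeferenced raster grid
#'
#' In-memory representation of an ESRI ASCII grid: a numeric matrix whose
#' first row is the northernmost row, the lower-left corner coordinates,
#' a square cell size in degrees and a nodata sentinel. Nodata cells are
#' stored as `NA` internally and written back as the sentinel.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xll,yll coordinates of the lower-left corner.
#' @param cellsize cell size (degrees), positive.
#' @param nodata nodata sentinel used on disk (default -9999).
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid dimensions must be positive")
  stopifnot(is.numeric(cellsize), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d rows x %d cols, cellsize %g, ll (%g, %g), %d nodata\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              sum(is.na(x$values))))
  invisible(x)
}

.same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                     c(b$xll, b$yll, b$cellsize)))
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`; the nodata line is optional)
#' followed by row-major values, northern row first. Malformed headers
#' and ragged rows are rejected with the offending line number.
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) == 2L &&
        tolower(parts[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "cellsize", "nodata_value")) {
      v <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(v)) stop("line ", i + 1L, ": non-numeric header value")
      hdr[[tolower(parts[1])]] <- v
      i <- i + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]])) stop("missing header field '", key, "'")
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (ncols < 1 || nrows < 1) stop("grid dimensions must be positive")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- lines[(i + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nrows)
    stop("expected ", nrows, " data rows, found ", length(body),
         " (after line ", i, ")")
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != ncols)
      stop("line ", i + r, ": expected ", ncols, " values, found ", length(row))
    if (anyNA(row)) stop("line ", i + r, ": non-numeric cell value")
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  raster_grid(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]: write-then-read is the identity on
#' values, geometry and the nodata mask.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  num <- function(z) sprintf("%.17g", z)   # full double precision round-trip
  hdr <- c(
    paste("ncols", ncol(grid$values)),
    paste("nrows", nrow(grid$values)),
    paste("xllcorner", num(grid$xll)),
    paste("yllcorner", num(grid$yll)),
    paste("cellsize", num(grid$cellsize)),
    paste("NODATA_value", num(grid$nodata))
  )
  rows <- apply(v, 1, function(r) paste(num(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
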