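#' Lightweight planar raster grid
#'
#' A minimal single-band raster on an abstract equal-area Cartesian plane
#' (declared CRS metadata \code{"synthetic, unit = km"} by default). Values
#' are stored as a numeric matrix whose first row is the top (northmost) row
#' of the grid, matching on-disk row order of the Esri ASCII grid format used
#' for serialization.
#'
#' @param values numeric matrix; row 1 is the top row of the grid.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (grid cells are square).
#' @param crs free-text CRS label carried as metadata.
#' @return an object of class \code{rp_raster}.
#' @export
rp_raster <- function(values, xll = 0, yll = 0, cellsize = 1,
                      crs = "synthetic, unit = km") {
  stopifnot(is.matrix(values), is.numeric(values) || all(is.na(values)),
            cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs),
            class = "rp_raster")
}

#' @export
print.rp_raster <- function(x, ...) {
  cat(sprintf("<rp_raster %d x %d, cellsize %g, origin (%g, %g), crs '%s'>\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll, x$crs))
  cat(sprintf("  values: [%g, %g], %d NA\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Coordinates of every cell center
#'
#' @param r an \code{rp_raster}.
#' @return a list with matrices \code{x} and \code{y} of the same shape as
#'   \code{r$values} giving each cell center's coordinates.
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  x <- r$xll + (seq_len(nc) - 0.5) * r$cellsize
  y <- r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(x = matrix(x, nr, nc, byrow = TRUE),
       y = matrix(y, nr, nc))
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

raster_like <- function(template, values) {
  rp_raster(matrix(values, nrow(template$values), ncol(template$values)),
            template$xll, template$yll, template$cellsize, template$crs)
}

#' Write a raster as an Esri ASCII grid
#'
#' Plain-text, GIS-readable serialization. Numbers are formatted with
#' \code{\%.10g} so identical rasters serialize byte-identically.
#'
#' @param r an \code{rp_raster}.
#' @param path output file path (conventionally \code{.asc}).
#' @param nodata value standing in for \code{NA} cells.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(r$values)),
           sprintf("nrows %d", nrow(r$values)),
           sprintf("xllcorner %.10g", r$xll),
           sprintf("yllcorner %.10g", r$yll),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(v, 1, function(z) paste(sprintf("%.10g", z), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path file written by \code{\link{write_ascii_grid}} or any
#'   conforming ASCII grid.
#' @param crs CRS label to attach (the format itself carries none).
#' @return an \code{rp_raster}.
#' @export
read_ascii_grid <- function(path, crs = "synthetic, unit = km") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  v <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  }))
  stopifnot(nrow(v) == hdr$nrows, ncol(v) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  rp_raster(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs)
}
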