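#' Raster grid container
#'
#' The spatial substrate used throughout the package: a 2-D numeric matrix
#' with a cell resolution in meters. Indexing is 0-based `(row, col)` with
#' row 0 as the top (north) row, mirroring array storage; there is no
#' wrap-around. `NA` cells are treated as outside the landscape by all
#' placement and metric functions. Cell area is `resolution^2` square meters,
#' so at the default 10 m resolution a 200 x 200 grid spans 2 km x 2 km and
#' one hectare is 100 cells.
#'
#' @param values numeric matrix (rows = north to south).
#' @param resolution cell edge length in meters, > 0. Default 10.
#' @return An object of class `ag_grid`: a list with elements `values`,
#'   `nrow`, `ncol`, `resolution`.
#' @examples
#' g <- ag_grid(matrix(0, 5, 5))
#' g$resolution
#' @export
ag_grid <- function(values, resolution = 10) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, nrow = nrow(values), ncol = ncol(values),
         resolution = as.numeric(resolution)),
    class = "ag_grid"
  )
}

#' @export
print.ag_grid <- function(x, ...) {
  cat(sprintf("<ag_grid> %d x %d cells @ %g m (%g x %g m)\n",
              x$nrow, x$ncol, x$resolution,
              x$ncol * x$resolution, x$nrow * x$resolution))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @rdname ag_grid
#' @param x object to test.
#' @export
is_ag_grid <- function(x) inherits(x, "ag_grid")

stopifnot_grid <- function(x, arg = deparse(substitute(x))) {
  if (!is_ag_grid(x)) stop(sprintf("`%s` must be an ag_grid", arg), call. = FALSE)
  invisible(x)
}

stopifnot_binary <- function(g, arg = deparse(substitute(g))) {
  v <- g$values[!is.na(g$values)]
  bad <- unique(v[!(v %in% c(0, 1))])
  if (length(bad))
    stop(sprintf("`%s` must be binary (0/1); found values: %s", arg,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  invisible(g)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange in the ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed by
#' rows from north to south). This is the format FRAGSTATS and most GIS
#' packages read directly. Cells must be square (`cellsize`); grids written
#' here round-trip exactly for integer values and to full double precision
#' for continuous values (values are printed with 17 significant digits).
#'
#' @param path file path.
#' @param format raster format; only `"ascii_grid"` is supported.
#' @return `read_raster()` returns an [ag_grid]; `write_raster()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' write_raster(ag_grid(matrix(1:6, 2, 3)), f)
#' read_raster(f)
#' @export
read_raster <- function(path, format = c("ascii_grid")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read_ascii_grid(path)
}

#' @rdname read_raster
#' @param grid an [ag_grid] to write.
#' @export
write_raster <- function(grid, path, format = c("ascii_grid")) {
  format <- match.arg(format)
  stopifnot_grid(grid)
  write_ascii_grid(grid, path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "xllcenter", "yllcenter", "cellsize", "dx", "dy",
                     "nodata_value"))) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("not an ESRI ASCII grid: missing ncols/nrows header", call. = FALSE)
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy)
    stop("non-square cells (dx != dy) are not supported", call. = FALSE)
  cellsize <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  if (is.null(cellsize)) stop("missing cellsize header", call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  ag_grid(m, resolution = cellsize)
}

write_ascii_grid <- function(grid, path, nodata = -9999) {
  m <- grid$values
  if (any(!is.na(m) & m == nodata))
    stop("grid contains the nodata sentinel ", nodata, " as a data value",
         call. = FALSE)
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.17g", grid$resolution),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Connected components of a binary mask
#'
#' Labels maximal connected components of the foreground (non-zero, non-NA)
#' cells of a binary grid under 4- or 8-connectivity. Labels run 1..K in
#' row-major discovery order; background and `NA` cells get label 0.
#'
#' @param mask binary [ag_grid] (values 0/1, `NA` allowed).
#' @param connectivity 4 (rook) or 8 (queen). Default 8.
#' @return list with `labels` (an integer-valued [ag_grid]) and `n`
#'   (component count K, 0 for an empty mask).
#' @examples
#' m <- ag_grid(matrix(c(1, 0, 0, 1), 2, 2))
#' connected_components(m, connectivity = 8)$n  # diagonal cells join
#' connected_components(m, connectivity = 4)$n
#' @export
connected_components <- function(mask, connectivity = 8) {
  stopifnot_grid(mask)
  stopifnot_binary(mask)
  connectivity <- match_connectivity(connectivity)
  lab <- cc_label(mask$values, connectivity, FALSE)
  list(labels = ag_grid(matrix(as.numeric(lab), mask$nrow, mask$ncol),
                        resolution = mask$resolution),
       n = attr(lab, "n_components"))
}

match_connectivity <- function(connectivity) {
  if (!length(connectivity) == 1L || !connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  as.integer(connectivity)
}

#' In-bounds neighbors of a cell
#'
#' @param cell integer vector `c(row, col)`, 0-based.
#' @param grid an [ag_grid].
#' @param connectivity 4 or 8.
#' @return two-column matrix of 0-based `(row, col)` neighbor coordinates;
#'   out-of-bounds positions are dropped (grids are non-toroidal).
#' @export
neighbors <- function(cell, grid, connectivity = 8) {
  stopifnot_grid(grid)
  connectivity <- match_connectivity(connectivity)
  r <- cell[1]; c <- cell[2]
  if (r < 0 || r >= grid$nrow || c < 0 || c >= grid$ncol)
    stop(sprintf("cell (%d, %d) is out of bounds", r, c), call. = FALSE)
  if (connectivity == 4L) {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  } else {
    dr <- rep(-1:1, each = 3L)[-5L]; dc <- rep(-1:1, times = 3L)[-5L]
  }
  out <- cbind(row = r + dr, col = c + dc)
  out[out[, 1] >= 0 & out[, 1] < grid$nrow &
      out[, 2] >= 0 & out[, 2] < grid$ncol, , drop = FALSE]
}

# cells: two-column 0-based (row, col) matrix -> 1-based linear indices
cells_to_index <- function(cells, nrow) {
  cells[, 1L] + 1L + cells[, 2L] * nrow
}

index_to_cells <- function(idx, nrow) {
  cbind(row = (idx - 1L) %% nrow, col = (idx - 1L) %/% nrow)
}
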