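#' Define a raster grid
#'
#' A grid spec fixes the geometry shared by every layer in an analysis:
#' dimensions, cell size in decimal degrees, and the north-west corner of
#' the grid. Row 1 is the northern-most row; cells are addressed
#' half-open, so a point exactly on a cell edge belongs to the cell to its
#' north-west.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in decimal degrees.
#' @param origin_lon,origin_lat Longitude / latitude of the north-west
#'   corner of the grid (the outer corner of cell \[1, 1\]).
#' @param nodata Sentinel value used when grids are written to disk.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(50, 50, cell_size = 0.02, origin_lon = 35, origin_lat = 9)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1 / 120,
                      origin_lon = 34, origin_lat = 10, nodata = -9999) {
  if (length(n_rows) != 1 || length(n_cols) != 1 ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1) {
    stop("grid dimensions must be positive integers", call. = FALSE)
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("cell_size must be > 0", call. = FALSE)
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = cell_size,
      origin_lon = origin_lon, origin_lat = origin_lat,
      nodata = nodata
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %.6g deg, NW corner (%.4f, %.4f)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat
  ))
  invisible(x)
}

#' Longitude / latitude of cell centers
#'
#' @param spec A [grid_spec()].
#' @return A list with numeric vectors `lon` (length `n_cols`, west to
#'   east) and `lat` (length `n_rows`, north to south).
#' @export
cell_centers <- function(spec) {
  list(
    lon = spec$origin_lon + (seq_len(spec$n_cols) - 0.5) * spec$cell_size,
    lat = spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  )
}

#' Locate points on a grid
#'
#' Maps points to the row/column of the cell containing them, under the
#' half-open convention (a point on an edge resolves to the north-west
#' cell, i.e. the cell with the smaller column / row index).
#'
#' @param data A data frame with `lon` and `lat` columns.
#' @param spec A [grid_spec()].
#' @return The input with integer `row` and `col` columns appended; points
#'   outside the grid extent get `NA`.
#' @export
locate_cells <- function(data, spec) {
  col <- floor((data$lon - spec$origin_lon) / spec$cell_size) + 1
  row <- floor((spec$origin_lat - data$lat) / spec$cell_size) + 1
  # points exactly on the east / south outer edge belong to the last cell
  col[data$lon == spec$origin_lon + spec$n_cols * spec$cell_size] <- spec$n_cols
  row[data$lat == spec$origin_lat - spec$n_rows * spec$cell_size] <- spec$n_rows
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  dplyr::mutate(tibble::as_tibble(data),
                row = as.integer(row), col = as.integer(col))
}

#' Bundle named layers into a climate stack
#'
#' A `clim_stack` is a named list of co-registered matrices plus the
#' shared [grid_spec()] and a `kind` tag per layer
#' (`"temperature"`, `"precipitation"` or `"seasonality"`) that tells the
#' scenario machinery whether deltas are additive or multiplicative.
#' `NA` entries are the nodata mask and are carried through all
#' arithmetic.
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param spec A [grid_spec()] matching the matrix dimensions.
#' @param kind Character vector, one entry per layer.
#' @return An object of class `clim_stack`.
#' @export
clim_stack <- function(layers, spec, kind) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("layers must be named", call. = FALSE)
  }
  dims_ok <- vapply(
    layers, function(m) all(dim(m) == c(spec$n_rows, spec$n_cols)), logical(1)
  )
  if (!all(dims_ok)) {
    stop("all layers must match the grid_spec dimensions", call. = FALSE)
  }
  if (length(kind) != length(layers)) {
    stop("one kind per layer required", call. = FALSE)
  }
  kind <- match.arg(kind, c("temperature", "precipitation", "seasonality"),
                    several.ok = TRUE)
  structure(
    list(layers = layers, spec = spec,
         kind = stats::setNames(kind, names(layers))),
    class = "clim_stack"
  )
}

#' @export
print.clim_stack <- function(x, ...) {
  cat(sprintf("<clim_stack> %d layer(s) on a %d x %d grid\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols))
  for (nm in names(x$layers)) {
    v <- x$layers[[nm]]
    cat(sprintf("  %-28s [%s] range %.3g..%.3g\n", nm, x$kind[[nm]],
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
names.clim_stack <- function(x) names(x$layers)

#' Flatten a climate stack to a long tibble
#'
#' @param x A `clim_stack`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `row`, `col`, `lon`, `lat`,
#'   and one column per layer.
#' @export
as_tibble.clim_stack <- function(x, ...) {
  ctr <- cell_centers(x$spec)
  out <- tibble::tibble(
    row = rep(seq_len(x$spec$n_rows), times = x$spec$n_cols),
    col = rep(seq_len(x$spec$n_cols), each = x$spec$n_rows),
    lon = ctr$lon[rep(seq_len(x$spec$n_cols), each = x$spec$n_rows)],
    lat = ctr$lat[rep(seq_len(x$spec$n_rows), times = x$spec$n_cols)]
  )
  for (nm in names(x$layers)) out[[nm]] <- as.vector(x$layers[[nm]])
  out
}

#' Extract layer values at point locations
#'
#' Nearest-cell-center lookup: each point takes the value of the cell that
#' contains it under the half-open grid convention.
#'
#' @param data Data frame with `lon`, `lat`.
#' @param stack A `clim_stack`, or a single matrix plus `spec`.
#' @param spec Required when `stack` is a bare matrix.
#' @return `data` with one appended column per layer (or `value` for a
#'   bare matrix); `NA` outside the extent or on nodata.
#' @export
extract_at <- function(data, stack, spec = NULL) {
  if (inherits(stack, "clim_stack")) {
    located <- locate_cells(data, stack$spec)
    idx <- cbind(located$row, located$col)
    out <- located
    for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]][idx]
    return(out)
  }
  stopifnot(is.matrix(stack), inherits(spec, "grid_spec"))
  located <- locate_cells(data, spec)
  located$value <- stack[cbind(located$row, located$col)]
  located
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by
#' rows north to south). `NA` cells are written as the nodata value.
#'
#' @param m Numeric matrix (rows north to south).
#' @param spec A [grid_spec()].
#' @param path File path.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a list with `matrix` and `spec`.
#' @export
write_ascii_grid <- function(m, spec, path) {
  stopifnot(all(dim(m) == c(spec$n_rows, spec$n_cols)))
  header <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_lon),
    sprintf("yllcorner %.10g", spec$origin_lat - spec$n_rows * spec$cell_size),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %.10g", spec$nodata)
  )
  m[is.na(m)] <- spec$nodata
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 9),
                                        collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  n_cols <- val("ncols"); n_rows <- val("nrows")
  cell <- val("cellsize"); nodata <- val("NODATA_value")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  body <- lapply(lines[-(1:6)], function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  })
  m <- do.call(rbind, body)
  m[m == nodata] <- NA
  spec <- grid_spec(n_rows, n_cols, cell_size = cell,
                    origin_lon = xll, origin_lat = yll + n_rows * cell,
                    nodata = nodata)
  list(matrix = m, spec = spec)
}
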