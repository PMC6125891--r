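#' Grid specification for a raster landscape
#'
#' Defines the common raster geometry every layer of an analysis shares:
#' number of rows and columns, the edge length of a (square) cell in km, and
#' the map coordinates of the lower-left corner. Matrices indexed
#' `[row, col]` have row 1 at the *bottom* of the map (smallest y), so that
#' `cell_xy()` is a simple affine map.
#'
#' @param n_rows,n_cols Grid dimensions (each at least 2).
#' @param cell_size Cell edge length in km (default 1, i.e. 1 km^2 cells).
#' @param origin Numeric length-2, map coordinates of the lower-left corner.
#' @return An object of class `grid_spec`.
#' @examples
#' gs <- grid_spec(100, 100)
#' grid_area_km2(gs)  # 10000
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1, origin = c(0, 0)) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 2 || n_cols < 2 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be integers >= 2")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar (km)")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_spec")
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @export
grid_area_km2 <- function(spec) {
  spec$n_rows * spec$n_cols * spec$cell_size^2
}

#' Cell centres and cell lookup
#'
#' `cell_xy()` returns the map coordinates of cell centres for linear cell
#' indices (column-major, row 1 = bottom). `xy_cell()` is the inverse: the
#' linear index of the cell containing a point.
#'
#' @param spec A [grid_spec()].
#' @param cells Integer vector of linear cell indices.
#' @return `cell_xy()`: a two-column matrix `x, y`; `xy_cell()`: integer
#'   vector of cell indices (NA outside the grid).
#' @export
cell_xy <- function(spec, cells) {
  row <- (cells - 1L) %% spec$n_rows + 1L
  col <- (cells - 1L) %/% spec$n_rows + 1L
  cbind(x = spec$origin[1] + (col - 0.5) * spec$cell_size,
        y = spec$origin[2] + (row - 0.5) * spec$cell_size)
}

#' @rdname cell_xy
#' @param x,y Point coordinates (map units, km).
#' @export
xy_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin[1]) / spec$cell_size) + 1L
  row <- floor((y - spec$origin[2]) / spec$cell_size) + 1L
  out <- (col - 1L) * spec$n_rows + row
  bad <- col < 1L | col > spec$n_cols | row < 1L | row > spec$n_rows
  out[bad] <- NA_integer_
  as.integer(out)
}

.canonical_vars <- c("MAT", "MAP", "NFFD", "Eref",
                     "elevation", "aspect", "forest", "urban")

#' Environmental raster stack for one time period
#'
#' Bundles the eight canonical environmental layers (MAT, MAP, NFFD, Eref,
#' elevation, aspect, forest, urban) on one grid, with a validity mask.
#' Forest and urban are fractions in \[0, 1\].
#'
#' @param period Period label (e.g. `"1970s"`).
#' @param layers Named list of matrices (`n_rows` x `n_cols`), exactly the
#'   eight canonical variable names.
#' @param spec A [grid_spec()].
#' @param mask Logical matrix of valid cells (default all valid).
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(period, layers, spec, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, spec$n_rows, spec$n_cols)
  if (!setequal(names(layers), .canonical_vars))
    stop("layers must be exactly: ", paste(.canonical_vars, collapse = ", "))
  dims <- c(spec$n_rows, spec$n_cols)
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), dims))
      stop("layer '", nm, "' does not match the grid spec")
  }
  for (nm in c("forest", "urban")) {
    v <- layers[[nm]][mask]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("'", nm, "' must lie in [0, 1]")
  }
  structure(list(period = period, layers = layers[.canonical_vars],
                 mask = mask, spec = spec),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> period", x$period, "-",
      x$spec$n_rows, "x", x$spec$n_cols, "cells at",
      x$spec$cell_size, "km;", sum(x$mask), "valid\n")
  invisible(x)
}

#' Extract layer values at points or cells
#'
#' @param stack An [env_stack()].
#' @param vars Variable names (default: all eight).
#' @param cells Linear cell indices; or supply `xy`, a two-column matrix of
#'   point coordinates, instead.
#' @param xy Optional point coordinates (converted with [xy_cell()]).
#' @return Matrix of layer values, one row per point/cell.
#' @export
extract_env <- function(stack, cells = NULL, xy = NULL, vars = names(stack$layers)) {
  if (is.null(cells)) {
    if (is.null(xy)) stop("supply cells or xy")
    cells <- xy_cell(stack$spec, xy[, 1], xy[, 2])
  }
  if (anyNA(cells)) stop("some points fall outside the grid")
  out <- vapply(vars, function(v) stack$layers[[v]][cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, vars))
  out
}

# --- plain-text raster I/O (ESRI ASCII grid) ---------------------------------

#' Read and write single layers as ESRI ASCII grids
#'
#' Layers are serialized one per file as ESRI ASCII grid (`.asc`), a
#' plain-text single-band raster format; masked cells are written as the
#' nodata value. File naming convention for stacks is `<period>_<var>.asc`.
#'
#' @param layer Matrix (row 1 = bottom).
#' @param spec A [grid_spec()].
#' @param path File path.
#' @param mask Logical matrix; masked-out cells become nodata.
#' @param nodata Nodata sentinel written to the header.
#' @return `read_asc()` returns `list(layer, spec, mask)`.
#' @export
write_asc <- function(layer, spec, path, mask = NULL, nodata = -9999) {
  if (is.null(mask)) mask <- matrix(TRUE, spec$n_rows, spec$n_cols)
  m <- layer
  m[!mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", spec$n_cols),
    paste("nrows", spec$n_rows),
    paste("xllcorner", spec$origin[1]),
    paste("yllcorner", spec$origin[2]),
    paste("cellsize", spec$cell_size),
    paste("NODATA_value", nodata)), con)
  # ASCII grids store the top row first
  for (r in spec$n_rows:1)
    writeLines(paste(formatC(m[r, ], format = "g", digits = 10), collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  spec <- grid_spec(val[["nrows"]], val[["ncols"]], val[["cellsize"]],
                    c(val[["xllcorner"]], val[["yllcorner"]]))
  body <- utils::read.table(path, skip = 6L)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  m <- m[spec$n_rows:1, , drop = FALSE]  # back to row 1 = bottom
  mask <- m != val[["nodata_value"]]
  m[!mask] <- NA_real_
  list(layer = m, spec = spec, mask = mask)
}

#' Write or read a whole period stack as ASCII grids
#'
#' @param stack An [env_stack()].
#' @param dir Directory for the `<period>_<var>.asc` files.
#' @param period,spec For reading: period label and optional known spec.
#' @return `read_stack_asc()` returns an [env_stack()].
#' @export
write_stack_asc <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in names(stack$layers))
    write_asc(stack$layers[[v]], stack$spec,
              file.path(dir, paste0(stack$period, "_", v, ".asc")),
              mask = stack$mask)
  invisible(dir)
}

#' @rdname write_stack_asc
#' @export
read_stack_asc <- function(dir, period, spec = NULL) {
  layers <- list()
  mask <- NULL
  for (v in .canonical_vars) {
    r <- read_asc(file.path(dir, paste0(period, "_", v, ".asc")))
    if (is.null(mask)) { mask <- r$mask; spec <- r$spec }
    lay <- r$layer
    lay[!mask] <- 0
    layers[[v]] <- lay
  }
  env_stack(period, layers, spec, mask)
}
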