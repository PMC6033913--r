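#' Gridded environmental layer
#'
#' An `env_grid` is a single environmental raster on a regular lon/lat grid:
#' a numeric matrix with row 1 the northernmost row, an extent in decimal
#' degrees, a square cell size, and `NA` for nodata cells. Grids use
#' cell-center registration: the cell in row `r`, column `c` has its center at
#' `(xmin + (c - 0.5) * cell, ymax - (r - 0.5) * cell)`.
#'
#' @param values Numeric matrix, row 1 = northernmost row. `NA` marks nodata.
#' @param extent Numeric vector `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param cell_size Cell edge in decimal degrees (cells are square).
#' @param name Layer identifier, e.g. `"bio11"`.
#' @param units Free-text units, e.g. `"degC"` or `"mm"`.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, extent, cell_size, name = "layer", units = "") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("`extent` must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("`cell_size` must be > 0")
  nr <- round((extent[4] - extent[3]) / cell_size)
  nc <- round((extent[2] - extent[1]) / cell_size)
  if (nrow(values) != nr || ncol(values) != nc)
    stop(sprintf(
      "shape %dx%d inconsistent with extent/cell_size (expected %dx%d)",
      nrow(values), ncol(values), nr, nc))
  if (abs(nr * cell_size - (extent[4] - extent[3])) > 1e-6 ||
      abs(nc * cell_size - (extent[2] - extent[1])) > 1e-6)
    stop("extent is not an integer number of cells")
  structure(
    list(name = name, values = values, extent = extent,
         cell_size = cell_size, units = units),
    class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf(
    "<env_grid> %s: %d x %d cells @ %g deg, extent [%g, %g] x [%g, %g]%s\n",
    x$name, nrow(x$values), ncol(x$values), x$cell_size,
    x$extent[1], x$extent[2], x$extent[3], x$extent[4],
    if (nzchar(x$units)) paste0(" (", x$units, ")") else ""))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  valid cells: %d/%d, range [%g, %g]\n",
                length(v), length(x$values), min(v), max(v)))
  else cat("  all cells nodata\n")
  invisible(x)
}

#' @rdname env_grid
#' @param x Object to test or print.
#' @export
is_env_grid <- function(x) inherits(x, "env_grid")

#' Nodata mask of a grid
#'
#' @param grid An [env_grid].
#' @return Logical matrix, `TRUE` where the cell holds a valid value.
#' @export
valid_mask <- function(grid) {
  stopifnot(is_env_grid(grid))
  !is.na(grid$values)
}

#' Cell-center coordinates
#'
#' @param grid An [env_grid].
#' @return Data frame with columns `lon`, `lat`, `row`, `col`, one row per
#'   cell in row-major (north-to-south) order.
#' @export
cell_centers <- function(grid) {
  stopifnot(is_env_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  lon <- grid$extent[1] + (seq_len(nc) - 0.5) * grid$cell_size
  lat <- grid$extent[4] - (seq_len(nr) - 0.5) * grid$cell_size
  data.frame(lon = rep(lon, each = nr), lat = rep(lat, times = nc),
             row = rep(seq_len(nr), times = nc),
             col = rep(seq_len(nc), each = nr))
}

# Row/col of the cell containing each point. Cells are half-open
# [west, east) x [south, north): a point on a shared interior edge belongs to
# the cell to its east/north. Returns NA row/col for points outside the extent.
cell_index <- function(grid, lon, lat) {
  ext <- grid$extent; cs <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - ext[1]) / cs) + 1L
  row_from_s <- floor((lat - ext[3]) / cs) + 1L
  row <- nr - row_from_s + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr |
    is.na(lon) | is.na(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read a gridded layer from file
#'
#' Reads a single-layer raster in ESRI ASCII grid format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by
#' north-to-south rows of values). Cells equal to the declared nodata value
#' become `NA`.
#'
#' @param path File path.
#' @param format Only `"ascii"` (ESRI ASCII grid) is supported.
#' @param name,units Layer metadata; `name` defaults to the file name.
#' @return An [env_grid].
#' @export
read_grid <- function(path, format = c("ascii", "geotiff"),
                      name = NULL, units = "") {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not supported by this build; use ESRI ASCII grids")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed header line ", i, ": '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(req, names(hdr))
  if (length(miss))
    stop("missing georeferencing header field(s): ", paste(miss, collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  if (length(body) != nr)
    stop(sprintf("expected %d data rows, found %d", nr, length(body)))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc)
      stop(sprintf("row %d has %d values, expected ncols=%d (line %d)",
                   r, length(row), nc, i + r - 1L))
    if (anyNA(row))
      stop(sprintf("unparseable value in data row %d (line %d)", r, i + r - 1L))
    vals[r, ] <- row
  }
  vals[abs(vals - nodata) < 1e-9] <- NA_real_
  ext <- c(hdr$xllcorner, hdr$xllcorner + nc * hdr$cellsize,
           hdr$yllcorner, hdr$yllcorner + nr * hdr$cellsize)
  env_grid(vals, ext, hdr$cellsize,
           name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
           units = units)
}

#' Write a gridded layer to file
#'
#' @param grid An [env_grid].
#' @param path Output path.
#' @param format Only `"ascii"`.
#' @param nodata Value written for `NA` cells.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("ascii", "geotiff"),
                       nodata = -9999, digits = 10) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not supported by this build; use ESRI ASCII grids")
  stopifnot(is_env_grid(grid))
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$extent[1]),
    sprintf("yllcorner %.10g", grid$extent[3]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  writeLines(apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")), con)
  invisible(path)
}

#' Stack of aligned environmental layers
#'
#' Combines grids that share extent, cell size and shape into an ordered
#' stack. The stack's valid mask is the intersection of the layers' masks:
#' a cell is usable only where every layer holds a value.
#'
#' @param grids A list of [env_grid] objects (or several passed via `...`).
#' @return An object of class `grid_stack` with elements `layers` (named
#'   list of grids) and `mask` (logical matrix, `TRUE` = all layers valid).
#' @export
align_stack <- function(grids) {
  if (is_env_grid(grids)) grids <- list(grids)
  if (!length(grids)) stop("at least one grid required")
  stopifnot(all(vapply(grids, is_env_grid, logical(1))))
  nm <- vapply(grids, function(g) g$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate layer names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (any(abs(g$extent - ref$extent) > 1e-9) ||
        abs(g$cell_size - ref$cell_size) > 1e-9 ||
        !identical(dim(g$values), dim(ref$values)))
      stop(sprintf("layers '%s' and '%s' are not aligned", ref$name, g$name))
  }
  mask <- Reduce(`&`, lapply(grids, valid_mask))
  structure(list(layers = stats::setNames(grids, nm), mask = mask),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<grid_stack> %d layer(s): %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  %d x %d cells @ %g deg; %d jointly valid cells\n",
              nrow(g$values), ncol(g$values), g$cell_size, sum(x$mask)))
  invisible(x)
}

#' @rdname align_stack
#' @param x Object to test.
#' @export
is_grid_stack <- function(x) inherits(x, "grid_stack")

#' Layer names of a stack
#' @param stack A [grid_stack][align_stack].
#' @return Character vector of layer names.
#' @export
stack_names <- function(stack) {
  stopifnot(is_grid_stack(stack))
  names(stack$layers)
}

#' Extract layer values at points
#'
#' Looks up, for each lon/lat point, the value of every layer in the cell
#' containing the point. Cell membership is half-open: a point lying exactly
#' on a shared cell edge belongs to the cell to its east/north. Points
#' outside the extent or in a cell where any layer is nodata are flagged
#' invalid and carry `NA` values.
#'
#' @param stack A [grid_stack][align_stack].
#' @param points Data frame (or matrix) with columns `lon` and `lat`.
#' @return Data frame: `lon`, `lat`, one column per layer, and logical
#'   `valid`.
#' @export
extract_values <- function(stack, points) {
  stopifnot(is_grid_stack(stack))
  points <- as.data.frame(points)
  if (!nrow(points)) {
    out <- data.frame(lon = numeric(0), lat = numeric(0))
    for (nm in names(stack$layers)) out[[nm]] <- numeric(0)
    out$valid <- logical(0)
    return(out)
  }
  stopifnot(all(c("lon", "lat") %in% names(points)))
  ref <- stack$layers[[1]]
  idx <- cell_index(ref, points$lon, points$lat)
  inside <- !is.na(idx$row)
  flat <- ifelse(inside, (idx$col - 1L) * nrow(ref$values) + idx$row, NA_integer_)
  out <- data.frame(lon = points$lon, lat = points$lat)
  for (nm in names(stack$layers))
    out[[nm]] <- ifelse(inside, stack$layers[[nm]]$values[flat], NA_real_)
  out$valid <- inside & !is.na(flat) & ifelse(inside, stack$mask[flat], FALSE)
  # nodata in any layer invalidates the point; blank partial values
  out[!out$valid, names(stack$layers)] <- NA_real_
  out
}
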