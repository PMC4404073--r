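#' Regular raster grid in projected metres
#'
#' Lightweight container for gridded exposures and interpolated coefficient
#' surfaces: a rectangular grid of square cells with a lower-left corner
#' origin, a cell size in metres and a numeric value per cell. Cells with
#' no data carry `NA` internally and the `nodata` marker on disk.
#'
#' @param values Numeric matrix, `n_rows` x `n_cols`; row 1 is the NORTH
#'   (top) row, matching the on-disk ESRI ASCII layout.
#' @param x0,y0 Lower-left corner of the grid (metres).
#' @param cell_size Cell edge length in metres (default 200).
#' @param nodata Value written for `NA` cells on export.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, x0, y0, cell_size = 200, nodata = -9999) {
  values <- as.matrix(values)
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be positive", call. = FALSE)
  }
  structure(list(values = values, x0 = x0, y0 = y0,
                 cell_size = cell_size, nodata = nodata,
                 n_rows = nrow(values), n_cols = ncol(values)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells of %.0f m, origin (%.0f, %.0f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x0, x$y0))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d NA cells\n",
                min(v), max(v), sum(!is.finite(x$values))))
  }
  invisible(x)
}

#' Cell-centre coordinates of a raster grid
#'
#' @param grid A `raster_grid`.
#' @return Tibble `x_m`, `y_m`, `row`, `col`, `value`, one row per cell,
#'   in row-major (north to south) order.
#' @export
grid_centers <- function(grid) {
  cs <- grid$cell_size
  xs <- grid$x0 + (seq_len(grid$n_cols) - 0.5) * cs
  # row 1 is the top (northern) row
  ys <- grid$y0 + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * cs
  tibble::tibble(
    row = rep(seq_len(grid$n_rows), each = grid$n_cols),
    col = rep(seq_len(grid$n_cols), times = grid$n_rows),
    x_m = rep(xs, times = grid$n_rows),
    y_m = rep(ys, each = grid$n_cols),
    value = as.vector(t(grid$values))
  )
}

# Build an empty grid covering a bounding box.
empty_grid <- function(xmin, ymin, xmax, ymax, cell_size = 200) {
  nc <- max(1L, ceiling((xmax - xmin) / cell_size))
  nr <- max(1L, ceiling((ymax - ymin) / cell_size))
  raster_grid(matrix(NA_real_, nr, nc), x0 = xmin, y0 = ymin,
              cell_size = cell_size)
}

#' Read / write ESRI ASCII grids
#'
#' The plain-text raster interchange format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values, northernmost row
#' first.
#'
#' @param path File path.
#' @return `read_esri_ascii()` returns a `raster_grid`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("cell count does not match header in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, x0 = hdr$xllcorner, y0 = hdr$yllcorner,
              cell_size = hdr$cellsize, nodata = nodata)
}

#' @rdname read_esri_ascii
#' @param grid A `raster_grid`.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.6f", grid$x0),
    sprintf("yllcorner %.6f", grid$y0),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %g", grid$nodata)
  )
  m <- grid$values
  m[!is.finite(m)] <- grid$nodata
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Plot a raster grid
#'
#' @param object A `raster_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, ...) {
  d <- grid_centers(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_m, .data$y_m,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "transparent") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}
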