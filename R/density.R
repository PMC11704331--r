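#' Gaussian kernel density map of marker-positive cells
#'
#' Rasterizes the positions of cells carrying a given marker class into a
#' density surface (cells per um^2) on a regular grid. The value at a pixel
#' center p is `sum_i (2*pi*h^2)^-1 * exp(-|p - x_i|^2 / (2*h^2))` over the
#' positive cells, with the kernel truncated at `6*h` for speed; at that
#' radius the discarded mass is below 1e-8 of a cell. With all sources at
#' least `3*h` from the window edge, `sum(grid) * pixel_size^2` recovers the
#' number of source cells to within 2%.
#'
#' Coordinates are continuous micrometers with the origin at the top-left
#' and y increasing downward, the convention of common whole-slide exports.
#'
#' @param cells Cell table (data.frame with `x_um`, `y_um`, `class`).
#' @param marker Marker class of the source cells.
#' @param bandwidth Gaussian kernel sigma in um.
#' @param pixel_size Grid resolution in um.
#' @param window Numeric vector `c(xmin, ymin, xmax, ymax)` in um; defaults
#'   to the bounding box of all cells.
#'
#' @return An object of class `density_map`: list with `grid` (rows = y,
#'   cols = x), `origin_x`, `origin_y`, `pixel_size`, `bandwidth`,
#'   `n_source_cells`.
#' @export
compute_density_map <- function(cells, marker, bandwidth = 50, pixel_size = 10,
                                window = NULL) {
  check_scalar(bandwidth, "bandwidth", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot(is.data.frame(cells), all(c("x_um", "y_um", "class") %in% names(cells)))
  if (is.null(window)) {
    window <- c(min(cells$x_um), min(cells$y_um), max(cells$x_um), max(cells$y_um))
  }
  stopifnot(length(window) == 4L)
  if (window[3L] <= window[1L] || window[4L] <= window[2L]) {
    stop_spatsig("'window' is degenerate (xmax <= xmin or ymax <= ymin)")
  }

  nx <- max(1L, ceiling((window[3L] - window[1L]) / pixel_size))
  ny <- max(1L, ceiling((window[4L] - window[2L]) / pixel_size))
  grid <- matrix(0, nrow = ny, ncol = nx)

  src <- cells[cells$class == marker, , drop = FALSE]
  n_src <- nrow(src)
  if (n_src == 0L) {
    warning("no cells carry marker '", marker, "'; returning an empty density map")
  } else {
    h <- bandwidth
    norm <- 1 / (2 * pi * h^2)
    trunc_px <- ceiling(6 * h / pixel_size)
    # pixel centers
    cx <- window[1L] + (seq_len(nx) - 0.5) * pixel_size
    cy <- window[2L] + (seq_len(ny) - 0.5) * pixel_size
    for (i in seq_len(n_src)) {
      jx <- floor((src$x_um[i] - window[1L]) / pixel_size) + 1L
      jy <- floor((src$y_um[i] - window[2L]) / pixel_size) + 1L
      xs <- max(1L, jx - trunc_px):min(nx, jx + trunc_px)
      ys <- max(1L, jy - trunc_px):min(ny, jy + trunc_px)
      dx2 <- (cx[xs] - src$x_um[i])^2
      dy2 <- (cy[ys] - src$y_um[i])^2
      d2 <- outer(dy2, dx2, `+`)
      k <- norm * exp(-d2 / (2 * h^2))
      k[d2 > (6 * h)^2] <- 0
      grid[ys, xs] <- grid[ys, xs] + k
    }
  }

  structure(
    list(grid = grid, origin_x = window[1L], origin_y = window[2L],
         pixel_size = pixel_size, bandwidth = bandwidth,
         n_source_cells = n_src),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat("Density map:", nrow(x$grid), "x", ncol(x$grid), "pixels of",
      x$pixel_size, "um;", x$n_source_cells, "source cells, bandwidth",
      x$bandwidth, "um\n")
  cat("  integrated mass:",
      format(sum(x$grid) * x$pixel_size^2, digits = 4), "cells\n")
  invisible(x)
}

#' @export
plot.density_map <- function(x, ...) {
  nx <- ncol(x$grid)
  ny <- nrow(x$grid)
  graphics::image(
    x = x$origin_x + (seq_len(nx) - 0.5) * x$pixel_size,
    y = x$origin_y + (seq_len(ny) - 0.5) * x$pixel_size,
    z = t(x$grid),
    ylim = c(x$origin_y + ny * x$pixel_size, x$origin_y),  # y-down convention
    xlab = "x (um)", ylab = "y (um)",
    col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...
  )
  invisible(x)
}
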