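#' Per-cell distance to the nearest hotspot region
#'
#' For every marker-positive cell, the Euclidean distance (um) from its
#' centroid to the nearest point on the boundary of the nearest hotspot
#' region; cells whose centroid lies inside a region get distance 0. This
#' mirrors "distance to annotation" measurements on whole-slide images.
#'
#' @param cells Cell table (`cell_id`, `x_um`, `y_um`, `class`).
#' @param marker Marker class of the queried cells.
#' @param hotspots A non-empty `hotspot_set`.
#' @return An object of class `distance_result`: data.frame `per_cell`
#'   (`cell_id`, `distance_um`, `nearest_region`), plus `mean`, `sd`,
#'   `n_cells`.
#' @export
distance_to_hotspots <- function(cells, marker, hotspots) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  if (length(hotspots$regions) == 0L) {
    stop_spatsig("hotspot set is empty: distance is undefined")
  }
  q <- cells[cells$class == marker, , drop = FALSE]
  if (nrow(q) == 0L) {
    stop_spatsig("no cells carry marker '", marker, "'")
  }
  inside <- points_in_hotspots(q$x_um, q$y_um, hotspots)
  seg_all <- do.call(rbind, lapply(hotspots$regions, `[[`, "segments"))
  seg_region <- rep.int(
    vapply(hotspots$regions, `[[`, integer(1L), "region_id"),
    vapply(hotspots$regions, function(r) nrow(r$segments), integer(1L))
  )
  d <- numeric(nrow(q))
  nearest <- integer(nrow(q))
  for (i in seq_len(nrow(q))) {
    if (inside[i]) {
      # region containing the cell: nearest region by boundary distance
      dd <- dist_point_segments(q$x_um[i], q$y_um[i], seg_all)
      nearest[i] <- seg_region[which.min(dd)]
      d[i] <- 0
    } else {
      dd <- dist_point_segments(q$x_um[i], q$y_um[i], seg_all)
      j <- which.min(dd)
      d[i] <- dd[j]
      nearest[i] <- seg_region[j]
    }
  }
  structure(
    list(per_cell = data.frame(cell_id = q$cell_id, distance_um = d,
                               nearest_region = nearest,
                               stringsAsFactors = FALSE),
         mean = mean(d), sd = stats::sd(d), n_cells = nrow(q)),
    class = "distance_result"
  )
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("Distances of %d cells to hotspots: mean %.1f um, sd %.1f um\n",
              x$n_cells, x$mean, x$sd))
  invisible(x)
}

# Minimum distance from point (px, py) to each segment row of `seg`.
dist_point_segments <- function(px, py, seg) {
  ax <- seg[, 1L]; ay <- seg[, 2L]
  dx <- seg[, 3L] - ax; dy <- seg[, 4L] - ay
  len2 <- dx * dx + dy * dy
  t <- ((px - ax) * dx + (py - ay) * dy) / ifelse(len2 == 0, 1, len2)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Shortest distances of each cell to two competing hotspot classes
#'
#' Computes, per marker-positive cell, its distance to hotspot set A and to
#' hotspot set B (as in [distance_to_hotspots()]) and summarizes which class
#' each cell is closer to. Exact ties count in neither side and are reported
#' separately.
#'
#' @param cells Cell table.
#' @param marker Marker class of the queried cells.
#' @param hotspots_a,hotspots_b Non-empty `hotspot_set`s.
#' @return An object of class `distance_pairs`: data.frame `per_cell`
#'   (`cell_id`, `d_a`, `d_b`), `fraction_closer_a`, `fraction_closer_b`,
#'   `n_ties`, `n_cells`.
#' @export
shortest_distance_pairs <- function(cells, marker, hotspots_a, hotspots_b) {
  da <- distance_to_hotspots(cells, marker, hotspots_a)
  db <- distance_to_hotspots(cells, marker, hotspots_b)
  d_a <- da$per_cell$distance_um
  d_b <- db$per_cell$distance_um
  ties <- d_a == d_b
  structure(
    list(per_cell = data.frame(cell_id = da$per_cell$cell_id,
                               d_a = d_a, d_b = d_b,
                               stringsAsFactors = FALSE),
         fraction_closer_a = mean(d_a < d_b),
         fraction_closer_b = mean(d_b < d_a),
         n_ties = sum(ties), n_cells = length(d_a)),
    class = "distance_pairs"
  )
}

#' @export
print.distance_pairs <- function(x, ...) {
  cat(sprintf(
    "Distance pairs over %d cells: %.1f%% closer to A, %.1f%% closer to B, %d ties\n",
    x$n_cells, 100 * x$fraction_closer_a, 100 * x$fraction_closer_b, x$n_ties))
  invisible(x)
}
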