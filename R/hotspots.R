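#' Segment hotspot regions from a density map
#'
#' Thresholds a density surface into "hotspots": connected regions of high
#' marker-positive cell density. Pixels at or above the threshold (closed
#' threshold) form a binary mask, 8-connected components are extracted,
#' components smaller than `min_area_um2` are dropped, and each surviving
#' component is contoured into one or more closed polygon rings following
#' the pixel boundary. Regions are ordered by descending area.
#'
#' In quantile mode the threshold is taken over pixels with strictly
#' positive density only, so large empty slide areas do not dilute it.
#'
#' @param density A [compute_density_map()] result.
#' @param threshold_mode `"quantile"` (threshold in (0,1), over positive
#'   pixels) or `"absolute"` (a density in cells/um^2).
#' @param threshold Threshold value, interpreted per `threshold_mode`.
#' @param min_area_um2 Minimum region area kept, in um^2.
#' @param class_label Marker class the hotspots belong to (metadata).
#'
#' @return An object of class `hotspot_set`: list with `class_label`,
#'   `regions` (each with `pixels`, `area_um2`, `segments`, `rings`),
#'   `threshold_used`, `min_area_um2`, and the grid geometry. An all-empty
#'   mask yields zero regions (valid, not an error).
#' @export
derive_hotspots <- function(density, threshold_mode = c("quantile", "absolute"),
                            threshold = 0.9, min_area_um2 = 10000,
                            class_label = NA_character_) {
  stopifnot(inherits(density, "density_map"))
  threshold_mode <- match.arg(threshold_mode)
  check_scalar(min_area_um2, "min_area_um2", nonneg = TRUE)
  grid <- density$grid
  ps <- density$pixel_size

  if (threshold_mode == "quantile") {
    if (threshold <= 0 || threshold >= 1) {
      stop_spatsig("quantile threshold must lie in (0, 1)")
    }
    pos <- grid[grid > 0]
    thr <- if (length(pos) == 0L) Inf else stats::quantile(pos, threshold, names = FALSE)
  } else {
    check_scalar(threshold, "threshold", nonneg = TRUE)
    thr <- threshold
  }

  mask <- grid >= thr
  lab <- label_components_8(mask)
  n_lab <- max(lab)
  regions <- list()
  if (n_lab > 0L) {
    for (l in seq_len(n_lab)) {
      px <- which(lab == l)
      area <- length(px) * ps^2
      if (area < min_area_um2) next
      seg <- region_boundary_segments(px, dim(grid), density$origin_x,
                                      density$origin_y, ps)
      regions[[length(regions) + 1L]] <- list(
        pixels = px, area_um2 = area, segments = seg,
        rings = stitch_rings(seg)
      )
    }
    if (length(regions) > 0L) {
      ord <- order(vapply(regions, `[[`, numeric(1L), "area_um2"),
                   decreasing = TRUE)
      regions <- regions[ord]
      for (i in seq_along(regions)) regions[[i]]$region_id <- i
    }
  }

  structure(
    list(class_label = class_label, regions = regions, threshold_used = thr,
         min_area_um2 = min_area_um2, pixel_size = ps,
         origin_x = density$origin_x, origin_y = density$origin_y,
         grid_dim = dim(grid)),
    class = "hotspot_set"
  )
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("Hotspot set", if (!is.na(x$class_label)) paste0("[", x$class_label, "]"),
      "-", length(x$regions), "region(s), threshold",
      format(x$threshold_used, digits = 4), "\n")
  for (r in x$regions) {
    cat(sprintf("  region %d: %.0f um^2 (%d pixels)\n",
                r$region_id, r$area_um2, length(r$pixels)))
  }
  invisible(x)
}

#' Total area of a hotspot set
#' @param x A `hotspot_set`.
#' @return Total region area in um^2.
#' @export
hotspot_area <- function(x) {
  stopifnot(inherits(x, "hotspot_set"))
  sum(vapply(x$regions, `[[`, numeric(1L), "area_um2"))
}

# 8-connected component labeling by breadth-first search over the mask.
label_components_8 <- function(mask) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  nextlab <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    lab[s] <- nextlab
    frontier <- s
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% ny) + 1L
      cc <- ((frontier - 1L) %/% ny) + 1L
      nr <- rep(r, times = 8L) + rep(dr, each = length(r))
      nc <- rep(cc, times = 8L) + rep(dc, each = length(r))
      ok <- nr >= 1L & nr <= ny & nc >= 1L & nc <= nx
      ni <- (nc[ok] - 1L) * ny + nr[ok]
      ni <- unique(ni[mask[ni] & lab[ni] == 0L])
      lab[ni] <- nextlab
      frontier <- ni
    }
  }
  lab
}

# Boundary segments of a pixel set, as directed edges (x1,y1,x2,y2) in um.
# A pixel edge is boundary iff the 4-neighbor across it is outside the
# region. Orientation: top edge runs +x, right edge +y, bottom edge -x,
# left edge -y (y-down coordinates), so every ring closes.
region_boundary_segments <- function(pixels, grid_dim, origin_x, origin_y, ps) {
  ny <- grid_dim[1L]
  nx <- grid_dim[2L]
  inset <- logical(ny * nx)
  inset[pixels] <- TRUE
  r <- ((pixels - 1L) %% ny) + 1L
  cc <- ((pixels - 1L) %/% ny) + 1L
  xl <- origin_x + (cc - 1L) * ps
  xr <- xl + ps
  yt <- origin_y + (r - 1L) * ps
  yb <- yt + ps
  inreg <- function(rr, ccc) {
    ok <- rr >= 1L & rr <= ny & ccc >= 1L & ccc <= nx
    res <- logical(length(rr))
    res[ok] <- inset[(ccc[ok] - 1L) * ny + rr[ok]]
    res
  }
  top <- !inreg(r - 1L, cc)
  bottom <- !inreg(r + 1L, cc)
  left <- !inreg(r, cc - 1L)
  right <- !inreg(r, cc + 1L)
  seg <- rbind(
    cbind(xl[top], yt[top], xr[top], yt[top]),
    cbind(xr[right], yt[right], xr[right], yb[right]),
    cbind(xr[bottom], yb[bottom], xl[bottom], yb[bottom]),
    cbind(xl[left], yb[left], xl[left], yt[left])
  )
  colnames(seg) <- c("x1", "y1", "x2", "y2")
  seg
}

# Stitch directed boundary edges into closed rings. At pinch vertices
# (diagonally touching pixels) two outgoing edges exist; the sharpest right
# turn relative to the incoming direction is taken so rings touch at the
# vertex but never cross.
stitch_rings <- function(seg) {
  if (nrow(seg) == 0L) return(list())
  key <- function(x, y) paste(round(x, 6), round(y, 6))
  from <- key(seg[, 1L], seg[, 2L])
  out_by_vertex <- split(seq_len(nrow(seg)), from)
  used <- logical(nrow(seg))
  # direction codes: 1 = +x, 2 = +y, 3 = -x, 4 = -y (y-down)
  dir_of <- function(i) {
    dx <- sign(seg[i, 3L] - seg[i, 1L])
    dy <- sign(seg[i, 4L] - seg[i, 2L])
    if (dx > 0) 1L else if (dy > 0) 2L else if (dx < 0) 3L else 4L
  }
  rings <- list()
  for (start in seq_len(nrow(seg))) {
    if (used[start]) next
    path_x <- seg[start, 1L]
    path_y <- seg[start, 2L]
    cur <- start
    repeat {
      used[cur] <- TRUE
      path_x <- c(path_x, seg[cur, 3L])
      path_y <- c(path_y, seg[cur, 4L])
      nxt_key <- key(seg[cur, 3L], seg[cur, 4L])
      cand <- out_by_vertex[[nxt_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) > 1L) {
        # prefer right turn (dir + 1 mod 4), then straight, then left
        d <- dir_of(cur)
        pref <- c((d %% 4L) + 1L, d, ((d + 2L) %% 4L) + 1L)
        cand_dirs <- vapply(cand, dir_of, integer(1L))
        cand <- cand[order(match(cand_dirs, pref))]
      }
      cur <- cand[1L]
    }
    rings[[length(rings) + 1L]] <- cbind(x = path_x, y = path_y)
  }
  rings
}

# Is each point inside the region set? The closed pixel squares define the
# region, so points on a region boundary (shared pixel edges included)
# count as inside.
points_in_hotspots <- function(x, y, hotspots, tol = 1e-9) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  ny <- hotspots$grid_dim[1L]
  nx <- hotspots$grid_dim[2L]
  inset <- logical(ny * nx)
  for (r in hotspots$regions) inset[r$pixels] <- TRUE
  ps <- hotspots$pixel_size
  tx <- (x - hotspots$origin_x) / ps
  ty <- (y - hotspots$origin_y) / ps
  res <- logical(length(x))
  for (i in seq_along(x)) {
    ccs <- unique(pmax(1L, pmin(nx, c(floor(tx[i] - tol), floor(tx[i] + tol)) + 1L)))
    rrs <- unique(pmax(1L, pmin(ny, c(floor(ty[i] - tol), floor(ty[i] + tol)) + 1L)))
    # outside the grid entirely
    if (tx[i] < -tol || tx[i] > nx + tol || ty[i] < -tol || ty[i] > ny + tol) next
    for (rr in rrs) for (cc in ccs) {
      if (inset[(cc - 1L) * ny + rr]) {
        res[i] <- TRUE
      }
    }
  }
  res
}

#' Fraction of marker-positive cells inside hotspot regions
#'
#' Counts cells whose centroid lies inside any region of the hotspot set
#' (boundary counts as inside) and returns the marker-positive fraction
#' among them.
#'
#' @param cells Cell table (`x_um`, `y_um`, `class`).
#' @param marker Marker class defining positivity.
#' @param regions A `hotspot_set`.
#' @return A list of class `positive_fraction`: `fraction` (NA, flagged, if
#'   no cell falls inside any region), `n_positive`, `n_total`.
#' @export
positive_fraction_in_regions <- function(cells, marker, regions) {
  stopifnot(inherits(regions, "hotspot_set"))
  if (length(regions$regions) == 0L) stop_spatsig("hotspot set has no regions")
  inside <- points_in_hotspots(cells$x_um, cells$y_um, regions)
  n_total <- sum(inside)
  n_pos <- sum(inside & cells$class == marker)
  structure(
    list(fraction = if (n_total == 0L) NA_real_ else n_pos / n_total,
         n_positive = n_pos, n_total = n_total,
         undefined = n_total == 0L),
    class = "positive_fraction"
  )
}

#' @export
print.positive_fraction <- function(x, ...) {
  if (x$undefined) {
    cat("Positive fraction undefined: no cells inside any region\n")
  } else {
    cat(sprintf("Positive fraction: %.4f (%d of %d cells in regions)\n",
                x$fraction, x$n_positive, x$n_total))
  }
  invisible(x)
}
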