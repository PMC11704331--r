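# Independent oracle implementations, deliberately naive (loops, dense
# sampling, grid search) and kept separate from the package code paths they
# check.

# Even-odd point-in-polygon over a list of rings (closed coordinate
# matrices); a point is inside the region iff it is inside an odd number of
# rings.
oracle_point_in_rings <- function(px, py, rings) {
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    for (i in seq_len(n - 1L)) {
      x1 <- ring[i, 1L]; y1 <- ring[i, 2L]
      x2 <- ring[i + 1L, 1L]; y2 <- ring[i + 1L, 2L]
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) crossings <- crossings + 1L
      }
    }
  }
  (crossings %% 2L) == 1L
}

# Brute-force distance to a hotspot set: 0 if inside any region's rings,
# else the minimum distance over boundary points sampled every `step` um.
oracle_distance_to_hotspots <- function(px, py, hotspots, step = 0.01) {
  for (r in hotspots$regions) {
    if (oracle_point_in_rings(px, py, r$rings)) return(0)
  }
  best <- Inf
  for (r in hotspots$regions) {
    seg <- r$segments
    for (i in seq_len(nrow(seg))) {
      len <- sqrt((seg[i, 3L] - seg[i, 1L])^2 + (seg[i, 4L] - seg[i, 2L])^2)
      t <- seq(0, 1, by = step / max(len, step))
      sx <- seg[i, 1L] + t * (seg[i, 3L] - seg[i, 1L])
      sy <- seg[i, 2L] + t * (seg[i, 4L] - seg[i, 2L])
      best <- min(best, min(sqrt((sx - px)^2 + (sy - py)^2)))
    }
  }
  best
}

# Step-by-step evaluation of the single-sample enrichment statistic, written
# directly from its definition with explicit loops.
oracle_gsva <- function(expr, set_genes, tau = 1, kcdf = "gaussian") {
  G <- nrow(expr)
  n <- ncol(expr)
  z <- matrix(0, G, n)
  for (g in seq_len(G)) {
    x <- expr[g, ]
    if (kcdf == "gaussian") {
      h <- sd(x) / 4
      for (j in seq_len(n)) {
        if (h > 0) {
          z[g, j] <- mean(pnorm((x[j] - x) / h))
        } else {
          z[g, j] <- mean(x <= x[j])
        }
      }
    } else {
      for (j in seq_len(n)) z[g, j] <- mean(x <= x[j])
    }
  }
  in_set <- rownames(expr) %in% set_genes
  scores <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    weight <- abs(G / 2 - seq_len(G))^tau
    set_at <- in_set[ord]
    denom_up <- sum(weight[set_at])
    v <- 0
    vmax <- 0
    vmin <- 0
    for (k in seq_len(G)) {
      if (set_at[k]) {
        v <- v + weight[k] / denom_up
      } else {
        v <- v - 1 / (G - sum(in_set))
      }
      vmax <- max(vmax, v)
      vmin <- min(vmin, v)
    }
    scores[j] <- vmax + vmin
  }
  names(scores) <- colnames(expr)
  scores
}

# Loop evaluation of the preranked enrichment running sum.
oracle_gsea_es <- function(scores, gene_set, p = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  n <- length(s)
  denom_hit <- sum(abs(s[hit])^p)
  v <- 0
  best <- 0
  for (k in seq_len(n)) {
    if (hit[k]) {
      v <- v + abs(s[k])^p / denom_hit
    } else {
      v <- v - 1 / (n - sum(hit))
    }
    if (abs(v) > abs(best)) best <- v
  }
  unname(best)
}

# Breslow log partial likelihood for a two-group indicator covariate,
# evaluated on a grid of log hazard ratios.
oracle_cox_grid <- function(time, event, x, grid = seq(-3, 3, by = 1e-4)) {
  loglik <- vapply(grid, function(beta) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      d <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + beta * sum(x[d]) -
        length(d) * log(sum(exp(beta * x[risk])))
    }
    ll
  }, numeric(1L))
  grid[which.max(loglik)]
}

# Small deterministic cell table helper.
make_cells <- function(x, y, class, ids = NULL) {
  data.frame(
    cell_id = ids %||% sprintf("c%03d", seq_along(x)),
    x_um = x, y_um = y, class = class, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Density map built directly from a hand-made grid (for hotspot tests).
manual_density_map <- function(grid, pixel_size = 10, origin = c(0, 0),
                               bandwidth = 50) {
  structure(
    list(grid = grid, origin_x = origin[1L], origin_y = origin[2L],
         pixel_size = pixel_size, bandwidth = bandwidth,
         n_source_cells = NA_integer_),
    class = "density_map"
  )
}
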