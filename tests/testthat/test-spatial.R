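test_that("density map handles empty and single-cell inputs", {
  cells <- make_cells(500, 500, "TF_A")
  expect_warning(
    dm0 <- compute_density_map(cells, "TF_B", 50, 10, window = c(0, 0, 1000, 1000)),
    "no cells"
  )
  expect_true(all(dm0$grid == 0))
  expect_identical(dm0$n_source_cells, 0L)

  # unit mass for one centered cell
  dm1 <- compute_density_map(cells, "TF_A", 50, 10, window = c(0, 0, 1000, 1000))
  mass <- sum(dm1$grid) * dm1$pixel_size^2
  expect_gt(mass, 0.98)
  expect_lt(mass, 1.02)
})

test_that("density at the midpoint of two cells matches the closed-form kernel sum", {
  h <- 40
  d <- 60  # cells 2d apart, midpoint at distance d from each
  cells <- make_cells(c(500 - d, 500 + d), c(500, 500), "TF_A")
  # fine pixel grid so a pixel center falls on the midpoint
  dm <- compute_density_map(cells, "TF_A", bandwidth = h, pixel_size = 1,
                            window = c(0, 0, 1000, 1000))
  center_val <- dm$grid[500, 500]  # pixel center (499.5, 499.5)
  # direct hand evaluation of the kernel sum at that pixel center
  px <- 499.5; py <- 499.5
  expected <- sum((1 / (2 * pi * h^2)) *
                    exp(-((cells$x_um - px)^2 + (cells$y_um - py)^2) / (2 * h^2)))
  expect_equal(center_val, expected, tolerance = 1e-10)
})

test_that("KDE mass conservation holds across random configurations", {
  set.seed(42)
  for (i in 1:100) {
    h <- runif(1, 10, 60)
    ps <- runif(1, 2, h / 2)
    n <- sample(1:20, 1)
    w <- 1000
    margin <- 3 * h
    cells <- make_cells(runif(n, margin, w - margin),
                        runif(n, margin, w - margin), "M")
    dm <- compute_density_map(cells, "M", bandwidth = h, pixel_size = ps,
                              window = c(0, 0, w, w))
    mass <- sum(dm$grid) * ps^2
    expect_lt(abs(mass - n) / n, 0.02)
  }
})

test_that("hotspot segmentation matches constructed rasters", {
  # constant positive density with a threshold below it: one full-window region
  g <- matrix(1, 10, 10)
  hs <- derive_hotspots(manual_density_map(g), "absolute", 0.5, 0)
  expect_length(hs$regions, 1)
  expect_equal(hs$regions[[1]]$area_um2, 100 * 10^2)

  # two separated plateaus
  g2 <- matrix(0, 10, 10)
  g2[2:3, 2:4] <- 5   # 6 pixels
  g2[7:9, 7:9] <- 5   # 9 pixels
  hs2 <- derive_hotspots(manual_density_map(g2), "absolute", 1, 0)
  expect_length(hs2$regions, 2)
  expect_equal(sort(vapply(hs2$regions, `[[`, numeric(1), "area_um2")),
               c(6, 9) * 100)

  # threshold above the maximum: no regions
  hs3 <- derive_hotspots(manual_density_map(g2), "absolute", 10, 0)
  expect_length(hs3$regions, 0)

  # min-area filter drops the smaller plateau
  hs4 <- derive_hotspots(manual_density_map(g2), "absolute", 1, 700)
  expect_length(hs4$regions, 1)
  expect_equal(hs4$regions[[1]]$area_um2, 900)
})

test_that("diagonally touching pixels form one 8-connected region", {
  g <- matrix(0, 6, 6)
  g[2, 2] <- 1
  g[3, 3] <- 1
  hs <- derive_hotspots(manual_density_map(g), "absolute", 0.5, 0)
  expect_length(hs$regions, 1)
  expect_equal(hs$regions[[1]]$area_um2, 200)
  # rings close and their shoelace area equals the pixel area
  shoe <- function(ring) {
    x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
    sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
  }
  total <- sum(abs(vapply(hs$regions[[1]]$rings, shoe, numeric(1))))
  expect_equal(total, 200)
  for (ring in hs$regions[[1]]$rings) {
    expect_equal(ring[1, ], ring[nrow(ring), ])
  }
})

test_that("raising an absolute threshold never increases hotspot area", {
  set.seed(7)
  cells <- make_cells(runif(200, 0, 500), runif(200, 0, 500), "M")
  dm <- compute_density_map(cells, "M", 40, 10, window = c(0, 0, 500, 500))
  thr <- seq(0, max(dm$grid), length.out = 12)
  areas <- vapply(thr, function(t) {
    hotspot_area(derive_hotspots(dm, "absolute", t, 0))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("positive fraction counts cells inside regions, boundary inclusive", {
  g <- matrix(0, 10, 10)
  g[3:6, 3:6] <- 1  # region square [20,60] x [20,60]
  hs <- derive_hotspots(manual_density_map(g), "absolute", 0.5, 0)
  cells <- make_cells(
    x = c(30, 40, 50, 25, 55, 90, 95),
    y = c(30, 40, 50, 25, 55, 90, 95),
    class = c("P", "P", "P", "N", "N", "P", "P")
  )
  pf <- positive_fraction_in_regions(cells, "P", hs)
  expect_equal(pf$fraction, 3 / 5)
  # boundary cell counts as inside
  edge <- make_cells(c(20, 60, 5), c(40, 60, 5), c("P", "P", "N"))
  pf2 <- positive_fraction_in_regions(edge, "P", hs)
  expect_equal(pf2$n_total, 2)
  expect_equal(pf2$fraction, 1)
  # no cell inside: flagged undefined
  pf3 <- positive_fraction_in_regions(make_cells(90, 90, "P"), "P", hs)
  expect_true(pf3$undefined)
  expect_true(is.na(pf3$fraction))
})

test_that("positive fraction agrees with a brute-force point-in-polygon count", {
  set.seed(13)
  cells <- make_cells(runif(300, 0, 500), runif(300, 0, 500),
                      sample(c("P", "N"), 300, replace = TRUE))
  dm <- compute_density_map(cells, "P", 40, 10, window = c(0, 0, 500, 500))
  hs <- derive_hotspots(dm, "quantile", 0.8, 0)
  pf <- positive_fraction_in_regions(cells, "P", hs)
  inside <- vapply(seq_len(nrow(cells)), function(i) {
    any(vapply(hs$regions, function(r) {
      oracle_point_in_rings(cells$x_um[i], cells$y_um[i], r$rings)
    }, logical(1)))
  }, logical(1))
  # exclude cells within numerical reach of a boundary, where the inside
  # conventions of the two methods may legitimately differ
  d <- vapply(seq_len(nrow(cells)), function(i) {
    oracle_distance_to_hotspots(cells$x_um[i], cells$y_um[i], hs, step = 0.5)
  }, numeric(1))
  clear <- d == 0 | d > 1e-6
  expect_equal(pf$n_total, sum(inside))
  expect_equal(pf$fraction, sum(inside & cells$class == "P") / sum(inside))
})

test_that("distance to a square region matches hand geometry", {
  g <- matrix(0, 10, 10)
  g[1:10, 1:4] <- 1  # region x in [0, 40], all y
  hs <- derive_hotspots(manual_density_map(g), "absolute", 0.5, 0)
  cells <- make_cells(c(100, 20), c(50, 50), "Q")
  d <- distance_to_hotspots(cells, "Q", hs)
  expect_equal(d$per_cell$distance_um, c(60, 0))
  expect_equal(d$mean, 30)
  # brute-force boundary sampling agrees
  bf <- oracle_distance_to_hotspots(100, 50, hs, step = 0.01)
  expect_lt(abs(bf - 60), 0.05)
})

test_that("distances are invariant under a common translation", {
  set.seed(5)
  cells <- make_cells(runif(30, 0, 300), runif(30, 0, 300),
                      rep(c("M", "Q"), 15))
  dm <- compute_density_map(cells, "M", 30, 10, window = c(0, 0, 300, 300))
  hs <- derive_hotspots(dm, "quantile", 0.7, 0)
  d0 <- distance_to_hotspots(cells, "Q", hs)
  shift <- c(1234.5, -321.25)
  cells2 <- cells
  cells2$x_um <- cells2$x_um + shift[1]
  cells2$y_um <- cells2$y_um + shift[2]
  dm2 <- compute_density_map(cells2, "M", 30, 10,
                             window = c(shift[1], shift[2],
                                        300 + shift[1], 300 + shift[2]))
  hs2 <- derive_hotspots(dm2, "quantile", 0.7, 0)
  d2 <- distance_to_hotspots(cells2, "Q", hs2)
  expect_equal(d2$per_cell$distance_um, d0$per_cell$distance_um,
               tolerance = 1e-8)
})

test_that("distance errors on empty hotspot sets and absent markers", {
  g <- matrix(1, 5, 5)
  hs <- derive_hotspots(manual_density_map(g), "absolute", 2, 0)  # empty
  cells <- make_cells(10, 10, "Q")
  expect_error(distance_to_hotspots(cells, "Q", hs), "empty")
  hs_ok <- derive_hotspots(manual_density_map(g), "absolute", 0.5, 0)
  expect_error(distance_to_hotspots(cells, "ABSENT", hs_ok), "no cells")
})

test_that("identical hotspot sets give all ties in the pair analysis", {
  g <- matrix(0, 10, 10)
  g[3:5, 3:5] <- 1
  hs <- derive_hotspots(manual_density_map(g), "absolute", 0.5, 0)
  cells <- make_cells(c(80, 90, 10), c(80, 90, 10), "Q")
  pr <- shortest_distance_pairs(cells, "Q", hs, hs)
  expect_equal(pr$fraction_closer_a, 0)
  expect_equal(pr$fraction_closer_b, 0)
  expect_equal(pr$n_ties, 3)
})

test_that("a cell equidistant to two point-like regions is a tie", {
  ga <- matrix(0, 11, 11); ga[6, 2] <- 1   # pixel center x = 15, y = 55
  gb <- matrix(0, 11, 11); gb[6, 10] <- 1  # pixel center x = 95, y = 55
  hsa <- derive_hotspots(manual_density_map(ga), "absolute", 0.5, 0)
  hsb <- derive_hotspots(manual_density_map(gb), "absolute", 0.5, 0)
  cells <- make_cells(55, 55, "Q")  # exact midpoint between the two pixels
  pr <- shortest_distance_pairs(cells, "Q", hsa, hsb)
  expect_equal(pr$n_ties, 1)
})

test_that("welch test matches hand computation and is antisymmetric", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  w <- welch_test(a, b)
  # hand evaluation of the Welch formulas
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(w$t_statistic, t_hand)
  expect_equal(w$t_statistic, -1.095445, tolerance = 1e-6)
  expect_equal(w$df, 6)
  expect_equal(w$p_two_tailed, 2 * pt(t_hand, 6), tolerance = 1e-12)
  # cross-check against the reference implementation
  ref <- t.test(a, b)
  expect_equal(w$t_statistic, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p_two_tailed, ref$p.value)
  # antisymmetry
  w2 <- welch_test(b, a)
  expect_equal(w2$t_statistic, -w$t_statistic)
  expect_equal(w2$p_two_tailed, w$p_two_tailed)
  # degenerate cases
  eq <- welch_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_two_tailed, 1)
  deg <- welch_test(c(1, 1, 1), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_two_tailed, .Machine$double.xmin)
})
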