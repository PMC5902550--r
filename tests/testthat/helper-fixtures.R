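# Fixture builders shared across test files. Everything is generated in
# code; coordinates are planar metres.

# Unit-ish square basin of side `s` with corner at (x0, y0).
square_basin <- function(id = "b1", s = 1000, x0 = 0, y0 = 0,
                         flow_min = 350, flow_max = 10) {
  sub_basin(id, rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s),
                      c(x0, y0 + s)), flow_min, flow_max)
}

# Graph-paper landscape used for hand-computed distance checks:
# one horizontal weir along y = 100 (x in [0, 1000]) and one vertical
# causeway along x = 800 (y in [0, 1000]) inside a 1000 m square basin.
graph_paper_landscape <- function() {
  weir <- linear_feature("w1", "weir", rbind(c(0, 100), c(1000, 100)))
  cwy <- linear_feature("c1", "causeway", rbind(c(800, 0), c(800, 1000)))
  ponds <- list(
    pond("p1", c(100, 130), 500),  # 30 m above the weir, 700 m from causeway
    pond("p2", c(795, 500), 500),  # 5 m from the causeway, 400 m from weir
    pond("p3", c(0, 100), 500)     # exactly on a weir vertex
  )
  landscape(list(square_basin()), list(weir, cwy), list(), ponds)
}

# Minimal single-feature-per-class landscape for IO tests (coordinates
# large enough not to trip the lon/lat guard).
minimal_landscape <- function() {
  basin <- square_basin(s = 1000, x0 = 5000, y0 = 5000)
  weir <- linear_feature("w1", "weir",
                         rbind(c(5000, 5500), c(5400, 5520), c(5800, 5480)))
  p <- pond("p1", c(5400, 5540), area = 321.5, berm_status = "present",
            berm_high_azimuth = 12.5, berm_arc_start = 340,
            berm_arc_end = 45)
  landscape(list(basin), list(weir), list(), list(p))
}

# Independent dense-sampling oracle for point-to-segment distance: the
# minimum distance from p to k points sampled regularly along the segment.
dense_segment_distance <- function(p, a, b, k = 50000) {
  t <- seq(0, 1, length.out = k)
  qx <- a[1] + t * (b[1] - a[1])
  qy <- a[2] + t * (b[2] - a[2])
  sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2))
}

# Triangulation-fan area oracle for convex polygons.
fan_area <- function(poly) {
  n <- nrow(poly)
  a <- 0
  for (i in 2:(n - 1)) {
    v1 <- poly[i, ] - poly[1, ]
    v2 <- poly[i + 1, ] - poly[1, ]
    a <- a + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  a
}

# Random convex polygon: convex hull of random points, counter-clockwise.
random_convex_polygon <- function(n = 8, r = 100) {
  pts <- matrix(stats::runif(3 * n * 2, -r, r), ncol = 2)
  hull <- rev(grDevices::chull(pts))
  pts[hull, , drop = FALSE]
}

# Small landscape whose association p-value is moderately significant and
# whose null within-cutoff probability is high (~0.5: seven weirs spaced
# 140 m, so 35 m buffers tile half the basin). The high null probability
# makes the undetected-pond p-trace rise steeply — about one step of 10
# ponds separates p < 0.01 from p > 0.05 — so the estimated threshold is
# stable across Monte Carlo reruns.
sensitivity_fixture <- function() {
  basin <- square_basin(s = 1000)
  weirs <- lapply(1:7, function(k)
    linear_feature(sprintf("w%d", k), "weir",
                   rbind(c(0, k * 140 - 70), c(1000, k * 140 - 70))))
  # 30 ponds on weirs, 10 midway between weirs (70 m from the nearest)
  on_weir <- lapply(1:30, function(i)
    pond(sprintf("on%02d", i), c((i * 31) %% 1000,
                                 ((i - 1) %% 7 + 1) * 140 - 70 + (i %% 5)),
         100))
  off <- lapply(1:10, function(i)
    pond(sprintf("off%02d", i), c((i * 97) %% 1000, ((i %% 7) + 1) * 140),
         100))
  landscape(list(basin), weirs, list(), c(on_weir, off))
}
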