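#' @useDynLib fishweirs, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2 || any(!is.finite(p))) {
    stop(what, " must be two finite coordinates (x, y) in metres")
  }
  p
}

as_coord_matrix <- function(xy, what = "coordinates") {
  m <- if (is.matrix(xy)) xy else do.call(rbind, lapply(xy, as_point))
  if (!is.numeric(m) || ncol(m) != 2 || any(!is.finite(m))) {
    stop(what, " must be a 2-column matrix of finite numbers")
  }
  unname(m)
}

#' Distance from a point to a closed segment
#'
#' Euclidean distance in the projected plane from `p` to the segment with
#' endpoints `a` and `b` (endpoints included).
#'
#' @param p,a,b numeric length-2 vectors `(x, y)` in metres.
#' @return distance in metres, `>= 0`.
#' @examples
#' point_segment_distance(c(1, 1), c(0, 0), c(2, 0))  # 1
#' @export
point_segment_distance <- function(p, a, b) {
  p <- as_point(p); a <- as_point(a, "a"); b <- as_point(b, "b")
  if (all(a == b)) stop("degenerate segment: a and b coincide")
  cpp_min_dist_points_segments(p[1], p[2], a[1], a[2], b[1], b[2])
}

# Decompose a vertex matrix into a segment table (one row per edge).
polyline_segments <- function(vertices) {
  v <- as_coord_matrix(vertices, "polyline vertices")
  n <- nrow(v)
  if (n < 2) stop("a polyline needs at least 2 vertices")
  cbind(ax = v[-n, 1], ay = v[-n, 2], bx = v[-1, 1], by = v[-1, 2])
}

# Pool the segment tables of several linear features; attribute each
# segment to its parent feature.
features_segment_table <- function(features) {
  if (length(features) == 0) stop("empty feature set")
  segs <- lapply(features, function(f) polyline_segments(f$vertices))
  ids <- rep(vapply(features, function(f) f$id, character(1)),
             vapply(segs, nrow, integer(1)))
  list(segments = do.call(rbind, segs), feature_id = ids)
}

#' Distance from a point to a polyline feature
#'
#' Minimum over the feature's segments of [point_segment_distance()].
#'
#' @param p numeric length-2 point `(x, y)` in metres.
#' @param feature a `linear_feature` (or any list with a `vertices` matrix).
#' @return distance in metres.
#' @export
point_polyline_distance <- function(p, feature) {
  p <- as_point(p)
  s <- polyline_segments(feature$vertices)
  cpp_min_dist_points_segments(p[1], p[2], s[, 1], s[, 2], s[, 3], s[, 4])
}

#' Signed shoelace area helpers
#'
#' `polygon_area()` returns the absolute (orientation-independent) area of a
#' simple polygon by the shoelace formula; `point_in_polygon()` tests
#' containment by the even-odd rule, with boundary points counting as
#' inside.
#'
#' @param poly a 2-column matrix of polygon vertices in order (an explicitly
#'   repeated closing vertex is tolerated and dropped).
#' @param p a length-2 point, or a 2-column matrix of points.
#' @return `polygon_area()`: area in square metres; `point_in_polygon()`: a
#'   logical vector, one element per point.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygon_area(sq)                 # 1
#' point_in_polygon(c(0.5, 0.5), sq)
#' @export
polygon_area <- function(poly) {
  v <- close_ring(as_coord_matrix(poly, "polygon"))
  n <- nrow(v)
  if (n < 3) stop("polygon needs at least 3 distinct vertices")
  i <- seq_len(n)
  j <- c(2:n, 1)
  abs(sum(v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2])) / 2
}

# Drop an explicit closing vertex if present.
close_ring <- function(v) {
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v
}

#' @rdname polygon_area
#' @export
point_in_polygon <- function(p, poly) {
  v <- close_ring(as_coord_matrix(poly, "polygon"))
  pm <- if (is.matrix(p)) as_coord_matrix(p, "points") else
    matrix(as_point(p), ncol = 2)
  as.logical(cpp_point_in_polygon(pm[, 1], pm[, 2], v[, 1], v[, 2]))
}

# Simple self-intersection check used by sub-basin validation: O(n^2) over
# non-adjacent edge pairs; adequate for digitized basin outlines.
polygon_is_simple <- function(poly) {
  v <- close_ring(as_coord_matrix(poly, "polygon"))
  n <- nrow(v)
  if (n < 3) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1), ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (segments_intersect(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, a, b) {
    cross2(a, b, p) == 0 &&
      min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
  }
  on_seg(p1, q1, q2) || on_seg(p2, q1, q2) ||
    on_seg(q1, p1, p2) || on_seg(q2, p1, p2)
}

#' Uniform random points inside a polygon
#'
#' Rejection sampling from the polygon's bounding box; suitable for the
#' near-convex sub-basin outlines this package works with. Fails loudly if
#' the acceptance rate is pathologically low.
#'
#' @param poly polygon vertex matrix.
#' @param n number of points (`>= 0`).
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @param max_tries cap on total candidate draws.
#' @return an `n` x 2 matrix of points.
#' @export
random_points_in_polygon <- function(poly, n, seed = NULL,
                                     max_tries = 1000 * (n + 10)) {
  stopifnot(n >= 0)
  v <- close_ring(as_coord_matrix(poly, "polygon"))
  if (polygon_area(v) <= 0) stop("polygon has zero area")
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  xr <- range(v[, 1]); yr <- range(v[, 2])
  frac <- polygon_area(v) / ((xr[2] - xr[1]) * (yr[2] - yr[1]))
  with_rng(seed, {
    out <- matrix(NA_real_, nrow = n, ncol = 2)
    got <- 0L; tried <- 0L
    while (got < n) {
      k <- max(64L, ceiling((n - got) / max(frac, 1e-3)))
      if (tried + k > max_tries) stop("rejection sampling exceeded max_tries; ",
                                      "polygon too thin for box rejection")
      cx <- stats::runif(k, xr[1], xr[2])
      cy <- stats::runif(k, yr[1], yr[2])
      tried <- tried + k
      keep <- which(as.logical(cpp_point_in_polygon(cx, cy, v[, 1], v[, 2])))
      if (length(keep) > 0) {
        take <- keep[seq_len(min(length(keep), n - got))]
        out[(got + 1):(got + length(take)), ] <- cbind(cx[take], cy[take])
        got <- got + length(take)
      }
    }
    out
  })
}

#' Uniform random points along a set of polylines
#'
#' Points are uniform by arc length over the union of the features'
#' segments: a segment is chosen with probability proportional to its
#' length, then the offset along it is uniform.
#'
#' @param features a list of `linear_feature` objects.
#' @param n number of points.
#' @param seed optional integer seed.
#' @return an `n` x 2 matrix of points lying on the features.
#' @export
random_points_on_polylines <- function(features, n, seed = NULL) {
  stopifnot(n >= 0)
  st <- features_segment_table(features)
  s <- st$segments
  len <- sqrt((s[, 3] - s[, 1])^2 + (s[, 4] - s[, 2])^2)
  total <- sum(len)
  if (total <= 0) stop("total polyline length is zero")
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  with_rng(seed, {
    j <- sample.int(nrow(s), n, replace = TRUE, prob = len)
    t <- stats::runif(n)
    cbind(s[j, 1] + t * (s[j, 3] - s[j, 1]),
          s[j, 2] + t * (s[j, 4] - s[j, 2]))
  })
}
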