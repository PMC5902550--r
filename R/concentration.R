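# --- polygon splitting ------------------------------------------------------

# Parametric intersection of segment p1->p2 with segment q1->q2.
# Returns c(t, s) in [0,1]^2 or NULL.
segment_intersection_params <- function(p1, p2, q1, q2, eps = 1e-9) {
  d <- p2 - p1; e <- q2 - q1
  denom <- d[1] * e[2] - d[2] * e[1]
  if (abs(denom) < eps * (sum(abs(d)) * sum(abs(e)) + eps)) return(NULL)
  w <- q1 - p1
  t <- (w[1] * e[2] - w[2] * e[1]) / denom
  s <- (w[1] * d[2] - w[2] * d[1]) / denom
  if (t < -eps || t > 1 + eps || s < -eps || s > 1 + eps) return(NULL)
  c(t = min(max(t, 0), 1), s = min(max(s, 0), 1))
}

# Split a simple polygon by a polyline that enters and leaves it exactly
# once (endpoints outside). Returns a list of two vertex matrices whose
# areas sum to the input's.
split_polygon_by_polyline <- function(poly, line) {
  v <- close_ring(as_coord_matrix(poly, "polygon"))
  L <- as_coord_matrix(line, "polyline")
  n <- nrow(v); m <- nrow(L)
  hits <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq_len(n)) {
      q1 <- v[j, ]; q2 <- v[if (j == n) 1 else j + 1, ]
      ts <- segment_intersection_params(L[i, ], L[i + 1, ], q1, q2)
      if (!is.null(ts)) {
        hits[[length(hits) + 1]] <- list(
          tline = (i - 1) + ts[["t"]], edge = j, s = ts[["s"]],
          pt = L[i, ] + ts[["t"]] * (L[i + 1, ] - L[i, ]))
      }
    }
  }
  if (length(hits) < 2) stop("polyline does not span the polygon ",
                             "(needs exactly 2 boundary crossings, got ",
                             length(hits), ")")
  ord <- order(vapply(hits, function(h) h$tline, numeric(1)))
  hits <- hits[ord]
  # collapse near-duplicate crossings (polyline vertex on the boundary)
  keep <- c(TRUE, vapply(seq_along(hits)[-1], function(k) {
    hits[[k]]$tline - hits[[k - 1]]$tline > 1e-9
  }, logical(1)))
  hits <- hits[keep]
  if (length(hits) != 2) stop("polyline does not span the polygon ",
                              "(needs exactly 2 boundary crossings, got ",
                              length(hits), ")")
  hin <- hits[[1]]; hout <- hits[[2]]
  # chain of the polyline interior to the polygon, entry -> exit
  inner_idx <- which(seq_len(m) - 1 > hin$tline & seq_len(m) - 1 < hout$tline)
  chain <- rbind(hin$pt, L[inner_idx, , drop = FALSE], hout$pt)

  # ring walk: from one crossing, forward along the boundary, to the other
  walk <- function(from, to) {
    pts <- list(from$pt)
    if (!(from$edge == to$edge && to$s >= from$s)) {
      j <- from$edge %% n + 1  # first ring vertex after the 'from' crossing
      repeat {
        pts[[length(pts) + 1]] <- v[j, ]
        if (j == to$edge) break
        j <- j %% n + 1
      }
    }
    pts[[length(pts) + 1]] <- to$pt
    do.call(rbind, pts)
  }
  interior <- chain[-c(1, nrow(chain)), , drop = FALSE]
  # piece 1: boundary entry -> exit, then the polyline interior walked back
  p1 <- dedupe_ring(rbind(walk(hin, hout),
                          interior[rev(seq_len(nrow(interior))), ,
                                   drop = FALSE]))
  # piece 2: boundary exit -> entry, then the polyline interior forward
  p2 <- dedupe_ring(rbind(walk(hout, hin), interior))
  list(p1, p2)
}

dedupe_ring <- function(v) {
  if (nrow(v) >= 2) {
    d <- c(TRUE, rowSums((v[-1, , drop = FALSE] -
                          v[-nrow(v), , drop = FALSE])^2) > 1e-18)
    v <- v[d, , drop = FALSE]
    if (nrow(v) >= 2 && all(abs(v[1, ] - v[nrow(v), ]) < 1e-9)) {
      v <- v[-nrow(v), , drop = FALSE]
    }
  }
  v
}

# Circular midpoint of a sub-basin's flow interval.
flow_azimuth_mid <- function(basin) {
  normalize_azimuth(basin$flow_azimuth_min +
                      clockwise_span(basin$flow_azimuth_min,
                                     basin$flow_azimuth_max) / 2)
}

#' Partition a sub-basin into inter-weir areas
#'
#' Splits the sub-basin polygon by each weir polyline in turn (each weir
#' must span the basin, i.e. cross its boundary exactly twice), producing
#' the capture areas between successive weirs. Pieces are ordered from
#' upstream to downstream along the basin's flow direction; each piece
#' except the most downstream is bounded downstream by a weir, which is the
#' weir whose collecting structures drain that piece.
#'
#' @param basin a `sub_basin`.
#' @param weirs list of `linear_feature` objects of kind `"weir"`.
#' @return a list of `interweir_area` objects: `id`, `polygon`, `area_m2`,
#'   `downstream_weir_id` (`NA` for the most downstream piece),
#'   `collecting_pond_ids`, `pondless_v_ids`, `fishway_count` (the last
#'   three filled by [assign_collecting_structures()]).
#' @export
partition_interweir_areas <- function(basin, weirs) {
  stopifnot(inherits(basin, "sub_basin"), length(weirs) >= 1)
  u <- azimuth_to_unit(flow_azimuth_mid(basin))[1, ]
  proj <- function(m) mean(m[, 1] * u[1] + m[, 2] * u[2])
  weirs <- weirs[order(vapply(weirs, function(w) proj(w$vertices), numeric(1)))]

  pieces <- list(basin$boundary)
  for (w in weirs) {
    split_done <- FALSE
    for (k in seq_along(pieces)) {
      res <- tryCatch(split_polygon_by_polyline(pieces[[k]], w$vertices),
                      error = function(e) NULL)
      if (!is.null(res)) {
        pieces <- c(pieces[-k], res)
        split_done <- TRUE
        break
      }
    }
    if (!split_done) stop("weir ", w$id, " does not span the basin")
  }

  pieces <- pieces[order(vapply(pieces, proj, numeric(1)))]
  weir_ids <- vapply(weirs, function(w) w$id, character(1))
  lapply(seq_along(pieces), function(i) {
    structure(list(
      id = sprintf("%s_iw%02d", basin$id, i),
      polygon = pieces[[i]],
      area_m2 = polygon_area(pieces[[i]]),
      downstream_weir_id = if (i <= length(weir_ids)) weir_ids[i] else
        NA_character_,
      collecting_pond_ids = character(0),
      pondless_v_ids = character(0),
      fishway_count = 0L
    ), class = "interweir_area")
  })
}

#' Attach collecting structures to inter-weir areas
#'
#' For each inter-weir area, the collecting structures are (i) the ponds
#' whose centroids lie inside the area (isolated ponds plus the ponds
#' associated with the weir bounding it downstream), (ii) the V-shaped
#' structures of the downstream weir with no pond within `cutoff` metres of
#' their apex ("pondless" Vs), and, for trap-based systems, (iii) the Vs of
#' the downstream weir carrying a fishway gap.
#'
#' @param areas list of `interweir_area` from [partition_interweir_areas()].
#' @param landscape a `landscape`.
#' @param cutoff pond-V association cutoff in metres (default 35).
#' @return the list of areas with collecting sets filled.
#' @export
assign_collecting_structures <- function(areas, landscape, cutoff = 35) {
  pts <- pond_centroids(landscape)
  pond_ids <- vapply(landscape$ponds, function(p) p$id, character(1))
  vs <- landscape$v_structures
  lapply(areas, function(a) {
    if (nrow(pts) > 0) {
      inside <- point_in_polygon(pts, a$polygon)
      a$collecting_pond_ids <- pond_ids[inside]
    }
    if (!is.na(a$downstream_weir_id) && length(vs) > 0) {
      on_weir <- Filter(function(v) identical(v$weir_id, a$downstream_weir_id),
                        vs)
      if (length(on_weir) > 0) {
        pondless <- vapply(on_weir, function(v) {
          if (nrow(pts) == 0) return(TRUE)
          min(cpp_min_dist_points_segments(pts[, 1], pts[, 2], v$apex[1],
                                           v$apex[2], v$apex[1],
                                           v$apex[2])) > cutoff
        }, logical(1))
        a$pondless_v_ids <- vapply(on_weir[pondless], function(v) v$id,
                                   character(1))
        a$fishway_count <- sum(vapply(on_weir, function(v) v$gap_present,
                                      logical(1)))
      }
    }
    a
  })
}

#' Collecting-structure surface of an inter-weir area
#'
#' In pond-based systems the collecting surface is the summed surface area
#' of the area's ponds plus, for each pondless V, the area of the triangle
#' spanned by its apex and two arm endpoints (the minimal geometric surface
#' attributable to a V with no mapped pond). In trap-based systems each
#' fishway is a circular interception area of 1 m diameter, so the surface
#' is `fishway_count * pi * 0.5^2` square metres.
#'
#' @param area an `interweir_area` with collecting sets assigned.
#' @param landscape a `landscape`.
#' @param mode `"ponds"` or `"traps"`.
#' @return surface in square metres.
#' @export
collecting_surface <- function(area, landscape, mode = c("ponds", "traps")) {
  mode <- match.arg(mode)
  if (mode == "traps") {
    if (area$fishway_count == 0) stop("inter-weir area ", area$id,
                                      ": no fishways to collect into")
    return(area$fishway_count * pi * 0.5^2)
  }
  ponds <- Filter(function(p) p$id %in% area$collecting_pond_ids,
                  landscape$ponds)
  vs <- Filter(function(v) v$id %in% area$pondless_v_ids,
               landscape$v_structures)
  if (length(ponds) == 0 && length(vs) == 0) {
    stop("inter-weir area ", area$id, ": empty collecting set")
  }
  pond_area <- sum(vapply(ponds, function(p) p$area, numeric(1)))
  v_area <- sum(vapply(vs, function(v) {
    polygon_area(rbind(v$apex, v$arm_left_end, v$arm_right_end))
  }, numeric(1)))
  pond_area + v_area
}

#' Fish-concentration ratio of an inter-weir area
#'
#' The concentration factor is the capture-area surface (the floodplain
#' between successive weirs, draining toward the downstream weir) divided
#' by the collecting-structure surface. Large ratios mean the system
#' funnels fish from a large area into small collecting structures.
#'
#' @param area an `interweir_area`.
#' @param landscape a `landscape`.
#' @param mode `"ponds"` or `"traps"`.
#' @return an object of class `concentration_result`: `area_capture`,
#'   `area_collecting`, `ratio`.
#' @export
concentration_ratio <- function(area, landscape, mode = c("ponds", "traps")) {
  mode <- match.arg(mode)
  collecting <- collecting_surface(area, landscape, mode)
  if (collecting <= 0) stop("zero collecting surface in area ", area$id)
  structure(list(id = area$id, area_capture = area$area_m2,
                 area_collecting = collecting,
                 ratio = area$area_m2 / collecting, mode = mode),
            class = "concentration_result")
}

#' Batch concentration table with summary statistics
#'
#' @param areas list of `interweir_area` objects with collecting sets
#'   assigned; areas without a downstream weir are skipped.
#' @param landscape a `landscape`.
#' @param mode `"ponds"` or `"traps"`.
#' @return list with `table` (per-area data frame) and `summary`
#'   (`mean`, `sd`, `min`, `max`, `n`).
#' @export
concentration_table <- function(areas, landscape, mode = c("ponds", "traps")) {
  mode <- match.arg(mode)
  usable <- Filter(function(a) !is.na(a$downstream_weir_id), areas)
  if (length(usable) == 0) stop("no inter-weir areas with a downstream weir")
  rows <- lapply(usable, function(a) {
    r <- concentration_ratio(a, landscape, mode)
    data.frame(id = r$id, area_capture = r$area_capture,
               area_collecting = r$area_collecting, ratio = r$ratio,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = list(mean = mean(tab$ratio),
                      sd = if (nrow(tab) > 1) stats::sd(tab$ratio) else NA_real_,
                      min = min(tab$ratio), max = max(tab$ratio),
                      n = nrow(tab)))
}
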