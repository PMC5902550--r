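#' Landscape feature constructors
#'
#' The data model mirrors how floodplain fishery earthworks are digitized
#' from aerial imagery: sub-basin polygons with a putative flood-flow
#' direction interval; linear features (zigzag weirs, rectilinear causeways
#' and canals) as polylines; V-shaped structures as three points (apex plus
#' the two arm endpoints, the arms being straight embankment segments); and
#' ponds as centroids with a surface area and berm attributes. All
#' coordinates are planar metres in a shared projected plane; the package
#' never reprojects.
#'
#' @param id character feature identifier, unique within its class.
#' @param kind for linear features, one of `"weir"`, `"causeway"`, `"canal"`.
#' @param vertices 2-column matrix of polyline vertices (metres, `>= 2` rows,
#'   consecutive vertices distinct).
#' @param apex,arm_left_end,arm_right_end length-2 points defining a V.
#' @param weir_id id of the weir carrying the V, or `NA`.
#' @param gap_present logical: is there a gap (potential fishway) at the apex?
#' @param gap_width gap width in metres when `gap_present`, else `NA`.
#' @param centroid pond centroid, length-2 point in metres.
#' @param area pond surface area in square metres (`>= 0`).
#' @param berm_status one of `"present"`, `"absent"`, `"undetermined"`.
#' @param berm_high_azimuth azimuth (degrees clockwise from north) from pond
#'   centre to the highest berm point; only when a berm is present.
#' @param berm_arc_start,berm_arc_end extreme azimuths of the woody-vegetation
#'   arc marking the berm, running clockwise from start to end; only when a
#'   berm is present.
#' @param depth pond depth in metres, or `NA`.
#' @param boundary sub-basin outline: 2-column matrix forming a simple polygon.
#' @param flow_azimuth_min,flow_azimuth_max the clockwise circular interval of
#'   plausible high-water flow directions for the sub-basin.
#' @return an object of class `linear_feature`, `v_structure`, `pond`, or
#'   `sub_basin` respectively.
#' @name landscape-features
NULL

#' @rdname landscape-features
#' @export
linear_feature <- function(id, kind, vertices) {
  kind <- match.arg(kind, c("weir", "causeway", "canal"))
  v <- as_coord_matrix(vertices, "vertices")
  if (nrow(v) < 2) stop("linear feature ", id, ": needs at least 2 vertices")
  dup <- rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2) == 0
  if (any(dup)) stop("linear feature ", id, ": consecutive vertices coincide")
  structure(list(id = as.character(id), kind = kind, vertices = v),
            class = "linear_feature")
}

feature_length <- function(feature) {
  s <- polyline_segments(feature$vertices)
  sum(sqrt((s[, 3] - s[, 1])^2 + (s[, 4] - s[, 2])^2))
}

#' Orientation of a V-shaped structure from its geometry
#'
#' The orientation of a V is the azimuth from the middle of the wide opening
#' (the midpoint of the two arm endpoints) to the apex — the direction the
#' point of the V faces, which in a fish weir points downstream.
#'
#' @param v a `v_structure`, or any list with `apex`, `arm_left_end`,
#'   `arm_right_end` points.
#' @return azimuth in degrees, `[0, 360)`.
#' @examples
#' recompute_v_orientation(list(apex = c(0, 10), arm_left_end = c(-5, 0),
#'                              arm_right_end = c(5, 0)))  # 0 (due north)
#' @export
recompute_v_orientation <- function(v) {
  mid <- (as_point(v$arm_left_end) + as_point(v$arm_right_end)) / 2
  apex <- as_point(v$apex)
  if (all(apex == mid)) stop("degenerate V: apex coincides with opening midpoint")
  azimuth_from_displacement(apex[1] - mid[1], apex[2] - mid[2])
}

#' @rdname landscape-features
#' @export
v_structure <- function(id, apex, arm_left_end, arm_right_end,
                        weir_id = NA_character_, gap_present = FALSE,
                        gap_width = NA_real_) {
  apex <- as_point(apex, "apex")
  al <- as_point(arm_left_end, "arm_left_end")
  ar <- as_point(arm_right_end, "arm_right_end")
  v <- list(id = as.character(id), weir_id = as.character(weir_id),
            apex = apex, arm_left_end = al, arm_right_end = ar)
  v$orientation <- recompute_v_orientation(v)
  v$median_length <- sqrt(sum((apex - (al + ar) / 2)^2))
  v$opening_width <- sqrt(sum((al - ar)^2))
  if (v$median_length <= 0) stop("V ", id, ": median length must be > 0")
  if (v$opening_width <= 0) stop("V ", id, ": opening width must be > 0")
  v$gap_present <- isTRUE(gap_present)
  if (!v$gap_present && !is.na(gap_width)) {
    stop("V ", id, ": gap_width set but gap_present is FALSE")
  }
  v$gap_width <- as.numeric(gap_width)
  structure(v, class = "v_structure")
}

#' @rdname landscape-features
#' @export
pond <- function(id, centroid, area, berm_status = "undetermined",
                 berm_high_azimuth = NA_real_, berm_arc_start = NA_real_,
                 berm_arc_end = NA_real_, depth = NA_real_) {
  berm_status <- match.arg(berm_status, c("present", "absent", "undetermined"))
  area <- as.numeric(area)
  if (!is.finite(area) || area < 0) stop("pond ", id, ": area must be >= 0")
  if (berm_status != "present" &&
      (!is.na(berm_high_azimuth) || !is.na(berm_arc_start) ||
       !is.na(berm_arc_end))) {
    stop("pond ", id, ": berm attributes set but berm_status is not 'present'")
  }
  structure(list(
    id = as.character(id), centroid = as_point(centroid, "centroid"),
    area = area, berm_status = berm_status,
    berm_high_azimuth = if (is.na(berm_high_azimuth)) NA_real_ else
      normalize_azimuth(berm_high_azimuth),
    berm_arc_start = if (is.na(berm_arc_start)) NA_real_ else
      normalize_azimuth(berm_arc_start),
    berm_arc_end = if (is.na(berm_arc_end)) NA_real_ else
      normalize_azimuth(berm_arc_end),
    depth = as.numeric(depth)
  ), class = "pond")
}

#' @rdname landscape-features
#' @export
sub_basin <- function(id, boundary, flow_azimuth_min, flow_azimuth_max) {
  b <- close_ring(as_coord_matrix(boundary, "boundary"))
  if (polygon_area(b) <= 0) stop("sub-basin ", id, ": polygon area must be > 0")
  if (!polygon_is_simple(b)) stop("sub-basin ", id, ": polygon self-intersects")
  structure(list(
    id = as.character(id), boundary = b,
    flow_azimuth_min = normalize_azimuth(flow_azimuth_min),
    flow_azimuth_max = normalize_azimuth(flow_azimuth_max)
  ), class = "sub_basin")
}

#' Assemble and validate a landscape
#'
#' A `landscape` is the container every analysis stage consumes: sub-basins,
#' linear features, V-structures and ponds sharing one projected plane.
#' Validation checks id uniqueness, that every `weir_id` reference on a V
#' resolves to a weir, and that every stored V orientation is recomputable
#' from its geometry to within 1e-6 degrees.
#'
#' @param sub_basins,linear_features,v_structures,ponds lists of the
#'   corresponding feature objects.
#' @param crs_note free-text note on the projected coordinate reference
#'   system (the package treats coordinates as planar metres throughout).
#' @return an object of class `landscape`.
#' @export
landscape <- function(sub_basins = list(), linear_features = list(),
                      v_structures = list(), ponds = list(),
                      crs_note = "projected metres (unspecified CRS)") {
  ls <- structure(list(
    sub_basins = sub_basins, linear_features = linear_features,
    v_structures = v_structures, ponds = ponds,
    crs_note = as.character(crs_note)
  ), class = "landscape")
  validate_landscape(ls)
  ls
}

#' @rdname landscape
#' @param x a `landscape`.
#' @export
validate_landscape <- function(x) {
  stopifnot(inherits(x, "landscape"))
  check_ids <- function(items, what) {
    ids <- vapply(items, function(f) f$id, character(1))
    if (anyDuplicated(ids)) stop("duplicate ", what, " ids: ",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids
  }
  check_ids(x$sub_basins, "sub-basin")
  feat_ids <- check_ids(x$linear_features, "linear feature")
  check_ids(x$v_structures, "V-structure")
  check_ids(x$ponds, "pond")
  weir_ids <- feat_ids[vapply(x$linear_features,
                              function(f) f$kind == "weir", logical(1))]
  for (v in x$v_structures) {
    if (!is.na(v$weir_id) && !(v$weir_id %in% weir_ids)) {
      stop("V-structure ", v$id, ": weir_id '", v$weir_id,
           "' does not resolve to a weir")
    }
    delta <- abs(v$orientation - recompute_v_orientation(v))
    if (min(delta, 360 - delta) > 1e-6) {
      stop("V-structure ", v$id, ": stored orientation disagrees with geometry")
    }
  }
  invisible(x)
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", length(x$sub_basins), " sub-basin(s), ",
      length(x$linear_features), " linear feature(s), ",
      length(x$v_structures), " V-structure(s), ",
      length(x$ponds), " pond(s)\n", sep = "")
  cat("  CRS: ", x$crs_note, "\n", sep = "")
  invisible(x)
}

# Convenience extractors -----------------------------------------------------

landscape_features_of_kind <- function(x, kinds) {
  Filter(function(f) f$kind %in% kinds, x$linear_features)
}

pond_centroids <- function(x) {
  if (length(x$ponds) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, lapply(x$ponds, function(p) p$centroid))
}

v_apexes <- function(x) {
  if (length(x$v_structures) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, lapply(x$v_structures, function(v) v$apex))
}
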