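#' Write a landscape to GeoJSON and attribute CSV files
#'
#' One GeoJSON FeatureCollection per feature class (`sub_basins.geojson`,
#' `linear_features.geojson`, `v_structures.geojson`, `ponds.geojson`),
#' with all ids and attributes carried in feature properties, plus
#' human-readable attribute CSVs (`ponds.csv`, `v_structures.csv`,
#' `sub_basins.csv`). Numbers are serialized at full precision so that
#' `load_landscape(save_landscape(x))` reproduces coordinates exactly.
#'
#' V-structures are stored as MultiPoint geometries with the apex first,
#' then the left and right arm endpoints.
#'
#' @param x a `landscape`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named character vector of files written.
#' @export
save_landscape <- function(x, out_dir) {
  validate_landscape(x)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }

  fc <- function(features) list(type = "FeatureCollection", features = features)
  feat <- function(geom, props) list(type = "Feature", geometry = geom,
                                     properties = props)
  coords <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))

  basins <- lapply(x$sub_basins, function(b) {
    ring <- rbind(b$boundary, b$boundary[1, ])
    feat(list(type = "Polygon", coordinates = list(coords(ring))),
         list(id = b$id, flow_azimuth_min = b$flow_azimuth_min,
              flow_azimuth_max = b$flow_azimuth_max))
  })
  lines <- lapply(x$linear_features, function(f) {
    feat(list(type = "LineString", coordinates = coords(f$vertices)),
         list(id = f$id, kind = f$kind))
  })
  vs <- lapply(x$v_structures, function(v) {
    feat(list(type = "MultiPoint",
              coordinates = coords(rbind(v$apex, v$arm_left_end,
                                         v$arm_right_end))),
         list(id = v$id, weir_id = v$weir_id, orientation = v$orientation,
              median_length = v$median_length, opening_width = v$opening_width,
              gap_present = v$gap_present, gap_width = v$gap_width))
  })
  ponds <- lapply(x$ponds, function(p) {
    feat(list(type = "Point", coordinates = c(p$centroid[1], p$centroid[2])),
         list(id = p$id, area = p$area, berm_status = p$berm_status,
              berm_high_azimuth = p$berm_high_azimuth,
              berm_arc_start = p$berm_arc_start,
              berm_arc_end = p$berm_arc_end, depth = p$depth))
  })

  write_geojson <- function(obj, path) {
    # 17 significant digits round-trip IEEE doubles exactly
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                             null = "null", na = "null")
    writeLines(json, path)
  }
  paths <- c(
    sub_basins = file.path(out_dir, "sub_basins.geojson"),
    linear_features = file.path(out_dir, "linear_features.geojson"),
    v_structures = file.path(out_dir, "v_structures.geojson"),
    ponds = file.path(out_dir, "ponds.geojson")
  )
  write_geojson(fc(basins), paths[["sub_basins"]])
  write_geojson(fc(lines), paths[["linear_features"]])
  write_geojson(fc(vs), paths[["v_structures"]])
  write_geojson(fc(ponds), paths[["ponds"]])

  # Attribute CSVs: a tabular view for spreadsheet users; geometry and the
  # authoritative attributes live in the GeoJSON properties.
  props_df <- function(features) {
    if (length(features) == 0) return(data.frame())
    rows <- lapply(features, function(f) {
      p <- f$properties
      p[vapply(p, is.null, logical(1))] <- NA
      as.data.frame(p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  csvs <- c(ponds = file.path(out_dir, "ponds.csv"),
            v_structures = file.path(out_dir, "v_structures.csv"),
            sub_basins = file.path(out_dir, "sub_basins.csv"))
  utils::write.csv(props_df(ponds), csvs[["ponds"]], row.names = FALSE)
  utils::write.csv(props_df(vs), csvs[["v_structures"]], row.names = FALSE)
  utils::write.csv(props_df(basins), csvs[["sub_basins"]], row.names = FALSE)

  note_path <- file.path(out_dir, "crs_note.txt")
  writeLines(x$crs_note, note_path)
  invisible(c(paths, csvs, crs_note = note_path))
}

#' Load a landscape from GeoJSON files
#'
#' Reads the four FeatureCollections written by [save_landscape()] (or
#' digitized to the same layout) and rebuilds a validated [landscape()].
#' Because the whole package works in projected metres, loading refuses
#' coordinates whose bounding box looks like longitude/latitude degrees
#' unless `assume_projected = TRUE`.
#'
#' @param dir directory containing `sub_basins.geojson`,
#'   `linear_features.geojson`, `v_structures.geojson`, `ponds.geojson`
#'   (missing files yield empty feature classes), or a named list of
#'   explicit file paths with those names.
#' @param assume_projected set `TRUE` to accept small coordinate values that
#'   would otherwise trip the lon/lat guard.
#' @return a validated `landscape`.
#' @export
load_landscape <- function(dir, assume_projected = FALSE) {
  if (is.character(dir) && length(dir) == 1 && dir.exists(dir)) {
    paths <- list(
      sub_basins = file.path(dir, "sub_basins.geojson"),
      linear_features = file.path(dir, "linear_features.geojson"),
      v_structures = file.path(dir, "v_structures.geojson"),
      ponds = file.path(dir, "ponds.geojson"),
      crs_note = file.path(dir, "crs_note.txt")
    )
  } else if (is.list(dir)) {
    paths <- dir
  } else {
    stop("dir must be an existing directory or a named list of file paths")
  }

  read_fc <- function(path) {
    if (is.null(path) || !file.exists(path)) return(list())
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(obj$type, "FeatureCollection")) {
      stop("not a GeoJSON FeatureCollection: ", path)
    }
    obj$features
  }
  num_or_na <- function(v) if (is.null(v) || is.na(suppressWarnings(as.numeric(v)))) NA_real_ else as.numeric(v)
  chr_or_na <- function(v) if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
  coord_mat <- function(cc) do.call(rbind, lapply(cc, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  need_geom <- function(f, type, path) {
    if (!identical(f$geometry$type, type)) {
      stop("feature '", f$properties$id, "' in ", path, ": expected ", type,
           " geometry, got ", f$geometry$type)
    }
  }

  bp <- paths$sub_basins
  basins <- lapply(read_fc(bp), function(f) {
    need_geom(f, "Polygon", bp)
    sub_basin(f$properties$id, coord_mat(f$geometry$coordinates[[1]]),
              num_or_na(f$properties$flow_azimuth_min),
              num_or_na(f$properties$flow_azimuth_max))
  })
  lp <- paths$linear_features
  lines <- lapply(read_fc(lp), function(f) {
    need_geom(f, "LineString", lp)
    linear_feature(f$properties$id, f$properties$kind,
                   coord_mat(f$geometry$coordinates))
  })
  vp <- paths$v_structures
  vs <- lapply(read_fc(vp), function(f) {
    need_geom(f, "MultiPoint", vp)
    m <- coord_mat(f$geometry$coordinates)
    if (nrow(m) != 3) stop("V-structure '", f$properties$id,
                           "': MultiPoint must hold apex + 2 arm ends")
    v_structure(f$properties$id, apex = m[1, ], arm_left_end = m[2, ],
                arm_right_end = m[3, ],
                weir_id = chr_or_na(f$properties$weir_id),
                gap_present = isTRUE(f$properties$gap_present),
                gap_width = num_or_na(f$properties$gap_width))
  })
  pp <- paths$ponds
  ponds <- lapply(read_fc(pp), function(f) {
    need_geom(f, "Point", pp)
    p <- f$properties
    pond(p$id, c(as.numeric(f$geometry$coordinates[[1]]),
                 as.numeric(f$geometry$coordinates[[2]])),
         area = num_or_na(p$area),
         berm_status = if (is.null(p$berm_status)) "undetermined" else p$berm_status,
         berm_high_azimuth = num_or_na(p$berm_high_azimuth),
         berm_arc_start = num_or_na(p$berm_arc_start),
         berm_arc_end = num_or_na(p$berm_arc_end),
         depth = num_or_na(p$depth))
  })

  crs_note <- if (!is.null(paths$crs_note) && file.exists(paths$crs_note)) {
    paste(readLines(paths$crs_note, warn = FALSE), collapse = "\n")
  } else "projected metres (unspecified CRS)"

  ls <- landscape(basins, lines, vs, ponds, crs_note = crs_note)

  if (!assume_projected) {
    xy <- rbind(pond_centroids(ls), v_apexes(ls),
                do.call(rbind, c(lapply(ls$sub_basins, function(b) b$boundary),
                                 lapply(ls$linear_features, function(f) f$vertices),
                                 list(matrix(numeric(0), ncol = 2)))))
    if (nrow(xy) > 0 && all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90)) {
      stop("coordinate bounding box lies within [-180, 180] x [-90, 90]; ",
           "this looks like longitude/latitude degrees, but the package ",
           "requires projected metres. Reproject the data, or pass ",
           "assume_projected = TRUE if these really are metres.")
    }
  }
  ls
}
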