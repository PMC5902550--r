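#' Configuration for the synthetic landscape generator
#'
#' Defaults describe a desk-scale version of a pond-based floodplain
#' fishery: two rectangular sub-basins sharing one dominant flood-flow
#' azimuth, each crossed by zigzag weirs whose V-shaped structures point
#' downstream, with most ponds placed just upstream of V apexes and pond
#' areas lognormal with mean about 525 m2 and s.d. about 548 m2, the values
#' reported for the mapped Bolivian ponds. V dimensions default to the
#' Bolivian published summaries (median length 30.0 +/- 18.5 m, opening
#' width 38.5 +/- 34.3 m).
#'
#' @param seed integer seed; geometry and attribute draws use separate
#'   substreams derived from it, so changing the pond count never
#'   reshuffles the weirs.
#' @param n_sub_basins number of side-by-side rectangular sub-basins.
#' @param basin_width,basin_height basin extent in metres: width measured
#'   across the flow, height along it.
#' @param flow_azimuth dominant downstream flow direction, degrees
#'   clockwise from north.
#' @param flow_half_range half-width in degrees of each basin's plausible
#'   flow-direction interval.
#' @param n_weirs weirs per sub-basin, laid across the flow.
#' @param v_spacing spacing of successive Vs along a weir, metres.
#' @param v_length_mean,v_length_sd V median length draw (normal truncated
#'   at 0.1 m), metres.
#' @param v_width_mean,v_width_sd V opening width draw (truncated normal,
#'   capped at 90% of `v_spacing`), metres.
#' @param v_orientation_kappa von Mises concentration of V orientations
#'   about the flow azimuth.
#' @param gap_fraction fraction of Vs with a fishway gap at the apex.
#' @param gap_width_mean,gap_width_sd gap width draw, metres.
#' @param n_causeways straight causeways per sub-basin, running along flow.
#' @param n_ponds total ponds across all sub-basins.
#' @param assoc_fraction fraction of ponds placed within `assoc_radius` of
#'   a V apex (on the upstream side); the rest are uniform in the basins.
#' @param assoc_radius association placement radius, metres.
#' @param pond_area_mean,pond_area_sd target moments of the lognormal pond
#'   area law, square metres (log-moments matched analytically).
#' @param berm_present_prob,berm_undetermined_prob berm detectability mix.
#' @param berm_kappa von Mises concentration of berm high-point azimuths
#'   about the flow azimuth.
#' @param berm_arc_mean,berm_arc_sd woody-arc extent draw, degrees
#'   (truncated to (0, 360)).
#' @param pondless_v_fraction fraction of Vs withheld from pond placement.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             n_sub_basins = 2,
                             basin_width = 1500, basin_height = 1200,
                             flow_azimuth = 30, flow_half_range = 15,
                             n_weirs = 3,
                             v_spacing = 60,
                             v_length_mean = 30.0, v_length_sd = 18.5,
                             v_width_mean = 38.5, v_width_sd = 34.3,
                             v_orientation_kappa = 8,
                             gap_fraction = 0.1,
                             gap_width_mean = 1.0, gap_width_sd = 0.3,
                             n_causeways = 1,
                             n_ponds = 382,
                             assoc_fraction = 0.6, assoc_radius = 35,
                             pond_area_mean = 525, pond_area_sd = 548,
                             berm_present_prob = 0.58,
                             berm_undetermined_prob = 0.36,
                             berm_kappa = 8,
                             berm_arc_mean = 60, berm_arc_sd = 30,
                             pondless_v_fraction = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_sub_basins >= 1, cfg$basin_width > 0, cfg$basin_height > 0,
            cfg$n_weirs >= 0, cfg$v_spacing > 0,
            cfg$v_length_mean > 0, cfg$v_width_mean > 0,
            cfg$v_orientation_kappa >= 0,
            cfg$gap_fraction >= 0, cfg$gap_fraction <= 1,
            cfg$n_ponds >= 0,
            cfg$assoc_fraction >= 0, cfg$assoc_fraction <= 1,
            cfg$assoc_radius > 0,
            cfg$pond_area_mean > 0, cfg$pond_area_sd > 0,
            cfg$berm_present_prob >= 0, cfg$berm_undetermined_prob >= 0,
            cfg$berm_present_prob + cfg$berm_undetermined_prob <= 1,
            cfg$berm_kappa >= 0,
            cfg$pondless_v_fraction >= 0, cfg$pondless_v_fraction <= 1)
  if (cfg$v_spacing > cfg$basin_width) {
    stop("infeasible geometry: v_spacing exceeds basin width")
  }
  structure(cfg, class = "generator_config")
}

# normal draw truncated below (redraw), used for physical dimensions
rtruncnorm_pos <- function(n, mean, sd, lower = 0.1, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1
  }
  out[out < lower] <- lower
  out[out > upper] <- upper
  out
}

# lognormal parameters matched to a target mean and sd
lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a synthetic fish-weir landscape with known ground truth
#'
#' Builds a landscape in which every latent quantity the analyses estimate
#' is known: weirs are zigzag polylines crossing each sub-basin
#' perpendicular to the flow, their V apexes displaced downstream with von
#' Mises orientation noise about the flow azimuth; a configurable fraction
#' of ponds is placed just upstream of randomly chosen V apexes within the
#' association radius, the rest uniform in the basins; berm high-point
#' azimuths follow a von Mises law about the flow azimuth, with woody-arc
#' extents truncated normal.
#'
#' @param config a [generator_config()].
#' @return list with `landscape` (a validated [landscape()]) and
#'   `ground_truth` (list: the config, per-basin flow azimuths, a pond
#'   table of latent placement draws, and a V table of latent orientation
#'   noise).
#' @export
generate_landscape <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  u <- azimuth_to_unit(cfg$flow_azimuth)[1, ]        # downstream unit vector
  w <- c(u[2], -u[1])                                 # cross-flow unit vector
  gap_between_basins <- 80

  geometry_seed <- substream_seed(cfg$seed, "geometry")
  attr_seed <- substream_seed(cfg$seed, "attributes")

  basins <- list(); weirs <- list(); causeways <- list(); vs <- list()
  v_basin <- integer(0)

  with_rng(geometry_seed, {
    for (bi in seq_len(cfg$n_sub_basins)) {
      origin <- (bi - 1) * (cfg$basin_width + gap_between_basins) * w
      to_world <- function(s, t) {
        cbind(origin[1] + s * w[1] + t * u[1],
              origin[2] + s * w[2] + t * u[2])
      }
      corners <- to_world(c(0, cfg$basin_width, cfg$basin_width, 0),
                          c(0, 0, cfg$basin_height, cfg$basin_height))
      basins[[bi]] <- sub_basin(
        sprintf("basin%02d", bi), corners,
        cfg$flow_azimuth - cfg$flow_half_range,
        cfg$flow_azimuth + cfg$flow_half_range)

      for (wi in seq_len(cfg$n_weirs)) {
        t0 <- cfg$basin_height * wi / (cfg$n_weirs + 1)
        weir_id <- sprintf("basin%02d_weir%02d", bi, wi)
        n_v <- max(1L, floor(cfg$basin_width / cfg$v_spacing))
        centers <- (seq_len(n_v) - 0.5) * cfg$basin_width / n_v
        wid <- rtruncnorm_pos(n_v, cfg$v_width_mean, cfg$v_width_sd,
                              lower = 0.5,
                              upper = 0.9 * cfg$basin_width / n_v)
        len <- rtruncnorm_pos(n_v, cfg$v_length_mean, cfg$v_length_sd,
                              lower = 0.1)
        noise <- rvonmises_azimuth(n_v, 0, cfg$v_orientation_kappa)
        noise <- ifelse(noise > 180, noise - 360, noise)  # signed deg
        verts <- to_world(0, t0)
        for (k in seq_len(n_v)) {
          sl <- centers[k] - wid[k] / 2
          sr <- centers[k] + wid[k] / 2
          mid <- to_world(centers[k], t0)[1, ]
          apex_dir <- azimuth_to_unit(cfg$flow_azimuth + noise[k])[1, ]
          apex <- mid + len[k] * apex_dir
          left <- to_world(sl, t0)[1, ]
          right <- to_world(sr, t0)[1, ]
          verts <- rbind(verts, left, apex, right)
          vid <- sprintf("%s_v%03d", weir_id, k)
          has_gap <- stats::runif(1) < cfg$gap_fraction
          vs[[length(vs) + 1]] <- v_structure(
            vid, apex = apex, arm_left_end = left, arm_right_end = right,
            weir_id = weir_id, gap_present = has_gap,
            gap_width = if (has_gap)
              rtruncnorm_pos(1, cfg$gap_width_mean, cfg$gap_width_sd,
                             lower = 0.1) else NA_real_)
          v_basin <- c(v_basin, bi)
        }
        verts <- rbind(verts, to_world(cfg$basin_width, t0))
        weirs[[length(weirs) + 1]] <- linear_feature(weir_id, "weir", verts)
      }

      for (ci in seq_len(cfg$n_causeways)) {
        s0 <- stats::runif(1, 0.1, 0.9) * cfg$basin_width
        causeways[[length(causeways) + 1]] <- linear_feature(
          sprintf("basin%02d_cwy%02d", bi, ci), "causeway",
          to_world(c(s0, s0), c(0, cfg$basin_height)))
      }
    }
  })

  # pond placement + attributes --------------------------------------------
  areas_b <- vapply(basins, function(b) polygon_area(b$boundary), numeric(1))
  lp <- lognormal_params(cfg$pond_area_mean, cfg$pond_area_sd)
  n_v_total <- length(vs)
  ponds <- list()
  gt_pond <- NULL

  with_rng(attr_seed, {
    # Vs withheld from pond placement ("pondless" ground truth)
    eligible <- rep(TRUE, n_v_total)
    if (n_v_total > 0 && cfg$pondless_v_fraction > 0) {
      n_off <- floor(cfg$pondless_v_fraction * n_v_total)
      if (n_off > 0) eligible[sample.int(n_v_total, n_off)] <- FALSE
    }
    eligible_idx <- which(eligible)

    n <- cfg$n_ponds
    if (n > 0) {
      assoc <- stats::runif(n) < cfg$assoc_fraction &
        length(eligible_idx) > 0
      which_v <- rep(NA_integer_, n)
      centro <- matrix(NA_real_, n, 2)
      n_free <- sum(!assoc)
      if (n_free > 0) {
        free_pts <- random_points_in_basins(basins, n_free)
        centro[!assoc, ] <- free_pts
      }
      for (i in which(assoc)) {
        vi <- eligible_idx[sample.int(length(eligible_idx), 1)]
        which_v[i] <- vi
        # upstream side of the apex, within the association radius
        r <- stats::runif(1, 2, cfg$assoc_radius * 0.95)
        ang <- cfg$flow_azimuth + 180 + stats::runif(1, -60, 60)
        centro[i, ] <- vs[[vi]]$apex + r * azimuth_to_unit(ang)[1, ]
      }
      area_draw <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
      berm_u <- stats::runif(n)
      berm_status <- ifelse(berm_u < cfg$berm_present_prob, "present",
                     ifelse(berm_u < cfg$berm_present_prob +
                              cfg$berm_undetermined_prob, "undetermined",
                            "absent"))
      high_az <- rvonmises_azimuth(n, cfg$flow_azimuth, cfg$berm_kappa)
      arc_ext <- rtruncnorm_pos(n, cfg$berm_arc_mean, cfg$berm_arc_sd,
                                lower = 1, upper = 359)
      for (i in seq_len(n)) {
        present <- berm_status[i] == "present"
        ponds[[i]] <- pond(
          sprintf("pond%04d", i), centro[i, ], area_draw[i],
          berm_status = berm_status[i],
          berm_high_azimuth = if (present) high_az[i] else NA_real_,
          berm_arc_start = if (present)
            normalize_azimuth(high_az[i] - arc_ext[i] / 2) else NA_real_,
          berm_arc_end = if (present)
            normalize_azimuth(high_az[i] + arc_ext[i] / 2) else NA_real_)
      }
      gt_pond <- data.frame(
        pond_id = sprintf("pond%04d", seq_len(n)),
        associated = assoc,
        v_id = ifelse(is.na(which_v), NA_character_,
                      vapply(vs, function(v) v$id, character(1))[which_v]),
        berm_high_azimuth = ifelse(berm_status == "present", high_az,
                                   NA_real_),
        berm_arc_extent = ifelse(berm_status == "present", arc_ext, NA_real_),
        stringsAsFactors = FALSE)
    }
  })

  ls <- landscape(basins, c(weirs, causeways), vs, ponds,
                  crs_note = "synthetic planar metres")
  gt_v <- if (n_v_total > 0) data.frame(
    v_id = vapply(vs, function(v) v$id, character(1)),
    basin = v_basin,
    orientation = vapply(vs, function(v) v$orientation, numeric(1)),
    stringsAsFactors = FALSE) else NULL
  list(landscape = ls,
       ground_truth = list(config = cfg, flow_azimuth = cfg$flow_azimuth,
                           ponds = gt_pond, v_structures = gt_v))
}

#' Generate fishery-system-specific V samples
#'
#' `generate_bolivia_like()` draws V-structures whose dimensions follow the
#' published summaries for the pre-Columbian Bolivian system (large, wide
#' Vs without fishway gaps, ponds present); `generate_zambia_like()` draws
#' the present-day Zambian analogue (small, narrow Vs, every apex carrying
#' a fishway gap of width about 1.0 +/- 0.3 m, and no ponds). Both return
#' plain landscapes whose Vs sit on simple carrier weirs; they exist to
#' feed the morphometric comparison with samples of known provenance.
#'
#' Length and width are drawn as a correlated bivariate lognormal whose
#' log-moments are matched analytically to the published mean and s.d. of
#' length, width, *and* their ratio: dimensions are positive and strongly
#' size-correlated in real structures, and independent (or truncated
#' normal) draws cannot reproduce the ratio summaries when the width
#' coefficient of variation is large.
#'
#' @param n_v number of V-structures to draw.
#' @param seed integer seed.
#' @return a validated `landscape`.
#' @export
generate_bolivia_like <- function(n_v = 100, seed = 1) {
  generate_system_vs(n_v, seed, length_mean = 30.0, length_sd = 18.5,
                     width_mean = 38.5, width_sd = 34.3,
                     ratio_mean = 0.98, ratio_sd = 0.49,
                     gap = FALSE, label = "bolivia")
}

#' @rdname generate_bolivia_like
#' @export
generate_zambia_like <- function(n_v = 100, seed = 1) {
  generate_system_vs(n_v, seed, length_mean = 5.3, length_sd = 2.4,
                     width_mean = 3.7, width_sd = 1.5,
                     ratio_mean = 1.60, ratio_sd = 0.98,
                     gap = TRUE, label = "zambia")
}

generate_system_vs <- function(n_v, seed, length_mean, length_sd,
                               width_mean, width_sd, ratio_mean, ratio_sd,
                               gap, label) {
  stopifnot(n_v >= 1)
  lpL <- lognormal_params(length_mean, length_sd)
  lpW <- lognormal_params(width_mean, width_sd)
  # correlation of (log L, log W) implied by the ratio's log-variance:
  # var(log L/W) = sL^2 + sW^2 - 2 rho sL sW
  s_ratio2 <- log(1 + (ratio_sd / ratio_mean)^2)
  rho <- (lpL$sdlog^2 + lpW$sdlog^2 - s_ratio2) /
    (2 * lpL$sdlog * lpW$sdlog)
  rho <- min(max(rho, -0.999), 0.999)
  with_rng(substream_seed(seed, paste0("system_", label)), {
    z1 <- stats::rnorm(n_v); z2 <- stats::rnorm(n_v)
    len <- exp(lpL$meanlog + lpL$sdlog * z1)
    wid <- exp(lpW$meanlog + lpW$sdlog *
                 (rho * z1 + sqrt(1 - rho^2) * z2))
    gapw <- if (gap) rtruncnorm_pos(n_v, 1.0, 0.3, lower = 0.1) else
      rep(NA_real_, n_v)
    spacing <- max(wid) * 1.5 + 10
    weir_id <- paste0(label, "_weir01")
    verts <- matrix(c(-spacing / 2, 0), ncol = 2)
    vs <- vector("list", n_v)
    for (k in seq_len(n_v)) {
      x0 <- (k - 1) * spacing
      left <- c(x0 - wid[k] / 2, 0)
      right <- c(x0 + wid[k] / 2, 0)
      apex <- c(x0, len[k])
      verts <- rbind(verts, left, apex, right)
      vs[[k]] <- v_structure(sprintf("%s_v%03d", label, k), apex = apex,
                             arm_left_end = left, arm_right_end = right,
                             weir_id = weir_id, gap_present = gap,
                             gap_width = gapw[k])
    }
    verts <- rbind(verts, c((n_v - 0.5) * spacing, 0))
    landscape(linear_features = list(linear_feature(weir_id, "weir", verts)),
              v_structures = vs,
              crs_note = paste0("synthetic planar metres (", label,
                                "-style V sample)"))
  })
}
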