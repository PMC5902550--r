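#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the analysis stages end-to-end: `simulate` (or load an
#' existing landscape), `associate`, `sensitivity`, `orient`, `morpho`,
#' `concentrate`, and `report`. The configuration is a YAML (plain
#' key-value) file or an equivalent named list with top-level keys:
#'
#' * `seed`: integer; fanned out to per-stage substreams via
#'   [substream_seed()] so stages can be re-run in isolation.
#' * `stages`: character vector of stages to run, executed in canonical
#'   order; `report` is always implied.
#' * `landscape_dir`: directory of GeoJSON files to load (alternative to
#'   `simulate`).
#' * `generator`: named list of [generator_config()] overrides.
#' * `association`: optional `cutoff`, `n_sims`.
#' * `sensitivity`: optional `alpha`, `step`, `sims_per_step`, `max_extra`.
#'
#' All numerical results are aggregated into `results.json` in `out_dir`
#' (deterministic for a fixed config and seed); the run manifest, including
#' wall-clock stamps and per-stage output paths, goes to `manifest.json`.
#'
#' @param config path to a YAML config file, or a named list.
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = "fishweirs_run") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  all_stages <- c("simulate", "associate", "sensitivity", "orient", "morpho",
                  "concentrate")
  stages <- if (is.null(cfg$stages)) all_stages else
    intersect(all_stages, cfg$stages)
  if (length(setdiff(cfg$stages, c(all_stages, "report"))) > 0) {
    stop("unknown stage(s): ",
         paste(setdiff(cfg$stages, c(all_stages, "report")), collapse = ", "))
  }
  assoc_cfg <- cfg$association
  cutoff <- if (is.null(assoc_cfg$cutoff)) 35 else as.numeric(assoc_cfg$cutoff)
  if (!is.finite(cutoff) || cutoff <= 0) {
    stop("config error: association cutoff must be a positive number")
  }
  n_sims <- if (is.null(assoc_cfg$n_sims)) 10000 else
    as.integer(assoc_cfg$n_sims)
  if (n_sims < 1) stop("config error: n_sims must be >= 1")

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t_start <- Sys.time()
  outputs <- character(0)
  results <- list(seed = seed, stages = stages)
  log_stage <- function(name, ...) {
    message(sprintf("[fishweirs] stage=%s %s", name,
                    paste(sprintf("%s=%s", names(list(...)), list(...)),
                          collapse = " ")))
  }

  # landscape: simulate or load ---------------------------------------------
  gt <- NULL
  if ("simulate" %in% stages) {
    gen_args <- cfg$generator
    gen_args$seed <- substream_seed(seed, "simulate")
    gcfg <- do.call(generator_config, gen_args)
    sim <- generate_landscape(gcfg)
    ls <- sim$landscape
    gt <- sim$ground_truth
    sim_dir <- file.path(out_dir, "landscape")
    outputs <- c(outputs, save_landscape(ls, sim_dir))
    if (!is.null(gt$ponds)) {
      gt_path <- file.path(out_dir, "ground_truth_ponds.csv")
      utils::write.csv(gt$ponds, gt_path, row.names = FALSE)
      outputs <- c(outputs, gt_path)
    }
    log_stage("simulate", ponds = length(ls$ponds),
              features = length(ls$linear_features),
              vs = length(ls$v_structures))
  } else if (!is.null(cfg$landscape_dir)) {
    ls <- load_landscape(cfg$landscape_dir)
    log_stage("load", ponds = length(ls$ponds),
              features = length(ls$linear_features))
  } else {
    stop("config error: either include the 'simulate' stage or give ",
         "'landscape_dir'")
  }

  if ("associate" %in% stages) {
    res_f <- mc_association_test(ls, "features", cutoff = cutoff,
                                 n_sims = n_sims,
                                 seed = substream_seed(seed, "associate"))
    res_v <- tryCatch(
      mc_association_test(ls, "v_structures", cutoff = cutoff,
                          n_sims = n_sims,
                          seed = substream_seed(seed, "associate_v")),
      error = function(e) NULL)
    nd <- nearest_feature_distances(ls)
    nd_path <- file.path(out_dir, "nearest_distances.csv")
    utils::write.csv(nd, nd_path, row.names = FALSE)
    outputs <- c(outputs, nd_path)
    strip <- function(r) r[setdiff(names(r), "null_counts")]
    results$association <- list(
      features = strip(unclass(res_f)),
      v_structures = if (is.null(res_v)) NULL else strip(unclass(res_v)))
    nc_path <- file.path(out_dir, "null_counts_features.csv")
    utils::write.csv(data.frame(count = res_f$null_counts), nc_path,
                     row.names = FALSE)
    outputs <- c(outputs, nc_path)
    log_stage("associate", observed = res_f$observed_within,
              n = res_f$n_ponds, sims = n_sims)
  }

  if ("sensitivity" %in% stages) {
    sens_cfg <- cfg$sensitivity
    sens <- undetected_pond_sensitivity(
      ls, cutoff = cutoff,
      alpha = if (is.null(sens_cfg$alpha)) 0.05 else sens_cfg$alpha,
      step = if (is.null(sens_cfg$step)) 10 else sens_cfg$step,
      sims_per_step = if (is.null(sens_cfg$sims_per_step)) 100 else
        sens_cfg$sims_per_step,
      max_extra = if (is.null(sens_cfg$max_extra)) 2000 else
        sens_cfg$max_extra,
      seed = substream_seed(seed, "sensitivity"))
    tr_path <- file.path(out_dir, "sensitivity_trace.csv")
    utils::write.csv(sens$trace, tr_path, row.names = FALSE)
    outputs <- c(outputs, tr_path)
    results$sensitivity <- unclass(sens)
    results$sensitivity$trace <- NULL
    log_stage("sensitivity", threshold = sens$threshold_extra_ponds)
  }

  if ("orient" %in% stages) {
    v_or <- vapply(ls$v_structures, function(v) v$orientation, numeric(1))
    berm_az <- Filter(Negate(is.na),
                      vapply(ls$ponds, function(p) p$berm_high_azimuth,
                             numeric(1)))
    orient <- list()
    if (length(v_or) >= 5) {
      k <- kuiper_uniformity(v_or)
      orient$v_orientation_kuiper <- unclass(k)
      orient$v_orientation_mean <- circular_mean(v_or)
    }
    if (length(berm_az) >= 5) {
      orient$berm_azimuth_kuiper <- unclass(kuiper_uniformity(berm_az))
      orient$berm_azimuth_mean <- circular_mean(berm_az)
    }
    if (length(v_or) >= 5 && length(berm_az) >= 5) {
      orient$v_vs_berm_watson_williams <- unclass(watson_williams(v_or,
                                                                  berm_az))
    }
    arcs <- do.call(rbind, lapply(ls$ponds, function(p) {
      if (p$berm_status == "present" && !is.na(p$berm_arc_start)) {
        data.frame(start = p$berm_arc_start, end = p$berm_arc_end)
      } else NULL
    }))
    if (!is.null(arcs) && nrow(arcs) > 0) {
      occ <- cumulate_arcs(arcs)
      occ_path <- file.path(out_dir, "berm_arc_occupancy.csv")
      utils::write.csv(occ, occ_path, row.names = FALSE)
      outputs <- c(outputs, occ_path)
      orient$berm_arc_total_extent <- sum(arc_extent(arcs$start, arcs$end))
    }
    results$orientation <- orient
    log_stage("orient", n_v = length(v_or), n_berm = length(berm_az))
  }

  if ("morpho" %in% stages) {
    vd <- v_dimension_table(ls)
    vd_path <- file.path(out_dir, "v_dimensions.csv")
    utils::write.csv(vd, vd_path, row.names = FALSE)
    outputs <- c(outputs, vd_path)
    results$morphometry <- list(
      published_comparison = compare_published_v_dimensions(),
      landscape_summary = if (nrow(vd) > 0) list(
        n = nrow(vd), length_mean = mean(vd$median_length),
        length_sd = stats::sd(vd$median_length),
        width_mean = mean(vd$opening_width),
        width_sd = stats::sd(vd$opening_width)) else NULL)
    log_stage("morpho", n_v = nrow(vd))
  }

  if ("concentrate" %in% stages) {
    conc <- list()
    for (b in ls$sub_basins) {
      weirs_b <- Filter(function(f) f$kind == "weir" &&
                          startsWith(f$id, b$id), ls$linear_features)
      if (length(weirs_b) == 0) next
      areas <- partition_interweir_areas(b, weirs_b)
      areas <- assign_collecting_structures(areas, ls, cutoff = cutoff)
      tab <- tryCatch(concentration_table(areas, ls, "ponds"),
                      error = function(e) NULL)
      if (!is.null(tab)) {
        conc[[b$id]] <- tab$summary
        cpath <- file.path(out_dir, paste0("concentration_", b$id, ".csv"))
        utils::write.csv(tab$table, cpath, row.names = FALSE)
        outputs <- c(outputs, cpath)
      }
    }
    results$concentration <- conc
    log_stage("concentrate", basins = length(conc))
  }

  res_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(results, res_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  outputs <- c(outputs, res_path)

  manifest <- list(
    config = cfg, seed = seed, stages = stages,
    outputs = unname(outputs),
    package_version = as.character(utils::packageVersion("fishweirs")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  missing <- manifest$outputs[!file.exists(manifest$outputs)]
  if (length(missing) > 0) stop("manifest lists missing outputs: ",
                                paste(missing, collapse = ", "))
  invisible(manifest)
}
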