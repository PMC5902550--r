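test_that("the generator is deterministic and streams are independent", {
  a <- generate_landscape(generator_config(seed = 42, n_ponds = 25))
  b <- generate_landscape(generator_config(seed = 42, n_ponds = 25))
  expect_identical(a$landscape, b$landscape)
  expect_identical(a$ground_truth$ponds, b$ground_truth$ponds)
  # changing the pond count must not reshuffle the geometry stream
  c3 <- generate_landscape(generator_config(seed = 42, n_ponds = 60))
  expect_identical(a$landscape$linear_features, c3$landscape$linear_features)
  expect_identical(a$landscape$sub_basins, c3$landscape$sub_basins)
  # a different seed changes the geometry
  d4 <- generate_landscape(generator_config(seed = 43, n_ponds = 25))
  expect_false(identical(a$landscape$linear_features,
                         d4$landscape$linear_features))
})

test_that("generated landscapes validate and honour the config counts", {
  cfg <- generator_config(seed = 2, n_sub_basins = 2, n_weirs = 3,
                          n_ponds = 80, n_causeways = 1)
  sim <- generate_landscape(cfg)
  ls <- sim$landscape
  expect_silent(validate_landscape(ls))
  expect_length(ls$sub_basins, 2)
  kinds <- vapply(ls$linear_features, function(f) f$kind, character(1))
  expect_equal(sum(kinds == "weir"), 6)
  expect_equal(sum(kinds == "causeway"), 2)
  expect_length(ls$ponds, 80)
  expect_error(generator_config(v_spacing = 5000, basin_width = 1000),
               "infeasible")
})

test_that("V orientations concentrate about the flow azimuth", {
  cfg <- generator_config(seed = 6, v_orientation_kappa = 50, n_ponds = 0,
                          n_weirs = 4, v_spacing = 30)
  sim <- generate_landscape(cfg)
  ors <- vapply(sim$landscape$v_structures, function(v) v$orientation,
                numeric(1))
  expect_gte(length(ors), 200)
  dev_rad <- pmin(abs(ors - 30), 360 - abs(ors - 30)) * pi / 180
  # 99% von Mises envelope at kappa = 50
  expect_true(all(dev_rad <= 4 / sqrt(50)))
  cm <- circular_mean(ors)
  expect_lt(min(abs(cm$mean - 30), 360 - abs(cm$mean - 30)), 3)
})

test_that("a null generator produces near-geometric association rates", {
  # assoc_fraction = 0: the within-cutoff fraction of ponds should match
  # the buffered-feature share of the basin area
  cfg <- generator_config(seed = 9, n_sub_basins = 1, basin_width = 1200,
                          basin_height = 1000, n_weirs = 2, n_ponds = 10000,
                          assoc_fraction = 0, n_causeways = 0)
  sim <- generate_landscape(cfg)
  nd <- nearest_feature_distances(sim$landscape)
  frac_obs <- mean(nd$distance_m <= 35)
  # geometric expectation by dense quadrature over the basin
  basin <- sim$landscape$sub_basins[[1]]
  grid <- as.matrix(expand.grid(
    x = seq(min(basin$boundary[, 1]) + 1, max(basin$boundary[, 1]) - 1,
            length.out = 180),
    y = seq(min(basin$boundary[, 2]) + 1, max(basin$boundary[, 2]) - 1,
            length.out = 180)))
  inside <- point_in_polygon(grid, basin$boundary)
  gd <- vapply(which(inside), function(i) {
    min(vapply(sim$landscape$linear_features, function(f)
      point_polyline_distance(grid[i, ], f), numeric(1)))
  }, numeric(1))
  frac_geom <- mean(gd <= 35)
  se <- sqrt(frac_geom * (1 - frac_geom) / 10000)
  expect_lt(abs(frac_obs - frac_geom), 3 * se + 0.01)
})

test_that("pond areas match the target lognormal moments", {
  cfg <- generator_config(seed = 10, n_ponds = 20000)
  sim <- generate_landscape(cfg)
  areas <- vapply(sim$landscape$ponds, function(p) p$area, numeric(1))
  expect_equal(mean(areas), 525, tolerance = 0.05 * 525)
  expect_equal(sd(areas), 548, tolerance = 0.15 * 548)
  expect_true(all(areas > 0))
})

test_that("system-specific generators match their published summaries", {
  bol <- generate_bolivia_like(n_v = 1000, seed = 5)
  dims_b <- v_dimension_table(bol)
  # sample mean within 2 s.e. of the published mean (truncation bias is
  # absorbed by the tolerance for the wide width distribution)
  expect_lt(abs(mean(dims_b$median_length) - 30.0), 2 * 18.5 / sqrt(1000) + 1)
  expect_false(any(dims_b$gap_present))
  zam <- generate_zambia_like(n_v = 1000, seed = 5)
  dims_z <- v_dimension_table(zam)
  expect_lt(abs(mean(dims_z$median_length) - 5.3), 2 * 2.4 / sqrt(1000) + 0.1)
  expect_lt(abs(mean(dims_z$opening_width) - 3.7), 2 * 1.5 / sqrt(1000) + 0.1)
  expect_true(all(dims_z$gap_present))
  gw <- dims_z$gap_width
  expect_lt(abs(mean(gw) - 1.0), 0.1)
  # Zambian Vs are relatively narrower: larger length/width ratio
  expect_gt(mean(dims_z$ratio), mean(dims_b$ratio))
})

test_that("planted associations are detectable end to end", {
  sim <- generate_landscape(generator_config(
    seed = 15, n_sub_basins = 1, basin_width = 1000, basin_height = 900,
    n_weirs = 2, n_ponds = 120, assoc_fraction = 1, assoc_radius = 35))
  r <- mc_association_test(sim$landscape, "features", n_sims = 1000,
                           seed = 16)
  expect_equal(r$p_value, 1 / 1000)
  expect_match(r$p_label, "^<")
})

test_that("berm azimuth recovery: circular mean finds the flow azimuth", {
  cfg <- generator_config(seed = 20, n_ponds = 400, berm_kappa = 8,
                          flow_azimuth = 30)
  sim <- generate_landscape(cfg)
  berms <- Filter(Negate(is.na),
                  vapply(sim$landscape$ponds, function(p) p$berm_high_azimuth,
                         numeric(1)))
  expect_gte(length(berms), 200)
  cm <- circular_mean(berms[seq_len(200)])
  expect_lt(min(abs(cm$mean - 30), 360 - abs(cm$mean - 30)), 5)
})
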