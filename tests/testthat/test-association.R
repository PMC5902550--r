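test_that("nearest-feature distances match hand calculations", {
  ls <- graph_paper_landscape()
  nd <- nearest_feature_distances(ls)
  expect_equal(nrow(nd), 3)
  expect_equal(nd$distance_m[nd$pond_id == "p1"], 30)
  expect_equal(nd$kind[nd$pond_id == "p1"], "weir")
  expect_equal(nd$distance_m[nd$pond_id == "p2"], 5)
  expect_equal(nd$kind[nd$pond_id == "p2"], "causeway")
  expect_equal(nd$distance_m[nd$pond_id == "p3"], 0)
})

test_that("nearest-feature distances agree with brute force over features", {
  sim <- generate_landscape(generator_config(seed = 17, n_ponds = 30))
  ls <- sim$landscape
  nd <- nearest_feature_distances(ls)
  for (i in seq_along(ls$ponds)) {
    manual <- min(vapply(ls$linear_features, function(f)
      point_polyline_distance(ls$ponds[[i]]$centroid, f), numeric(1)))
    expect_equal(nd$distance_m[i], manual, tolerance = 1e-12)
  }
})

test_that("exact weir/causeway ties are attributed to the weir", {
  basin <- square_basin()
  weir <- linear_feature("w1", "weir", rbind(c(0, 490), c(1000, 490)))
  cwy <- linear_feature("c1", "causeway", rbind(c(0, 510), c(1000, 510)))
  ls <- landscape(list(basin), list(weir, cwy), list(),
                  list(pond("p1", c(500, 500), 10)))
  nd <- nearest_feature_distances(ls)
  expect_equal(nd$kind, "weir")
  expect_equal(nd$distance_m, 10)
})

test_that("distance histogram bins left-closed from zero and conserves n", {
  expect_equal(nrow(distance_histogram(numeric(0), 35)), 0)
  h <- distance_histogram(c(1, 36), 35)
  expect_equal(h$count, c(1L, 1L))
  expect_equal(h$bin_start, c(0, 35))
  set.seed(5)
  d <- runif(500, 0, 300)
  h2 <- distance_histogram(d, 10)
  expect_equal(sum(h2$count), 500)
  # boundary value falls in the right-hand bin (left-closed convention)
  h3 <- distance_histogram(c(35), 35)
  expect_equal(h3$count, c(0L, 1L))
})

test_that("a cutoff beyond the basin diameter saturates the test at p = 1", {
  ls <- graph_paper_landscape()
  r <- mc_association_test(ls, "features", cutoff = 5000, n_sims = 50,
                           seed = 1)
  expect_equal(r$observed_within, r$n_ponds)
  expect_true(all(r$null_counts == r$n_ponds))
  expect_equal(r$p_value, 1)
})

test_that("ponds planted on weirs give p below 1/n_sims", {
  sim <- generate_landscape(generator_config(
    seed = 4, n_sub_basins = 1, basin_width = 800, basin_height = 800,
    n_weirs = 2, n_ponds = 60, assoc_fraction = 1, n_causeways = 0))
  r <- mc_association_test(sim$landscape, "features", n_sims = 1000,
                           seed = 99)
  expect_equal(sum(r$null_counts >= r$observed_within), 0)
  expect_equal(r$p_value, 1 / 1000)  # reported as an upper bound
  expect_match(r$p_label, "^<")
  expect_equal(r$p_add_one, 1 / 1001)
})

test_that("null counts respect the AssociationResult invariants", {
  sim <- generate_landscape(generator_config(seed = 12, n_ponds = 50))
  r <- mc_association_test(sim$landscape, "features", n_sims = 300, seed = 5)
  expect_true(all(r$null_counts >= 0 & r$null_counts <= r$n_ponds))
  expect_true(r$observed_within >= 0 && r$observed_within <= r$n_ponds)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_length(r$null_counts, 300)
})

test_that("the V-structure test restricts to weir-associated ponds", {
  sim <- generate_landscape(generator_config(seed = 23, n_ponds = 120))
  nd <- nearest_feature_distances(sim$landscape)
  n_weir_assoc <- sum(nd$kind == "weir" & nd$distance_m <= 35)
  r <- mc_association_test(sim$landscape, "v_structures", n_sims = 100,
                           seed = 3)
  expect_equal(r$n_ponds, n_weir_assoc)
})

test_that("adding features can only decrease nearest distances", {
  sim <- generate_landscape(generator_config(seed = 31, n_ponds = 40,
                                             n_causeways = 0))
  ls <- sim$landscape
  d_weirs_only <- nearest_feature_distances(ls, kinds = "weir")$distance_m
  extra <- linear_feature("extra", "canal", rbind(c(-100, -100), c(900, 900)))
  ls2 <- ls
  ls2$linear_features <- c(ls$linear_features, list(extra))
  d_all <- nearest_feature_distances(ls2)$distance_m
  expect_true(all(d_all <= d_weirs_only + 1e-12))
})

test_that("sensitivity threshold is zero when the association is already weak", {
  # ponds deliberately placed far from the only weir
  basin <- square_basin()
  weir <- linear_feature("w1", "weir", rbind(c(0, 950), c(1000, 950)))
  ponds <- lapply(1:30, function(i)
    pond(sprintf("p%02d", i), c((i * 31) %% 1000, (i * 17) %% 500), 10))
  ls <- landscape(list(basin), list(weir), list(), ponds)
  s <- undetected_pond_sensitivity(ls, sims_per_step = 200, seed = 6)
  expect_true(s$threshold_reached)
  expect_equal(s$threshold_extra_ponds, 0)
  expect_equal(nrow(s$trace), 1)
})

test_that("sensitivity trace increases by the step size and stops at alpha", {
  ls <- sensitivity_fixture()
  s <- undetected_pond_sensitivity(ls, step = 20, sims_per_step = 150,
                                   seed = 44)
  expect_true(all(diff(s$trace$n_total) == 20))
  if (s$threshold_reached) {
    expect_true(all(s$trace$p_hat[-nrow(s$trace)] <= 0.05))
    expect_gt(s$trace$p_hat[nrow(s$trace)], 0.05)
  }
})
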