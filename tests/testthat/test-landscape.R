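test_that("constructors enforce feature invariants", {
  expect_error(linear_feature("w", "weir", rbind(c(0, 0))), "at least 2")
  expect_error(linear_feature("w", "weir", rbind(c(0, 0), c(0, 0))),
               "coincide")
  expect_error(linear_feature("w", "road", rbind(c(0, 0), c(1, 1))))
  expect_error(pond("p", c(0, 0), -5), "area")
  expect_error(pond("p", c(0, 0), 10, berm_status = "absent",
                    berm_high_azimuth = 45), "berm")
  expect_error(v_structure("v", apex = c(0, 0), arm_left_end = c(-1, 0),
                           arm_right_end = c(1, 0)), "degenerate")
  expect_error(v_structure("v", apex = c(0, 5), arm_left_end = c(-1, 0),
                           arm_right_end = c(1, 0), gap_width = 1),
               "gap_present")
  # self-intersecting bow-tie polygon rejected
  expect_error(sub_basin("b", rbind(c(0, 0), c(4, 0), c(1, 2), c(3, 2)),
                         0, 10), "self-intersects")
})

test_that("V orientation follows the opening-midpoint-to-apex azimuth", {
  expect_equal(recompute_v_orientation(list(apex = c(0, 10),
                                            arm_left_end = c(-5, 0),
                                            arm_right_end = c(5, 0))), 0)
  expect_equal(recompute_v_orientation(list(apex = c(10, 0),
                                            arm_left_end = c(0, -5),
                                            arm_right_end = c(0, 5))), 90)
  # random Vs vs an independent atan2 oracle
  set.seed(21)
  for (i in 1:25) {
    al <- runif(2, -100, 100); ar <- runif(2, -100, 100)
    apex <- runif(2, -100, 100)
    mid <- (al + ar) / 2
    if (all(apex == mid)) next
    oracle <- (atan2(apex[1] - mid[1], apex[2] - mid[2]) * 180 / pi) %% 360
    v <- list(apex = apex, arm_left_end = al, arm_right_end = ar)
    expect_equal(recompute_v_orientation(v), oracle, tolerance = 1e-9)
  }
})

test_that("landscape validation catches dangling ids and stale orientations", {
  w <- linear_feature("w1", "weir", rbind(c(0, 0), c(100, 0)))
  v_ok <- v_structure("v1", apex = c(50, 20), arm_left_end = c(40, 0),
                      arm_right_end = c(60, 0), weir_id = "w1")
  expect_silent(landscape(linear_features = list(w),
                          v_structures = list(v_ok)))
  expect_error(landscape(linear_features = list(w), v_structures = list(
    v_structure("v1", apex = c(50, 20), arm_left_end = c(40, 0),
                arm_right_end = c(60, 0), weir_id = "nope"))),
    "does not resolve")
  # a causeway is not a valid weir reference
  cw <- linear_feature("c1", "causeway", rbind(c(0, 0), c(100, 0)))
  expect_error(landscape(linear_features = list(cw), v_structures = list(
    v_structure("v1", apex = c(50, 20), arm_left_end = c(40, 0),
                arm_right_end = c(60, 0), weir_id = "c1"))),
    "does not resolve")
  v_bad <- v_ok
  v_bad$orientation <- v_ok$orientation + 1
  expect_error(landscape(linear_features = list(w),
                         v_structures = list(v_bad)), "disagrees")
  expect_error(landscape(ponds = list(pond("p", c(0, 0), 1),
                                      pond("p", c(1, 1), 1))), "duplicate")
})

test_that("every generated V satisfies the stored-orientation invariant", {
  sim <- generate_landscape(generator_config(seed = 3, n_ponds = 10))
  for (v in sim$landscape$v_structures) {
    delta <- abs(v$orientation - recompute_v_orientation(v))
    expect_lt(min(delta, 360 - delta), 1e-6)
  }
})

test_that("save/load round-trips a landscape exactly", {
  ls1 <- minimal_landscape()
  d <- withr::local_tempdir()
  save_landscape(ls1, d)
  ls2 <- load_landscape(d)
  expect_equal(length(ls2$sub_basins), 1)
  expect_equal(length(ls2$linear_features), 1)
  expect_equal(length(ls2$v_structures), 0)
  expect_equal(length(ls2$ponds), 1)
  expect_identical(ls1$ponds[[1]], ls2$ponds[[1]])
  expect_identical(unname(ls1$linear_features[[1]]$vertices),
                   unname(ls2$linear_features[[1]]$vertices))

  # a generated landscape round-trips bit-for-bit on all coordinates
  sim <- generate_landscape(generator_config(seed = 8, n_ponds = 40))
  d2 <- withr::local_tempdir()
  save_landscape(sim$landscape, d2)
  back <- load_landscape(d2)
  expect_identical(lapply(sim$landscape$ponds, `[[`, "centroid"),
                   lapply(back$ponds, `[[`, "centroid"))
  expect_identical(lapply(sim$landscape$ponds, `[[`, "area"),
                   lapply(back$ponds, `[[`, "area"))
  expect_identical(lapply(sim$landscape$v_structures, `[[`, "apex"),
                   lapply(back$v_structures, `[[`, "apex"))
  expect_identical(
    lapply(sim$landscape$linear_features, function(f) unname(f$vertices)),
    lapply(back$linear_features, function(f) unname(f$vertices)))
  expect_identical(
    lapply(sim$landscape$sub_basins, function(b) unname(b$boundary)),
    lapply(back$sub_basins, function(b) unname(b$boundary)))
})

test_that("an empty landscape saves to valid empty collections", {
  d <- withr::local_tempdir()
  save_landscape(landscape(), d)
  back <- load_landscape(d, assume_projected = TRUE)
  expect_equal(length(back$ponds), 0)
  expect_equal(length(back$sub_basins), 0)
})

test_that("loading refuses coordinates that look like lon/lat", {
  small <- landscape(ponds = list(pond("p1", c(-65.2, -13.5), 10)))
  d <- withr::local_tempdir()
  save_landscape(small, d)
  expect_error(load_landscape(d), "longitude/latitude")
  expect_silent(load_landscape(d, assume_projected = TRUE))
})

test_that("saving to an uncreatable path errors", {
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)
  expect_error(save_landscape(minimal_landscape(),
                              file.path(blocker, "out")),
               "cannot create")
})
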