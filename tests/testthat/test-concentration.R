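test_that("a straight weir splits a square basin into equal halves", {
  basin <- square_basin(s = 1000)
  weir <- linear_feature("w1", "weir", rbind(c(-50, 500), c(1050, 500)))
  areas <- partition_interweir_areas(basin, list(weir))
  expect_length(areas, 2)
  got <- sort(vapply(areas, function(a) a$area_m2, numeric(1)))
  expect_equal(got, c(500000, 500000))
  expect_equal(sum(got), polygon_area(basin$boundary))
  # the upstream piece is bounded downstream by the weir
  expect_equal(areas[[1]]$downstream_weir_id, "w1")
  expect_true(is.na(areas[[2]]$downstream_weir_id))
})

test_that("zigzag weirs partition the basin with exact area conservation", {
  sim <- generate_landscape(generator_config(seed = 19, n_ponds = 0))
  ls <- sim$landscape
  for (b in ls$sub_basins) {
    weirs <- Filter(function(f) f$kind == "weir" && startsWith(f$id, b$id),
                    ls$linear_features)
    areas <- partition_interweir_areas(b, weirs)
    expect_length(areas, length(weirs) + 1)
    total <- sum(vapply(areas, function(a) a$area_m2, numeric(1)))
    basin_area <- polygon_area(b$boundary)
    expect_equal(total, basin_area, tolerance = 1e-6 * basin_area)
  }
})

test_that("a hand-built zigzag split matches manually digitized pieces", {
  basin <- square_basin(s = 100, flow_min = 170, flow_max = 190)
  zig <- linear_feature("z", "weir",
                        rbind(c(-10, 40), c(25, 40), c(50, 60), c(75, 40),
                              c(110, 40)))
  areas <- partition_interweir_areas(basin, list(zig))
  got <- sort(vapply(areas, function(a) a$area_m2, numeric(1)))
  # manual shoelace of the two digitized halves:
  lower <- rbind(c(0, 0), c(100, 0), c(100, 40), c(75, 40), c(50, 60),
                 c(25, 40), c(0, 40))
  upper <- rbind(c(0, 40), c(25, 40), c(50, 60), c(75, 40), c(100, 40),
                 c(100, 100), c(0, 100))
  expect_equal(got, sort(c(polygon_area(lower), polygon_area(upper))),
               tolerance = 1e-3)
  expect_equal(sum(got), 10000, tolerance = 1e-6 * 10000)
})

test_that("a weir that does not span the basin is rejected", {
  basin <- square_basin(s = 1000)
  short <- linear_feature("s", "weir", rbind(c(200, 500), c(800, 500)))
  expect_error(partition_interweir_areas(basin, list(short)),
               "does not span")
})

test_that("collecting surfaces follow the pond/trap definitions", {
  basin <- square_basin(s = 1000, flow_min = 350, flow_max = 10)
  weir <- linear_feature("w1", "weir", rbind(c(-10, 400), c(1010, 400)))
  v_with_pond <- v_structure("v1", apex = c(300, 380),
                             arm_left_end = c(280, 400),
                             arm_right_end = c(320, 400), weir_id = "w1")
  v_pondless <- v_structure("v2", apex = c(600, 380),
                            arm_left_end = c(580, 400),
                            arm_right_end = c(620, 400), weir_id = "w1",
                            gap_present = TRUE, gap_width = 1)
  p1 <- pond("p1", c(300, 390), area = 450)   # 10 m from v1's apex
  p2 <- pond("p2", c(100, 200), area = 250)   # isolated, same piece
  ls <- landscape(list(basin), list(weir), list(v_with_pond, v_pondless),
                  list(p1, p2))
  areas <- partition_interweir_areas(basin, list(weir))
  areas <- assign_collecting_structures(areas, ls, cutoff = 35)
  up <- areas[[which(vapply(areas, function(a)
    !is.na(a$downstream_weir_id), logical(1)))]]
  expect_setequal(up$collecting_pond_ids, c("p1", "p2"))
  expect_equal(up$pondless_v_ids, "v2")
  expect_equal(up$fishway_count, 1L)
  # ponds mode: pond areas + pondless-V triangle (base 40 x height 20 / 2)
  expect_equal(collecting_surface(up, ls, "ponds"), 450 + 250 + 400)
  # traps mode: one fishway = circle of 1 m diameter
  expect_equal(collecting_surface(up, ls, "traps"), pi / 4)
  r <- concentration_ratio(up, ls, "ponds")
  expect_equal(r$ratio, up$area_m2 / 1100)
})

test_that("trap-mode ratios dominate pond-mode ratios on matched fixtures", {
  sim <- generate_landscape(generator_config(seed = 29, n_ponds = 200,
                                             gap_fraction = 0.5))
  ls <- sim$landscape
  b <- ls$sub_basins[[1]]
  weirs <- Filter(function(f) f$kind == "weir" && startsWith(f$id, b$id),
                  ls$linear_features)
  areas <- assign_collecting_structures(
    partition_interweir_areas(b, weirs), ls)
  ponds_tab <- concentration_table(areas, ls, "ponds")
  traps_tab <- concentration_table(areas, ls, "traps")
  expect_true(all(traps_tab$table$ratio >
                    ponds_tab$table$ratio[match(traps_tab$table$id,
                                                ponds_tab$table$id)]))
})

test_that("the concentration ratio is invariant under coordinate scaling", {
  basin <- square_basin(s = 1000)
  weir <- linear_feature("w1", "weir", rbind(c(-10, 400), c(1010, 400)))
  p <- pond("p1", c(500, 200), area = 500)
  ls <- landscape(list(basin), list(weir), list(), list(p))
  areas <- assign_collecting_structures(
    partition_interweir_areas(basin, list(weir)), ls)
  r1 <- concentration_ratio(areas[[1]], ls, "ponds")
  # scale all coordinates and areas by s (areas by s^2)
  s <- 2.5
  basin2 <- square_basin(s = 1000 * s)
  weir2 <- linear_feature("w1", "weir",
                          rbind(c(-10 * s, 400 * s), c(1010 * s, 400 * s)))
  p2 <- pond("p1", c(500 * s, 200 * s), area = 500 * s^2)
  ls2 <- landscape(list(basin2), list(weir2), list(), list(p2))
  areas2 <- assign_collecting_structures(
    partition_interweir_areas(basin2, list(weir2)), ls2)
  r2 <- concentration_ratio(areas2[[1]], ls2, "ponds")
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-9)
  expect_equal(r2$area_capture, r1$area_capture * s^2, tolerance = 1e-9)
})

test_that("empty collecting sets are an error", {
  basin <- square_basin(s = 1000)
  weir <- linear_feature("w1", "weir", rbind(c(-10, 400), c(1010, 400)))
  ls <- landscape(list(basin), list(weir), list(), list())
  areas <- assign_collecting_structures(
    partition_interweir_areas(basin, list(weir)), ls)
  up <- areas[[1]]
  expect_error(collecting_surface(up, ls, "ponds"), "empty collecting set")
  expect_error(collecting_surface(up, ls, "traps"), "no fishways")
})
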