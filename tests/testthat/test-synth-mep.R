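test_that("sampled endplates stay inside the muscle and hug the lamella", {
  sc <- generate_mep_map("gastrocnemius", n_points = 2000, seed = 7)
  expect_equal(nrow(sc$mep$points), 2000)
  expect_true(all(point_in_mask(sc$mep$points, sc$geometry)))
  # at least 95% of points within one nominal half-thickness of the sheet
  d <- mep_sheet_distance(sc)
  expect_gte(mean(d <= sc$mep$params$half_thickness_um), 0.95)
})

test_that("tibialis anterior sampler honours the requested count", {
  sc <- generate_mep_map("tibialis_anterior", n_points = 500, seed = 1)
  expect_equal(nrow(sc$mep$points), 500)
  expect_true(all(point_in_mask(sc$mep$points, sc$geometry)))
})

test_that("the density is a proper distribution on the muscle mask", {
  for (muscle in c("gastrocnemius", "tibialis_anterior")) {
    sc <- generate_mep_map(muscle, n_points = 10, seed = 2)
    dens <- sc$mep$density
    expect_true(all(dens >= 0))
    expect_equal(sum(dens[!sc$geometry$mask]), 0)
    expect_equal(sum(dens) * sc$geometry$voxel_size_um^3, 1, tolerance = 1e-9)
  }
})

test_that("generation is a pure function of its seed", {
  a <- generate_mep_map("gastrocnemius", n_points = 300, seed = 3)
  b <- generate_mep_map("gastrocnemius", n_points = 300, seed = 3)
  expect_identical(a$mep$density, b$mep$density)
  expect_identical(a$mep$points, b$mep$points)
  c <- generate_mep_map("gastrocnemius", n_points = 300, seed = 4)
  expect_false(identical(a$mep$points, c$mep$points))
})

test_that("bad generator arguments are rejected", {
  expect_error(generate_mep_map("gastrocnemius", n_points = 0),
               "n_points")
  expect_error(generate_mep_map("soleus"))
  g <- muscle_geometry("gastrocnemius", voxel_size_um = 200)
  expect_error(generate_mep_map("tibialis_anterior", geometry = g),
               "different muscle")
  expect_error(generate_mep_map("gastrocnemius",
                                shape_params = list(bogus = 1)),
               "unknown shape_params")
})

test_that("muscle geometry is sane", {
  g <- muscle_geometry("tibialis_anterior", voxel_size_um = 200)
  expect_s3_class(g, "muscle_geometry")
  expect_gt(sum(g$mask), 0)
  s <- surface_depth_map(g)
  occ <- apply(g$mask, c(2, 3), any)
  expect_identical(!is.na(s), occ)
  expect_error(muscle_geometry("gastrocnemius", voxel_size_um = -1))
})
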