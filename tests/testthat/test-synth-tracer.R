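geom <- muscle_geometry("gastrocnemius")
# site at the central voxel's centre, so the kernel peak is unambiguous
center_um <- (floor(dim(geom$mask) / 2) - 0.5) * geom$voxel_size_um

central_site <- function(volume_nl) {
  manual_plan(data.frame(depth_um = center_um[1], row_um = center_um[2],
                         col_um = center_um[3], depth_mm = 1.35,
                         volume_nl = volume_nl))
}

test_that("a single deposit peaks at its own voxel and stays in the fascia", {
  f <- simulate_tracer_diffusion(central_site(500), geom)
  conc <- f$concentration
  peak <- arrayInd(which.max(conc), dim(conc))
  site_vox <- floor(center_um / geom$voxel_size_um) + 1
  expect_equal(as.integer(peak), as.integer(site_vox))
  expect_equal(sum(conc[!geom$mask]), 0)
})

test_that("total tracer mass is proportional to injected volume", {
  f1 <- simulate_tracer_diffusion(central_site(500), geom)
  expect_equal(sum(f1$concentration), 500, tolerance = 1e-9)
  sc <- generate_mep_map("gastrocnemius", n_points = 400, seed = 5)
  p <- make_injection_plan(sc, "3D")
  f <- simulate_tracer_diffusion(p, sc$geometry)
  expect_equal(sum(f$concentration), 3500, tolerance = 1e-9)
})

test_that("spatial spread scales with the cube root of volume", {
  # deep-interior site and a small spread keep mask clipping negligible, so
  # the empirical SD ratio approaches the closed form (4000/500)^(1/3) = 2
  sd1 <- tracer_spatial_sd(simulate_tracer_diffusion(central_site(500), geom,
                                                     spread_um_per_500nl = 150))
  sd2 <- tracer_spatial_sd(simulate_tracer_diffusion(central_site(4000), geom,
                                                     spread_um_per_500nl = 150))
  expect_equal(sd2 / sd1, 2, tolerance = 0.05)
})

test_that("sites outside the muscle are rejected", {
  bad <- manual_plan(data.frame(depth_um = 50, row_um = 50, col_um = 50,
                                depth_mm = 0.05, volume_nl = 500))
  expect_error(simulate_tracer_diffusion(bad, geom), "outside the muscle")
})
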