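# hand-built sections with binary channels: manual threshold 0.5 makes the
# segmentation exact, so per-depth coverages are known by construction
section_pair <- function(depth, n_mep, n_in) {
  tracer <- matrix(0, 10, 10)
  mep <- matrix(0, 10, 10)
  mep[1, seq_len(n_mep)] <- 1
  tracer[1, seq_len(n_in)] <- 1
  list(depth_um = depth, tracer = tracer, mep = mep)
}

manual <- threshold_spec("manual", 0.5)

test_that("mean coverage is the unweighted mean over depths", {
  secs <- list(section_pair(100, 10, 4), section_pair(200, 10, 6))
  res <- coverage_profile(secs, filter = "none", threshold = manual)
  expect_equal(res$per_depth$coverage, c(0.4, 0.6))
  expect_equal(res$mean_coverage, 0.5)
  expect_equal(res$per_depth$mep_pixels, c(10, 10))
  expect_equal(res$per_depth$mep_pixels_in_ctb, c(4, 6))
})

test_that("a single section's mean is its own coverage", {
  res <- coverage_profile(list(section_pair(50, 8, 2)), filter = "none",
                          threshold = manual)
  expect_equal(res$mean_coverage, 0.25)
})

test_that("sections without MEP signal are excluded with a warning", {
  empty <- section_pair(300, 0, 0)
  secs <- list(section_pair(100, 10, 5), empty)
  expect_warning(res <- coverage_profile(secs, filter = "none",
                                         threshold = manual),
                 "empty MEP mask")
  expect_true(is.na(res$per_depth$coverage[2]))
  expect_equal(res$mean_coverage, 0.5)
})

test_that("duplicate depths and empty input are rejected", {
  expect_error(coverage_profile(list()), "at least one")
  secs <- list(section_pair(100, 5, 1), section_pair(100, 5, 2))
  expect_error(coverage_profile(secs, filter = "none", threshold = manual),
               "distinct")
})

test_that("applied thresholds are recorded for audit", {
  scene <- tiny_ta_scene(seed = 8)
  plan <- make_injection_plan(scene, "3D")
  field <- simulate_tracer_diffusion(plan, scene$geometry)
  secs <- render_section_images(field, scene, mep_section_depths(scene, 2),
                                seed = 1)
  res <- coverage_profile(secs)
  expect_true(all(is.finite(res$per_depth$tracer_threshold)))
  expect_true(all(is.finite(res$per_depth$mep_threshold)))
})
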