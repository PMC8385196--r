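tight_pool <- function(...) {
  defaults <- list(spread_rc_um = 500, spread_ml_um = 200,
                   spread_vd_um = 150)
  do.call(pool_params, utils::modifyList(defaults, list(...)))
}

test_that("a lone soma is found within a voxel of its true centre", {
  cs <- render_cord_scene(1, tight_pool(), seed = 41)
  sp <- detect_spots(cs$volume, cs$voxel_size_um)
  expect_equal(count_neurons(sp), 1)
  err <- sqrt(sum((sp$centroids[1, ] - cs$truth_spots$centroids[1, ])^2))
  expect_lte(err, max(cs$voxel_size_um))
})

test_that("well-separated somata are counted individually", {
  p <- tight_pool(min_separation_um = 60)   # 3x the soma diameter
  cs <- render_cord_scene(2, p, seed = 42)
  sp <- detect_spots(cs$volume, cs$voxel_size_um)
  expect_equal(count_neurons(sp), 2)
})

test_that("pure background produces no spots", {
  cs <- render_cord_scene(0, tight_pool(), seed = 43)
  sp <- detect_spots(cs$volume, cs$voxel_size_um)
  expect_equal(count_neurons(sp), 0)
  expect_equal(count_neurons(spot_set(matrix(numeric(0), 0, 3))), 0)
})

test_that("counts and centroids recover the ground truth", {
  p <- tight_pool(spread_rc_um = 900, min_separation_um = 30)
  for (seed in 44:45) {
    cs <- render_cord_scene(60, p, seed = seed)
    sp <- detect_spots(cs$volume, cs$voxel_size_um)
    expect_equal(count_neurons(sp), 60)
    dmin <- apply(cs$truth_spots$centroids, 1, function(ctr)
      min(sqrt(colSums((t(sp$centroids) - ctr)^2))))
    expect_lte(mean(dmin), max(cs$voxel_size_um))
  }
})

test_that("detection is deterministic for a fixed volume", {
  cs <- render_cord_scene(20, tight_pool(), seed = 46)
  a <- detect_spots(cs$volume, cs$voxel_size_um)
  b <- detect_spots(cs$volume, cs$voxel_size_um)
  expect_identical(a$centroids, b$centroids)
})

test_that("detector rejects malformed inputs", {
  cs <- render_cord_scene(1, tight_pool(), seed = 47)
  expect_error(detect_spots(matrix(0, 3, 3), 5), "3D")
  expect_error(detect_spots(cs$volume, c(5, 5)), "each axis")
  expect_error(detect_spots(cs$volume, 15), "at least 2 voxels")
})

test_that("pool extent reduces to the coordinate ranges", {
  sp <- spot_set(rbind(c(0, 0, 0), c(100, 20, 10)))
  ext <- pool_extent(sp)
  expect_equal(c(ext$range_rc_um, ext$range_ml_um, ext$range_vd_um),
               c(100, 20, 10))
  one <- pool_extent(spot_set(matrix(c(5, 5, 5), 1)))
  expect_equal(c(one$range_rc_um, one$range_ml_um, one$range_vd_um),
               c(0, 0, 0))
  expect_error(pool_extent(spot_set(matrix(numeric(0), 0, 3))), "empty")
})

test_that("minmax extent approaches the box size; percentile sits inside", {
  set.seed(48)
  L <- 1000
  pts <- cbind(runif(1000, 0, L), runif(1000, 0, L), runif(1000, 0, L))
  sp <- spot_set(pts)
  mm <- pool_extent(sp, "minmax")
  pc <- pool_extent(sp, "percentile")
  for (f in c("range_rc_um", "range_ml_um", "range_vd_um")) {
    expect_gt(mm[[f]], 0.99 * L)       # E[range] = L * (n-1)/(n+1)
    expect_lt(pc[[f]], mm[[f]])
  }
})

test_that("extents are translation invariant and scale linearly", {
  set.seed(49)
  pts <- matrix(runif(60, 0, 500), ncol = 3)
  a <- pool_extent(spot_set(pts))
  b <- pool_extent(spot_set(sweep(pts, 2, c(100, -50, 7), `+`)))
  expect_equal(unlist(a[1:3]), unlist(b[1:3]))
  c2 <- pool_extent(spot_set(pts * 2))
  expect_equal(unlist(c2[1:3]), 2 * unlist(a[1:3]))
})

test_that("maximum intensity projection behaves like a per-pixel max", {
  v <- array(0, c(4, 5, 6))
  v[2, 3, 4] <- 7
  expect_equal(max_intensity_projection(v, 1)[3, 4], 7)
  expect_equal(max_intensity_projection(v, 3)[2, 3], 7)
  expect_true(all(max_intensity_projection(array(2, c(3, 3, 3)), 2) == 2))
  # commutes with a monotone intensity map
  set.seed(50)
  r <- array(runif(4 * 5 * 6), c(4, 5, 6))
  expect_equal(max_intensity_projection(2 * r + 1, 2),
               2 * max_intensity_projection(r, 2) + 1)
  expect_error(max_intensity_projection(r, 4), "axis")
})
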