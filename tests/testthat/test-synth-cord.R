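# small pool keeps these volumes light
small_pool <- function(...) {
  pool_params(spread_rc_um = 600, spread_ml_um = 200, spread_vd_um = 150, ...)
}

test_that("requested somata are all placed inside the pool box", {
  cs <- render_cord_scene(50, small_pool(), seed = 4)
  cent <- cs$truth_spots$centroids
  expect_equal(nrow(cent), 50)
  for (a in 1:3)
    expect_true(all(cent[, a] >= cs$pool_bounds["lo", a] &
                    cent[, a] <= cs$pool_bounds["hi", a]))
  dd <- as.matrix(dist(cent))
  diag(dd) <- Inf
  expect_gte(min(dd), cs$pool$min_separation_um)
})

test_that("an empty scene is pure background", {
  p <- small_pool()
  cs <- render_cord_scene(0, p, seed = 5)
  expect_equal(nrow(cs$truth_spots$centroids), 0)
  expect_lt(abs(mean(cs$volume) - p$background), 0.05)
  expect_lt(max(cs$volume), p$background + 6 * p$background_sd)
})

test_that("realized peak over background noise matches the requested SNR", {
  p <- small_pool(peak = 10, background_sd = 1)
  cs <- render_cord_scene(40, p, seed = 6)
  vs <- cs$voxel_size_um
  at_centroid <- apply(cs$truth_spots$centroids, 1, function(ctr) {
    i <- pmin(pmax(floor(ctr / vs) + 1, 1), dim(cs$volume))
    cs$volume[i[1], i[2], i[3]]
  })
  # the leading rostro-caudal slab is signal-free (pool margin > blob reach)
  bg <- cs$volume[1:4, , ]
  snr <- (mean(at_centroid) - mean(bg)) / sd(bg)
  expect_equal(snr, 10, tolerance = 0.1)
})

test_that("cord scenes are seed-deterministic", {
  a <- render_cord_scene(10, small_pool(), seed = 7)
  b <- render_cord_scene(10, small_pool(), seed = 7)
  expect_identical(a$volume, b$volume)
  expect_identical(a$truth_spots$centroids, b$truth_spots$centroids)
})

test_that("an overfull pool is reported, not silently under-filled", {
  tight <- pool_params(spread_rc_um = 60, spread_ml_um = 60,
                       spread_vd_um = 60, min_separation_um = 40)
  expect_error(render_cord_scene(50, tight, seed = 1, max_tries = 500),
               "pool too small")
})
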