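test_that("a bright ring encircling a dark centre fills to a disk", {
  img <- matrix(0, 8, 8)
  img[3:6, 3:6] <- 1          # ring of intensity 1 ...
  img[4:5, 4:5] <- 0.2        # ... enclosing a dimmer 2x2 centre
  m <- segment_tracer_region(img, threshold_spec("manual", 0.5))
  expect_true(all(m$pixels[4:5, 4:5]))          # the hole became foreground
  expect_identical(m$pixels, brute_force_fill(img > 0.5))
})

test_that("hole filling matches the flood-fill oracle and never erases", {
  set.seed(31)
  for (i in 1:30) {
    m <- rand_mask(24, 24, p = runif(1, 0.25, 0.6))
    filled <- fill_holes(m)
    expect_identical(filled, brute_force_fill(m))
    expect_true(all(filled[m]))                 # foreground preserved
    # only enclosed background may change
    changed <- filled & !m
    enclosed <- brute_force_fill(m) & !m
    expect_true(all(changed == enclosed))
  }
})

test_that("binary image with no enclosed background segments to itself", {
  img <- matrix(0, 6, 6); img[2:3, 2:5] <- 1
  m <- segment_tracer_region(img, threshold_spec("manual", 0.5))
  expect_identical(m$pixels, img > 0.5)
  expect_identical(segment_tracer_region(matrix(0, 5, 5),
                                         threshold_spec("manual", 0.5))$pixels,
                   matrix(FALSE, 5, 5))
})

test_that("a constant image yields an empty mask with a warning", {
  img <- matrix(2, 10, 10)
  expect_warning(m <- segment_tracer_region(img), "constant image")
  expect_equal(sum(m$pixels), 0)
  expect_warning(m2 <- segment_mep_signal(img, filter = "none"),
                 "constant image")
  expect_equal(sum(m2$pixels), 0)
})

test_that("the exact 3x3 median matches a sort-based oracle", {
  set.seed(32)
  for (i in 1:5) {
    img <- matrix(runif(20 * 17), 20, 17)
    expect_equal(median_filter3(img), median3_oracle(img))
  }
})

test_that("median prefilter kills impulse noise but keeps 3x3 puncta", {
  img <- matrix(0, 20, 20)
  puncta_at <- list(c(3, 3), c(10, 14), c(16, 6))
  for (p in puncta_at)
    img[p[1] + (-1:1), p[2] + (-1:1)] <- 1          # solid 3x3 puncta
  noise_at <- list(c(6, 18), c(14, 10), c(19, 19), c(1, 10))
  for (p in noise_at) img[p[1], p[2]] <- 1          # isolated single pixels
  m <- segment_mep_signal(img, filter = "median3",
                          threshold = threshold_spec("manual", 0.5))
  for (p in puncta_at) expect_true(m$pixels[p[1], p[2]])
  for (p in noise_at) expect_false(m$pixels[p[1], p[2]])
  # no hole filling on the MEP channel: an annulus stays an annulus
  ring <- matrix(0, 9, 9); ring[3:7, 3:7] <- 1; ring[5, 5] <- 0
  mr <- segment_mep_signal(ring, filter = "none",
                           threshold = threshold_spec("manual", 0.5))
  expect_false(mr$pixels[5, 5])
})

test_that("manual thresholds above the maximum give an empty MEP mask", {
  img <- matrix(runif(64), 8, 8)
  m <- segment_mep_signal(img, filter = "none",
                          threshold = threshold_spec("manual", 2))
  expect_equal(sum(m$pixels), 0)
})

test_that("threshold specifications are validated", {
  expect_error(threshold_spec("manual"), "requires")
  expect_error(threshold_spec("auto", 0.3), "absent")
})

test_that("coverage ratio counts pixels exactly", {
  mep <- matrix(FALSE, 5, 5); mep[1, 1:5] <- TRUE; mep[2, 1:5] <- TRUE
  ctb <- matrix(FALSE, 5, 5); ctb[1, 1:5] <- TRUE; ctb[2, 1:2] <- TRUE
  expect_equal(coverage_ratio(mep, ctb), 0.7)       # 7 of 10
  expect_equal(coverage_ratio(mep, matrix(TRUE, 5, 5)), 1)
  expect_equal(coverage_ratio(mep, !mep), 0)
})

test_that("coverage matches a double-loop oracle on random masks", {
  set.seed(33)
  for (i in 1:10) {
    mep <- rand_mask(64, 64); ctb <- rand_mask(64, 64)
    if (!any(mep)) next
    expect_equal(coverage_ratio(mep, ctb), coverage_loop_oracle(mep, ctb))
  }
})

test_that("growing the tracer mask never lowers coverage", {
  set.seed(34)
  mep <- rand_mask(32, 32)
  ctb <- rand_mask(32, 32, p = 0.3)
  base <- coverage_ratio(mep, ctb)
  grown <- ctb | rand_mask(32, 32, p = 0.2)
  expect_gte(coverage_ratio(mep, grown), base)
})

test_that("undefined coverage raises instead of faking zero", {
  expect_error(coverage_ratio(matrix(FALSE, 3, 3), matrix(TRUE, 3, 3)),
               "undefined")
  expect_error(coverage_ratio(matrix(TRUE, 3, 3), matrix(TRUE, 4, 4)),
               "shapes differ")
})

test_that("display inversion is cosmetic: no computed count changes", {
  set.seed(35)
  mep <- rand_mask(16, 16); ctb <- rand_mask(16, 16)
  before <- coverage_ratio(mep, ctb)
  disp <- as_display(mep, invert = TRUE)
  expect_setequal(unique(as.vector(disp)), c(0L, 255L))
  # inverted rendering maps back to the identical mask
  expect_identical(disp == 0L, mep)
  expect_equal(coverage_ratio(disp == 0L, ctb), before)
})
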