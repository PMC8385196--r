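test_that("clean normal samples route to the pooled t-test", {
  set.seed(101)
  a <- rnorm(30, 5, 1); b <- rnorm(30, 4, 1)
  r <- compare_groups(a, b)
  expect_equal(r$branch, "pooled_t")
  expect_true(all(r$normality_p >= 0.05))
  expect_gte(r$levene_p, 0.05)
  expect_lt(r$p_value, 0.001)
})

test_that("a heavily skewed sample routes to Mann-Whitney", {
  set.seed(202)
  a <- exp(rnorm(30)); b <- rnorm(30, 2, 1)
  r <- compare_groups(a, b)
  expect_equal(r$branch, "mann_whitney")
  expect_true(any(r$normality_p < 0.05))
  expect_true(is.na(r$levene_p))          # variance gate never reached
})

test_that("unequal variances route to the Welch t-test", {
  set.seed(303)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 0, 5)
  r <- compare_groups(a, b)
  expect_equal(r$branch, "welch_t")
  expect_lt(r$levene_p, 0.05)
})

test_that("the branch is a pure function of the gate p-values", {
  set.seed(404)
  for (i in 1:25) {
    a <- switch(1 + i %% 3, rnorm(12), exp(rnorm(12)), rnorm(12, 0, 4))
    b <- rnorm(12)
    r <- compare_groups(a, b)
    expected <- if (any(r$normality_p < r$alpha)) "mann_whitney"
      else if (r$levene_p < r$alpha) "welch_t" else "pooled_t"
    expect_equal(r$branch, expected)
  }
})

test_that("degenerate groups are caught", {
  expect_warning(r <- compare_groups(c(3, 3, 3, 3), c(1, 2, 4, 5)),
                 "zero-variance")
  expect_equal(r$branch, "mann_whitney")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
  expect_error(compare_groups(c(1, 2, Inf), c(1, 2, 3)), "finite")
})

test_that("percent improvement reproduces the printed worked example", {
  expect_identical(percent_improvement(183, 109), 67.89)
  expect_identical(percent_improvement(5, 5), 0)
  expect_identical(percent_improvement(2, 1), 100)
  expect_error(percent_improvement(2, 0), "positive")
})

test_that("improvement and its inverse compose to unity", {
  for (pair in list(c(183, 109), c(7, 3), c(2.5, 4))) {
    p <- percent_improvement(pair[1], pair[2])
    q <- percent_improvement(pair[2], pair[1])
    expect_equal((1 + p / 100) * (1 + q / 100), 1, tolerance = 2e-4)
  }
})

test_that("mean and SEM follow the closed form", {
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(unname(ms["mean"]), 2)
  expect_equal(unname(ms["sem"]), 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(unname(mean_sem(rep(4, 6))["sem"]), 0)
  expect_error(mean_sem(1), "n >= 2")
})

test_that("the SEM agrees with a bootstrap standard error", {
  set.seed(505)
  x <- rnorm(40, 10, 3)
  boot <- replicate(2000, mean(sample(x, replace = TRUE)))
  expect_equal(unname(mean_sem(x)["sem"]), sd(boot), tolerance = 0.05)
})
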