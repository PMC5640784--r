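DOSES12 <- c(0.1, 0.25, 0.5, 1, 2.5, 5, 10, 25, 50, 100, 250, 500)

test_that("noiseless 4PL data are recovered exactly", {
  y <- hill4(DOSES12, 0.1, 10, 5, 2)
  fit <- fit_hill4(DOSES12, y)
  expect_equal(fit$y_min, 0.1, tolerance = 1e-6)
  expect_equal(fit$y_max, 10, tolerance = 1e-6)
  expect_equal(fit$ec50, 5, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-6)
  expect_true(fit$reliable)
})

test_that("inversion round-trips within 1e-8 on the curve range", {
  y <- hill4(DOSES12, 0.1, 10, 5, 2)
  fit <- fit_hill4(DOSES12, y)
  for (d in c(0.5, 2, 5, 20, 100)) {
    inv <- invert_signal(fit, hill4(d, fit$y_min, fit$y_max, fit$ec50,
                                    fit$hill))
    expect_equal(inv$lower, d, tolerance = 1e-8)
    expect_equal(inv$upper, d, tolerance = 1e-8)
  }
})

test_that("EC50 recovered within 10% (median) at 5% noise", {
  set.seed(101)
  ec <- replicate(40, {
    y <- hill4(DOSES12, 0.1, 10, 5, 2)
    fit <- fit_hill4(DOSES12, y + stats::rnorm(12, 0, 0.05 * diff(range(y))))
    fit$ec50
  })
  expect_lt(abs(stats::median(ec) - 5) / 5, 0.1)
})

test_that("signals outside the curve range are censored", {
  fit <- fit_hill4(DOSES12, hill4(DOSES12, 0.1, 10, 7, 2))
  top <- invert_signal(fit, 11)
  expect_true(top$censored_high)
  expect_equal(top$midpoint, 500)
  bottom <- invert_signal(fit, 0.05)
  expect_true(bottom$censored_low)
  expect_equal(bottom$midpoint, 0.1)
})

test_that("midpoint reporting reproduces the printed averages", {
  # printed PHx interval (6.8, 7.9) -> 7.4; LPS (28.1, 500) -> 264.1
  expect_equal(round_half_up((6.8 + 7.9) / 2, 1), 7.4)
  expect_equal(round_half_up((28.1 + 500) / 2, 1), 264.1)
})

test_that("unreliable fits are flagged when the half-maximum is not bracketed", {
  d <- c(50, 100, 200, 350, 500)
  y <- hill4(d, 0.1, 10, 0.5, 2)  # all points near the upper asymptote
  y <- y + c(-2e-3, -1e-3, 0, 1e-3, 2e-3)
  fit <- fit_hill4(d, y)
  expect_false(fit$reliable)
})

test_that("4PL fit requires enough dose levels", {
  expect_error(fit_hill4(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("potency conversion round-trips and matches 7.5 -> 1.8", {
  expect_equal(potency_convert(7.5, "human_to_mouse"), 1.8)
  expect_equal(potency_convert(1.8, "mouse_to_human"), 7.5)
  d <- c(0.3, 40, 500)
  expect_equal(
    potency_convert(potency_convert(d, "human_to_mouse"), "mouse_to_human"),
    d, tolerance = 1e-12)
  expect_error(potency_convert(-1), ">= 0")
})
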