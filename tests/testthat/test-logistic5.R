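p_ref <- list(a = 0.4, d = 0.1, c = 3, b = 2, g = 1)

test_that("eval_5pl matches its closed form at anchor points", {
  expect_equal(eval_5pl(p_ref, 0), 0.4)          # left plateau
  expect_equal(eval_5pl(p_ref, 3), 0.25)         # g = 1 midpoint at x = c
  # hand evaluation with asymmetry: 0.1 + 0.3 / sqrt(2)
  p <- list(a = 0.4, d = 0.1, c = 3, b = 2, g = 0.5)
  expect_equal(eval_5pl(p, 3), 0.1 + 0.3 / sqrt(2), tolerance = 1e-12)
  # right plateau limit
  expect_equal(eval_5pl(p_ref, 1e8), 0.1, tolerance = 1e-6)
  expect_error(eval_5pl(list(a = 1, d = 0, c = -1, b = 1, g = 1), 1), "c, b, g")
  expect_error(eval_5pl(p_ref, -1), "x")
})

test_that("eval_5pl is strictly monotone between plateaus", {
  for (g in c(0.3, 1, 2.7)) {
    p <- list(a = 0.45, d = 0.05, c = 5, b = 1.7, g = g)
    x <- seq(0, 40, length.out = 200)
    expect_true(all(diff(eval_5pl(p, x)) < 0))
    p_inc <- list(a = 0.05, d = 0.45, c = 5, b = 1.7, g = g)
    expect_true(all(diff(eval_5pl(p_inc, x)) > 0))
  }
})

test_that("invert_5pl is the exact inverse on the interior", {
  set.seed(42)
  for (i in 1:20) {
    p <- list(a = runif(1, 0.3, 1), d = runif(1, 0, 0.2),
              c = runif(1, 0.5, 10), b = runif(1, 0.5, 4),
              g = runif(1, 0.3, 3))
    x <- p$c * c(0.1, 1, 10)
    y <- eval_5pl(p, x)
    expect_equal(invert_5pl(p, y), x, tolerance = 1e-8)
    # grid identity on the interior
    xg <- seq(0.05, 5, length.out = 41) * p$c
    expect_equal(invert_5pl(p, eval_5pl(p, xg)), xg, tolerance = 1e-8)
  }
  # g = 1: inverting the mid-plateau response returns c
  expect_equal(invert_5pl(p_ref, 0.25), 3, tolerance = 1e-12)
})

test_that("invert_5pl rejects responses at or beyond the plateaus", {
  expect_error(invert_5pl(p_ref, 0.4), "plateau")
  expect_error(invert_5pl(p_ref, 0.1), "plateau")
  expect_error(invert_5pl(p_ref, 0.5), "plateau")
})

test_that("characteristic times match their closed forms", {
  expect_equal(characteristic_times(list(a = 1, d = 0, c = 4, b = 1,
                                         g = 1))$x50, 4)
  p <- list(a = 1, d = 0, c = 4, b = 2, g = 0.5)
  expect_equal(characteristic_times(p)$x50, 4 * sqrt(3), tolerance = 1e-12)
  # x50 is where the response is exactly mid-plateau
  set.seed(7)
  for (i in 1:10) {
    p <- list(a = runif(1, 0.5, 2), d = runif(1, 0, 0.3),
              c = runif(1, 1, 9), b = runif(1, 0.4, 5), g = runif(1, 0.3, 4))
    ct <- characteristic_times(p)
    expect_equal(eval_5pl(p, ct$x50), (p$a + p$d) / 2, tolerance = 1e-10)
    if (ct$inflection_defined) {
      # second derivative changes sign at x_inf
      h <- 1e-4 * ct$x_inf
      f <- function(x) eval_5pl(p, x)
      d2 <- function(x) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
      expect_lt(d2(ct$x_inf * 1.05) * d2(ct$x_inf * 0.95), 0)
    }
  }
  expect_false(characteristic_times(list(a = 1, d = 0, c = 4, b = 1,
                                         g = 2))$inflection_defined)
})

test_that("fit_5pl recovers generating parameters from noiseless data", {
  x <- rep(c(1, 4, 8, 10, 14, 18, 22), each = 6)
  p <- list(a = 0.45, d = 0.05, c = 8.24, b = 2, g = 1)
  fit <- fit_5pl(x, eval_5pl(p, x), seed = 1)
  expect_true(fit$converged)
  expect_equal(unlist(fit$params), unlist(p), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fit_5pl nests the 4PL: zero-noise 4PL data recovers g near 1", {
  x <- rep(seq(0.5, 30, length.out = 10), each = 3)
  p4 <- list(a = 1.2, d = 0.2, c = 6, b = 1.5, g = 1)
  fit <- fit_5pl(x, eval_5pl(p4, x), seed = 1)
  expect_equal(fit$params$g, 1, tolerance = 1e-4)
})

test_that("fit_5pl input contracts and degenerate data", {
  expect_error(fit_5pl(1:5, 1:5), "at least 6")
  expect_error(fit_5pl(rep(c(1, 2), 3), rnorm(6)), "3 distinct")
  flat <- fit_5pl(rep(c(1, 5, 9, 13), each = 3), rep(2.5, 12), seed = 1)
  expect_true(flat$degenerate)
  expect_equal(flat$params$a, 2.5, tolerance = 1e-3)
  expect_equal(flat$params$d, 2.5, tolerance = 1e-3)
})

test_that("rescaling x rescales location parameters and nothing else", {
  p <- list(a = 0.45, d = 0.05, c = 6, b = 2, g = 1.4)
  dat <- make_5pl_data(p, sd = 0.02, seed = 3)
  f1 <- fit_5pl(dat$x, dat$y, seed = 1)
  k <- 7
  f2 <- fit_5pl(dat$x * k, dat$y, seed = 1)
  expect_equal(f2$params$c, k * f1$params$c, tolerance = 1e-4)
  expect_equal(f2$params$a, f1$params$a, tolerance = 1e-5)
  expect_equal(f2$params$d, f1$params$d, tolerance = 1e-5)
  expect_equal(f2$params$b, f1$params$b, tolerance = 1e-4)
  expect_equal(f2$params$g, f1$params$g, tolerance = 1e-4)
  expect_equal(f2$rss, f1$rss, tolerance = 1e-6)
  ct1 <- characteristic_times(f1$params)
  ct2 <- characteristic_times(f2$params)
  expect_equal(ct2$x50, k * ct1$x50, tolerance = 1e-4)
  expect_equal(ct2$x_inf, k * ct1$x_inf, tolerance = 1e-4)
})

test_that("goodness_of_fit reproduces the Gaussian Maddala identity", {
  set.seed(11)
  for (i in 1:10) {
    p <- list(a = runif(1, 0.4, 1), d = runif(1, 0, 0.2), c = runif(1, 2, 9),
              b = runif(1, 0.8, 3), g = runif(1, 0.5, 2))
    dat <- make_5pl_data(p, sd = runif(1, 0.01, 0.3), seed = 100 + i)
    fit <- fit_5pl(dat$x, dat$y, seed = 1)
    gof <- goodness_of_fit(fit)
    rss0 <- sum((dat$y - mean(dat$y))^2)
    expect_equal(gof$r2_maddala, 1 - fit$rss / rss0, tolerance = 1e-10)
    expect_gte(gof$chi2, 0)
    expect_equal(gof$chi2, length(dat$y) * log(rss0 / fit$rss),
                 tolerance = 1e-8)
    expect_equal(gof$p_value, pchisq(gof$chi2, 1, lower.tail = FALSE))
  }
})

test_that("goodness_of_fit handles the null-equivalent and saturated limits", {
  # essentially flat data: fitted curve explains nothing
  flat <- fit_5pl(rep(c(1, 5, 9, 13), each = 3), rep(2.5, 12), seed = 1)
  gof_sat <- goodness_of_fit(flat)  # rss0 = 0 and rss1 = 0: saturated-null
  expect_equal(gof_sat$chi2, 0)
  expect_equal(gof_sat$p_value, 1)

  # perfect fit on curved data
  x <- rep(c(1, 4, 8, 12, 16, 22), each = 2)
  exact <- fit_5pl(x, eval_5pl(p_ref, x), seed = 1)
  gof <- goodness_of_fit(exact)
  expect_equal(gof$r2_maddala, 1, tolerance = 1e-9)
})

test_that("calibrate_5pl passes exactly through its anchor points", {
  p <- calibrate_5pl(a = 7.2, d = 4.8, x1 = 0.2250, y1 = 5.6,
                     x2 = 0.2125, y2 = 6.1)
  expect_equal(eval_5pl(p, c(0.2250, 0.2125)), c(5.6, 6.1),
               tolerance = 1e-10)
  expect_equal(invert_5pl(p, c(5.6, 6.1)), c(0.2250, 0.2125),
               tolerance = 1e-10)
  q <- calibrate_5pl(a = 0.28, d = 0.40, x1 = 0.2100, y1 = 0.339,
                     x2 = 0.1216, y2 = 0.300)
  expect_equal(eval_5pl(q, c(0.2100, 0.1216)), c(0.339, 0.300),
               tolerance = 1e-10)
  expect_error(calibrate_5pl(1, 0, 0.1, 1.5, 0.2, 0.5), "between the plateaus")
})
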