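test_that("a zero-radius sweep is the trivial baseline point", {
  sw <- robustness_sweep(2, "rest", radius = 0, step = 0.05, n_cycles = 40)
  expect_equal(sort(unique(sw$table$value)), 0)
  expect_equal(sw$sign_preserving_radius, 0)
})

test_that("sweeps are deterministic", {
  a <- robustness_sweep(2, "rest", radius = 0.1, step = 0.05, n_cycles = 40)
  b <- robustness_sweep(2, "rest", radius = 0.1, step = 0.05, n_cycles = 40)
  expect_identical(a$table, b$table)
  expect_identical(a$sign_preserving_radius, b$sign_preserving_radius)
})

test_that("input sweeps report whether labels stay constant", {
  sw <- robustness_sweep(2, "input", input_factors = c(0.5, 1),
                         n_cycles = 60)
  expect_type(sw$labels_constant, "logical")
  expect_equal(nrow(sw$table), 4L)
})

test_that("bisection finds sign changes and honours its edge cases", {
  # analytic check
  expect_equal(polarity_boundary(function(x) x - 2, 1, 9, tol = 1e-6), 2,
               tolerance = 1e-5)
  # an endpoint with summary exactly zero is returned
  expect_equal(polarity_boundary(function(x) x, 0, 5), 0)
  expect_equal(polarity_boundary(function(x) x - 5, 0, 5), 5)
  # degenerate or same-sign brackets are rejected
  expect_error(polarity_boundary(function(x) x, 2, 2), "lo < hi")
  expect_error(polarity_boundary(function(x) x + 10, 1, 2), "same sign")
})

test_that("a single neighbor flips polarity at some input level in (1, 9)", {
  f <- function(inp) {
    res <- run_simulation_3(input_levels = inp, n_neighbors = 1L,
                            n_cycles = 60)
    res$summary[1]
  }
  s_lo <- f(1); s_hi <- f(9)
  expect_gt(s_lo, 0)
  expect_lt(s_hi, 0)
  xing <- polarity_boundary(f, 1, 9, tol = 0.05)
  expect_gt(xing, 1)
  expect_lt(xing, 9)
  # the summary near the boundary is smaller than at both endpoints
  expect_lt(abs(f(xing)), abs(s_lo))
  expect_lt(abs(f(xing)), abs(s_hi))
})
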