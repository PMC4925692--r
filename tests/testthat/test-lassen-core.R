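test_that("forward transform reproduces hand-computed count ratios", {
  # reference region maps to itself; zero flow gives zero count
  expect_identical(lassen_forward(1, 0.5), 1)
  expect_identical(lassen_forward(0, 0.5), 0)
  # direct evaluation: 2 * 1.5 / 2.5 and 0.5 * 1.5 / 1.0
  expect_equal(lassen_forward(2, 0.5), 1.2)
  expect_equal(lassen_forward(0.5, 0.5), 0.75)
  # vectorised
  expect_equal(lassen_forward(c(0.5, 1, 2), 0.5), c(0.75, 1, 1.2))
})

test_that("forward transform saturates below 1 + alpha and compresses contrast", {
  for (a in c(0.25, 0.5, 1.5, 3)) {
    x <- seq(0.01, 10, length.out = 400)
    y <- lassen_forward(x, a)
    expect_true(all(y < 1 + a))
    expect_true(all(diff(y) > 0))  # strictly increasing
    # asymptote: within 1e-5 of 1 + alpha at very high flow
    expect_equal(lassen_forward(1e6, a), 1 + a, tolerance = 1e-5)
    # compression: counts understate flow above reference, overstate below
    expect_true(all(y[x > 1] < x[x > 1]))
    expect_true(all(y[x < 1 & x > 0] > x[x < 1 & x > 0]))
  }
})

test_that("inverse transform matches hand-computed corrections", {
  expect_identical(lassen_inverse(1, 0.5), 1)       # fixed point
  expect_equal(lassen_inverse(1.2, 0.5), 2)         # 0.5*1.2/0.3
  expect_equal(lassen_inverse(1.2, 1.5), 1.8 / 1.3) # weaker at larger alpha
  expect_equal(lassen_inverse(0.75, 0.5), 0.5)
})

test_that("inverse is the exact functional inverse of the forward map", {
  x <- seq(0.001, 10, length.out = 500)
  for (a in c(0.25, 0.5, 1.5, 3)) {
    expect_equal(lassen_inverse(lassen_forward(x, a), a), x,
                 tolerance = 1e-12)
    # and in the other direction, on the invertible interval
    cc <- seq(1e-3, 1 + a - 1e-3, length.out = 200)
    expect_equal(lassen_forward(lassen_inverse(cc, a), a), cc,
                 tolerance = 1e-12)
  }
})

test_that("smaller alpha compensates more strongly; inverse is monotone", {
  alphas <- c(0.25, 0.5, 1.5, 3)
  for (cc in c(1.05, 1.1, 1.2)) {  # above reference: within all domains
    vals <- vapply(alphas, function(a) lassen_inverse(cc, a), numeric(1))
    expect_true(all(diff(vals) < 0))  # stronger correction at smaller alpha
  }
  for (cc in c(0.3, 0.6, 0.9)) {  # below reference the ordering reverses
    vals <- vapply(alphas, function(a) lassen_inverse(cc, a), numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  for (a in alphas) {
    cc <- seq(0.01, 1 + a - 0.01, length.out = 300)
    expect_true(all(diff(lassen_inverse(cc, a)) > 0))
  }
})

test_that("domain errors are raised, not coerced", {
  expect_error(lassen_forward(1, 0), "alpha")
  expect_error(lassen_forward(1, -0.5), "alpha")
  expect_error(lassen_forward(-0.1, 0.5), "non-negative")
  expect_error(lassen_inverse(1, -1), "alpha")
  # exact singularity under raw is an explicit error, not Inf
  expect_error(lassen_inverse(1.5, 0.5, guard = "raw"), "singular")
})

test_that("guard policies flag, exclude or clip out-of-domain counts", {
  cc <- c(0.75, 1.0, 1.2, 1.6, -0.05)  # last two outside (0, 1.5)

  raw <- lassen_correct(cc, 0.5, guard = "raw")
  expect_equal(raw$corrected[1:3], c(0.5, 1, 2))
  expect_identical(raw$flagged, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(raw$n_flagged, 2L)
  # raw computes as-is: beyond the singularity the value is negative
  expect_lt(raw$corrected[4], 0)
  expect_lt(raw$corrected[5], 0)

  exc <- lassen_correct(cc, 0.5, guard = "exclude")
  expect_equal(exc$corrected[1:3], c(0.5, 1, 2))
  expect_true(all(is.na(exc$corrected[4:5])))

  clp <- lassen_correct(cc, 0.5, guard = "clip")
  expect_true(all(is.finite(clp$corrected)))
  expect_gt(clp$corrected[4], 1e8)   # clamped just inside the singularity
  expect_gt(clp$corrected[5], 0)
  expect_identical(clp$n_flagged, 2L)

  # in-domain values are identical under every policy
  for (g in c("exclude", "clip")) {
    expect_equal(lassen_correct(cc[1:3], 0.5, guard = g)$corrected,
                 raw$corrected[1:3])
  }
})

test_that("correction series refuses empty or fully excluded input", {
  expect_error(lassen_correct(numeric(0), 0.5), "non-empty")
  expect_error(lassen_correct(1.6, 0.5, guard = "exclude"), "no data left")
  # the same single out-of-domain point is kept (and flagged) under raw
  raw <- lassen_correct(1.6, 0.5, guard = "raw")
  expect_identical(raw$n_flagged, 1L)
})
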