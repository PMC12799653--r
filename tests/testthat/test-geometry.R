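# Hypersphere geometry kernel: closed forms, conservation, symmetry,
# monotonicity, Monte-Carlo agreement, and radius solving.

test_that("ball volume matches closed forms and rejects bad dimensions", {
  expect_equal(ball_volume(2, 1), pi)
  expect_equal(ball_volume(3, 1), 4 * pi / 3)
  expect_equal(ball_volume(1, 2), 4)
  expect_identical(ball_volume(7, 0), 0)
  expect_error(ball_volume(0, 1), "positive integer")
  expect_error(ball_volume(-2, 1), "positive integer")
})

test_that("high-dimensional probability ratios stay finite and sane", {
  # raw volumes over/underflow long before p = 450; the probability path is
  # log-space throughout and must stay usable at that scale
  pr <- containment_probability(450, 1, 0.9, 0.3)
  expect_true(is.finite(pr) && pr >= 0 && pr <= 1)
  expect_equal(containment_probability(450, 1, 1.3, 0.3), 1)
  expect_equal(containment_probability(500, 2, 2 * 0.5^(1 / 500), 0),
               0.5, tolerance = 1e-10)
})

test_that("cap volume matches closed forms and conserves the ball", {
  expect_equal(cap_volume(2, 1, 0), pi / 2)
  expect_equal(cap_volume(3, 1, 1), 0)
  h <- 0.5 # height of the cap cut at offset a = 0.5 on the unit sphere
  expect_equal(cap_volume(3, 1, 0.5), pi * h^2 * (3 * 1 - h) / 3,
               tolerance = 1e-12)
  expect_error(cap_volume(3, 1, 1.2), "abs\\(a\\)")
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- sample(1:50, 1)
      rp <- runif(1, 0.3, 3)
      a <- runif(1, -rp, rp)
      expect_equal(cap_volume(p, rp, a) + cap_volume(p, rp, -a),
                   ball_volume(p, rp), tolerance = 1e-10)
    }
  })
})

test_that("intersection volume follows the piecewise cases", {
  expect_identical(intersection_volume(5, 1, 0.3, 2)$volume, 0)
  expect_equal(intersection_volume(4, 1, 0.2, 0.1)$volume, ball_volume(4, 0.2))
  expect_equal(intersection_volume(1, 1, 0.5, 1)$volume, 0.5)
  # cap offsets only evaluated in the lens case
  expect_true(is.na(intersection_volume(5, 1, 0.3, 2)$c1))
  expect_true(is.na(intersection_volume(4, 1, 0.2, 0.1)$c2))
  lens <- intersection_volume(2, 1, 0.8, 1.2)
  expect_equal(lens$c1 + lens$c2, 1.2, tolerance = 1e-12)
  # d = 0 with equal radii resolves through the containment branch
  expect_equal(intersection_volume(3, 1, 1, 0)$volume, ball_volume(3, 1))
  expect_error(intersection_volume(3, -1, 1, 0.5), "non-negative")
})

test_that("intersection volume is symmetric in the two radii", {
  withr::with_seed(21, {
    for (i in 1:25) {
      p <- sample(1:30, 1)
      tr <- random_lens_triple()
      expect_equal(intersection_volume(p, tr$r, tr$ri, tr$d)$volume,
                   intersection_volume(p, tr$ri, tr$r, tr$d)$volume,
                   tolerance = 1e-12)
    }
  })
})

test_that("intersection volume agrees with 1-D/2-D/3-D closed-form oracles", {
  withr::with_seed(31, {
    for (i in 1:40) {
      tr <- random_lens_triple()
      d_cases <- c(tr$d, 0, abs(tr$r - tr$ri) / 2, tr$r + tr$ri + 0.1)
      for (d in d_cases) {
        expect_equal(intersection_volume(1, tr$r, tr$ri, d)$volume,
                     interval_overlap(tr$r, tr$ri, d), tolerance = 1e-8)
        expect_equal(intersection_volume(2, tr$r, tr$ri, d)$volume,
                     lens_area(tr$r, tr$ri, d), tolerance = 1e-8)
        expect_equal(intersection_volume(3, tr$r, tr$ri, d)$volume,
                     sphere_overlap_3d(tr$r, tr$ri, d), tolerance = 1e-8)
      }
    }
  })
})

test_that("containment probability matches Monte-Carlo up to p = 100", {
  cases <- list(list(p = 3, r = 1, ri = 0.8, d = 0.9),
                list(p = 10, r = 1, ri = 0.95, d = 0.5),
                list(p = 50, r = 1, ri = 1.1, d = 0.7),
                list(p = 100, r = 1, ri = 1.3, d = 0.9))
  for (cs in cases) {
    mc <- mc_containment_estimate(cs$p, cs$r, cs$ri, cs$d, n_samples = 2e5,
                                  seed = 101)
    expect_lt(abs(mc$estimate -
                    containment_probability(cs$p, cs$r, cs$ri, cs$d)),
              3 * mc$se + 1e-12)
  }
})

test_that("containment probability is monotone and respects boundaries", {
  withr::with_seed(41, {
    for (i in 1:20) {
      p <- sample(1:40, 1)
      r <- runif(1, 0.5, 2)
      d <- runif(1, 0, 1.5 * r)
      ri <- sort(runif(2, 0.01, d + r))
      expect_lte(containment_probability(p, r, ri[1], d),
                 containment_probability(p, r, ri[2], d) + 1e-12)
      dd <- sort(runif(2, 0, 2 * r))
      rr <- runif(1, 0.1, 2 * r)
      expect_gte(containment_probability(p, r, rr, dd[1]) + 1e-12,
                 containment_probability(p, r, rr, dd[2]))
      expect_identical(containment_probability(p, r, 0, d), 0)
      expect_equal(containment_probability(p, r, d + r, d), 1)
      expect_equal(containment_probability(p, r, d + r + 0.5, d), 1)
    }
  })
})

test_that("containment probability at d = 0 is the radial closed form", {
  withr::with_seed(51, {
    for (i in 1:20) {
      p <- sample(1:60, 1)
      r <- runif(1, 0.5, 2)
      ri <- runif(1, 0, 1.5 * r)
      expect_equal(containment_probability(p, r, ri, 0),
                   (min(ri, r) / r)^p, tolerance = 1e-12)
    }
  })
  expect_error(containment_probability(3, 0, 1, 0.2), "strictly positive")
})

test_that("solve_radius inverts the containment probability", {
  expect_equal(solve_radius(2, 1, 0, 0.1), sqrt(0.1), tolerance = 1e-9)
  expect_identical(solve_radius(7, 1.3, 0.4, 1), 0.4 + 1.3)
  expect_error(solve_radius(3, 1, 0.5, 0), "tau")
  expect_error(solve_radius(3, 1, 0.5, 1.2), "tau")
  ri <- solve_radius(10, 1, 0.5, 0.3)
  expect_equal(containment_probability(10, 1, ri, 0.5), 0.3,
               tolerance = 1e-8)
  mc <- mc_containment_estimate(10, 1, ri, 0.5, n_samples = 2e5, seed = 61)
  expect_lt(abs(mc$estimate - 0.3), 3 * mc$se)
  withr::with_seed(71, {
    for (i in 1:25) {
      p <- sample(1:40, 1)
      r <- runif(1, 0.5, 2)
      d <- runif(1, 0, 2 * r)
      tau <- runif(1, 0.01, 0.99)
      ri <- solve_radius(p, r, d, tau)
      expect_true(ri > 0 && ri <= d + r)
      expect_equal(containment_probability(p, r, ri, d), tau,
                   tolerance = 1e-8)
    }
  })
})
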