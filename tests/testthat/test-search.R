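# The escalating-tau search: exact agreement with brute force, termination,
# candidate accounting, and tie-breaking.

test_that("top-k selection is a full-sort prefix with index tie-break", {
  sel <- top_k_select(c(7L, 2L, 9L), c(3, 1, 2), 2)
  expect_identical(sel$idx, c(2L, 9L))
  expect_identical(sel$dist, c(1, 2))
  tied <- top_k_select(c(5L, 3L, 8L), c(1, 1, 1), 3)
  expect_identical(tied$idx, c(3L, 5L, 8L))
  withr::with_seed(23, {
    idx <- sample.int(1000, 200)
    d <- round(runif(200, 0, 5), 1) # coarse grid forces ties
    sel <- top_k_select(idx, d, 50)
    full <- order(d, idx)
    expect_identical(sel$idx, idx[full][1:50])
  })
  expect_error(top_k_select(1:3, 1:3, 5), "contract violation")
})

test_that("search equals brute force exactly, in order, per distribution", {
  withr::with_seed(29, {
    for (dist in c("spherical_uniform", "mv_normal", "mv_t")) {
      for (k in c(1, 7, 40)) {
        sc <- make_scenario(dist, n = 400, m = 30, p = 8, k_spec = k,
                            seed = sample.int(1e6, 1))
        res <- stnn_search(stnn_index(sc$training), sc$query, sc$k,
                           schedule = sc$schedule)
        ref <- brute_force_knn(sc$training, sc$query, sc$k)
        expect_identical(res$indices, ref$indices)
        expect_identical(res$distances, ref$distances)
      }
    }
  })
})

test_that("edge cases: k = n, coincident query, degenerate training set", {
  withr::with_seed(37, x <- sample_mv_normal(50, 3))
  idx <- stnn_index(x)
  # k = n returns every training row in ascending-distance order
  res <- stnn_search(idx, x[c(1, 25), , drop = FALSE], k = 50)
  ref <- brute_force_knn(x, x[c(1, 25), , drop = FALSE], k = 50)
  expect_identical(res$indices, ref$indices)
  expect_identical(sort(res$indices[1, ]), 1:50)
  # a query equal to a training row finds it first at distance 0
  res1 <- stnn_search(idx, x[7, , drop = FALSE], k = 3)
  expect_identical(res1$indices[1, 1], 7L)
  expect_identical(res1$distances[1, 1], 0)
  # all training rows identical: geometry bypassed, first k rows returned
  flat <- matrix(1, 20, 4)
  resf <- stnn_search(stnn_index(flat), matrix(2, 2, 4), k = 5)
  expect_identical(resf$indices, matrix(rep(1:5, each = 2), 2, 5))
  expect_equal(resf$distances[1, ], rep(2, 5))
  expect_error(stnn_search(idx, x[1, , drop = FALSE], k = 51), "exceed")
})

test_that("sweep terminates within the schedule with k' >= k", {
  withr::with_seed(41, {
    sc <- make_scenario("mv_t", n = 600, m = 40, p = 12, k_spec = 0.05,
                        seed = 99)
    idx <- stnn_index(sc$training)
    res <- stnn_search(idx, sc$query, sc$k, G = 3, schedule = sc$schedule)
    expect_true(all(res$iterations >= 1L &
                      res$iterations <= length(sc$schedule)))
    expect_true(all(res$k_prime >= sc$k))
    # adversarial query far outside the bounding sphere still terminates
    far <- matrix(idx$centroid + c(100 * idx$bounding_radius, rep(0, 11)), 1)
    resf <- stnn_search(idx, far, sc$k, schedule = sc$schedule)
    expect_lte(resf$iterations[1], length(sc$schedule))
    expect_identical(resf$indices,
                     brute_force_knn(sc$training, far, sc$k)$indices)
  })
})

test_that("at most G x t group equations are solved, lazily", {
  withr::with_seed(43, {
    sc <- make_scenario("spherical_uniform", n = 500, m = 60, p = 10,
                        k_spec = 0.05, seed = 7)
    for (G in c(1L, 4L)) {
      res <- stnn_search(stnn_index(sc$training), sc$query, sc$k, G = G,
                         schedule = sc$schedule)
      expect_lte(res$n_equations, G * length(sc$schedule))
      # mostly one iteration -> far fewer than the cap actually solved
      expect_lte(res$n_equations, G * max(res$iterations))
    }
  })
})

test_that("results are invariant to the number of ring groups", {
  withr::with_seed(47, {
    for (dist in c("spherical_uniform", "mv_normal")) {
      sc <- make_scenario(dist, n = 500, m = 40, p = 10, k_spec = 0.03,
                          seed = 1234)
      idx <- stnn_index(sc$training)
      base <- stnn_search(idx, sc$query, sc$k, G = 1, schedule = sc$schedule)
      for (G in c(2L, 5L, 10L)) {
        alt <- stnn_search(idx, sc$query, sc$k, G = G, schedule = sc$schedule)
        expect_identical(alt$indices, base$indices)
        expect_identical(alt$distances, base$distances)
      }
    }
  })
})

test_that("a tidy result table round-trips indices and ranks", {
  withr::with_seed(53, {
    x <- sample_mv_normal(100, 4)
    q <- sample_mv_normal(6, 4)
  })
  res <- stnn_search(stnn_index(x), q, k = 3)
  df <- as.data.frame(res)
  expect_identical(nrow(df), 18L)
  expect_identical(df$train_index[df$query_id == 2], res$indices[2, ])
  expect_true(all(tapply(df$distance, df$query_id, function(d)
    !is.unsorted(d))))
})
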