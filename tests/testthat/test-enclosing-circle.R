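test_that("degenerate point sets give the obvious circles", {
  one <- smallest_enclosing_circle(rbind(c(3, 4)))
  expect_equal(one$center, c(3, 4))
  expect_equal(one$radius, 0)

  two <- smallest_enclosing_circle(rbind(c(0, 0), c(2, 0)))
  expect_equal(two$center, c(1, 0))
  expect_equal(two$radius, 1)

  expect_error(smallest_enclosing_circle(matrix(numeric(0), 0, 2)), "empty")
})

test_that("matches the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    p <- matrix(stats::runif(2 * n, 0, 100), n, 2)
    mec <- smallest_enclosing_circle(p)
    bf <- brute_force_mec(p)
    expect_equal(mec$radius, bf$radius, tolerance = 1e-9)
    # every point must be inside
    d <- sqrt((p[, 1] - mec$center[1])^2 + (p[, 2] - mec$center[2])^2)
    expect_true(all(d <= mec$radius + 1e-8))
  }
})

test_that("result is deterministic and order-independent in radius", {
  set.seed(7)
  p <- matrix(stats::rnorm(40), 20, 2)
  a <- smallest_enclosing_circle(p)
  b <- smallest_enclosing_circle(p[rev(seq_len(20)), ])
  expect_equal(a$radius, b$radius, tolerance = 1e-12)
  expect_identical(smallest_enclosing_circle(p), smallest_enclosing_circle(p))
})
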