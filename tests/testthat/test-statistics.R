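test_that("influence moments use the population variance convention", {
  even <- influence_moments(c(1, 1, 1, 1))
  expect_equal(even$k_bar, 1)
  expect_equal(even$sigma2, 0)

  skew <- influence_moments(c(4, 0, 0, 0))
  expect_equal(skew$k_bar, 1)
  expect_equal(skew$sigma2, 3)  # = (N-1)/R for N = 4, R = 1

  mixed <- influence_moments(c(2, 0, 1, 1))
  expect_equal(mixed$k_bar, 1)
  expect_equal(mixed$sigma2, 0.5)
  expect_error(influence_moments(numeric(0)), "non-empty")
})

test_that("inbreeding and variance Ne separate in the two-parent thought experiment", {
  m <- tibble::tibble(k_bar = 500, sigma2 = 250, pool_size = 2)
  expect_equal(inbreeding_ne(m), 999 / 499.5)  # = 2: offspring often share a parent
  expect_equal(variance_ne(m), 1000)           # frequencies still near 50%
})

test_that("both effective sizes collapse to (N-1)/sigma2 when k_bar is 1", {
  set.seed(61)
  for (i in 1:20) {
    pool <- sample(5:500, 1)
    sigma2 <- runif(1, 0.1, 5)
    m <- tibble::tibble(k_bar = 1, sigma2 = sigma2, pool_size = pool)
    expect_equal(inbreeding_ne(m), (pool - 1) / sigma2)
    expect_equal(variance_ne(m), (pool - 1) / sigma2)
    expect_equal(simple_ne(pool, sigma2), (pool - 1) / sigma2)
  }
})

test_that("undefined effective sizes are flagged as NA, not numbers", {
  expect_true(is.na(variance_ne(tibble::tibble(k_bar = 1, sigma2 = 0,
                                               pool_size = 10))))
  expect_true(is.na(inbreeding_ne(tibble::tibble(k_bar = 0.5, sigma2 = 0.1,
                                                 pool_size = 10))))
  expect_true(is.na(simple_ne(1000, 0)))
  expect_error(simple_ne(1, 1), "at least 2")
  expect_error(simple_ne(10, -1), "non-negative")
})

test_that("the exchange closed form follows from the Ne formulas", {
  n <- 1000; e <- 0.5
  pool <- n * (1 + e)
  k_bar <- 1 / (1 + e)
  sigma2 <- n * (1 / pool) * (1 - 1 / pool)  # binomial copying from the pool
  m <- tibble::tibble(k_bar = k_bar, sigma2 = sigma2, pool_size = pool)
  expect_equal(inbreeding_ne(m), (n - 1) * (1 + e), tolerance = 0.002)
  expect_equal(variance_ne(m), n, tolerance = 0.002)
})

test_that("harmonic-mean Ne is dominated by bottleneck generations", {
  expect_equal(harmonic_mean_ne(c(10, rep(1000, 9))), 91.74311927,
               tolerance = 1e-8)
  expect_equal(harmonic_mean_ne(rep(500, 10)), 500)
  expect_equal(harmonic_mean_ne(73), 73)
  expect_error(harmonic_mean_ne(numeric(0)), "non-empty")
  expect_error(harmonic_mean_ne(c(10, 0)), "at least 1")
  # harmonic <= arithmetic, equality iff constant
  set.seed(62)
  for (i in 1:10) {
    sizes <- sample(1:1000, 5)
    expect_lte(harmonic_mean_ne(sizes), mean(sizes))
  }
  expect_lt(harmonic_mean_ne(c(10, 1000)), mean(c(10, 1000)))
})

test_that("Simpson diversity spans single-variant to all-distinct populations", {
  expect_equal(simpson_index(5), 0)
  expect_equal(simpson_index(c(50, 50)), 0.5)
  expect_equal(simpson_index(c(2, 1, 1)), 0.625)
  expect_equal(simpson_index(culture_pop(20)), 1 - 1 / 20)  # maximal
  # invariant under relabeling
  p1 <- culture_pop(variants = c(1, 1, 2, 3))
  p2 <- culture_pop(variants = c(9, 9, 4, 7))
  expect_equal(simpson_index(p1), simpson_index(p2))
  expect_equal(unique_count(c(2, 3)), 2)
  expect_equal(unique_count(culture_pop(variants = rep(1, 5))), 1)
  expect_error(simpson_index(numeric(0)), "positive")
})

test_that("replicate summaries report the mean and 90% prediction interval", {
  s <- summarize_replicates(1:100)
  expect_equal(s$mean, 50.5)
  expect_equal(s$lower, 5.95)
  expect_equal(s$upper, 95.05)

  const <- summarize_replicates(rep(7, 10))
  expect_equal(const$mean, 7)
  expect_equal(const$lower, 7)
  expect_equal(const$upper, 7)

  two <- summarize_replicates(c(0, 10))
  expect_gte(two$lower, 0)
  expect_lte(two$upper, 10)
  expect_equal(two$mean, 5)
  expect_error(summarize_replicates(c(1, NA)), "at least two")
})
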