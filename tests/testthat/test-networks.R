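test_that("graph construction rejects self-loops and duplicate edges", {
  expect_error(culture_graph(rbind(c(1, 1)), n = 3), "self-loops")
  expect_error(culture_graph(rbind(c(1, 2), c(2, 1)), n = 3), "duplicate")
  expect_error(culture_graph(rbind(c(1, 4)), n = 3), "endpoints")
  g <- culture_graph(rbind(c(1, 2), c(2, 3)), n = 4)
  expect_equal(graph_degrees(g), c(1, 2, 1, 0))
})

test_that("random graphs hit their boundary cases and expected density", {
  set.seed(51)
  expect_equal(nrow(graph_erdos_renyi(10, 0)$edges), 0)
  expect_equal(nrow(graph_erdos_renyi(10, 1)$edges), 45)  # N(N-1)/2
  degs <- unlist(lapply(1:5, function(i) graph_degrees(graph_erdos_renyi(500, 0.1))))
  expect_equal(mean(degs), 499 * 0.1, tolerance = 0.03)
  expect_error(graph_erdos_renyi(10, 1.2), "p")
})

test_that("scale-free growth has exact edge counts and power-controlled tails", {
  set.seed(52)
  for (power in c(0, 1, 3)) {
    g <- graph_barabasi_albert(200, power)
    expect_equal(nrow(g$edges), 2 * (200 - 2) + 1)
  }
  strong <- graph_barabasi_albert(500, 3)
  expect_gt(max(graph_degrees(strong)), 0.9 * 500)  # near-star
  uniform <- graph_barabasi_albert(500, 0)
  expect_lt(max(graph_degrees(uniform)), 0.2 * 500)  # light-tailed
  expect_error(graph_barabasi_albert(2, 1), "at least 3")
})

test_that("small-world rewiring preserves the N*K edge count", {
  set.seed(53)
  ring <- graph_watts_strogatz(100, 2, 0)
  expect_true(all(graph_degrees(ring) == 4))  # 2K
  expect_equal(nrow(ring$edges), 200)         # N*K

  scrambled <- graph_watts_strogatz(100, 2, 1)
  expect_equal(nrow(scrambled$edges), 200)
  expect_gt(stats::var(graph_degrees(scrambled)), 0)

  # expected number of rewired edges ~ Binomial(N*K, p_r)
  lattice_key <- function(g) {
    paste(pmin(g$edges[, 1], g$edges[, 2]), pmax(g$edges[, 1], g$edges[, 2]))
  }
  base <- lattice_key(graph_watts_strogatz(500, 4, 0))
  moved <- vapply(1:5, function(i) {
    sum(!lattice_key(graph_watts_strogatz(500, 4, 0.05)) %in% base)
  }, numeric(1))
  expect_equal(mean(moved), 2000 * 0.05, tolerance = 0.25)
  expect_error(graph_watts_strogatz(10, 5, 0.1), "k")
})

test_that("on a star every leaf copies the hub and the hub copies a leaf", {
  set.seed(54)
  star <- culture_graph(cbind(1, 2:6), n = 6)
  pop <- culture_pop(6)
  s <- step_network(pop, star, mu = 0)
  expect_equal(s$population$variants[2:6], rep(1, 5))  # leaves adopt the hub's variant
  expect_true(s$population$variants[1] %in% 2:6)
  expect_equal(unclass(s$counts)[1], 5)
  # counts are 5 (hub), 1 (one leaf), 0 x 4: population variance = 20/6
  m <- influence_moments(s$counts)
  expect_equal(m$k_bar, 1)
  expect_equal(m$sigma2, (16 + 0 + 4) / 6)
})

test_that("isolated nodes retain their variant and influence is conserved", {
  set.seed(55)
  empty <- culture_graph(matrix(integer(0), ncol = 2), n = 8)
  pop <- culture_pop(8)
  s <- step_network(pop, empty, mu = 0)
  expect_equal(s$population$variants, pop$variants)
  expect_equal(as.numeric(s$counts), rep(1, 8))
  expect_equal(sum(unclass(s$counts)) + attr(s$counts, "n_innovators"), 8)

  one <- culture_pop(variants = rep(9, 8))
  ring <- graph_watts_strogatz(8, 1, 0)
  expect_equal(step_network(one, ring, mu = 0)$population$variants, rep(9, 8))
  expect_error(step_network(culture_pop(5), ring, 0), "census")
})

test_that("a complete graph behaves like unbiased copying with self excluded", {
  set.seed(56)
  n <- 50
  g <- graph_erdos_renyi(n, 1)
  pop <- culture_pop(n)
  sig <- numeric(1500)
  for (i in seq_along(sig)) {
    s <- step_network(pop, g, mu = 0)
    sig[i] <- influence_moments(s$counts)$sigma2
    pop <- s$population
  }
  # each parent is copied Binomial(N-1, 1/(N-1)) times
  expect_equal(mean(sig), 1 - 1 / (n - 1), tolerance = 0.02)
  expect_equal(mean((n - 1) / sig), n, tolerance = 0.06)
})

test_that("graphs round-trip through the 0-based edge-list format", {
  set.seed(57)
  g <- graph_watts_strogatz(30, 2, 0.2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_edgelist(g, path)
  first <- scan(path, what = integer(), n = 2, quiet = TRUE)
  expect_true(all(first >= 0 & first < 30))  # 0-based on disk
  back <- read_edgelist(path, n = 30)
  expect_equal(graph_degrees(back), graph_degrees(g))
  expect_equal(nrow(back$edges), nrow(g$edges))
})
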