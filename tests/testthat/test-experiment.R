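test_that("invalid configurations are rejected with the offending field named", {
  expect_error(experiment_config("one_to_many", n = 100, mu = 1e-4), "r_models")
  expect_error(experiment_config("frequency_dependent", n = 100, mu = 1e-4),
               "theta")
  expect_error(experiment_config("migration", n = 100, mu = 0, m = 2), "m")
  expect_error(experiment_config("network_ws", n = 100, mu = 0, k = 4),
               "p_rewire")
  expect_error(experiment_config("unbiased", n = 1, mu = 0), "n")
  expect_error(experiment_config("unbiased", n = 100, mu = 0, generations = 0),
               "generations")
  expect_error(experiment_config("nosuchmode", n = 100, mu = 0))
})

test_that("identical configurations reproduce bit-identical records", {
  cfg <- experiment_config("frequency_dependent", n = 60, mu = 0.01,
                           theta = 1.5, burn_in = 40, generations = 15,
                           replicates = 4, seed = 99)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # and a different seed gives different draws
  cfg2 <- experiment_config("frequency_dependent", n = 60, mu = 0.01,
                            theta = 1.5, burn_in = 40, generations = 15,
                            replicates = 4, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(run_experiment(cfg2))))
})

test_that("without innovation the variant count can only decay", {
  cfg <- experiment_config("unbiased", n = 100, mu = 0, burn_in = 0,
                           generations = 10, replicates = 3, seed = 7)
  x <- run_experiment(cfg)
  for (r in split(x, x$replicate)) {
    expect_true(all(diff(r$unique) <= 0))
  }
})

test_that("burn-in of zero generations leaves the state untouched", {
  pop <- culture_pop(12)
  expect_equal(burn_in(pop, 0, mu = 0.1), pop)
  meta <- metapopulation(5, 5)
  after <- burn_in(meta, 3, mu = 0.5)
  expect_equal(after$pop_a$next_label, after$pop_b$next_label)
  expect_true(all(after$pop_a$variants < after$pop_a$next_label))
})

test_that("experiment records carry the full per-generation schema", {
  cfg <- experiment_config("exchange", n = 30, mu = 0.01, e = 0.3,
                           burn_in = 20, generations = 8, replicates = 3,
                           seed = 5)
  x <- run_experiment(cfg)
  expect_s3_class(x, "culture_experiment")
  expect_equal(nrow(x), 3 * 8 * 2)  # replicates x generations x demes
  expect_true(all(c("replicate", "generation", "deme", "k_bar", "sigma2",
                    "pool_size", "offspring_size", "nei", "nev", "ne_simple",
                    "simpson", "unique") %in% names(x)))
  s <- summarize_experiment(x)
  expect_true(all(s$lower <= s$mean + 1e-12 & s$mean <= s$upper + 1e-12))
  expect_s3_class(tidy(x), "tbl_df")
  g <- glance(x)
  expect_equal(g$mode, "exchange")
  expect_equal(g$replicates, 3)
})

test_that("sweeps add the swept column and a single replicate degenerates cleanly", {
  cfg <- experiment_config("one_to_many", n = 40, mu = 0, r_models = 1,
                           burn_in = 0, generations = 5, replicates = 2,
                           seed = 3)
  sw <- run_sweep(cfg, "r_models", c(1, 40))
  expect_setequal(unique(sw$r_models), c(1, 40))
  s <- summarize_experiment(sw, stats = "ne_simple")
  expect_equal(nrow(s), 2)
  expect_equal(s$mean[s$r_models == 1], 1)  # Ne = 1 exactly at R = 1, mu = 0

  one <- experiment_config("unbiased", n = 30, mu = 0.01, burn_in = 5,
                           generations = 5, replicates = 1, seed = 2)
  s1 <- summarize_experiment(run_experiment(one), stats = "simpson")
  expect_equal(s1$lower, s1$mean)
  expect_equal(s1$upper, s1$mean)
  expect_error(run_sweep(cfg, "bogus", 1:2), "unknown configuration field")
})

test_that("experiment outputs round-trip through the output directory", {
  cfg <- experiment_config("unbiased", n = 25, mu = 0.02, burn_in = 10,
                           generations = 6, replicates = 3, seed = 8)
  x <- run_experiment(cfg)
  dir <- withr::local_tempdir()
  write_experiment(x, dir)
  expect_true(all(file.exists(file.path(dir, c("records.csv", "summary.csv",
                                               "meta.json")))))
  back <- readr::read_csv(file.path(dir, "records.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(x))
  expect_equal(back$ne_simple, x$ne_simple)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$config$seed, 8)
})

test_that("autoplot and plot_drift build ggplot objects", {
  cfg <- experiment_config("unbiased", n = 20, mu = 0.05, burn_in = 5,
                           generations = 5, replicates = 3, seed = 4)
  p <- ggplot2::autoplot(run_experiment(cfg), statistic = "simpson")
  expect_s3_class(p, "ggplot")
  set.seed(1)
  expect_s3_class(plot_drift(20, replicates = 3, generations = 10), "ggplot")
})
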