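MODES <- c("unbiased", "one_to_many", "frequency_dependent", "migration",
           "exchange", "influx", "network_er", "network_ba", "network_ws")

#' Specify a simulation experiment
#'
#' Bundles every parameter of one experiment: transmission mode, census size,
#' innovation rate, the mode's own parameters, burn-in length, number of
#' recorded generations, replicate count and master seed. Replicates are
#' independently seeded from the master seed so any single replicate is
#' reproducible in isolation; identical configurations produce bit-identical
#' result tables.
#'
#' Burn-in defaults to `4 * n` generations of unbiased transmission (the
#' population turnover timescale is of order `n` generations). Network modes
#' burn in under the network-constrained dynamic itself, since the network is
#' the population's permanent structure; two-population modes burn in each
#' deme in isolation before coupling.
#'
#' @param mode One of `r paste0('"', MODES, '"', collapse = ", ")`.
#' @param n Census size (for two-population modes, the size of each deme; for
#'   `"influx"`, the initial focal size).
#' @param mu Innovation probability in `[0, 1]`.
#' @param r_models One-to-many: number of role models per generation.
#' @param theta Frequency dependence exponent; the burn-in always runs
#'   unbiased (`theta = 1`) and generation 1 is the first to use `theta`.
#' @param m,e Migration / cultural exchange rate in `[0, 1]`.
#' @param influx_count,n_source Influx: immigrants per generation and source
#'   census size.
#' @param p,power,k,p_rewire Network parameters (Erdos-Renyi edge
#'   probability; Barabasi-Albert attachment power; Watts-Strogatz neighbours
#'   per side and rewiring probability). A fresh graph is drawn per replicate
#'   and kept fixed across its generations.
#' @param burn_in Burn-in generations (default `4 * n`).
#' @param generations Recorded generations (default 300).
#' @param replicates Independent replicates (default 1000).
#' @param seed Master seed (positive integer).
#' @param fixed_count Use deterministic migrant/borrower counts
#'   `round(rate * n)` instead of binomial draws.
#' @return A `culture_config` list.
#' @examples
#' experiment_config("one_to_many", n = 100, mu = 1e-4, r_models = 10,
#'                   generations = 50, replicates = 10, seed = 1)
#' @export
experiment_config <- function(mode, n, mu, r_models = NULL, theta = NULL,
                              m = NULL, e = NULL, influx_count = NULL,
                              n_source = NULL, p = NULL, power = NULL,
                              k = NULL, p_rewire = NULL, burn_in = NULL,
                              generations = 300, replicates = 1000, seed = 1,
                              fixed_count = FALSE) {
  mode <- match.arg(mode, MODES)
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("field `n`: census size must be a whole number >= 2")
  }
  check_mu(mu)
  if (!is.numeric(generations) || generations < 1) {
    stop("field `generations`: at least one recorded generation is required")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("field `replicates`: at least one replicate is required")
  }
  if (is.null(burn_in)) burn_in <- 4 * n
  if (!is.numeric(burn_in) || burn_in < 0) {
    stop("field `burn_in`: burn-in generations must be >= 0")
  }
  need <- function(value, field) {
    if (is.null(value)) {
      stop(sprintf("field `%s` is required for mode \"%s\"", field, mode),
           call. = FALSE)
    }
    value
  }
  switch(mode,
    one_to_many = check_otm(n, need(r_models, "r_models")),
    frequency_dependent = check_theta(need(theta, "theta")),
    migration = check_rate(need(m, "m"), "m"),
    exchange = check_rate(need(e, "e"), "e"),
    influx = {
      need(influx_count, "influx_count")
      if (is.null(n_source)) n_source <- 100 * n
      if (influx_count < 0 || influx_count > n_source) {
        stop("field `influx_count`: must lie between 0 and `n_source`")
      }
    },
    network_er = check_rate(need(p, "p"), "p"),
    network_ba = need(power, "power"),
    network_ws = {
      need(k, "k"); check_rate(need(p_rewire, "p_rewire"), "p_rewire")
    },
    NULL)
  structure(list(mode = mode, n = as.integer(n), mu = mu,
                 r_models = r_models, theta = theta, m = m, e = e,
                 influx_count = influx_count, n_source = n_source,
                 p = p, power = power, k = k, p_rewire = p_rewire,
                 burn_in = as.integer(burn_in),
                 generations = as.integer(generations),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), fixed_count = fixed_count),
            class = "culture_config")
}

#' @export
print.culture_config <- function(x, ...) {
  pars <- x[!vapply(x, is.null, logical(1))]
  cat("<culture_config>\n")
  for (nm in names(pars)) cat(sprintf("  %s: %s\n", nm, format(pars[[nm]])))
  invisible(x)
}

#' Equilibrate a population under unbiased dynamics
#'
#' Runs the stated number of unperturbed generations before measurement:
#' unbiased transmission for bare populations (the full parental pool is the
#' role-model set), network-constrained unbiased copying when a graph is
#' supplied, and isolated unbiased evolution of each deme for a
#' metapopulation.
#'
#' @param x A [culture_pop()] or [metapopulation()].
#' @param generations Number of burn-in generations (`>= 0`).
#' @param mu Innovation probability.
#' @param graph Optional [culture_graph()] constraining transmission.
#' @return The equilibrated object, same class as `x`.
#' @export
burn_in <- function(x, generations, mu, graph = NULL) {
  stopifnot(is.numeric(generations), generations >= 0)
  mu <- check_mu(mu)
  if (inherits(x, "culture_meta")) {
    x$pop_a <- burn_in(x$pop_a, generations, mu)
    x$pop_b <- burn_in(x$pop_b, generations, mu)
    shared <- max(x$pop_a$next_label, x$pop_b$next_label)
    x$pop_a$next_label <- shared
    x$pop_b$next_label <- shared
    return(x)
  }
  check_pop(x)
  v <- x$variants; nl <- x$next_label
  for (g in seq_len(generations)) {
    s <- if (is.null(graph)) kernel_unbiased(v, nl, mu) else
      kernel_network(v, nl, graph, mu)
    v <- s$variants; nl <- s$next_label
  }
  culture_pop(variants = v, next_label = nl)
}

# one row of per-generation statistics, as a bare numeric vector
REC_COLS <- c("k_bar", "sigma2", "pool_size", "offspring_size",
              "nei", "nev", "ne_simple", "simpson", "unique")

stat_vec <- function(counts, pool, offspring, v) {
  k_bar <- sum(counts) / pool
  sigma2 <- sum((counts - k_bar)^2) / pool
  den <- k_bar - 1 + sigma2 / k_bar
  uv <- unique(v)
  cnt <- tabulate(match(v, uv), length(uv))
  c(k_bar, sigma2, pool, offspring,
    if (is.finite(den) && den > 0) (pool * k_bar - 1) / den else NA_real_,
    if (sigma2 > 0) (pool - 1) * k_bar^2 / sigma2 else NA_real_,
    if (sigma2 > 0) (pool - 1) / sigma2 else NA_real_,
    1 - sum((cnt / length(v))^2),
    length(uv))
}

replicate_single <- function(cfg) {
  n <- cfg$n
  graph <- switch(cfg$mode,
    network_er = graph_erdos_renyi(n, cfg$p),
    network_ba = graph_barabasi_albert(n, cfg$power),
    network_ws = graph_watts_strogatz(n, cfg$k, cfg$p_rewire),
    NULL)
  v <- as.numeric(seq_len(n)); nl <- n + 1
  for (g in seq_len(cfg$burn_in)) {
    s <- if (is.null(graph)) kernel_unbiased(v, nl, cfg$mu) else
      kernel_network(v, nl, graph, cfg$mu)
    v <- s$variants; nl <- s$next_label
  }
  res <- matrix(NA_real_, cfg$generations, length(REC_COLS))
  for (g in seq_len(cfg$generations)) {
    s <- switch(cfg$mode,
      unbiased = kernel_unbiased(v, nl, cfg$mu),
      one_to_many = kernel_one_to_many(v, nl, cfg$r_models, cfg$mu),
      frequency_dependent = kernel_frequency(v, nl, cfg$theta, cfg$mu),
      kernel_network(v, nl, graph, cfg$mu))
    v <- s$variants; nl <- s$next_label
    res[g, ] <- stat_vec(s$counts, s$pool_size, length(v), v)
  }
  res
}

replicate_two_pop <- function(cfg) {
  meta <- metapopulation(cfg$n, cfg$n)
  meta <- burn_in(meta, cfg$burn_in, cfg$mu)
  res <- matrix(NA_real_, 2 * cfg$generations, length(REC_COLS))
  for (g in seq_len(cfg$generations)) {
    s <- if (cfg$mode == "migration") {
      step_migration(meta, cfg$m, cfg$mu, cfg$fixed_count)
    } else {
      step_exchange(meta, cfg$e, cfg$mu, cfg$fixed_count)
    }
    meta <- s$metapopulation
    res[2 * g - 1, ] <- stat_vec(unclass(s$counts_a),
                                 attr(s$counts_a, "pool_size"), cfg$n,
                                 meta$pop_a$variants)
    res[2 * g, ] <- stat_vec(unclass(s$counts_b),
                             attr(s$counts_b, "pool_size"), cfg$n,
                             meta$pop_b$variants)
  }
  res
}

replicate_influx <- function(cfg) {
  source <- culture_pop(variants = seq_len(cfg$n_source),
                        next_label = cfg$n_source + cfg$n + 1)
  focal <- culture_pop(variants = cfg$n_source + seq_len(cfg$n),
                       next_label = cfg$n_source + cfg$n + 1)
  source <- burn_in(source, cfg$burn_in, cfg$mu)
  focal <- burn_in(focal, cfg$burn_in, cfg$mu)
  res <- matrix(NA_real_, cfg$generations, length(REC_COLS))
  for (g in seq_len(cfg$generations)) {
    s <- step_influx(source, focal, cfg$influx_count, cfg$mu)
    source <- s$source; focal <- s$focal
    res[g, ] <- stat_vec(unclass(s$counts), attr(s$counts, "pool_size"),
                         census_size(focal), focal$variants)
  }
  res
}

#' Run a replicated simulation experiment
#'
#' Executes the configured experiment: for each replicate a fresh seed (and,
#' for network modes, a fresh graph), the burn-in, then the recorded
#' generations under the configured transmission mode, with one row of
#' statistics per generation (per deme for two-population modes).
#'
#' @param config A [experiment_config()].
#' @return A tibble of class `culture_experiment` with columns `replicate`,
#'   `generation`, `deme` (two-population modes only), `k_bar`, `sigma2`,
#'   `pool_size`, `offspring_size`, `nei`, `nev`, `ne_simple`, `simpson` and
#'   `unique`. `nei`/`nev`/`ne_simple` are `NA` for generations where the
#'   formula is undefined. The configuration is attached as attribute
#'   `config`.
#' @examples
#' cfg <- experiment_config("unbiased", n = 50, mu = 0.01, burn_in = 50,
#'                          generations = 20, replicates = 3, seed = 42)
#' run_experiment(cfg)
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "culture_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(2^31 - 2, config$replicates)
  two_pop <- config$mode %in% c("migration", "exchange")
  worker <- switch(config$mode,
    migration = replicate_two_pop, exchange = replicate_two_pop,
    influx = replicate_influx, replicate_single)
  out <- purrr::map(seq_len(config$replicates), function(r) {
    set.seed(rep_seeds[r])
    res <- worker(config)
    colnames(res) <- REC_COLS
    df <- tibble::as_tibble(res)
    if (two_pop) {
      df <- tibble::add_column(df,
        replicate = r,
        generation = rep(seq_len(config$generations), each = 2),
        deme = rep(c("a", "b"), config$generations), .before = 1)
    } else {
      df <- tibble::add_column(df, replicate = r,
                               generation = seq_len(config$generations),
                               .before = 1)
    }
    df
  })
  out <- dplyr::bind_rows(out)
  attr(out, "config") <- config
  class(out) <- c("culture_experiment", class(out))
  out
}

#' Sweep one parameter of an experiment
#'
#' Re-runs an experiment for every value of one configuration field, binding
#' the results with an added column named after the swept parameter. Each
#' value gets its own master seed derived from the configuration seed, so the
#' sweep is reproducible end to end.
#'
#' @param config A [experiment_config()] providing all other fields.
#' @param param Name of the configuration field to sweep (e.g. `"r_models"`,
#'   `"theta"`, `"mu"`, `"m"`, `"e"`, `"p"`, `"power"`, `"k"`).
#' @param values Vector of values for `param`.
#' @return A `culture_experiment` tibble with the extra sweep column; the
#'   swept parameter name is attached as attribute `sweep_param`.
#' @export
run_sweep <- function(config, param, values) {
  stopifnot(inherits(config, "culture_config"))
  if (!param %in% names(config)) {
    stop(sprintf("unknown configuration field `%s`", param))
  }
  out <- purrr::map(seq_along(values), function(i) {
    cfg <- unclass(config)
    cfg[[param]] <- values[i]
    cfg$seed <- (config$seed + i * 1000003L) %% (2^31 - 1)
    cfg <- do.call(experiment_config, cfg[!vapply(cfg, is.null, logical(1))])
    res <- run_experiment(cfg)
    res[[param]] <- values[i]
    res
  })
  out <- dplyr::bind_rows(out)
  attr(out, "config") <- config
  attr(out, "sweep_param") <- param
  class(out) <- c("culture_experiment", class(out))
  out
}

group_cols <- function(x) {
  intersect(c(attr(x, "sweep_param"), "deme"), names(x))
}

#' Summarise an experiment across replicates
#'
#' Averages each requested statistic over the recorded generations within a
#' replicate (generations where an estimator is undefined are excluded), then
#' reports the across-replicate mean and 90% prediction interval (5th/95th
#' percentiles), per swept parameter value and deme where applicable.
#'
#' @param x A `culture_experiment` from [run_experiment()] or [run_sweep()].
#' @param stats Character vector of statistic columns to summarise.
#' @return A tibble with the grouping columns plus `statistic`, `mean`,
#'   `lower`, `upper`.
#' @export
summarize_experiment <- function(x, stats = c("nei", "nev", "ne_simple",
                                              "simpson", "unique")) {
  stopifnot(inherits(x, "culture_experiment"))
  gc <- group_cols(x)
  long <- tidyr::pivot_longer(
    dplyr::select(x, dplyr::all_of(c(gc, "replicate", stats))),
    dplyr::all_of(stats), names_to = "statistic", values_to = "value")
  per_rep <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(gc, "statistic",
                                                        "replicate")))),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_rep,
                    dplyr::across(dplyr::all_of(c(gc, "statistic")))),
    mean = mean(.data$value),
    lower = stats::quantile(.data$value, 0.05, names = FALSE),
    upper = stats::quantile(.data$value, 0.95, names = FALSE),
    .groups = "drop")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an experiment into its replicate summary
#'
#' `tidy()` is [summarize_experiment()]; `glance()` returns a one-row
#' overview of the run.
#'
#' @param x A `culture_experiment`.
#' @param ... Passed to [summarize_experiment()].
#' @return A tibble.
#' @export
tidy.culture_experiment <- function(x, ...) summarize_experiment(x, ...)

#' @rdname tidy.culture_experiment
#' @export
glance.culture_experiment <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(mode = cfg$mode, n = cfg$n, mu = cfg$mu,
                 replicates = cfg$replicates, generations = cfg$generations,
                 burn_in = cfg$burn_in,
                 mean_ne = mean(x$ne_simple, na.rm = TRUE),
                 mean_nei = mean(x$nei, na.rm = TRUE),
                 mean_nev = mean(x$nev, na.rm = TRUE),
                 mean_simpson = mean(x$simpson),
                 mean_unique = mean(x$unique))
}

#' Write experiment outputs to a directory
#'
#' Writes `records.csv` (the per-generation table), `summary.csv` (the
#' replicate summary) and `meta.json` (the full configuration, seed, package
#' version and a timestamp, kept out of the CSVs so repeated runs produce
#' byte-identical tables).
#'
#' @param x A `culture_experiment`.
#' @param dir Output directory (created if missing).
#' @return `x`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "culture_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(x), file.path(dir, "records.csv"))
  readr::write_csv(summarize_experiment(x), file.path(dir, "summary.csv"))
  cfg <- attr(x, "config")
  meta <- list(config = cfg[!vapply(cfg, is.null, logical(1))],
               sweep_param = attr(x, "sweep_param"),
               package_version = as.character(utils::packageVersion("cultne")),
               written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(x)
}
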