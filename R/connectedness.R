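#' Two connected cultural populations
#'
#' A metapopulation couples two populations that share one innovation
#' counter, so labels stay globally unique and a variant observed in both
#' demes always traces back to a single innovation event.
#'
#' @param n_a,n_b Census sizes of demes "a" and "b". Both start with all
#'   labels distinct, across demes as well as within.
#' @param pop_a,pop_b Alternatively, existing [culture_pop()] objects; their
#'   label sets must be compatible with a shared counter.
#' @return An object of class `culture_meta` with elements `pop_a`, `pop_b`.
#' @export
metapopulation <- function(n_a, n_b = n_a, pop_a = NULL, pop_b = NULL) {
  if (is.null(pop_a) != is.null(pop_b)) {
    stop("supply either both populations or neither")
  }
  if (is.null(pop_a)) {
    pop_a <- culture_pop(variants = seq_len(n_a), next_label = n_a + n_b + 1)
    pop_b <- culture_pop(variants = n_a + seq_len(n_b),
                         next_label = n_a + n_b + 1)
  } else {
    check_pop(pop_a); check_pop(pop_b)
    shared <- max(pop_a$next_label, pop_b$next_label)
    pop_a$next_label <- shared
    pop_b$next_label <- shared
  }
  structure(list(pop_a = pop_a, pop_b = pop_b), class = "culture_meta")
}

#' @export
print.culture_meta <- function(x, ...) {
  cat(sprintf("<culture_meta> demes of %d and %d, next label %s\n",
              census_size(x$pop_a), census_size(x$pop_b),
              format(x$pop_a$next_label, scientific = FALSE)))
  invisible(x)
}

check_rate <- function(rate, name) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0 ||
      rate > 1) {
    stop(sprintf("`%s` must be a single rate in [0, 1]", name), call. = FALSE)
  }
  rate
}

n_moved <- function(n, rate, fixed_count) {
  if (fixed_count) round(n * rate) else stats::rbinom(1, n, rate)
}

#' Swap migrants between the two demes
#'
#' Draws the number of migrants X (binomially as `Binomial(N, m)`, or exactly
#' `round(m * N)` with `fixed_count = TRUE`) and exchanges disjoint uniformly
#' chosen sets of X individuals symmetrically, so both census sizes are
#' unchanged. Migrants carry their variants with them permanently.
#'
#' @param meta A [metapopulation()] with equal-sized demes.
#' @param m Migration rate in `[0, 1]`.
#' @param fixed_count Use the deterministic count `round(m * N)` instead of a
#'   binomial draw.
#' @return The post-migration `culture_meta`.
#' @export
swap_migrants <- function(meta, m, fixed_count = FALSE) {
  stopifnot(inherits(meta, "culture_meta"))
  check_rate(m, "m")
  n <- census_size(meta$pop_a)
  if (census_size(meta$pop_b) != n) {
    stop("migration requires equal-sized demes")
  }
  x <- n_moved(n, m, fixed_count)
  if (x > 0) {
    ia <- sample.int(n, x)
    ib <- sample.int(n, x)
    moved_a <- meta$pop_a$variants[ia]
    meta$pop_a$variants[ia] <- meta$pop_b$variants[ib]
    meta$pop_b$variants[ib] <- moved_a
  }
  meta
}

meta_package <- function(a, b, next_label) {
  shared <- max(a$next_label, next_label)
  metapopulation(
    pop_a = culture_pop(variants = a$variants, next_label = shared),
    pop_b = culture_pop(variants = b$variants, next_label = shared)
  )
}

#' One generation of two connected populations
#'
#' `step_migration()` first swaps migrants permanently ([swap_migrants()]),
#' then each deme performs an independent unbiased generation over its own
#' post-migration parents. `step_exchange()` instead borrows, for this
#' generation only, `X ~ Binomial(N, e)` members of the other deme as
#' additional role models: learners copy uniformly from the enlarged pool of
#' `N + X` parents while census sizes stay `N`, which raises the inbreeding
#' but not the variance effective size.
#'
#' @param meta A [metapopulation()] with equal-sized demes.
#' @param m,e Migration / cultural exchange rate in `[0, 1]`.
#' @param mu Innovation probability in `[0, 1]`.
#' @param fixed_count Use deterministic counts `round(rate * N)` instead of
#'   binomial draws.
#' @return A list with elements `metapopulation`, `counts_a` and `counts_b`
#'   (per-deme [offspring_counts()]; under exchange their pool spans the
#'   `N + X` borrowed-augmented parents, home parents first).
#' @export
step_migration <- function(meta, m, mu, fixed_count = FALSE) {
  mu <- check_mu(mu)
  meta <- swap_migrants(meta, m, fixed_count)
  a <- kernel_unbiased(meta$pop_a$variants, meta$pop_a$next_label, mu)
  b <- kernel_unbiased(meta$pop_b$variants, a$next_label, mu)
  list(
    metapopulation = meta_package(a, b, b$next_label),
    counts_a = offspring_counts(a$counts, pool_size = a$pool_size,
                                offspring_size = length(a$variants),
                                n_innovators = a$n_innovators),
    counts_b = offspring_counts(b$counts, pool_size = b$pool_size,
                                offspring_size = length(b$variants),
                                n_innovators = b$n_innovators)
  )
}

kernel_pool <- function(pool_variants, n_learners, next_label, mu) {
  innovate <- stats::runif(n_learners) < mu
  idx <- sample.int(length(pool_variants), n_learners - sum(innovate),
                    replace = TRUE)
  out <- kernel_finish(numeric(n_learners), next_label, pool_variants[idx],
                       innovate)
  out$counts <- tabulate(idx, length(pool_variants))
  out$pool_size <- length(pool_variants)
  out
}

#' @rdname step_migration
#' @export
step_exchange <- function(meta, e, mu, fixed_count = FALSE) {
  stopifnot(inherits(meta, "culture_meta"))
  check_rate(e, "e"); mu <- check_mu(mu)
  n_a <- census_size(meta$pop_a)
  n_b <- census_size(meta$pop_b)
  # borrowed role models are sampled independently for the two demes and stay
  # members (and potential parents) of their home deme in the same generation
  xa <- n_moved(n_b, e, fixed_count)
  xb <- n_moved(n_a, e, fixed_count)
  pool_a <- c(meta$pop_a$variants,
              meta$pop_b$variants[sample.int(n_b, xa)])
  pool_b <- c(meta$pop_b$variants,
              meta$pop_a$variants[sample.int(n_a, xb)])
  a <- kernel_pool(pool_a, n_a, meta$pop_a$next_label, mu)
  b <- kernel_pool(pool_b, n_b, a$next_label, mu)
  list(
    metapopulation = meta_package(a, b, b$next_label),
    counts_a = offspring_counts(a$counts, pool_size = n_a + xa,
                                offspring_size = n_a,
                                n_innovators = a$n_innovators),
    counts_b = offspring_counts(b$counts, pool_size = n_b + xb,
                                offspring_size = n_b,
                                n_innovators = b$n_innovators)
  )
}

#' One generation of fixed immigrant influx into a growing focal population
#'
#' Each generation a fixed number of individuals, drawn uniformly without
#' replacement from the source population's parental generation, join the
#' focal parental pool; the focal offspring generation is then formed by
#' unbiased copying from that pool and its census grows by `influx_count`.
#' The source population performs its own unbiased generation at constant
#' size. Because parental and offspring sizes now differ, effective sizes for
#' the focal deme should be computed with the inbreeding / variance
#' formulations ([inbreeding_ne()], [variance_ne()]).
#'
#' @param source,focal [culture_pop()] objects sharing an innovation counter
#'   (see [metapopulation()]); `source` should be at its own unbiased
#'   equilibrium.
#' @param influx_count Number of immigrants per generation (`>= 0`, at most
#'   the source census size).
#' @param mu Innovation probability in `[0, 1]`.
#' @return A list with elements `source`, `focal` (the new generations) and
#'   `counts` (focal [offspring_counts()] over the `N + influx_count` pool,
#'   home parents first).
#' @export
step_influx <- function(source, focal, influx_count, mu) {
  check_pop(source); check_pop(focal); mu <- check_mu(mu)
  n_src <- census_size(source)
  if (!is.numeric(influx_count) || length(influx_count) != 1 ||
      influx_count < 0 || influx_count > n_src) {
    stop("`influx_count` must lie between 0 and the source census size")
  }
  influx_count <- as.integer(influx_count)
  shared <- max(source$next_label, focal$next_label)
  pool <- c(focal$variants,
            if (influx_count > 0) source$variants[sample.int(n_src, influx_count)])
  f <- kernel_pool(pool, length(pool), shared, mu)
  s <- kernel_unbiased(source$variants, f$next_label, mu)
  list(
    source = culture_pop(variants = s$variants, next_label = s$next_label),
    focal = culture_pop(variants = f$variants, next_label = s$next_label),
    counts = offspring_counts(f$counts, pool_size = length(pool),
                              offspring_size = length(pool),
                              n_innovators = f$n_innovators)
  )
}
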