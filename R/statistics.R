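#' Moments of cultural influence
#'
#' Summarises per-parent cultural offspring counts into the mean and the
#' population-convention variance (divisor = role-model pool size, not
#' pool - 1) used by the effective-size formulas. With the population
#' convention the simulated one-to-many variance matches its closed form
#' `(N - 1) / R` exactly in expectation.
#'
#' @param counts An [offspring_counts()] object, or a bare numeric vector of
#'   per-parent counts (then the pool is `length(counts)` and the offspring
#'   generation `sum(counts)`).
#' @return A one-row tibble with columns `k_bar`, `sigma2`, `pool_size`,
#'   `offspring_size`.
#' @examples
#' influence_moments(c(2, 0, 1, 1))
#' @export
influence_moments <- function(counts) {
  x <- as.numeric(counts)
  if (length(x) == 0) stop("the role-model pool must be non-empty")
  pool <- attr(counts, "pool_size") %||% length(x)
  off <- attr(counts, "offspring_size") %||% sum(x)
  k_bar <- sum(x) / pool
  tibble::tibble(k_bar = k_bar,
                 sigma2 = sum((x - k_bar)^2) / pool,
                 pool_size = pool,
                 offspring_size = off)
}

#' Effective population sizes from influence moments
#'
#' The inbreeding effective size tracks the probability that two random
#' offspring share a cultural parent,
#' `Nei = (N[t-1] * k_bar - 1) / (k_bar - 1 + sigma2 / k_bar)`;
#' the variance effective size tracks random variant-frequency change,
#' `Nev = (N[t-1] - 1) * k_bar^2 / sigma2`. Both collapse to the simplified
#' `Ne = (N - 1) / sigma2` when the mean offspring number is 1 (constant
#' population size). Generations where a formula is undefined (non-positive
#' denominator, or zero variance meaning no drift) yield `NA` and should be
#' excluded from averages.
#'
#' @param moments A data frame with columns `k_bar`, `sigma2`, `pool_size`
#'   (as returned by [influence_moments()], possibly many rows), or an
#'   [offspring_counts()] object.
#' @return A numeric vector, one effective size per row.
#' @examples
#' # two parents, 1000 offspring: low inbreeding Ne, high variance Ne
#' m <- tibble::tibble(k_bar = 500, sigma2 = 250, pool_size = 2)
#' inbreeding_ne(m)  # 2
#' variance_ne(m)    # 1000
#' @export
inbreeding_ne <- function(moments) {
  m <- as_moments(moments)
  denom <- m$k_bar - 1 + m$sigma2 / m$k_bar
  ifelse(is.finite(denom) & denom > 0,
         (m$pool_size * m$k_bar - 1) / denom, NA_real_)
}

#' @rdname inbreeding_ne
#' @export
variance_ne <- function(moments) {
  m <- as_moments(moments)
  ifelse(m$sigma2 > 0, (m$pool_size - 1) * m$k_bar^2 / m$sigma2, NA_real_)
}

as_moments <- function(moments) {
  if (inherits(moments, "offspring_counts") || !is.data.frame(moments)) {
    moments <- influence_moments(moments)
  }
  stopifnot(all(c("k_bar", "sigma2", "pool_size") %in% names(moments)))
  moments
}

#' Simplified effective population size
#'
#' For constant population size (mean offspring number 1) both effective-size
#' formulations reduce to `Ne = (N - 1) / sigma2`.
#'
#' @param n Census size (`>= 2`).
#' @param sigma2 Population-convention variance in offspring number.
#' @return `(n - 1) / sigma2`, or `NA` where `sigma2` is 0 (no drift).
#' @examples
#' simple_ne(1000, 0.999)  # 1000
#' simple_ne(1000, 99.9)   # 10: one-to-many with R = 10
#' @export
simple_ne <- function(n, sigma2) {
  stopifnot(is.numeric(n), is.numeric(sigma2))
  if (any(n < 2)) stop("`n` must be at least 2")
  if (any(sigma2 < 0)) stop("`sigma2` must be non-negative")
  ifelse(sigma2 > 0, (n - 1) / sigma2, NA_real_)
}

#' Harmonic-mean effective size over fluctuating census sizes
#'
#' Across generations the rate of drift compounds through the harmonic mean,
#' so a single bottleneck generation dominates: ten generations at sizes
#' `c(10, rep(1000, 9))` give an effective size of about 92 even though the
#' census has recovered to 1000.
#'
#' @param sizes Per-generation census sizes (all `>= 1`).
#' @return `length(sizes) / sum(1 / sizes)`.
#' @examples
#' harmonic_mean_ne(c(10, rep(1000, 9)))  # ~91.7
#' harmonic_mean_ne(rep(500, 10))         # 500
#' @export
harmonic_mean_ne <- function(sizes) {
  if (length(sizes) == 0) stop("`sizes` must be non-empty")
  if (!is.numeric(sizes) || any(sizes < 1)) {
    stop("all census sizes must be at least 1")
  }
  length(sizes) / sum(1 / sizes)
}

#' Simpson diversity index
#'
#' `D = 1 - sum((n_i / N)^2)`: the probability that two randomly drawn
#' individuals carry different variants. 0 for a single-variant population;
#' maximal (`1 - 1/N`) when every individual carries a distinct variant.
#' Computed on the whole population (a census, not a sample) without
#' finite-sample correction.
#'
#' @param x A [culture_pop()], a [variant_counts()] tibble, or a bare numeric
#'   vector of variant counts.
#' @return A single number in `[0, 1 - 1/N]`.
#' @examples
#' simpson_index(c(2, 1, 1))  # 0.625
#' @export
simpson_index <- function(x) {
  n_i <- as_count_vector(x)
  1 - sum((n_i / sum(n_i))^2)
}

#' Number of unique cultural variants
#'
#' @inheritParams simpson_index
#' @return The number of distinct variants present.
#' @export
unique_count <- function(x) {
  if (inherits(x, "culture_pop")) return(length(unique(x$variants)))
  length(as_count_vector(x))
}

as_count_vector <- function(x) {
  if (inherits(x, "culture_pop")) {
    x <- variant_counts(x)
  }
  n_i <- if (is.data.frame(x)) x$n else as.numeric(x)
  if (length(n_i) == 0 || any(n_i <= 0)) {
    stop("variant counts must be positive and non-empty")
  }
  n_i
}

#' Replicate mean and 90% prediction interval
#'
#' Summarises a per-replicate statistic into its mean and empirical 5th/95th
#' percentiles (linear-interpolation quantiles), the prediction band used
#' throughout the package's experiment summaries.
#'
#' @param values Numeric vector of per-replicate values (length >= 2; `NA`s
#'   from undefined generations are dropped).
#' @return A one-row tibble with columns `mean`, `lower`, `upper`.
#' @examples
#' summarize_replicates(1:100)
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("at least two replicate values are required")
  q <- stats::quantile(values, c(0.05, 0.95), names = FALSE)
  tibble::tibble(mean = mean(values), lower = q[1], upper = q[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
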