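# Generation kernels.
#
# All transmission modes share the same skeleton: each of the `n_learners`
# members of the new generation innovates with probability `mu` (receiving a
# fresh label and crediting no parent) or copies a member of the role-model
# pool. Kernels work on bare vectors for speed inside replicate loops; the
# exported step_*() functions wrap them with validation and packaging. Kernels
# return the parent index chosen by every copying learner, tabulated over the
# pool, so that per-parent cultural influence is recorded exactly.

kernel_finish <- function(variants, next_label, parent_variants, innovate) {
  n_inn <- sum(innovate)
  new_v <- numeric(length(innovate))
  new_v[!innovate] <- parent_variants
  if (n_inn > 0) new_v[innovate] <- next_label + seq_len(n_inn) - 1
  list(variants = new_v, next_label = next_label + n_inn, n_innovators = n_inn)
}

kernel_unbiased <- function(v, next_label, mu) {
  n <- length(v)
  innovate <- stats::runif(n) < mu
  idx <- sample.int(n, n - sum(innovate), replace = TRUE)
  out <- kernel_finish(v, next_label, v[idx], innovate)
  out$counts <- tabulate(idx, n)
  out$pool_size <- n
  out
}

kernel_one_to_many <- function(v, next_label, r_models, mu) {
  n <- length(v)
  models <- if (r_models == n) seq_len(n) else sample.int(n, r_models)
  innovate <- stats::runif(n) < mu
  idx <- models[sample.int(r_models, n - sum(innovate), replace = TRUE)]
  out <- kernel_finish(v, next_label, v[idx], innovate)
  out$counts <- tabulate(idx, n)  # non-models keep count 0
  out$pool_size <- n
  out
}

kernel_frequency <- function(v, next_label, theta, mu) {
  n <- length(v)
  innovate <- stats::runif(n) < mu
  # Adopting variant i with probability n_i^theta / sum(n_m^theta) and then
  # crediting a uniformly random carrier of i is equivalent to choosing a
  # parent directly with per-parent weight n_{v(parent)}^(theta - 1).
  uv <- unique(v)
  cnt <- tabulate(match(v, uv), length(uv))
  w <- cnt[match(v, uv)]^(theta - 1)
  idx <- sample.int(n, n - sum(innovate), replace = TRUE, prob = w)
  out <- kernel_finish(v, next_label, v[idx], innovate)
  out$counts <- tabulate(idx, n)
  out$pool_size <- n
  out
}

kernel_network <- function(v, next_label, graph, mu) {
  n <- length(v)
  innovate <- stats::runif(n) < mu
  learners <- which(!innovate)
  deg <- graph$deg[learners]
  # uniform neighbour via the flattened adjacency; isolated nodes have no
  # role model and retain their own variant (credited to themselves so that
  # influence is conserved)
  pick <- graph$offsets[learners] + floor(stats::runif(length(learners)) * deg) + 1
  idx <- ifelse(deg > 0, graph$flat[pmax(pick, 1)], learners)
  out <- kernel_finish(v, next_label, v[idx], innovate)
  out$counts <- tabulate(idx, n)
  out$pool_size <- n
  out
}

package_step <- function(pop, out) {
  list(
    population = culture_pop(variants = out$variants,
                             next_label = max(out$next_label,
                                              max(out$variants) + 1)),
    counts = offspring_counts(out$counts, pool_size = out$pool_size,
                              offspring_size = length(out$variants),
                              n_innovators = out$n_innovators)
  )
}

#' One generation of unbiased cultural transmission
#'
#' Each learner independently innovates with probability `mu` (adopting a
#' brand-new variant) or copies a uniformly random member of the parental
#' generation, i.e. adopts variant i with probability `(n_i / N) * (1 - mu)`.
#'
#' @param pop A [culture_pop()] object (the parental generation).
#' @param mu Innovation probability in `[0, 1]`.
#' @return A list with elements `population` (the new generation, same census
#'   size) and `counts` (an [offspring_counts()] with one entry per parent).
#' @examples
#' set.seed(1)
#' step <- step_unbiased(culture_pop(20), mu = 0.05)
#' sum(step$counts) + attr(step$counts, "n_innovators")  # = 20
#' @export
step_unbiased <- function(pop, mu) {
  check_pop(pop); check_mu(mu)
  package_step(pop, kernel_unbiased(pop$variants, pop$next_label, mu))
}

#' One generation of one-to-many transmission
#'
#' `r_models` individuals are drawn uniformly without replacement as the only
#' eligible role models of this generation; every learner innovates with
#' probability `mu` or copies a uniformly random role model. Influence counts
#' still cover all parents: ineligible individuals receive count 0, which is
#' what inflates the variance of cultural influence to `(N - 1) / R`.
#'
#' @inheritParams step_unbiased
#' @param r_models Number of role models `R`, `1 <= R <= N`. With
#'   `r_models = N` the step is distributionally identical to
#'   [step_unbiased()].
#' @return As [step_unbiased()].
#' @export
step_one_to_many <- function(pop, r_models, mu) {
  check_pop(pop); check_mu(mu)
  n <- census_size(pop)
  if (!is.numeric(r_models) || length(r_models) != 1 || r_models < 1 ||
      r_models > n || r_models != round(r_models)) {
    stop("`r_models` must be a whole number between 1 and the census size")
  }
  package_step(pop, kernel_one_to_many(pop$variants, pop$next_label,
                                       as.integer(r_models), mu))
}

#' One generation of frequency-dependent transmission
#'
#' A learner that does not innovate adopts variant i with probability
#' `n_i^theta / sum(n_m^theta)`: `theta > 1` is conformity (common variants
#' over-adopted), `theta < 1` anti-conformity, and `theta = 1` reduces exactly
#' to unbiased transmission. The adopting learner is credited as the cultural
#' offspring of a uniformly random carrier of the adopted variant, keeping
#' influence counts per-parent.
#'
#' @inheritParams step_unbiased
#' @param theta Frequency-dependence exponent, `> 0`.
#' @return As [step_unbiased()].
#' @export
step_frequency_dependent <- function(pop, theta, mu) {
  check_pop(pop); check_mu(mu); check_theta(theta)
  package_step(pop, kernel_frequency(pop$variants, pop$next_label, theta, mu))
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta <= 0) {
    stop("`theta` must be a single positive number", call. = FALSE)
  }
  theta
}

#' Variant adoption probabilities under frequency-dependent transmission
#'
#' Evaluates the per-variant adoption probabilities
#' `p_i = n_i^theta / sum(n_m^theta) * (1 - mu)` for a tally of variant
#' counts. With `theta = 1` these are the unbiased probabilities
#' `(n_i / N) * (1 - mu)`; the remaining probability mass `mu` is innovation.
#'
#' @param counts Data frame with columns `variant` and `n` (as returned by
#'   [variant_counts()]), or a bare numeric vector of counts.
#' @param theta Frequency-dependence exponent, `> 0`.
#' @param mu Innovation probability in `[0, 1]`.
#' @return A tibble with columns `variant` and `prob`; `sum(prob) == 1 - mu`.
#' @examples
#' adoption_probs(data.frame(variant = c("A", "B"), n = c(90, 10)), theta = 1.5)
#' @export
adoption_probs <- function(counts, theta = 1, mu = 0) {
  check_theta(theta); check_mu(mu)
  if (is.data.frame(counts)) {
    variant <- counts$variant
    n <- counts$n
  } else {
    n <- as.numeric(counts)
    variant <- seq_along(n)
  }
  if (any(n <= 0)) stop("variant counts must be positive")
  w <- n^theta
  tibble::tibble(variant = variant, prob = w / sum(w) * (1 - mu))
}

#' Closed-form variance of cultural influence under one-to-many transmission
#'
#' With `R` of `N` individuals eligible as role models the pooled variance of
#' per-parent offspring counts is `(N - 1) / R` in expectation; the
#' corresponding effective population size is `R`, the size of the
#' transmitting sub-population.
#'
#' @param n Census size `N`.
#' @param r_models Number of role models `R`, `1 <= R <= N`.
#' @return A single number: the expected variance (for `otm_sigma2()`) or the
#'   effective size (for `otm_ne()`).
#' @examples
#' otm_sigma2(1000, 10)  # 99.9
#' otm_ne(1000, 10)      # 10
#' @export
otm_sigma2 <- function(n, r_models) {
  check_otm(n, r_models)
  (n - 1) / r_models
}

#' @rdname otm_sigma2
#' @export
otm_ne <- function(n, r_models) {
  check_otm(n, r_models)
  (n - 1) / otm_sigma2(n, r_models)
}

check_otm <- function(n, r_models) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be >= 1")
  if (!is.numeric(r_models) || length(r_models) != 1 || r_models < 1 ||
      r_models > n) {
    stop("`r_models` must lie between 1 and `n`")
  }
  invisible(NULL)
}

#' Neutral drift trajectories of a focal variant
#'
#' Simulates pure drift of a two-variant trait without innovation: the focal
#' variant count follows the exact Wright-Fisher binomial resampling chain,
#' starting from `round(n * p0)` copies, absorbing at frequency 0 and 1.
#'
#' @param n Census size.
#' @param p0 Initial focal-variant frequency in `[0, 1]`.
#' @param generations Number of generations to simulate.
#' @param replicates Number of independent populations.
#' @return A tibble with columns `replicate`, `generation` (0 to
#'   `generations`) and `frequency`.
#' @examples
#' set.seed(1)
#' drift_trajectory(n = 100, p0 = 0.5, generations = 50, replicates = 4)
#' @export
drift_trajectory <- function(n, p0 = 0.5, generations = 100, replicates = 1) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (!is.numeric(p0) || length(p0) != 1 || p0 < 0 || p0 > 1) {
    stop("`p0` must be a single frequency in [0, 1]")
  }
  one <- function(rep) {
    x <- round(n * p0)
    freq <- numeric(generations + 1)
    freq[1] <- x / n
    for (t in seq_len(generations)) {
      if (x > 0 && x < n) x <- stats::rbinom(1, n, x / n)
      freq[t + 1] <- x / n
    }
    tibble::tibble(replicate = rep, generation = 0:generations, frequency = freq)
  }
  purrr::map_dfr(seq_len(replicates), one)
}
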