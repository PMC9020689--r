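# Exact enumeration oracles for one-generation transition distributions.
#
# For modes where learners choose independently (unbiased,
# frequency-dependent, network-constrained with mu = 0) the distribution of
# the full offspring variant assignment is the product of per-learner
# marginals; for one-to-many it is a uniform mixture over role-model subsets.
# These enumerations are independent of the step kernels they check.

# `probs` is a list with one named probability vector per learner position
enum_assignment_dist <- function(probs) {
  grid <- expand.grid(lapply(probs, names), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  prob <- Reduce(`*`, lapply(seq_along(probs), function(i) {
    unname(probs[[i]][grid[[i]]])
  }))
  key <- do.call(paste, c(grid, list(sep = "-")))
  stats::aggregate(data.frame(prob = prob), by = list(key = key), FUN = sum)
}

# iid learners: every position has the same variant-adoption distribution
enum_iid <- function(variant_probs, n) {
  enum_assignment_dist(rep(list(variant_probs), n))
}

unbiased_variant_probs <- function(variants) {
  tab <- table(variants)
  stats::setNames(as.numeric(tab) / length(variants), names(tab))
}

freq_variant_probs <- function(variants, theta) {
  tab <- table(variants)
  w <- as.numeric(tab)^theta
  stats::setNames(w / sum(w), names(tab))
}

# one-to-many: average the iid enumeration over all role-model subsets
enum_one_to_many <- function(variants, r) {
  n <- length(variants)
  subsets <- utils::combn(n, r)
  pieces <- lapply(seq_len(ncol(subsets)), function(j) {
    enum_iid(unbiased_variant_probs(variants[subsets[, j]]), n)
  })
  agg <- stats::aggregate(prob ~ key, data = do.call(rbind, pieces), FUN = sum)
  agg$prob <- agg$prob / ncol(subsets)
  agg
}

# network: per-node uniform over its neighbours' variants
enum_network <- function(variants, graph) {
  probs <- lapply(seq_along(variants), function(v) {
    d <- graph$deg[v]
    nb <- if (d > 0) graph$flat[graph$offsets[v] + seq_len(d)] else v
    unbiased_variant_probs(variants[nb])
  })
  enum_assignment_dist(probs)
}

# chi-square goodness of fit of observed assignment keys against an
# enumerated distribution, lumping low-expectation cells
oracle_chisq_p <- function(keys, expected, min_expected = 10) {
  draws <- length(keys)
  obs <- table(factor(keys, levels = expected$key))
  stopifnot(sum(obs) == draws)  # every outcome must be enumerated
  keep <- expected$prob * draws >= min_expected
  obs2 <- c(as.numeric(obs[keep]), sum(obs[!keep]))
  p2 <- c(expected$prob[keep], sum(expected$prob[!keep]))
  if (p2[length(p2)] == 0) {
    obs2 <- obs2[-length(obs2)]
    p2 <- p2[-length(p2)]
  }
  suppressWarnings(stats::chisq.test(obs2, p = p2 / sum(p2))$p.value)
}

draw_keys <- function(step_fun, draws) {
  vapply(seq_len(draws),
         function(i) paste(step_fun(), collapse = "-"), character(1))
}

# shared small helper: per-replicate means of a statistic
replicate_means <- function(x, stat) {
  tapply(x[[stat]], x$replicate, mean, na.rm = TRUE)
}

pi90 <- function(values) stats::quantile(values, c(0.05, 0.95), names = FALSE)
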