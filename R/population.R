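#' Create a cultural Wright-Fisher population
#'
#' A population holds one cultural variant label per individual plus a global
#' innovation counter. Under the infinite-alleles assumption every innovation
#' receives a brand-new label: the counter records the smallest label never
#' yet used, so labels are globally unique over a simulation's lifetime (and,
#' for coupled populations, across populations sharing the counter).
#'
#' @param n Census size (number of individuals, >= 1). Ignored when
#'   `variants` is supplied.
#' @param variants Optional numeric vector of variant labels (positive
#'   integers stored as doubles). Defaults to one distinct label per
#'   individual (`1:n`), the maximal-diversity starting state used before
#'   burn-in.
#' @param next_label Smallest label never yet used. Defaults to
#'   `max(variants) + 1`.
#'
#' @return An object of class `culture_pop`: a list with elements `variants`
#'   and `next_label`.
#' @examples
#' pop <- culture_pop(10)
#' variant_counts(pop)
#' @export
culture_pop <- function(n, variants = NULL, next_label = NULL) {
  if (is.null(variants)) {
    stopifnot(is.numeric(n), length(n) == 1, n >= 1)
    variants <- as.numeric(seq_len(n))
  } else {
    variants <- as.numeric(variants)
    if (length(variants) < 1) stop("a population needs at least one individual")
    if (anyNA(variants)) stop("variant labels must not be missing")
  }
  if (is.null(next_label)) next_label <- max(variants) + 1
  if (any(variants >= next_label)) {
    stop("all variant labels must be smaller than `next_label`")
  }
  structure(list(variants = variants, next_label = as.numeric(next_label)),
            class = "culture_pop")
}

#' @export
print.culture_pop <- function(x, ...) {
  n <- length(x$variants)
  m <- length(unique(x$variants))
  cat(sprintf("<culture_pop> N = %d, %d distinct variant%s, next label %s\n",
              n, m, if (m == 1) "" else "s",
              format(x$next_label, scientific = FALSE)))
  invisible(x)
}

#' Census size of a population
#' @param pop A [culture_pop()] object.
#' @return Integer census size.
#' @export
census_size <- function(pop) length(pop$variants)

#' Tally variant frequencies
#'
#' Counts how many individuals carry each variant present in the population.
#'
#' @param pop A [culture_pop()] object.
#' @return A tibble with columns `variant` (label) and `n` (count), one row
#'   per distinct variant, in order of first appearance. Counts sum to the
#'   census size.
#' @export
variant_counts <- function(pop) {
  stopifnot(inherits(pop, "culture_pop"))
  uv <- unique(pop$variants)
  tibble::tibble(variant = uv,
                 n = tabulate(match(pop$variants, uv), length(uv)))
}

#' Per-parent cultural offspring counts
#'
#' Constructs the record of "cultural influence" produced by one generation
#' step: for every member of the role-model pool, the number of learners that
#' copied it. Innovating learners have no cultural parent and contribute to no
#' count, so `sum(counts) + n_innovators` equals the offspring population
#' size.
#'
#' @param counts Non-negative integer vector, one entry per member of the
#'   eligible role-model pool (eligible-but-uncopied models get 0).
#' @param pool_size Number of eligible role models (defaults to
#'   `length(counts)`).
#' @param offspring_size Number of learners in the new generation.
#' @param n_innovators Number of learners that innovated instead of copying.
#' @return An `offspring_counts` object (numeric vector with attributes).
#' @export
offspring_counts <- function(counts, pool_size = length(counts),
                             offspring_size = sum(counts), n_innovators = 0) {
  counts <- as.numeric(counts)
  if (length(counts) != pool_size) {
    stop("`counts` must have one entry per member of the role-model pool")
  }
  if (any(counts < 0)) stop("offspring counts must be non-negative")
  if (sum(counts) + n_innovators != offspring_size) {
    stop("counts + innovators must equal the offspring population size")
  }
  structure(counts, class = "offspring_counts", pool_size = pool_size,
            offspring_size = offspring_size, n_innovators = n_innovators)
}

#' @export
print.offspring_counts <- function(x, ...) {
  cat(sprintf(
    "<offspring_counts> pool %d, offspring %d (%d innovator%s), mean %.3f\n",
    attr(x, "pool_size"), attr(x, "offspring_size"),
    attr(x, "n_innovators"), if (attr(x, "n_innovators") == 1) "" else "s",
    mean(unclass(x))))
  invisible(x)
}

#' Write or read a population as a single CSV row
#'
#' A population serialises to one comma-separated row of variant labels; the
#' innovation counter is recovered as one more than the largest label.
#' Intended for small fixtures and debugging, not bulk output.
#'
#' @param pop A [culture_pop()] object.
#' @param path File path.
#' @return `write_population()` returns `pop` invisibly; `read_population()`
#'   returns a [culture_pop()].
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "culture_pop"))
  writeLines(paste(format(pop$variants, scientific = FALSE, trim = TRUE),
                   collapse = ","), path)
  invisible(pop)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  labels <- as.numeric(strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]])
  culture_pop(variants = labels)
}

# shared validation helpers ---------------------------------------------------

check_mu <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0 || mu > 1) {
    stop("`mu` must be a single innovation probability in [0, 1]", call. = FALSE)
  }
  mu
}

check_pop <- function(pop) {
  if (!inherits(pop, "culture_pop")) {
    stop("`pop` must be a `culture_pop` object", call. = FALSE)
  }
  pop
}
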