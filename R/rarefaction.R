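# Analytic rarefaction and Good's coverage.
#
# Rarefaction here is the exact hypergeometric expectation: the expected
# number of distinct species observed in a uniform random subsample of n
# sequences drawn without replacement from a group. Computed with
# log-binomial arithmetic so large groups do not overflow.

#' Expected species richness in a random subsample
#'
#' For a group with species abundances `N_i` (total `N`), the expected
#' richness at depth `n` is
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`,
#' with `choose(a, b) = 0` when `a < b`. Endpoints are exact:
#' `E[S_1] = 1` and `E[S_N] = S`, the observed species count.
#'
#' @param abundances Integer vector of sequences per species (all >= 1).
#' @param n Subsample depth(s), each in `[1, sum(abundances)]`.
#' @return Numeric vector of expected richness values, parallel to `n`.
#' @examples
#' expected_richness(c(3, 1, 1), 3)
#' @export
expected_richness <- function(abundances, n) {
  if (length(abundances) == 0L || any(abundances < 1))
    stop("abundances must be a nonempty vector of counts >= 1")
  N <- sum(abundances)
  if (any(n < 1) || any(n > N))
    stop("subsample depth must lie in [1, ", N, "]")
  vapply(n, function(k) {
    sum(1 - exp(lchoose(N - abundances, k) - lchoose(N, k)))
  }, numeric(1L))
}

#' Good's coverage estimator
#'
#' `1 - F1 / N`, where `F1` is the number of singleton species and `N` the
#' number of sequences: the estimated fraction of the community represented
#' by species seen more than once.
#'
#' @param abundances Integer vector of sequences per species (all >= 1).
#' @return Fraction in `[0, 1]`; exactly 1 iff there are no singletons.
#' @examples
#' goods_coverage(c(3, 1, 1))  # 0.6
#' @export
goods_coverage <- function(abundances) {
  if (length(abundances) == 0L || any(abundances < 1))
    stop("abundances must be a nonempty vector of counts >= 1")
  1 - sum(abundances == 1) / sum(abundances)
}

#' Rarefaction curves for a family of groups
#'
#' Evaluates [expected_richness()] for each group over a depth grid; the
#' grid is clipped to each group's own total so curves of unequal groups
#' can share one grid.
#'
#' @param groups Named list of abundance vectors (one per group, e.g. per
#'   abundant suborder or per environmental category).
#' @param depths Integer vector of subsample depths. Default: 25 depths
#'   spread evenly from 1 to the largest group total.
#' @return Data.frame with columns `group`, `n`, `expected_richness`.
#' @export
curve_family <- function(groups, depths = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (length(groups) == 0L)
    return(data.frame(group = character(0), n = integer(0),
                      expected_richness = numeric(0)))
  if (is.null(depths)) {
    nmax <- max(vapply(groups, sum, numeric(1L)))
    depths <- unique(round(seq(1L, nmax, length.out = min(25L, nmax))))
  }
  depths <- sort(unique(as.integer(depths)))
  rows <- lapply(names(groups), function(g) {
    ab <- groups[[g]]
    N <- sum(ab)
    d <- unique(pmin(depths[depths >= 1L], N))
    data.frame(group = g, n = d,
               expected_richness = expected_richness(ab, d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coverage summary for a family of groups
#'
#' @inheritParams curve_family
#' @return Data.frame with columns `group`, `N` (sequences), `S` (species),
#'   `F1` (singletons) and `coverage` (Good's estimator).
#' @export
coverage_table <- function(groups) {
  rows <- lapply(names(groups), function(g) {
    ab <- groups[[g]]
    data.frame(group = g, N = sum(ab), S = length(ab),
               F1 = sum(ab == 1), coverage = goods_coverage(ab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Species abundance vectors per group
#'
#' Helper connecting the delineation to rarefaction: species abundances
#' (sequences per species) within each level of a grouping variable, using
#' the pipeline's own species partition.
#'
#' @param assignment Data.frame with `id` and `species` columns.
#' @param group Character vector parallel to `assignment` rows (e.g.
#'   suborder label or environmental category per sequence).
#' @return Named list of abundance vectors.
#' @export
abundance_by_group <- function(assignment, group) {
  stopifnot(length(group) == nrow(assignment))
  lapply(split(assignment$species, group),
         function(sp) as.integer(table(sp)))
}
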