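# Environmental categorisation, abundance classification, taxa-by-
# environment distributions, culturability breakdown and the habitat
# specialist/cosmopolitan classifier.

#' The ten environmental categories
#'
#' The closed vocabulary used to categorise isolation sources: marine
#' organisms, marine sediments, seawater, soil, terrestrial sediments,
#' activated sludge, terrestrial organisms, freshwater, human, and an
#' explicit category for unknown isolation sources.
#'
#' @return Character vector of the 10 category labels.
#' @export
env_categories <- function() {
  c("M_organism", "M_sediment", "Seawater", "Soil", "T_sediment",
    "Activated_sludge", "T_organism", "Freshwater", "Human", "The_unknown")
}

#' Habitat-specificity parameters
#'
#' A taxon is a habitat specialist when it has at least `min_obs`
#' observations and at least a `dominance` fraction of them fall in a
#' single environmental category (both bounds inclusive); otherwise it is
#' cosmopolitan. Defaults: 5 observations, 80 percent dominance.
#'
#' @param min_obs Minimum number of observations (sequences) per taxon.
#' @param dominance Required fraction in the dominant category, in `(0, 1]`.
#' @param exclude_unknown Drop `The_unknown` observations before applying
#'   the criterion (default `FALSE`: unknown-source observations count).
#' @return A named list with class `specificity_params`.
#' @export
specificity_params <- function(min_obs = 5L, dominance = 0.80,
                               exclude_unknown = FALSE) {
  min_obs <- as.integer(min_obs)
  stopifnot(min_obs >= 1L, dominance > 0, dominance <= 1,
            is.logical(exclude_unknown))
  structure(list(min_obs = min_obs, dominance = dominance,
                 exclude_unknown = exclude_unknown),
            class = "specificity_params")
}

#' Classify taxa as abundant or rare
#'
#' A taxon is abundant when it holds at least `cutoff` (default 0.5
#' percent, inclusive) of all sequences, rare otherwise.
#'
#' @param count Sequence count(s) per taxon (vectorised).
#' @param total Total number of sequences (> 0).
#' @param cutoff Abundance cutoff as a fraction of `total`.
#' @return Character vector of `"abundant"` / `"rare"`.
#' @examples
#' classify_abundance(144, 4997)  # abundant
#' classify_abundance(15, 4997)   # rare
#' @export
classify_abundance <- function(count, total, cutoff = 0.005) {
  stopifnot(length(total) == 1L, total > 0, cutoff > 0, cutoff < 1)
  if (any(count < 0) || any(count > total))
    stop("counts must lie in [0, total]")
  ifelse(count / total >= cutoff, "abundant", "rare")
}

#' Taxon-by-environment observation matrix
#'
#' Counts sequences per (taxon, environmental category) at a chosen rank.
#' All ten categories appear as columns, `The_unknown` included.
#'
#' @param assignment Data.frame with `id` and rank label columns.
#' @param records Records data.frame with `id` and `env_category`.
#' @param rank One of `"suborder"`, `"family"`, `"genus"`, `"species"`.
#' @return Integer matrix, taxa as rows (sorted by label), the 10
#'   environmental categories as columns.
#' @export
distribution_matrix <- function(assignment, records,
                                rank = c("suborder", "family", "genus",
                                         "species")) {
  rank <- match.arg(rank)
  if (nrow(assignment) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 10L,
                  dimnames = list(character(0), env_categories())))
  }
  miss <- setdiff(assignment$id, records$id)
  if (length(miss) > 0L)
    stop("assigned id(s) without a record: ", paste(miss, collapse = ", "))
  env <- records$env_category[match(assignment$id, records$id)]
  tab <- table(factor(assignment[[rank]]),
               factor(env, levels = env_categories()))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), env_categories()))
  m
}

#' Classify one taxon as habitat specialist or cosmopolitan
#'
#' Specialist iff the taxon has at least `params$min_obs` observations and
#' the most-observed environmental category holds at least
#' `params$dominance` of them; both comparisons are inclusive, so five
#' observations all from soil, or eight of ten from soil, qualify.
#' Taxa with fewer observations than `min_obs` are cosmopolitan.
#'
#' @param env_counts Non-negative counts per environmental category (named
#'   when `exclude_unknown` is in force).
#' @param params A [specificity_params()] object.
#' @return `"specialist"` or `"cosmopolitan"`.
#' @export
classify_specificity <- function(env_counts, params = specificity_params()) {
  stopifnot(inherits(params, "specificity_params"))
  if (any(env_counts < 0)) stop("negative counts")
  if (sum(env_counts) == 0)
    stop("taxon has no observations")
  if (params$exclude_unknown && !is.null(names(env_counts)))
    env_counts <- env_counts[names(env_counts) != "The_unknown"]
  total <- sum(env_counts)
  if (total >= params$min_obs && max(env_counts) / total >= params$dominance)
    "specialist"
  else
    "cosmopolitan"
}

#' Specialist/cosmopolitan proportions at every rank
#'
#' Applies [classify_specificity()] to every taxon at each of the four
#' ranks and reports the fraction of taxa in each class; the two fractions
#' sum to one per rank.
#'
#' @param assignment Data.frame with `id` and the four rank columns.
#' @param records Records data.frame with `id` and `env_category`.
#' @param params A [specificity_params()] object.
#' @return Data.frame with columns `rank`, `n_taxa`, `specialist`,
#'   `cosmopolitan`.
#' @export
specificity_profile <- function(assignment, records,
                                params = specificity_params()) {
  rows <- lapply(RANKS, function(rank) {
    m <- distribution_matrix(assignment, records, rank)
    cls <- apply(m, 1L, classify_specificity, params = params)
    data.frame(rank = rank, n_taxa = nrow(m),
               specialist = mean(cls == "specialist"),
               cosmopolitan = mean(cls == "cosmopolitan"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Culturability breakdown
#'
#' Global counts of cultured / uncultured / unknown sequences, the
#' percentage composition of each environmental category, and (when an
#' assignment is supplied) per-suborder counts.
#'
#' @param records Records data.frame with `env_category` and `cultured`.
#' @param assignment Optional data.frame with `id` and `suborder`.
#' @return A list with elements `global` (named counts),
#'   `by_environment` (data.frame of percentages summing to 100 per row)
#'   and `by_suborder` (data.frame of counts, or `NULL`).
#' @export
culturability_breakdown <- function(records, assignment = NULL) {
  classes <- c("cultured", "uncultured", "unknown")
  cult <- factor(records$cultured, levels = classes)
  global <- table(cult)
  env <- factor(records$env_category, levels = env_categories())
  tab <- table(env, cult)
  pct <- 100 * prop.table(tab + 0, margin = 1L)
  pct[is.nan(pct)] <- 0
  by_env <- data.frame(env_category = rownames(tab),
                       n = as.integer(rowSums(tab)),
                       pct_cultured = unname(pct[, "cultured"]),
                       pct_uncultured = unname(pct[, "uncultured"]),
                       pct_unknown = unname(pct[, "unknown"]),
                       stringsAsFactors = FALSE)
  by_sub <- NULL
  if (!is.null(assignment)) {
    sub <- assignment$suborder
    cult_a <- factor(records$cultured[match(assignment$id, records$id)],
                     levels = classes)
    stab <- table(factor(sub), cult_a)
    by_sub <- data.frame(suborder = rownames(stab),
                         cultured = as.integer(stab[, "cultured"]),
                         uncultured = as.integer(stab[, "uncultured"]),
                         unknown = as.integer(stab[, "unknown"]),
                         stringsAsFactors = FALSE)
  }
  list(global = setNames(as.integer(global), classes),
       by_environment = by_env,
       by_suborder = by_sub)
}
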