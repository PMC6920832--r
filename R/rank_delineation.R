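# Nested four-rank taxonomic delineation from a pairwise identity matrix.
#
# The delineation applies complete-linkage (furthest-neighbour)
# agglomerative clustering at fixed identity thresholds: two sequences at
# or below the threshold identity belong to distinct taxa, so clusters are
# merged only while *every* cross-pair identity stays strictly above the
# threshold. Suborders are delineated first, then each suborder is split
# into families, families into genera and genera into species, so the four
# partitions are nested by construction.
#
# Rank labels are dotted paths ("2", "2.1", "2.1.3", "2.1.3.1"): globally
# unique at every rank, with within-parent indices assigned by the
# lexicographically smallest member id, so partitions are invariant to
# input order.

RANKS <- c("suborder", "family", "genus", "species")

#' Identity thresholds for the four taxonomic ranks
#'
#' Two sequences with identity at or below a rank's threshold are taken as
#' evidence for distinct taxa at that rank. Defaults: species 0.970,
#' genus 0.945, family 0.890, suborder 0.850 — the conservative cutoffs in
#' routine use for 16S rRNA gene surveys.
#'
#' @param species,genus,family,suborder Identity cutoffs in `(0, 1)`,
#'   strictly decreasing from species to suborder.
#' @return Named numeric vector with class `rank_thresholds`.
#' @export
rank_thresholds <- function(species = 0.970, genus = 0.945,
                            family = 0.890, suborder = 0.850) {
  th <- c(species = species, genus = genus, family = family,
          suborder = suborder)
  if (any(th <= 0) || any(th >= 1))
    stop("thresholds must lie in (0, 1)")
  if (!(species > genus && genus > family && family > suborder))
    stop("thresholds must satisfy species > genus > family > suborder")
  structure(th, class = "rank_thresholds")
}

#' Complete-linkage clustering of an identity matrix at a threshold
#'
#' Agglomerative clustering where the linkage between two clusters is the
#' minimum cross-pair identity. Clusters are merged, highest linkage first,
#' while that linkage is strictly greater than `threshold`; consequently
#' every within-cluster pair has identity strictly above the threshold, and
#' a pair at identity exactly equal to the threshold ends up in distinct
#' clusters. Equal-linkage merges are broken by the lexicographically
#' smallest member id (then the other cluster's smallest id), so the result
#' is deterministic and invariant to input order.
#'
#' @param dm Symmetric identity matrix with sequence ids as dimnames
#'   (see [distance_matrix()] with `metric = "identity"`).
#' @param threshold Identity cutoff in `(0, 1)`.
#' @return Named integer vector mapping each id to a cluster index;
#'   clusters are numbered by their smallest member id.
#' @export
cluster_at_threshold <- function(dm, threshold) {
  met <- attr(dm, "metric")
  if (!is.null(met) && met != "identity")
    stop("clustering requires an identity matrix, got metric '", met, "'")
  ids <- rownames(dm)
  if (is.null(ids)) stop("identity matrix must have ids as dimnames")
  n <- length(ids)
  if (n == 0L) stop("empty matrix")
  if (n == 1L) return(setNames(1L, ids))

  link <- unclass(dm)
  attr(link, "metric") <- NULL
  diag(link) <- NA_real_
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  minid <- ids

  repeat {
    idx <- which(active)
    if (length(idx) == 1L) break
    sub <- link[idx, idx, drop = FALSE]
    best <- max(sub, na.rm = TRUE)
    if (best <= threshold) break
    w <- which(sub == best, arr.ind = TRUE)
    w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
    a <- idx[w[, 1L]]
    b <- idx[w[, 2L]]
    k1 <- pmin(minid[a], minid[b])
    k2 <- pmax(minid[a], minid[b])
    pick <- order(k1, k2)[1L]
    i <- a[pick]
    j <- b[pick]
    merged <- pmin(link[i, ], link[j, ])
    link[i, ] <- merged
    link[, i] <- merged
    link[i, i] <- NA_real_
    link[j, ] <- NA_real_
    link[, j] <- NA_real_
    active[j] <- FALSE
    members[[i]] <- c(members[[i]], members[[j]])
    minid[i] <- min(minid[i], minid[j])
  }

  clusters <- members[active]
  ord <- order(vapply(clusters, function(m) min(ids[m]), character(1L)))
  clusters <- clusters[ord]
  out <- integer(n)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  setNames(out, ids)
}

# Within-parent renumbering helper: children of each parent label are
# numbered by their smallest member id.
.nest_labels <- function(parent, raw_child, ids) {
  out <- character(length(ids))
  for (p in unique(parent)) {
    sel <- parent == p
    key <- raw_child[sel]
    smallest <- vapply(split(ids[sel], key), min, character(1L))
    num <- setNames(seq_along(smallest), names(sort(smallest)))
    out[sel] <- paste(p, num[key], sep = ".")
  }
  out
}

#' Nested species/genus/family/suborder delineation
#'
#' Clusters the full identity matrix at the suborder threshold, then
#' re-clusters each suborder at the family threshold, each family at the
#' genus threshold and each genus at the species threshold. The four
#' partitions are therefore nested by construction, and the
#' complete-linkage guarantee (every within-taxon pair strictly above the
#' rank threshold) is asserted on the result before it is returned.
#'
#' @param dm Identity matrix (see [distance_matrix()]).
#' @param thresholds A [rank_thresholds()] object.
#' @return A `taxonomy_assignment`: data.frame with columns `id`,
#'   `suborder`, `family`, `genus`, `species` holding dotted-path labels,
#'   with the thresholds stored as an attribute.
#' @export
nested_delineation <- function(dm, thresholds = rank_thresholds()) {
  stopifnot(inherits(thresholds, "rank_thresholds"))
  ids <- rownames(dm)
  n <- length(ids)
  sub <- cluster_at_threshold(dm, thresholds[["suborder"]])
  lab_sub <- as.character(sub)
  lab_fam <- lab_gen <- lab_sp <- character(n)

  split_rank <- function(parent_lab, threshold) {
    out <- character(n)
    for (p in unique(parent_lab)) {
      sel <- which(parent_lab == p)
      cl <- cluster_at_threshold(dm[sel, sel, drop = FALSE], threshold)
      out[sel] <- paste(p, cl, sep = ".")
    }
    out
  }
  lab_fam <- split_rank(lab_sub, thresholds[["family"]])
  lab_gen <- split_rank(lab_fam, thresholds[["genus"]])
  lab_sp <- split_rank(lab_gen, thresholds[["species"]])

  assignment <- structure(
    data.frame(id = ids, suborder = lab_sub, family = lab_fam,
               genus = lab_gen, species = lab_sp,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("taxonomy_assignment", "data.frame"),
    thresholds = thresholds)
  .assert_threshold_guarantee(assignment, dm, thresholds)
  assignment
}

# Assert the complete-linkage guarantee at every rank.
.assert_threshold_guarantee <- function(assignment, dm, thresholds) {
  pos <- match(assignment$id, rownames(dm))
  for (rank in RANKS) {
    t <- thresholds[[rank]]
    for (sel in split(pos, assignment[[rank]])) {
      if (length(sel) < 2L) next
      if (min(dm[sel, sel]) <= t)
        stop("internal error: within-", rank,
             " identity at or below threshold ", t)
    }
  }
  invisible(TRUE)
}

# Maximal monophyletic subgroups of `members` within a rooted tree:
# the tip sets of the deepest clades composed entirely of members whose
# parent clade also contains a non-member.
.max_monophyletic_groups <- function(tree, members) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  pure <- c(tree$tip.label %in% members, rep(TRUE, nnode))
  for (k in seq_len(nrow(edge)))
    pure[edge[k, 1L]] <- pure[edge[k, 1L]] && pure[edge[k, 2L]]
  parent <- rep(NA_integer_, ntip + nnode)
  parent[edge[, 2L]] <- edge[, 1L]
  maximal <- which(pure & (is.na(parent) | !pure[parent]))
  # collect tip descendants of each maximal pure node
  tips_below <- vector("list", ntip + nnode)
  for (v in seq_len(ntip)) tips_below[[v]] <- v
  for (k in seq_len(nrow(edge)))
    tips_below[[edge[k, 1L]]] <- c(tips_below[[edge[k, 1L]]],
                                   tips_below[[edge[k, 2L]]])
  groups <- lapply(maximal, function(v) sort(tree$tip.label[tips_below[[v]]]))
  groups[order(vapply(groups, min, character(1L)))]
}

#' Refine a taxonomy assignment against a rooted tree
#'
#' For every taxon at every rank (species first, suborder last), members
#' that are not monophyletic in the tree are split into their maximal
#' monophyletic subgroups — formalising manual, tree-guided curation of
#' threshold clusters. Splitting (never merging) preserves the identity
#' threshold guarantee; nesting is re-derived afterwards, with within-parent
#' renumbering by smallest member id.
#'
#' @param assignment A `taxonomy_assignment` (see [nested_delineation()]).
#' @param tree A rooted `phylo` object, or a path to a Newick file. Tips
#'   must be a superset of the assigned ids.
#' @return The refined `taxonomy_assignment`.
#' @export
refine_with_tree <- function(assignment, tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or path")
  miss <- setdiff(assignment$id, tree$tip.label)
  if (length(miss) > 0L)
    stop("tree is missing tip(s): ", paste(miss, collapse = ", "))

  raw <- assignment[RANKS]
  for (rank in rev(RANKS)) {  # species -> suborder
    lab <- raw[[rank]]
    for (tx in unique(lab)) {
      memb <- assignment$id[lab == tx]
      groups <- .max_monophyletic_groups(tree, memb)
      if (length(groups) > 1L) {
        for (k in seq_along(groups))
          lab[assignment$id %in% groups[[k]]] <- paste(tx, k, sep = "m")
      }
    }
    raw[[rank]] <- lab
  }

  ids <- assignment$id
  # rebuild globally unique nested labels; pasting the parent label into the
  # child key re-enforces nesting even if a split straddled a parent
  sub_small <- vapply(split(ids, raw$suborder), min, character(1L))
  sub_num <- setNames(seq_along(sub_small), names(sort(sub_small)))
  lab_sub <- as.character(sub_num[raw$suborder])
  lab_fam <- .nest_labels(lab_sub, paste(lab_sub, raw$family), ids)
  lab_gen <- .nest_labels(lab_fam, paste(lab_fam, raw$genus), ids)
  lab_sp <- .nest_labels(lab_gen, paste(lab_gen, raw$species), ids)

  structure(
    data.frame(id = ids, suborder = lab_sub, family = lab_fam,
               genus = lab_gen, species = lab_sp,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("taxonomy_assignment", "data.frame"),
    thresholds = attr(assignment, "thresholds"))
}

#' Hierarchical taxon names
#'
#' Converts dotted-path labels into display names of the form
#' `<Suborder>_Family_i_Genus_j_Species_k`. Suborders containing an
#' anchored sequence take the anchor's name (e.g. a classical suborder name
#' attached via its type strain); the remaining suborders are named
#' `Suborder_N` by descending member count (ties by smallest member id),
#' with numbering skipping anchored suborders. Families, genera and species
#' are numbered within their parent, also by descending size then smallest
#' member id.
#'
#' @param assignment A `taxonomy_assignment`.
#' @param anchors Optional map from sequence id to a known suborder name:
#'   a named character vector (names = ids) or a data.frame with columns
#'   `id` and `suborder_name`. Two anchors naming one suborder differently
#'   is an error.
#' @return Data.frame with columns `id`, `suborder`, `family`, `genus`,
#'   `species` holding display names.
#' @export
name_taxa <- function(assignment, anchors = NULL) {
  ids <- assignment$id
  if (!is.null(anchors) && is.data.frame(anchors))
    anchors <- setNames(anchors$suborder_name, anchors$id)

  rank_order <- function(labels) {
    sz <- table(labels)
    smallest <- vapply(split(ids, labels), min, character(1L))
    u <- names(sz)
    u[order(-as.integer(sz[u]), smallest[u])]
  }

  sub_sorted <- rank_order(assignment$suborder)
  sub_name <- setNames(rep(NA_character_, length(sub_sorted)), sub_sorted)
  if (!is.null(anchors)) {
    unknown <- setdiff(names(anchors), ids)
    if (length(unknown) > 0L)
      stop("anchor id(s) not in assignment: ", paste(unknown, collapse = ", "))
    for (s in sub_sorted) {
      hit <- anchors[names(anchors) %in% ids[assignment$suborder == s]]
      if (length(hit) > 0L) {
        if (length(unique(hit)) > 1L)
          stop("conflicting anchor names in one suborder: ",
               paste(unique(hit), collapse = " vs "))
        sub_name[s] <- hit[[1L]]
      }
    }
  }
  free <- is.na(sub_name)
  sub_name[free] <- paste0("Suborder_", seq_len(sum(free)))

  name_children <- function(parent_lab, child_lab, parent_names, tag) {
    out <- character(length(ids))
    for (p in unique(parent_lab)) {
      sel <- parent_lab == p
      sz <- table(child_lab[sel])
      smallest <- vapply(split(ids[sel], child_lab[sel]), min, character(1L))
      u <- names(sz)
      u <- u[order(-as.integer(sz[u]), smallest[u])]
      num <- setNames(seq_along(u), u)
      out[sel] <- paste0(parent_names[sel], "_", tag, "_",
                         num[child_lab[sel]])
    }
    out
  }

  nm_sub <- unname(sub_name[assignment$suborder])
  nm_fam <- name_children(assignment$suborder, assignment$family, nm_sub, "Family")
  nm_gen <- name_children(assignment$family, assignment$genus, nm_fam, "Genus")
  nm_sp <- name_children(assignment$genus, assignment$species, nm_gen, "Species")

  data.frame(id = ids, suborder = nm_sub, family = nm_fam,
             genus = nm_gen, species = nm_sp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a per-suborder taxon table from counts
#'
#' The summary table reported by rank delineation: one row per suborder
#' with its family/genus/species/sequence counts, the percentage of all
#' sequences (two decimals) and the abundant/rare flag (abundant when the
#' suborder holds at least `abundant_cutoff` of all sequences), plus a
#' totals row. Rank-wise totals are also attached as the `totals`
#' attribute: number of suborders, families, genera, species and sequences.
#'
#' @param suborder Character vector of suborder names.
#' @param families,genera,species,sequences Integer count vectors parallel
#'   to `suborder`.
#' @param abundant_cutoff Abundance cutoff as a fraction of all sequences
#'   (default 0.005, inclusive).
#' @return A `taxon_table` data.frame.
#' @export
taxon_table <- function(suborder, families, genera, species, sequences,
                        abundant_cutoff = 0.005) {
  stopifnot(length(suborder) > 0,
            length(families) == length(suborder),
            length(genera) == length(suborder),
            length(species) == length(suborder),
            length(sequences) == length(suborder))
  total <- sum(sequences)
  status <- classify_abundance(sequences, total, abundant_cutoff)
  pct <- round(100 * sequences / total, 2L)
  body <- data.frame(suborder = suborder, status = status,
                     families = as.integer(families),
                     genera = as.integer(genera),
                     species = as.integer(species),
                     sequences = as.integer(sequences),
                     pct = pct, stringsAsFactors = FALSE)
  totals <- c(suborder = nrow(body),
              family = sum(body$families),
              genus = sum(body$genera),
              species = sum(body$species),
              sequences = sum(body$sequences))
  total_row <- data.frame(suborder = "Total", status = NA_character_,
                          families = unname(totals[["family"]]),
                          genera = unname(totals[["genus"]]),
                          species = unname(totals[["species"]]),
                          sequences = unname(totals[["sequences"]]),
                          pct = NA_real_, stringsAsFactors = FALSE)
  structure(rbind(body, total_row),
            class = c("taxon_table", "data.frame"),
            totals = totals, abundant_cutoff = abundant_cutoff)
}

#' Summarize a taxonomy assignment into a per-suborder table
#'
#' Counts distinct families, genera and species within each suborder, plus
#' sequence counts and percentages, and flags each suborder abundant or
#' rare. Works on raw dotted-path labels or on named taxa from
#' [name_taxa()]. Rows are ordered by descending sequence count.
#'
#' @param assignment Data.frame with columns `id`, `suborder`, `family`,
#'   `genus`, `species` (a `taxonomy_assignment` or [name_taxa()] output).
#' @param abundant_cutoff Abundance cutoff as a fraction of all sequences
#'   (default 0.005, inclusive).
#' @return A `taxon_table` (see [taxon_table()]).
#' @export
summarize_taxonomy <- function(assignment, abundant_cutoff = 0.005) {
  subs <- unique(assignment$suborder)
  cnt <- function(col, s) length(unique(assignment[[col]][assignment$suborder == s]))
  fam <- vapply(subs, cnt, integer(1L), col = "family")
  gen <- vapply(subs, cnt, integer(1L), col = "genus")
  sp <- vapply(subs, cnt, integer(1L), col = "species")
  nseq <- vapply(subs, function(s) sum(assignment$suborder == s), integer(1L))
  ord <- order(-nseq, subs)
  taxon_table(subs[ord], fam[ord], gen[ord], sp[ord], nseq[ord],
              abundant_cutoff = abundant_cutoff)
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("Taxon table (abundant cutoff ",
      100 * attr(x, "abundant_cutoff"), "% of ",
      attr(x, "totals")[["sequences"]], " sequences)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write a taxonomy assignment as TSV
#'
#' @param assignment Data.frame with `id` and the four rank columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assignment_tsv <- function(assignment, path) {
  write.table(as.data.frame(assignment), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
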