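# One-call pipeline: QC -> distances -> delineation -> biogeography ->
# rarefaction, with every table written as TSV and a JSON run manifest
# (parameters plus input/output checksums) so reruns are auditable.

#' Pipeline run configuration
#'
#' Collects the input paths and every tunable parameter of a full run.
#' Referenced paths must exist at construction.
#'
#' @param fasta Aligned multi-FASTA of 16S rRNA gene sequences.
#' @param out_dir Output directory (created by [run_all()]).
#' @param metadata Optional metadata TSV (see [read_metadata()]).
#' @param tree Optional rooted Newick tree for monophyly refinement.
#' @param anchors Optional anchors TSV with columns `id`,
#'   `suborder_name` mapping known sequences to suborder names.
#' @param qc [qc_params()].
#' @param thresholds [rank_thresholds()].
#' @param abundant_cutoff Abundance cutoff (fraction of all sequences).
#' @param specificity [specificity_params()].
#' @param rarefaction_depths Optional integer vector of subsample depths.
#' @param k2p_max_distance Cap substituted for saturated K2P pairs in the
#'   reported distance table (raw identity, not K2P, drives delineation).
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return A named list with class `run_config`.
#' @export
run_config <- function(fasta, out_dir, metadata = NULL, tree = NULL,
                       anchors = NULL, qc = qc_params(),
                       thresholds = rank_thresholds(),
                       abundant_cutoff = 0.005,
                       specificity = specificity_params(),
                       rarefaction_depths = NULL,
                       k2p_max_distance = 3,
                       seed = 1L) {
  for (p in c(fasta, metadata, tree, anchors))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(inherits(qc, "qc_params"),
            inherits(thresholds, "rank_thresholds"),
            inherits(specificity, "specificity_params"),
            abundant_cutoff > 0, abundant_cutoff < 1)
  structure(list(fasta = fasta, metadata = metadata, tree = tree,
                 anchors = anchors, out_dir = out_dir, qc = qc,
                 thresholds = thresholds,
                 abundant_cutoff = abundant_cutoff,
                 specificity = specificity,
                 rarefaction_depths = rarefaction_depths,
                 k2p_max_distance = k2p_max_distance,
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Run the full delineation pipeline
#'
#' Executes, in order: sequence QC and strain deduplication, identity and
#' K2P distance matrices, nested rank delineation (with optional
#' tree-guided refinement and anchor-based naming), the per-suborder taxon
#' table, taxon-by-environment distributions at all four ranks, the
#' specialist/cosmopolitan profile, the culturability breakdown, and
#' rarefaction curves plus Good's coverage by abundant suborder and by
#' environmental category. All tables are written under
#' `config$out_dir`, together with a `manifest.json` recording parameters
#' and MD5 checksums of inputs and outputs.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the in-memory results (`records`,
#'   `kept`, `rejected`, `assignment`, `names`, `taxon_table`,
#'   `distributions`, `specificity`, `culturability`, `rarefaction`,
#'   `coverage`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  records <- read_sequences(config$fasta, config$metadata)
  flt <- filter_sequences(records, config$qc)
  reps <- dedupe_by_strain(flt$kept)
  write_rejection_report(flt$rejected, file.path(out, "qc_rejected.tsv"))
  write_fasta(reps, file.path(out, "qc_passed.fasta"))

  seqs <- setNames(reps$residues, reps$id)
  im <- distance_matrix(seqs, "identity")
  write_distance_tsv(im, file.path(out, "identity_matrix.tsv"))
  .write_tsv(pairwise_table(seqs, max_distance = config$k2p_max_distance),
             file.path(out, "pairwise_distances.tsv"))

  assignment <- nested_delineation(im, config$thresholds)
  if (!is.null(config$tree))
    assignment <- refine_with_tree(assignment, config$tree)
  anchors <- NULL
  if (!is.null(config$anchors))
    anchors <- read.delim(config$anchors, colClasses = "character",
                          stringsAsFactors = FALSE)
  named <- name_taxa(assignment, anchors)
  write_assignment_tsv(named, file.path(out, "assignment.tsv"))

  tt <- summarize_taxonomy(named, config$abundant_cutoff)
  .write_tsv(as.data.frame(tt), file.path(out, "taxon_table.tsv"))

  distributions <- lapply(setNames(RANKS, RANKS), function(r) {
    m <- distribution_matrix(named, reps, r)
    .write_tsv(data.frame(taxon = rownames(m), m, check.names = FALSE),
               file.path(out, paste0("distribution_", r, ".tsv")))
    m
  })

  prof <- specificity_profile(named, reps, config$specificity)
  .write_tsv(prof, file.path(out, "specificity_profile.tsv"))

  cult <- culturability_breakdown(reps, named)
  .write_tsv(cult$by_environment, file.path(out, "culturability_environment.tsv"))
  .write_tsv(cult$by_suborder, file.path(out, "culturability_suborder.tsv"))

  body <- tt[tt$suborder != "Total", ]
  abundant <- body$suborder[body$status == "abundant"]
  groups_sub <- abundance_by_group(named[named$suborder %in% abundant, ],
                                   named$suborder[named$suborder %in% abundant])
  env_of <- reps$env_category[match(named$id, reps$id)]
  groups_env <- abundance_by_group(named, env_of)
  rare_sub <- curve_family(groups_sub, config$rarefaction_depths)
  rare_env <- curve_family(groups_env, config$rarefaction_depths)
  .write_tsv(rare_sub, file.path(out, "rarefaction_suborder.tsv"))
  .write_tsv(rare_env, file.path(out, "rarefaction_environment.tsv"))
  cov <- rbind(cbind(grouping = "suborder", coverage_table(groups_sub)),
               cbind(grouping = "environment", coverage_table(groups_env)))
  .write_tsv(cov, file.path(out, "coverage.tsv"))

  outputs <- list.files(out, pattern = "\\.(tsv|fasta)$", full.names = TRUE)
  inputs <- c(config$fasta, config$metadata, config$tree, config$anchors)
  manifest <- list(
    parameters = list(
      qc = unclass(config$qc),
      thresholds = as.list(unclass(config$thresholds)),
      abundant_cutoff = config$abundant_cutoff,
      specificity = unclass(config$specificity),
      k2p_max_distance = config$k2p_max_distance,
      linkage = "complete",
      linkage_rationale = paste(
        "complete linkage is the only standard linkage guaranteeing that",
        "every within-taxon pair exceeds the rank identity threshold"),
      seed = config$seed),
    counts = list(input = nrow(records), kept = nrow(flt$kept),
                  rejected = nrow(flt$rejected),
                  representatives = nrow(reps),
                  suborders = unname(attr(tt, "totals")[["suborder"]]),
                  families = unname(attr(tt, "totals")[["family"]]),
                  genera = unname(attr(tt, "totals")[["genus"]]),
                  species = unname(attr(tt, "totals")[["species"]])),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, kept = flt$kept,
                 rejected = flt$rejected, representatives = reps,
                 identity = im, assignment = assignment, names = named,
                 taxon_table = tt, distributions = distributions,
                 specificity = prof, culturability = cult,
                 rarefaction = list(suborder = rare_sub,
                                    environment = rare_env),
                 coverage = cov, manifest = manifest))
}

#' New-taxa counts relative to a reference classification
#'
#' Element-wise difference between a taxon table's rank totals and
#' reference per-rank counts (e.g. the re-classified validly described
#' type strains), giving the number of newly delineated taxa per rank.
#'
#' @param table A `taxon_table` (see [summarize_taxonomy()]).
#' @param reference_counts Named numeric vector with entries `suborder`,
#'   `family`, `genus`, `species`; must not exceed the table totals.
#' @return Named integer vector of new-taxon counts per rank.
#' @examples
#' tt <- with(reference_taxon_counts(),
#'            taxon_table(suborder, families, genera, species, sequences))
#' new_taxa_delta(tt, type_strain_rank_counts)
#' @export
new_taxa_delta <- function(table, reference_counts) {
  stopifnot(inherits(table, "taxon_table"))
  need <- c("suborder", "family", "genus", "species")
  if (!all(need %in% names(reference_counts)))
    stop("reference_counts must be named: ", paste(need, collapse = ", "))
  totals <- attr(table, "totals")[need]
  delta <- totals - as.integer(reference_counts[need])
  if (any(delta < 0))
    stop("reference counts exceed table totals at rank(s): ",
         paste(need[delta < 0], collapse = ", "))
  setNames(as.integer(delta), need)
}

#' Published per-suborder survey counts
#'
#' Per-suborder family/genus/species/sequence counts from a published
#' global survey of myxobacterial 16S rRNA gene diversity (4997
#' near-full-length sequences resolved into 20 suborders), bundled as a
#' plain-text reference for consistency checks of the summariser.
#'
#' @return Data.frame with columns `suborder`, `families`, `genera`,
#'   `species`, `sequences` (20 rows).
#' @export
reference_taxon_counts <- function() {
  path <- system.file("extdata", "survey_taxon_counts.tsv",
                      package = "myxotax", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Rank counts of re-classified validly described type strains
#'
#' Number of suborders, families, genera and species obtained when the
#' validly described type strains of the order Myxococcales are
#' re-classified under the same identity thresholds; the baseline against
#' which new-taxa counts are computed (see [new_taxa_delta()]).
#'
#' @format Named integer vector with entries `suborder`, `family`,
#'   `genus`, `species`.
#' @export
type_strain_rank_counts <- c(suborder = 4L, family = 7L, genus = 13L,
                             species = 24L)
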