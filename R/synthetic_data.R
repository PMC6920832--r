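# Synthetic aligned sequence communities with known nested taxonomy,
# environment labels and culturability, so every pipeline stage can be
# validated against ground truth without external data.
#
# Sequences are derived top-down from a random root: each taxon at each
# rank gets a representative obtained by applying a fixed number of
# substitutions to its parent's representative (transition:transversion
# mix set by kappa). Substitution counts per rank are calibrated from the
# midpoints of the requested identity bands; sibling edges draw their
# mutated sites disjointly, so realized pairwise identities concentrate
# tightly around the band midpoints. Every emitted community is audited:
# all pairwise identities must fall inside the band of their pair class,
# otherwise the community is regenerated from a derived seed.

#' Default environmental category weights for simulation
#'
#' A soil-dominated but flattened weight vector over the ten categories,
#' echoing the skew of public 16S collections while keeping the chance
#' that a small cosmopolitan taxon looks specialist by accident low.
#'
#' @return Named numeric vector over [env_categories()], summing to 1.
#' @export
default_env_weights <- function() {
  w <- c(M_organism = 0.09, M_sediment = 0.07, Seawater = 0.05,
         Soil = 0.30, T_sediment = 0.08, Activated_sludge = 0.07,
         T_organism = 0.05, Freshwater = 0.09, Human = 0.08,
         The_unknown = 0.12)
  w / sum(w)
}

# Per-edge substitution counts from band midpoints. The expected
# divergence between two members of the same class is the sum of the edge
# counts along their path minus homoplasy: when two path edges hit the same
# site the planted count drops by one (two substitutions realise at most
# one difference), and by two when the end states coincide. The top edges
# of a path are siblings and draw disjoint sites, so they never collide;
# for every other edge pair the expected collision count is m_e * m_f / L.
# Calibration solves for edge counts whose homoplasy-corrected expectation
# sits at each band midpoint (fixed-point iteration, then rounding).
.calibrate_edges <- function(len, bands, kappa = 2.0) {
  mid <- vapply(bands, mean, numeric(1L))
  d0 <- len * (1 - mid)  # midpoint differing sites per pair class
  p_ts <- kappa / (kappa + 2)
  reduction_factor <- 1 + p_ts^2 + (1 - p_ts)^2 / 2

  solve_m <- function(d) {
    m_seq <- d[["within_species"]] / 2
    m_species <- (d[["within_genus"]] - 2 * m_seq) / 2
    m_genus <- (d[["within_family"]] - 2 * m_species - 2 * m_seq) / 2
    m_family <- (d[["within_suborder"]] - 2 * m_genus - 2 * m_species -
                   2 * m_seq) / 2
    m_suborder <- (d[["between_suborders"]] - 2 * m_family - 2 * m_genus -
                     2 * m_species - 2 * m_seq) / 2
    c(suborder = m_suborder, family = m_family, genus = m_genus,
      species = m_species, seq = m_seq)
  }
  path_edges <- list(
    within_species = "seq",
    within_genus = c("species", "seq"),
    within_family = c("genus", "species", "seq"),
    within_suborder = c("family", "genus", "species", "seq"),
    between_suborders = c("suborder", "family", "genus", "species", "seq"))
  expected_reduction <- function(m) {
    vapply(path_edges, function(e) {
      s <- sum(m[e])
      reduction_factor * (2 * s^2 - m[e[1L]]^2 - sum(m[e]^2)) / len
    }, numeric(1L))
  }

  m <- solve_m(d0)
  for (iter in 1:4) m <- solve_m(d0 + expected_reduction(m))
  m <- round(m)
  if (any(m < 1))
    stop("infeasible divergence bands: calibrated substitution count(s) ",
         "below 1 per edge (", paste(names(m)[m < 1], collapse = ", "), ")")
  m
}

.default_bands <- function() {
  list(within_species = c(0.985, 1.0),
       within_genus = c(0.950, 0.965),
       within_family = c(0.905, 0.935),
       within_suborder = c(0.860, 0.882),
       between_suborders = c(0.70, 0.84))
}

.check_bands <- function(bands, thresholds, margin = 0.005) {
  need <- names(.default_bands())
  if (!identical(sort(names(bands)), sort(need)))
    stop("bands must be named: ", paste(need, collapse = ", "))
  for (b in bands)
    if (length(b) != 2L || b[1L] > b[2L] || b[1L] < 0 || b[2L] > 1)
      stop("each band must be an increasing pair within [0, 1]")
  ord <- c("between_suborders", "within_suborder", "within_family",
           "within_genus", "within_species")
  for (k in seq_len(length(ord) - 1L))
    if (bands[[ord[k]]][2L] >= bands[[ord[k + 1L]]][1L])
      stop("divergence bands must be pairwise disjoint and ordered")
  pairs <- list(c("species", "within_species", "within_genus"),
                c("genus", "within_genus", "within_family"),
                c("family", "within_family", "within_suborder"),
                c("suborder", "within_suborder", "between_suborders"))
  for (p in pairs) {
    t <- thresholds[[p[1L]]]
    if (bands[[p[2L]]][1L] < t + margin || bands[[p[3L]]][2L] > t - margin)
      stop("band(s) around the ", p[1L], " threshold (", t,
           ") are separated by less than ", margin, " identity")
  }
  invisible(TRUE)
}

.draw_count <- function(x) {
  if (length(x) == 1L) as.integer(x)
  else sample(seq.int(x[1L], x[2L]), 1L)
}

#' Simulation specification for a synthetic community
#'
#' Defines the planted taxonomy (counts per rank, each a fixed integer or
#' an inclusive `c(lo, hi)` range), the per-rank identity bands the
#' realized pairwise identities must fall into, the sequence model
#' (length, transition/transversion ratio `kappa`), the environment model
#' (target rank, specialist fraction, per-category weights) and the
#' culturability proportions. Band feasibility — pairwise disjoint and
#' separated from every rank threshold by at least 0.005 identity — and
#' the per-edge substitution calibration are checked at construction.
#'
#' @param n_suborders,families_per_suborder,genera_per_family,species_per_genus,seqs_per_species
#'   Planted counts; a single integer or an inclusive range `c(lo, hi)`.
#' @param length Alignment length in bases.
#' @param kappa Transition/transversion rate ratio (2.0 is the classic
#'   default for 16S-like data).
#' @param bands Named list of identity intervals: `within_species`,
#'   `within_genus`, `within_family`, `within_suborder`,
#'   `between_suborders`.
#' @param thresholds The [rank_thresholds()] the community must be
#'   recoverable under.
#' @param env Environment model: `target_rank` (rank at which specialists
#'   are planted), `specialist_fraction`, `home_dominance` (fraction of a
#'   specialist taxon's members drawn from its home category) and
#'   `weights` over [env_categories()].
#' @param culturability Named proportions for
#'   `cultured`/`uncultured`/`unknown` labels.
#' @param ambiguity_rate,gap_rate Optional per-site noise rates injecting
#'   `N` and `-` characters after generation, to exercise the QC and
#'   pairwise-deletion paths (default off).
#' @param seed Integer seed; the whole community is reproducible from it.
#' @param max_tries Attempts at regenerating a community whose realized
#'   identities violate a band before giving up.
#' @return A named list with class `sim_spec`.
#' @export
sim_spec <- function(n_suborders = 4L, families_per_suborder = 2L,
                     genera_per_family = 2L, species_per_genus = 3L,
                     seqs_per_species = c(3L, 7L),
                     length = 1400L, kappa = 2.0,
                     bands = .default_bands(),
                     thresholds = rank_thresholds(),
                     env = list(target_rank = "genus",
                                specialist_fraction = 0.5,
                                home_dominance = 0.9,
                                weights = default_env_weights()),
                     culturability = c(cultured = 0.2203,
                                       uncultured = 0.7785,
                                       unknown = 0.0012),
                     ambiguity_rate = 0, gap_rate = 0,
                     seed = 1L, max_tries = 20L) {
  counts <- list(n_suborders = n_suborders,
                 families_per_suborder = families_per_suborder,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 seqs_per_species = seqs_per_species)
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (!length(x) %in% c(1L, 2L) || any(x < 1) || any(x != round(x)))
      stop("'", nm, "' must be a positive integer or an integer range")
  }
  stopifnot(length >= 100L, kappa > 0,
            env$target_rank %in% RANKS,
            env$specialist_fraction >= 0, env$specialist_fraction <= 1,
            env$home_dominance >= 0.8, env$home_dominance <= 1,
            ambiguity_rate >= 0, ambiguity_rate < 1,
            gap_rate >= 0, gap_rate < 1)
  if (!identical(sort(names(env$weights)), sort(env_categories())))
    stop("env$weights must be named over the 10 environmental categories")
  if (!setequal(names(culturability), c("cultured", "uncultured", "unknown")) ||
      length(culturability) != 3L)
    stop("culturability must be named cultured/uncultured/unknown")
  .check_bands(bands, thresholds)
  edges <- .calibrate_edges(length, bands, kappa)
  max_sub <- if (base::length(n_suborders) == 2L) n_suborders[2L] else n_suborders
  if (edges[["suborder"]] * max_sub > length)
    stop("infeasible bands: suborder edges need more sites than the alignment")
  structure(c(counts,
              list(length = as.integer(length), kappa = kappa,
                   bands = bands, thresholds = thresholds, edges = edges,
                   env = env,
                   culturability = culturability / sum(culturability),
                   ambiguity_rate = ambiguity_rate, gap_rate = gap_rate,
                   seed = as.integer(seed),
                   max_tries = as.integer(max_tries))),
            class = "sim_spec")
}

# Apply `m` substitutions to `parent` (character vector) at the given
# sites; transitions with probability kappa/(kappa + 2).
.mutate_sites <- function(parent, sites, kappa) {
  if (length(sites) == 0L) return(parent)
  cur <- parent[sites]
  is_ts <- runif(length(sites)) < kappa / (kappa + 2)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  new <- character(length(sites))
  new[is_ts] <- ts_map[cur[is_ts]]
  tv <- which(!is_ts)
  if (length(tv) > 0L) {
    purine <- cur[tv] %in% c("A", "G")
    pick <- runif(length(tv)) < 0.5
    new[tv] <- ifelse(purine,
                      ifelse(pick, "C", "T"),
                      ifelse(pick, "A", "G"))
  }
  parent[sites] <- new
  parent
}

# Children of one node: sites drawn jointly without replacement so sibling
# edges never collide.
.child_seqs <- function(parent, n_children, m, kappa) {
  len <- length(parent)
  if (m * n_children > len)
    stop("infeasible bands: sibling edges need more sites than the alignment")
  pool <- sample.int(len, m * n_children)
  lapply(seq_len(n_children), function(k) {
    sites <- pool[seq.int((k - 1L) * m + 1L, k * m)]
    .mutate_sites(parent, sites, kappa)
  })
}

.generate_once <- function(spec) {
  len <- spec$length
  root <- sample(DNA_BASES, len, replace = TRUE)
  edges <- spec$edges
  kappa <- spec$kappa

  seqs <- list()
  tax <- list()
  counter <- 0L

  subs <- .child_seqs(root, .draw_count(spec$n_suborders),
                      edges[["suborder"]], kappa)
  for (si in seq_along(subs)) {
    fams <- .child_seqs(subs[[si]], .draw_count(spec$families_per_suborder),
                        edges[["family"]], kappa)
    for (fi in seq_along(fams)) {
      gens <- .child_seqs(fams[[fi]], .draw_count(spec$genera_per_family),
                          edges[["genus"]], kappa)
      for (gi in seq_along(gens)) {
        sps <- .child_seqs(gens[[gi]], .draw_count(spec$species_per_genus),
                           edges[["species"]], kappa)
        for (pi in seq_along(sps)) {
          leaves <- .child_seqs(sps[[pi]], .draw_count(spec$seqs_per_species),
                                edges[["seq"]], kappa)
          for (li in seq_along(leaves)) {
            counter <- counter + 1L
            id <- sprintf("seq%04d", counter)
            seqs[[id]] <- leaves[[li]]
            tax[[id]] <- c(si, fi, gi, pi)
          }
        }
      }
    }
  }

  ids <- names(seqs)
  # optional noise: ambiguity and gap injection per site
  if (spec$ambiguity_rate > 0 || spec$gap_rate > 0) {
    for (id in ids) {
      s <- seqs[[id]]
      u <- runif(len)
      s[u < spec$ambiguity_rate] <- "N"
      v <- runif(len)
      s[v < spec$gap_rate] <- GAP_CHAR
      seqs[[id]] <- s
    }
  }
  sequences <- vapply(seqs, paste, character(1L), collapse = "")

  m <- do.call(rbind, tax)
  taxonomy <- data.frame(
    id = ids,
    suborder = as.character(m[, 1L]),
    family = paste(m[, 1L], m[, 2L], sep = "."),
    genus = paste(m[, 1L], m[, 2L], m[, 3L], sep = "."),
    species = paste(m[, 1L], m[, 2L], m[, 3L], m[, 4L], sep = "."),
    stringsAsFactors = FALSE, row.names = NULL)
  list(sequences = sequences, taxonomy = taxonomy)
}

# Audit realized pairwise identities against the band of each pair class.
.audit_bands <- function(sequences, taxonomy, spec) {
  im <- distance_matrix(sequences, "identity")
  im <- im[taxonomy$id, taxonomy$id]
  same <- function(col) outer(taxonomy[[col]], taxonomy[[col]], "==")
  cls <- matrix("between_suborders", nrow(im), ncol(im))
  cls[same("suborder")] <- "within_suborder"
  cls[same("family")] <- "within_family"
  cls[same("genus")] <- "within_genus"
  cls[same("species")] <- "within_species"
  off <- upper.tri(im)
  rows <- lapply(names(spec$bands), function(b) {
    sel <- off & cls == b
    if (!any(sel))
      return(data.frame(class = b, n_pairs = 0L, lo = NA_real_, hi = NA_real_,
                        band_lo = spec$bands[[b]][1L],
                        band_hi = spec$bands[[b]][2L], ok = TRUE))
    v <- im[sel]
    data.frame(class = b, n_pairs = sum(sel), lo = min(v), hi = max(v),
               band_lo = spec$bands[[b]][1L], band_hi = spec$bands[[b]][2L],
               ok = min(v) >= spec$bands[[b]][1L] &&
                 max(v) <= spec$bands[[b]][2L],
               stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, rows)
  list(ok = all(audit$ok), table = audit)
}

#' Generate a synthetic sequence community
#'
#' Builds an aligned community from a [sim_spec()]: root sequence, rank
#' representatives derived top-down by planted substitutions, per-sequence
#' environment and culturability labels, and a ground-truth object. The
#' realized pairwise identities are audited against the spec's bands; a
#' violating draw is regenerated from a derived seed (`max_tries` cap).
#' Byte-identical output is guaranteed for a fixed spec.
#'
#' @param spec A [sim_spec()] object.
#' @return A list with class `myxo_community`: `sequences` (named aligned
#'   residue strings), `records` (metadata data.frame as in
#'   [read_sequences()]), and `truth` (list with the planted `taxonomy`,
#'   the band `audit`, the environment truth `env`, and the spec).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  base_seed <- abs(spec$seed) %% 1000000000L
  for (attempt in seq_len(spec$max_tries)) {
    set.seed(base_seed + attempt - 1L)
    g <- .generate_once(spec)
    aud <- .audit_bands(g$sequences, g$taxonomy, spec)
    if (aud$ok) {
      truth <- list(taxonomy = g$taxonomy, audit = aud$table,
                    attempt = attempt, spec = spec)
      records <- assign_environments(truth, spec)
      truth$env <- attr(records, "env_truth")
      attr(records, "env_truth") <- NULL
      out <- list(sequences = g$sequences, records = records, truth = truth)
      class(out) <- "myxo_community"
      return(out)
    }
  }
  stop("could not generate a community inside the divergence bands after ",
       spec$max_tries, " attempts; widen the bands or shorten the hierarchy")
}

#' Assign environment, culturability and geography labels
#'
#' At the spec's target rank each planted taxon is flagged specialist with
#' probability `env$specialist_fraction`; a specialist taxon draws a home
#' category from the weight vector and places `ceiling(home_dominance * n)`
#' of its members there (the rest from the remaining categories), so any
#' flagged taxon with at least five members satisfies the 80-percent
#' specificity criterion by construction. Cosmopolitan taxa draw all
#' members from the global weights. Culturability labels are drawn
#' independently per sequence. Seeded from the spec, independently of
#' sequence generation.
#'
#' @param truth Truth list holding the planted `taxonomy` (see
#'   [generate_community()]).
#' @param spec The [sim_spec()].
#' @return Records metadata data.frame (no residues); the per-taxon
#'   environment truth is attached as attribute `env_truth`.
#' @export
assign_environments <- function(truth, spec) {
  set.seed((abs(spec$seed) %% 1000000000L) + 104729L)
  tax <- truth$taxonomy
  rank <- spec$env$target_rank
  weights <- spec$env$weights[env_categories()]
  taxa <- unique(tax[[rank]])
  flagged <- runif(length(taxa)) < spec$env$specialist_fraction
  names(flagged) <- taxa

  env <- character(nrow(tax))
  home <- setNames(rep(NA_character_, length(taxa)), taxa)
  for (tx in taxa) {
    sel <- which(tax[[rank]] == tx)
    n <- length(sel)
    if (flagged[[tx]]) {
      h <- sample(names(weights), 1L, prob = weights)
      home[[tx]] <- h
      nh <- ceiling(spec$env$home_dominance * n)
      others <- weights[names(weights) != h]
      lab <- c(rep(h, nh),
               sample(names(others), n - nh, replace = TRUE, prob = others))
      env[sel] <- sample(lab)
    } else {
      env[sel] <- sample(names(weights), n, replace = TRUE, prob = weights)
    }
  }

  sizes <- as.integer(table(tax[[rank]])[taxa])
  env_truth <- data.frame(
    taxon = taxa, rank = rank, n = sizes,
    planted_specialist = unname(flagged),
    home_category = unname(home),
    planted_class = ifelse(flagged & sizes >= 5L, "specialist",
                           "cosmopolitan"),
    stringsAsFactors = FALSE)

  cultured <- sample(names(spec$culturability), nrow(tax), replace = TRUE,
                     prob = spec$culturability)
  countries <- c("China", "USA", "Germany", "Japan", "India",
                 "Mexico", "Denmark", "Spain", "France", "Panama")
  records <- data.frame(
    id = tax$id,
    strain_key = tax$id,
    env_category = env,
    country = sample(countries, nrow(tax), replace = TRUE),
    latitude = round(runif(nrow(tax), -60, 70), 4L),
    longitude = round(runif(nrow(tax), -180, 180), 4L),
    cultured = cultured,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(records, "env_truth") <- env_truth
  records
}

# Newick string of the planted hierarchy (topology only; singleton clades
# collapse onto their child so the tree parses cleanly).
.truth_newick <- function(taxonomy) {
  wrap <- function(children) {
    if (length(children) == 1L) children
    else paste0("(", paste(children, collapse = ","), ")")
  }
  sub_clades <- vapply(split(taxonomy, taxonomy$suborder), function(ts) {
    fam_clades <- vapply(split(ts, ts$family), function(tf) {
      gen_clades <- vapply(split(tf, tf$genus), function(tg) {
        sp_clades <- vapply(split(tg$id, tg$species), wrap, character(1L))
        wrap(unname(sp_clades))
      }, character(1L))
      wrap(unname(gen_clades))
    }, character(1L))
    wrap(unname(fam_clades))
  }, character(1L))
  paste0("(", paste(unname(sub_clades), collapse = ","), ");")
}

#' Write a synthetic community to disk as a reusable fixture
#'
#' Emits the aligned FASTA, the metadata TSV, the ground truth as JSON and
#' the planted hierarchy as a rooted Newick tree (every planted taxon is a
#' clade, so tree-guided refinement is a no-op on truth labels).
#'
#' @param community A `myxo_community` from [generate_community()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(community, dir) {
  stopifnot(inherits(community, "myxo_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "alignment.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"),
             tree = file.path(dir, "tree.nwk"))
  write_fasta(community$sequences, paths[["fasta"]])
  write.table(community$records, paths[["metadata"]], sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  spec <- community$truth$spec
  truth_json <- list(
    taxonomy = community$truth$taxonomy,
    audit = community$truth$audit,
    env = community$truth$env,
    attempt = community$truth$attempt,
    spec = list(length = spec$length, kappa = spec$kappa,
                bands = spec$bands,
                thresholds = as.numeric(spec$thresholds),
                edges = as.list(spec$edges), seed = spec$seed))
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(.truth_newick(community$truth$taxonomy), paths[["tree"]])
  invisible(paths)
}
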