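---
title: "Nested taxonomic delineation of 16S rRNA gene collections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested taxonomic delineation of 16S rRNA gene collections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxotax)
```

## The problem

Myxobacteria (order *Myxococcales*) are social, predatory
Deltaproteobacteria whose cultured representatives cover only a small
corner of the diversity visible in public 16S rRNA gene collections.
Large meta-surveys of such collections resolve thousands of deposited
sequences into operational taxa at several nested ranks, then ask which
taxa are abundant, which are habitat specialists, and how far sampling is
from saturation. `myxotax` implements that analysis chain as a tested,
reusable pipeline: quality control, pairwise distances, nested rank
delineation, biogeographic classification and rarefaction, plus a
synthetic-community generator that makes every stage verifiable against a
known ground truth.

The pipeline consumes an aligned multi-FASTA (alignment itself, e.g. with
MAFFT, is an upstream concern) and an optional metadata table and rooted
tree. Taxonomic pre-screening and chimera removal are likewise assumed to
have happened upstream; the QC stage implements the two record-level rules
that can be checked from the sequence alone.

## Quality control

Two filters define a usable record:

* **Length.** Near-full-length means at least 1200 ungapped bases.
  Length is measured on ungapped residues so a record passes or fails
  identically whether it arrives aligned or unaligned. (Whether alignment
  gaps should count toward length is not a settled convention; measuring
  ungapped residues is this package's choice, made so the filter is
  representation-invariant.)
* **Ambiguity.** The fraction of non-gap residues outside `A/C/G/T` must
  be *strictly* below 0.2% — the equivalent of fewer than three ambiguous
  bases in 1500, so a 1500-base sequence with exactly three `N`s is
  rejected. All IUPAC ambiguity codes count as ambiguous; `U` is
  normalised to `T` on ingest rather than treated as ambiguous.

Duplicate deposits of one strain (shared `strain_key`) collapse to the
longest high-quality sequence; length ties break to the lexicographically
smallest id, a rule chosen purely so the result is deterministic and
testable.

## Distances

All pairwise quantities use **pairwise deletion**: for each pair of rows,
alignment columns containing a gap or ambiguity code in either row are
dropped for that pair only. Complete deletion (dropping a column globally)
was rejected because a single poor sequence would then erase information
from every pair; pairwise deletion matches what the common identity tools
do.

Two values are computed for every pair:

* **Raw identity**: matching bases over compared sites.
* **Kimura two-parameter distance**: with transition proportion $P$
  (A↔G, C↔T) and transversion proportion $Q$ over compared sites,

  $$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).$$

  When $1-2P-Q \le 0$ or $1-2Q \le 0$ the correction is undefined
  (saturation); the default is an error naming the pair, with an optional
  configurable cap for reporting workflows.

The rank thresholds below are applied to **raw identity**, not to a
K2P-derived similarity. The thresholds in routine use in the 16S
literature are stated as percent identities, and identity is what the
boundary semantics ("97.0% or lower ⇒ distinct") are defined on; K2P
distances are computed and written alongside so the choice stays
auditable in the output tables.

## Nested rank delineation

Four fixed identity cutoffs delineate the ranks: 0.970 (species), 0.945
(genus), 0.890 (family), 0.850 (suborder). A pair at or *below* a cutoff
is evidence for distinct taxa at that rank, so co-membership requires
identity strictly above the cutoff — a pair at exactly 0.970 lands in two
species.

Three design choices deserve justification:

* **Complete linkage.** No clustering algorithm is forced by the
  threshold statement alone, but complete linkage (furthest neighbour) is
  the only standard linkage under which the pairwise statement holds for
  *every* within-taxon pair: clusters merge only while the minimum
  cross-pair identity stays above the cutoff. Single or average linkage
  would admit within-species pairs below 97%. The guarantee is asserted
  on every delineation run, and the run manifest records the linkage and
  this rationale.
* **Top-down nesting.** Suborders are delineated first; each suborder is
  then independently re-clustered at the family cutoff, and so on down to
  species. Nesting of the four partitions therefore holds by
  construction, with no reconciliation step. (Clustering each rank
  independently on the full matrix can violate nesting when linkage
  boundaries interleave.)
* **Deterministic tie-breaking.** Among equal-linkage merges the pair
  whose smallest member id sorts first is merged. This makes results
  reproducible and invariant to input order, which the tests exercise by
  permutation.

### Tree-guided refinement

Manual curation of threshold clusters against a phylogeny is common in
survey practice but rarely specified precisely. `refine_with_tree()`
formalises one defensible reading: each taxon whose members are not
monophyletic in a supplied rooted tree is split into its maximal
monophyletic subgroups, deepest rank first. Refinement only ever
*splits* — merging could silently violate the identity-threshold
guarantee, splitting cannot. The step is optional; when the tree is
consistent with the clusters (as the synthetic generator's truth tree is
by construction) it is a no-op.

### Naming

Suborders can be anchored to classical names (e.g. *Sorangiineae*)
through known member sequences; unanchored suborders are numbered by
descending size, skipping anchored ones. Families, genera and species are
numbered within their parent, giving names of the form
`Suborder_1_Family_2_Genus_3_Species_1`.

## Abundance, biogeography and specificity

Isolation sources map onto a closed vocabulary of ten environmental
categories (four marine and terrestrial pairs, activated sludge, human,
freshwater, and an explicit `The_unknown`). Classification rules, all
boundaries inclusive per their usual statement:

* a suborder holding **≥ 0.5%** of all sequences is *abundant*,
  otherwise *rare*;
* a taxon with **≥ 5** observations of which **≥ 80%** fall in one
  category is a habitat *specialist*; anything else — including taxa with
  fewer than five observations — is *cosmopolitan* (no third class: the
  criterion's "otherwise" covers small taxa);
* `The_unknown` observations count toward both the five-observation
  minimum and dominance by default, since excluding them is a separate
  modelling decision; `specificity_params(exclude_unknown = TRUE)` makes
  the other choice available.

## Rarefaction

Curves use the exact hypergeometric expectation rather than repeated
subsampling:

$$E[S_n] = \sum_i \left(1 - \binom{N - N_i}{n}\Big/\binom{N}{n}\right),$$

computed with `lchoose()` so large collections do not overflow. The
analytic form is deterministic and directly testable: $E[S_1] = 1$ and
$E[S_N] = S$ hold exactly, and the test suite checks agreement with a
seeded resampling oracle (and with the standard community-ecology
implementation in `vegan`). Species identity for rarefaction comes from
the pipeline's own 97% species partition, not from a separate clustering.
Good's coverage is reported as $1 - F_1/N$ with $F_1$ the singleton
count.

## The synthetic-community generator

`sim_spec()`/`generate_community()` emulate the structure of a curated
16S survey: a planted four-rank hierarchy whose within-rank pairwise
identities fall in controlled bands, defaulting to

| pair class                    | identity band   |
|------------------------------|-----------------|
| within species               | [0.985, 1.000]  |
| between species, same genus  | [0.950, 0.965]  |
| between genera, same family  | [0.905, 0.935]  |
| between families, same suborder | [0.860, 0.882] |
| between suborders            | [0.700, 0.840]  |

Every band keeps at least 0.005 identity clear of every rank threshold,
so the delineation of a generated community has a unique correct answer;
the default community (4 suborders × 2 families × 2 genera × 3 species,
3–7 sequences per species, ~200–270 sequences of length 1400) is the
problem size used throughout the tests and the acceptance script — large
enough for meaningful per-rank counts, small enough that the whole suite
runs in well under a minute.

Generation details that matter:

* Substitutions are placed per edge at sites drawn without replacement,
  transitions chosen with probability $\kappa/(\kappa+2)$ ($\kappa = 2$
  by default). Sibling edges draw disjoint sites.
* Edge substitution counts are calibrated from the band midpoints with an
  analytic homoplasy correction: two non-sibling edges on a pair's path
  collide at a site with expectation $m_e m_f / L$, and each collision
  removes one realised difference (two when the end states coincide,
  probability $p_{ts}^2 + (1-p_{ts})^2/2$). A short fixed-point iteration
  folds the expected reduction into the counts. Without this correction
  the deepest classes drift about ten sites too similar and leak out of
  their bands.
* Every generated community is audited: the realised minimum and maximum
  identity of each pair class must sit inside its band. A violating draw
  (homoplasy is still stochastic) is discarded and regenerated from a
  derived seed, up to a capped number of attempts; the audit table ships
  inside the truth object. Fixtures are therefore guaranteed, not merely
  likely, to satisfy the band contract.
* Environment labels are planted at a target rank (genus by default):
  each taxon is flagged specialist with the configured probability, and a
  flagged taxon places `ceiling(0.9 n)` of its members in a home category
  drawn from the weight vector, so every flagged taxon with ≥ 5 members
  passes the specificity criterion by construction. Cosmopolitan taxa
  draw from the global weights, which are deliberately flatter than real
  isolation-source skews so that accidental specialists among small taxa
  stay rare. Culturability labels are drawn i.i.d. with proportions
  matching the roughly 22% cultured / 78% uncultured split typical of
  such collections.

What the generator does *not* emulate: realistic substitution processes
(no rate heterogeneity, no indel process beyond the optional noise
knobs), uneven taxon sizes across the hierarchy, chimeras, or correlated
geography. Passing the recovery tests therefore shows the pipeline's
logic is correct under its stated assumptions — not that real, noisy,
unevenly sampled collections will be delineated without curation.

## Numerical and degenerate-input conventions

* Identity values are exact ratios of small integers; threshold
  comparisons are strict (`> t`) and behave exactly at representable
  boundaries such as 0.970.
* Percentages in the taxon table are rounded to two decimals with R's
  round-half-to-even.
* Empty inputs: QC on zero records yields empty outputs; a single
  sequence is one taxon at every rank; a pair with no mutually
  unambiguous columns is a hard error (`non-overlapping pair`), as is an
  all-gap sequence.
* All randomness (generator, environment assignment) is derived from the
  spec seed; reruns are byte-identical.

## Reproducing the survey-scale numbers

The headline dataset behind the bundled reference counts — 4997 public
near-full-length sequences — is not redistributable as sequence data, so
the package ships only the printed per-suborder count table
(`reference_taxon_counts()`). The summariser consumes those counts
exactly as it consumes its own delineation output, which is what
`scripts/acceptance.R` exercises: rank totals (20/58/445/998), the
7-abundant/13-rare split at 0.5%, the jointly 1.04% rare mass, and the
new-taxa arithmetic against the re-classified type strains
(4/7/13/24 → 16/51/432/974 new taxa per rank).

## Known limitations

* Complete-linkage delineation is quadratic in memory and roughly cubic
  in time in the number of representatives; the implementation is
  comfortable into the low thousands of sequences, which covers curated
  survey scale, but is not an amplicon-scale OTU picker.
* Threshold clusters near a boundary are sensitive to alignment quality;
  pairwise deletion softens but does not remove that dependence.
* `refine_with_tree()` trusts the supplied topology; it does not weigh
  branch support, and it never merges, so over-split trees propagate.
* The abundance and specificity rules are the survey conventions, with
  their boundary semantics implemented inclusively; they are not
  model-based classifications.
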