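---
title: "sweetR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweetR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sweetR is an integrative sequence-analysis toolkit for the SWEET/SemiSWEET
family of sugar transporters. SemiSWEETs are 3-TMH (transmembrane-helix)
prokaryotic transporters; eukaryotic SWEETs carry two tandem 3-TMH repeats
joined by a linker helix (7 TMHs); extraSWEETs (~14-15 TMHs) and
superSWEETs (18+ TMHs) are interpreted as higher-order fusions of those
repeat units. The family carries a Pro-Gln ("PQ-loop") signature upstream
of the first helix. The package implements the full desk-scale analysis
chain — screening, similarity networks, repeat-architecture calls,
conservation and coevolution profiling, distance trees, and binding-energy
bookkeeping — together with a synthetic-family generator that plants known
truth so that every stage can be validated end to end without downloads.

This vignette records the scientific definitions the package uses, the
tunable parameters and their defaults, and the design decisions taken where
published pipelines leave the details open.

## The synthetic-family generator

`generate_families()` builds protein families from 3-TMH repeat units. A
unit is `loop + block + loop + block + loop + block`: hydrophobic blocks of
21 residues separated by hydrophilic loops of 12, with the PQ dipeptide
planted near the end of the leading loop. Architecture plans concatenate
units and single-helix linkers: 3 TMHs = one unit; 7 = unit + linker +
unit; 15 = four units with three linkers; 25 = three 7-TMH halves plus a
unit-linker tail.

Two deliberate restrictions make the generator's truth *exactly*
recoverable:

* **Iso-hydropathy alphabets.** Blocks are drawn from {I, V}
  (Kyte-Doolittle 4.5/4.2) and loops from {D, E, N, Q} (all -3.5).
  With a two-level hydropathy profile, the window-19 mean crosses the
  1.6 threshold at a *fixed* offset (13 in-block residues), independent of
  the sampled composition; predicted helices are always
  `[block_start + 3, block_end - 3]`, and the loop-midpoint unit
  boundaries match the generative truth exactly. Substitutions resample
  within the same set, so the hydropathy profile — and hence the topology
  call — is invariant under mutation at any rate. A broader alphabet
  (L, F, A, M in blocks) would make the crossing composition-dependent
  and the boundary recovery approximate.
* **Identifiable invariant sites.** Planted invariant columns are written
  as Asp/Asn, the loop residues with the largest BLOSUM62 self-score.
  Under the sum-of-pairs conservation score an invariant Gln column
  (self-score 5) can rank *below* a ~95%-conserved background Asn column
  (self-score 6), so arbitrary-residue planting would make the truth
  unrecoverable by the very statistic meant to find it. The PQ dipeptide
  is also never mutated but is tracked separately (`pq_positions`), not in
  the invariant-column truth set.

Covarying pairs hold jointly drawn states from a configurable table
(default rows (D,E), (E,D), (N,Q), (Q,N)); per descendant the pair switches
to a random table row with probability `min(1, 2 * substitution_rate)`.
Fragments truncate a uniform 20-45% contiguous window of a record;
duplicates are byte-identical copies appended under fresh accessions.
Counts are deterministic (`round(rate * n_records)`), and one integer seed
drives a single RNG stream, so identical scenarios give byte-identical
FASTA and truth tables.

What the generator does **not** emulate: insertions/deletions (beyond
fragment truncation), realistic amino-acid composition, rate variation
across sites or lineages, and nucleotide-level processes. Green tests
therefore demonstrate that the pipeline's statistics recover *planted*
structure under the generator's assumptions; they are not a benchmark of
performance on natural sequence families.

## Screening

Filters run in a fixed order, and each removed record carries exactly the
first reason that failed it:

1. **Dedupe** at 100% identity; the lexicographically smallest accession
   among identical sequences is kept (deterministic, order-independent).
2. **Fragments**: length below `fragment_max_fraction` (default 0.5) of
   the *median* input length. Published screens typically state only that
   "fragments were removed"; the median rule is this package's explicit,
   configurable definition, and it presumes a reasonably homogeneous
   length distribution (mixed 3-TMH/7-TMH inputs shift the median, so the
   cutoff should then be set per set).
3. **PQ-loop motif**: a dipeptide scan (`strict_PQ`) or proline-only scan
   (`relaxed_P`, since Gln is conserved only in SemiSWEETs) over the first
   predicted helix extended by `flank = 10` residues on each side. This is
   a transparent motif test, not a profile-HMM search.
4. **Topology**: at least `min_tmh = 3` predicted helices.

The TMH predictor is a sliding-window Kyte-Doolittle hydropathy scan
(window 19, threshold 1.6, minimum run 15, merge gap 3; all configurable);
only full windows are evaluated. It is a deliberate, dependency-free
stand-in for HMM topology predictors: reproducible and oracle-testable,
documented as such rather than as an HMM clone.

## Sequence similarity networks

All-vs-all exact Smith-Waterman local alignment (BLOSUM62, gap open 11,
extend 1; a gap of length k costs `open + k * extend`) with
Karlin-Altschul statistics: `bitscore = (lambda * S - ln K) / ln 2`
(gapped defaults lambda = 0.267, K = 0.041) and
`evalue = m * n * 2^-bitscore`, where m is the query length and n the
total residue count of the set. Pairs are canonically oriented (smaller
accession = query), so the edge is identical whichever way it is computed.
Edges pass if `evalue <= evalue_cutoff`; clusters are connected components;
clusters with `min_cluster_size >= 10` members are labelled 1, 2, ... by
decreasing size (ties by smallest member accession) with per-cluster
taxonomic composition. The size rule follows the "10 or more members"
reading where sources also say "more than 10"; it is configurable.

For the synthetic two-family experiments the package uses a cutoff of
1e-95 rather than the 1e-55 used for large natural datasets. The reason is
the generator's deliberately low-complexity alphabet: two *unrelated*
generated families still share the block/loop composition, and the
expected per-position score of random {I,V} or {D,E,N,Q} columns is
positive, so background alignments of ~240-residue records reach e-values
near 1e-82 while within-family pairs (substitution rate 0.1) sit below
1e-110. Any cutoff between the two regimes separates the families; 1e-95
sits in the middle of the gap on the log scale. This calibration was
derived from the scoring model, and the same reasoning applies to natural
data: similarity cutoffs are corpus-dependent by design.

## Architecture calls

TMH counts map to classes through configurable bins: {3,4} SemiSWEET,
{6,7} SWEET, {14,15} extraSWEET, >= 18 superSWEET, everything else
atypical. Decomposition uses canonical plans for 3/4/7/15 helices
(triplet, triplet+linker, triplet+linker+triplet, and the 4-triplet /
3-linker plan). Non-canonical counts are decomposed greedily in 7-helix
chunks (`triplet, linker, triplet` while at least 7 helices remain), with
remainders 6 -> two triplets, 4 -> triplet + linker, 3 -> triplet, and 1-2
trailing helices marked unresolved; 25 helices therefore decompose into 7
triplets and 4 linkers. The chunk rule is a declared convention: published
reports of 18- and 23-TMH proteins do not state a decomposition.

Unit spans cut the sequence at loop midpoints rather than helix edges so
each repeat unit carries its flanking context — fusion evidence compares
whole repeat units. `detect_fusion()` aligns each triplet span locally
against reference sequences and flags best hits with identity at or above
`fusion_identity_threshold = 70`, the identity level at which repeated
units of natural multi-unit proteins match stand-alone 7-TMH SWEETs.

## Multiple alignment and conservation

`align_msa()` is a deterministic progressive aligner: 3-mer Jaccard
distances, a UPGMA guide tree (sequences are processed in accession order
so ties resolve identically across runs), and profile-profile global
alignment with affine gaps (BLOSUM62, open 10, extend 0.5; terminal gaps
charged). Column-vs-column scores are expected substitution scores under
the column frequency profiles, with gaps scoring 0; the inner Gotoh
recursion is compiled code. Ungapping any output row reproduces its input
sequence exactly — this invariant is tested.

Column conservation is the weighted sum over ungapped row pairs of the
min-max-normalised substitution score,
`raw(c) = sum_{i<j} w_i w_j s_norm(a_i, a_j)`, with optional sequence
weights (inverse cluster size after single-linkage clustering at 62%
identity). Relative scores are anchored so the best column is exactly 100;
columns with more than 50% gaps are excluded from the normalising maximum
(still scored), so alignment artifacts cannot claim the anchor. The
sum-of-normalised-pairs form is this package's declared definition; the
"highest conserved position = 100" normalisation is the field's reporting
convention for conservation tables. Logo matrices report
`log2(20) - H(c)` bits per column (no small-sample correction) with letter
heights `f_a * bits`.

## Coevolution

Mutual information between columns uses natural logs over weighted,
optionally pseudocounted joint frequencies; rows gapped in either column
are excluded (a gap-as-21st-symbol mode is available), and columns with
fewer than 5 ungapped rows are skipped. Significance uses an explicit
shuffle null: `n_shuffles >= 20` (default 100) seeded row permutations of
the second column give `mi_z = (MI - null_mean) / null_sd` (sd floored at
1e-12). The conventional significance threshold of 6.5 is interpreted here
as a threshold on this standardised score — published MI networks use a
comparable cutoff without defining its scale, so the package gives it a
defined meaning and documents it as a stand-in rather than a reimplementation
of any server's internal pipeline.

Significant edges are ranked by raw MI and coloured red (top 5%, count by
ceiling), black (down to the 70th percentile, count by floor) and gray
(the rest), with ties broken by column order. Cumulative MI per column
sums raw MI over its significant pairs; proximity MI averages cMI over
residues whose representative atoms (alpha-carbon by default) lie within
5 Angstrom, mapped through the reference-coordinate map of a chosen
reference row.

## Trees

Distance trees are a deliberate desk-scale stand-in for maximum-likelihood
inference: p-distances (or Poisson-corrected `-ln(identity)`, capped at 10
for saturated pairs) over pairwise ungapped columns feed canonical
neighbour joining with the Q criterion. Ties in Q break by the
lexicographically smallest pair of clade labels; negative branch lengths
are clamped to zero with the deficit shifted to the sibling edge. Bootstrap
support resamples alignment columns with replacement (seeded), rebuilds the
NJ tree per replicate, and reports the percentage of replicates containing
each internal bipartition of the point tree; supports travel as internal
node labels in Newick. No claim is made to reproduce likelihood-based
topologies or their log-likelihoods.

## Energetics

The MM/PBSA stage is bookkeeping over per-residue component tables, not an
MD engine: `E_MM = E_ele + E_vdw`, `G_sol = G_polar + G_np`,
`G_total = E_MM + G_sol - TdS`, with the nonpolar term
`G_np = gamma * SASA + beta` (defaults gamma = 0.0054 kcal/mol/A^2,
beta = 0.92 kcal/mol). The entropy term is carried as a fixed input
constant defaulting to 0 — the package does not pretend to compute TdS,
matching the common practice of omitting it for closely related
complexes. Residues are flagged favorable iff `G_total < 0`; an exact zero
is unfavorable by convention. All energies are kcal/mol; SASA only ever
appears in squared Angstrom.

## Pipeline, fixtures and problem sizes

`run_pipeline()` validates a nested config against the defaults (unknown
keys are rejected by name), runs the enabled stages in the fixed order
screen -> ssn -> architecture -> msa_profile -> coevolution -> phylo
(energetics independent), writes every table under one output directory,
and serialises a JSON run report (validated against a packaged schema)
holding the full config, seeds, paths and row counts; identical configs
reproduce identical outputs.

The package ships two small plain-text fixtures: the 19-row
mutation-outcome table for the most conserved SWEET residues (relative
conservation, OsSWEET2b/AtSWEET1 positions, substitution tested, impact)
and a residue-region annotation (extrafacial gate, binding pocket,
intrafacial gate) used only for labelling outputs — the spatial assignment
itself is not computed here.

Test and acceptance runs use deliberately small problem sizes chosen as
sufficient for the properties being checked: families of 50 sequences by
243 columns for conservation/coevolution recovery, 12 + 12 records for the
two-family network, 16 records for bootstrap trees at 100 replicates, and
1000 random component tables for the energy identities. Scores against
brute-force dynamic-programming and contingency-counting oracles are
checked on sequences up to 12 residues, where exhaustive computation is
cheap and exact.

## Known limitations

* The hydropathy TMH predictor is not an HMM; on natural sequences it
  will disagree with HMM-based counts near marginal helices.
* The conservation and MI definitions are declared conventions; numeric
  values are not comparable to any specific server's output, only the
  normalisation (max = 100) and thresholding semantics are.
* NJ trees approximate, and do not reproduce, likelihood-based inference.
* The generator's families are statistically much cleaner than natural
  ones (no indels, uniform rates, restricted alphabets); recovery results
  on synthetic data bound what the pipeline can do, not what real data
  will give.
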