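---
title: "Identifying protein conformational states with GLOCON clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying protein conformational states with GLOCON clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glocon)
```

## The problem

The same protein sequence is routinely solved many times — apo and
ligand-bound, open and closed, occasionally in entirely different folds.
Given a set of such chains, we want to group them into putative
*conformational states*, pick a representative structure per state, and
tell which state a predicted model (for example an AlphaFold-style model)
most resembles. Superposition-based RMSD alone conflates the choice of
frame with the conformational difference; this package instead compares
chains through their internal geometry.

## The dissimilarity

Each chain is reduced to its Cα trace indexed by reference-sequence
(UniProt-style) residue numbers. For a chain with residues
$r_1 < r_2 < \dots < r_n$ we form the Cα distance matrix
$D_{ij} = \lVert x_i - x_j \rVert$, which is invariant to any rigid motion
of the chain. Two chains $a, b$ are compared on the residues modeled in
both:

$$\Delta_{ij} = \bigl|D^{(a)}_{ij} - D^{(b)}_{ij}\bigr|, \qquad
  \tilde\Delta_{ij} = \begin{cases} 0 & \Delta_{ij} < \tau \\
  \Delta_{ij} & \text{otherwise,} \end{cases}$$

with noise threshold $\tau = 3\,$Å by default: sub-threshold entries are
experimental placement scatter, not conformational signal (the inequality
is strict, so an entry exactly at $\tau$ survives). The GLOCON
(GLObal CONformation) score is the filtered upper-triangle sum scaled by
the fraction of the segment modeled in both chains,

$$G(a,b) = \Bigl(\sum_{i<j} \tilde\Delta_{ij}\Bigr) \cdot f_{ab},
  \qquad f_{ab} = \frac{|\,\mathrm{res}(a) \cap \mathrm{res}(b)\,|}{L_{\text{segment}}},$$

so gaps in either chain reduce the score rather than silently shrinking
the comparison. $G$ is zero iff no filtered entry survives; it is
symmetric, transformation-independent, and sensitive to loop movements of
a few Å as well as to large domain motions.

Two normalisation readings are implemented. The default,
`literal_product`, is the sum times $f$ as above. Because a raw sum also
loses summands when residues are missing, a gappy pair is penalised
twice; the alternative `mean_then_fraction` divides by the number of
residue pairs first, keeping scores comparable across pairs with very
different coverage. Both are pure functions selected by
`glocon_params()`; clustering is agnostic to the choice. The denominator
of $f$ is the *segment* interval length (not either chain's length),
which keeps $f$ symmetric in the pair and comparable across all pairs of
one segment.

## Segments

Chains are first grouped into *segments*: sets of chains of one accession
covering the same contiguous region of the reference sequence. The
mapping table (SIFTS-style: structure id, chain id, accession, mapped
interval, author-to-reference offset) is taken as authoritative — shared
accession asserts 100% sequence identity and no sequences are re-aligned.
Two chains share a segment when their mapped intervals overlap by at
least `min_overlap_fraction` (default 0.8) of the shorter interval,
closed transitively. This tolerates expression-tag trimming while keeping
disjoint N- and C-terminal domain constructs apart. One caveat of the
shorter-interval rule: a construct strictly nested inside another always
overlaps 100% of itself, so even `min_overlap_fraction = 1` merges
nested intervals; only non-nested near-identical intervals are split at
that setting.

## Clustering and the cut

Within a segment, chains are clustered by UPGMA (unweighted pair-group
average linkage) on the GLOCON matrix: at each step the two clusters with
the smallest mean pairwise score merge, at a height equal to that mean.
Average linkage is monotone, so heights never decrease. Merge ties are
broken by the lexicographically smallest pair of cluster member-id
minima, making the tree reproducible across platforms and input
orderings.

The tree is cut at `cut_fraction` (default 0.7) of the **maximum**
off-diagonal GLOCON score; merges at exactly the cut height are kept.
Cutting the dendrogram by height, rather than re-thresholding the raw
matrix, follows directly from expressing the cut as a fraction of the
score scale. The 70% default separates states well in practice but is
deliberately exposed in the configuration — separation quality varies
between segments, and small differences can be masked in segments that
also contain very large ones. Each cluster is summarised by its *medoid*:
the member minimising the summed score to all other members (ties by
smallest chain key). The medoid is parameter-free and reuses the
already-computed matrix, which is why it is our representative-selection
rule.

Cluster labels are 1-based, ordered by decreasing cluster size (ties by
smallest member id), so "cluster 1" is always the most populated state.

## Superposition and predicted models

For display, and for comparing a predicted model against each state, the
package uses Kabsch least-squares superposition (SVD of the
cross-covariance, reflection branch corrected to a proper rotation) over
**all** residues common to the two chains. This is a deliberate,
documented deviation from conserved-core superposition engines: no
structurally conserved core is detected first, so reported RMSDs for
hinge or fold-switch pairs reflect the full conformational change and
will exceed core-based RMSDs. Chains of a segment are superposed onto
one reference (the largest cluster's medoid by default) — the pairwise
dissimilarity structure is already captured by the GLOCON matrix, so a
single common frame suffices for display. Multi-model (NMR-style) inputs
are reduced to the first model in file order before any comparison; the
same rule applies to any multi-model file, so there is exactly one
documented behaviour.

A predicted model, numbered in reference coordinates, is superposed onto
every cluster representative; the arg-min RMSD names the closest state. A
representative sharing no residues with the model yields an `NA` RMSD —
reported, never dropped.

## Parameters at a glance

| parameter | default | units | meaning |
|---|---|---|---|
| `noise_threshold` (τ) | 3 | Å | distance-difference entries below this are zeroed |
| `cut_fraction` (c) | 0.7 | — | dendrogram cut at c × max GLOCON |
| `normalization_mode` | `literal_product` | — | sum × f, or mean × f |
| `min_overlap_fraction` | 0.8 | — | interval overlap required to share a segment |

## Numerical choices and degenerate inputs

* Alternate locations: the highest-occupancy conformer wins; occupancy
  ties go to the lexicographically smallest altloc id.
* Residues without a Cα atom are unmodeled — the score is defined purely
  on Cα.
* Insertion-coded residues are an error by default: a constant offset
  cannot renumber them, and failing loudly beats silent misnumbering.
* Chains need ≥ 3 modeled residues; pairs need ≥ 3 common residues, else
  the segment fails with the offending pairs listed (never imputed).
* Non-finite coordinates, and Cα distances above 10⁴ Å, are hard errors
  (corrupt-input detection).
* Kabsch on (near-)collinear common residues is refused: the rotation is
  underdetermined.
* Distance-matrix comparison is insensitive to chirality: a mirror-image
  chain has an identical distance matrix and scores 0. Reflections do
  not occur under rigid motion of real structures, so this is accepted.

## The synthetic ensemble generator

All validation runs on ensembles built by `generate_ensemble()`: an
ideal helical Cα trace (rise 1.5 Å, 100°/residue, radius 2.3 Å, hence
consecutive Cα–Cα ≈ 3.8 Å) bent into planted states by rigid hinge
rotations and/or loop shifts, with seeded Gaussian jitter, optional
unmodeled gaps, author renumbering and NMR-style multi-model files. The
defaults — 150 residues, hinge at residue 75, states at 0° and 30°, five
chains per state, jitter σ = 0.2 Å — are the package's reference study
condition. The length matters: distance changes between two straight
arms are second-order in the bend angle, so a short chain bent 30° moves
most pair distances by only ~3 Å, right at the noise filter. At a
typical single-domain length of 150 residues the same hinge changes
inter-domain distances by up to ~8 Å, comfortably above τ, which is the
regime (5–20 Å motions) the method targets.

What the generator does **not** emulate: real secondary-structure
packing, correlated (non-isotropic) coordinate error, crystal-contact
deformations, sequence polymorphism, or partial-occupancy conformers.
Passing the planted-state tests therefore demonstrates the pipeline's
correctness and determinism, not archive-scale recall on experimental
data.

Test and acceptance runs use 10-chain segments of 150-residue chains,
20 seeded replicates for recovery checks, and 100-trial invariance
loops; a full suite completes in well under a minute.

## A complete run

```{r example, eval = FALSE}
ens <- generate_ensemble(ensemble_spec(seed = 1), "fixtures")
cfg <- pipeline_config("fixtures", ens$mapping_path, "results")
summary <- run_pipeline(cfg)
```

Per segment this writes the GLOCON matrix (CSV and PHYLIP square
format), the UPGMA dendrogram (Newick, leaves at depth root-height/2),
the cluster assignment CSV with medoid flags, a superposed multi-model
mmCIF, an optional model-vs-representative RMSD CSV, and a JSON run
summary with an order-independent content hash — two runs on the same
inputs are byte-identical, whatever the input file order.

## Known limitations

* Sums over all residue pairs make G grow roughly quadratically with
  chain length, so raw scores are not comparable *across* segments; all
  thresholds are intra-segment by construction.
* Within a segment, mixed large and small motions can mask the small
  ones at the default cut — the per-segment `cut_fraction` override
  exists for exactly this case.
* All-common-residue RMSD (no conserved-core detection) overstates
  model-to-state distances for partial-hinge matches.
* Chimeric chains mapping to two accessions are rejected, and point
  mutations are invisible if the mapping table assigns both variants one
  accession — the table is trusted as ground truth.
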