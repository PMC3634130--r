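---
title: "Methods: consensus binding-site mapping and its synthetic ground truth"
author: "consite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus binding-site mapping and its synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consite)
```

# The procedure and its assumptions

`consite` locates the shared ligand-binding site of a seven-transmembrane
receptor family by aggregation rather than by any single structure.  The
structural half assumes:

1. **A usable residue correspondence.** Each ensemble structure can be
   placed on the reference model through paired Cα atoms.  Superposition
   uses Cα only — side chains differ across receptor families and would
   bias the fit; the correspondence itself (all shared residues, or a
   user-supplied subset such as the transmembrane core) is a
   configuration choice because different anchors emphasise different
   parts of the fold.
2. **Transfer-side contacts.** Contacts are measured between the
   *transferred* ligand and the *reference* model's side chains (the
   receptor-model-side convention).  The alternative — measuring contacts
   inside each crystal frame and mapping them across by alignment — is
   available behind the `crystalSide` flag of `mapAndDetect()`; it gives
   similar answers when the folds are close and diverges when they are
   not, which is itself informative.
3. **Pooled ligands.** Agonists and antagonists are not distinguished;
   the consensus is over every bound ligand in the ensemble.

The sequence half assumes the alignment is trustworthy where it is used:
positions are always addressed through the numbering of a designated
reference sequence (`referenceAlignment()`), and sequences that cover too
little of the reference are removed before similarity analysis
(`filterIncomplete()`).

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| contact cutoff | 4.5 | Å | heavy-atom contact distance; 4.5 Å is the common upper end of van der Waals contact definitions. Configurable because published contact tables use anywhere from 4.0 to 5.0 Å. |
| bin edges | 0.25 / 0.75 | fraction | the published three-colour frequency scale; values exactly on an edge fall in the mid bin (the mid range is printed as an inclusive interval). |
| side-chain definition | Cβ outward | — | side chains make the specific contacts; glycine therefore can never register one. `wholeResidue = TRUE` adds backbone atoms when backbone contacts matter. |
| min coverage | 0.8 | fraction of reference positions | the exclusion of incomplete database entries is reported in the literature without a numeric criterion; 0.8 is this package's surrogate and is configurable. |
| distance model | p-distance | — | mismatches over shared non-gap columns; a normalized-similarity distance is available when residue type (not identity) should drive the tree. |
| permutations | 9999 (999 in the pipeline) | — | add-one-corrected permutation p-values; the pipeline default trades resolution (min p = 0.001) for runtime. |
| noiseSigma | 0.3 | Å, RMS per atom | ensemble coordinate noise is parameterised as the per-atom root-mean-square displacement (per-coordinate sd = σ/√3), so a value of 0.3 produces superposition RMSDs near 0.3 Å — the natural reading of "0.3 Å of structural noise". |

# Numerical choices

* **Kabsch superposition** is computed by SVD of the 3×3 covariance
  matrix; the reflection branch is excluded by forcing det = +1.
  Degenerate (collinear) point sets are refused — the rotation is not
  identifiable.  The test suite checks the fitted RMSD against Horn's
  closed-form quaternion solution, an independent route to the same
  optimum; agreement is required to 1e-6 Å.
* **Neighbor joining** follows the standard Q-criterion agglomeration and
  is exact on additive matrices (verified to RF distance 0 and cophenetic
  agreement 1e-9 on random additive inputs).  When several pairs tie on
  the minimal Q value the lexicographically smallest current index pair
  is joined, which makes degenerate inputs deterministic.  Negative
  branch-length estimates are clamped to zero.
* **Conservation** of a column is the mean pairwise score
  s(a,b)/√(s(a,a)s(b,b)) over non-gap pairs (computed from residue counts,
  equivalent to the explicit double loop), rescaled so the theoretical
  minimum maps to 0 and identity to exactly 1 — invariant columns score
  1.0 without floating-point slack.  Pairs involving a gap or X are
  excluded; columns with fewer than two scorable residues carry no score.
* **Cramér's V** is computed from the chi-square statistic of the
  contingency table after dropping empty rows/columns.  A position that
  is constant on either side is reported as *uninformative*, not as
  V = 0: "no variation to correlate" and "no correlation" are different
  findings.  Permutation p-values use the add-one correction, so p > 0
  always.  Among permutation-p ties the screen ranks stronger
  associations first.
* **Newick I/O** quotes labels containing metacharacters and writes
  branch lengths with 17 significant digits, sufficient for 1e-9 round
  trips.  Parenthesis balance is checked with a character offset before
  parsing.
* **PDB I/O** is strict fixed-column: first MODEL only, alternate
  locations restricted to blank/`A`, malformed numeric fields reported
  with their line number.  B-factors are written with two decimals, which
  bounds annotation round-trip error at 0.01 (values are stored ×100).

# What the synthetic generator emulates — and what it does not

`makeBundle()` builds an idealized antiparallel seven-helix bundle:
ideal α-helix geometry (rise 1.5 Å, twist 100°/residue, Cα radius
2.3 Å), helix axes on a circle of radius 12.5 Å, and 0–4 side-chain
pseudo-atoms per residue extending radially, with length growing by
residue size.  Helix phases are staggered so inward-facing residues of
neighbouring helices sit at different heights, keeping a workable central
lumen.  The bundle radius was chosen so that a planted contact point
(≈3 Å inward of a side-chain tip) can clear all other side chains by the
contact cutoff plus a 0.8 Å noise margin; tighter bundles make such
placements geometrically impossible, which `plantLigandEnsemble()`
refuses as infeasible rather than silently violating its contract.

`plantLigandEnsemble()` controls the planted contact fractions by
**balanced draws**: each pocket position receives a contact atom in
exactly ⌈0.9·n⌉ members and each placeable decoy position in ⌊0.1·n⌋
members.  Independent per-member coin flips would leave a substantial
probability, at n = 22, of a pocket position landing at or below the
0.75 bin edge — the planted truth would then not be the truth.  Balanced
draws realise the intended fractions by construction while the member
subsets remain random.  Ground truth is recorded per member by a direct
all-pairs distance scan in the generation frame, *after* noise, so it is
exact for the coordinates actually emitted.  Each member is finally
scattered by a random rigid transform, which the mapping pipeline must
undo; pocket recovery therefore genuinely exercises superposition,
transfer and detection together.

`simulateFamily()` evolves receptor sequences along a tree by per-site
substitution with a similarity-weighted proposal (conservative
replacements are likelier), rate 0 at invariant sites, and co-writes the
ligand's scaffold-variable positions; covarying pairs are enforced at the
leaves through a deterministic residue mapping.  The ligand scaffold
(Cys1, Cys6, Pro7, Gly9) is held fixed, mirroring the nonapeptide family.

What passing these tests shows: the pipeline's geometry, bookkeeping and
statistics are correct on data whose answer is known.  What it does not
show: robustness to real crystallographic pathology — missing side-chain
density, alternate conformations beyond the altloc-A policy, fold
divergence large enough to break the Cα correspondence, or alignment
error.  The pseudo-atom side chains have no rotamers, so the synthetic
pocket is geometrically cleaner than a real one; real contact frequencies
will be noisier at fixed cutoff.

# Conditions used by the checks

Problem sizes mirror the study design this package operationalises: a
22-member structure ensemble with 9 planted pocket positions (high
fraction 0.9, decoys ≤ 0.1, noise 0.3 Å RMS), receptor families of 40
(demo) to 69 (default) pairs, and calibration runs of 500 sequences or
500 replicates with 999 permutations.  Tree-recovery checks simulate
12-leaf families on trees whose internal branches are bounded away from
zero (0.15–0.4 expected substitutions/site at 500 sites): with branches
much shorter than the sampling noise of a 120-residue alignment, no
distance method can resolve every split — an unidentifiability of the
data, not a property of the implementation.

# Design choices that were genuinely open

* **Quantifying "correlation" between receptor and ligand positions.**
  The qualitative observation this package formalises names no statistic.
  Residues are unordered categories at small n, so a rank correlation is
  inappropriate; Cramér's V plus a permutation test is the natural
  categorical quantification, with a six-class physicochemical mode
  (nonpolar-aliphatic, aromatic, polar-uncharged, positive, negative,
  special) for conservative-substitution reasoning and an identity mode
  for strict claims.
* **The incompleteness criterion.** Reported exclusions of incomplete
  entries come without a threshold; reference coverage ≥ 0.8 is this
  package's operationalisation.
* **The tree method.** The published family tree derives from a ClustalW
  alignment workflow whose tree model is unstated.  Neighbor joining on
  alignment distances is the transparent, deterministic stand-in; the
  distance model is configurable.
* **Superposition anchors.** Whether to anchor on all shared residues or
  a binding-region subset is exposed as configuration; the demo uses all
  shared residues, appropriate when the ensemble shares one fold.

# Known limitations

* Covariation is not phylogenetically corrected: shared ancestry inflates
  associations, and the permutation null treats pairs as exchangeable.
  Tree-aware nulls (e.g. independent contrasts for categories) are a
  natural extension.
* No mmCIF input; NMR ensembles contribute only their first model.
* The consensus site is cutoff-dependent near bin edges; the monotonicity
  of contact sets in the cutoff (tested) makes the dependence predictable.
* The synthetic bundle is a geometric scaffold, not a physical model: no
  energies, no rotamers, no membrane.
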