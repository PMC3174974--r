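---
title: "Methods: detecting, classifying and measuring CDGSH iron-sulfur domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, classifying and measuring CDGSH iron-sulfur domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisdtools)
```

## The domain family

CDGSH iron-sulfur domains (CISDs) are small protein domains that bind a
[2Fe-2S] cluster through a highly conserved 17-residue motif,

```
Φ C X C X X (S/T) X X X P Φ C D G (S/T/A) H
1 2 3 4 5 6   7   8 9 10 11 12 13 14 15 16 17
```

where Φ is hydrophobic and X unconstrained. The cluster is held by an
atypical 3-Cys/1-His ligation: the cysteines at motif positions 2, 4 and 13
and the histidine at position 17. Two further conserved elements surround
the motif in every known structure: the *N-strand*, a β-strand immediately
N-terminal to the motif, and the *P motif* `[G P Φ X Φ]`, whose proline
(the *lid-proline*) caps a bridging sulfide of the cluster. CISD structures
always carry iron-sulfur binding modules in pairs — either through
homodimerization of single-motif domains or through tandem motifs in one
chain — flanked by a β-sandwich dimerization module.

The family divides into seven types by motif count, fusion partners and
taxonomy: types 1–4 carry a single motif and occur in eukaryotes,
apicomplexa, archaea and bacteria respectively; type 6 carries tandem
motifs about 20 residues apart; type 5 is a type 6 fused C-terminally to a
glutamate-synthase FMN-binding domain; and type 7 combines one or two
motifs with a DUF1271 domain (subtypes DC, DCC, CDC by segment order).

`cisdtools` implements this analysis end to end: motif scanning
(`scan_cdgsh()`, `scan_pmotif()`), classification (`assign_type()`),
phylogenetic profiling (`dedup_species()`, `tabulate_profile()`,
`genus_loss_stat()`), and structural measurement (`find_clusters()`
through `pseudo_dyad()`), plus a ground-truth generator (`gen_sequences()`,
`gen_dimer()`).

## Motif scanning

The scanner slides the 17-position consensus along the de-gapped sequence
and counts mismatches at the eleven constrained positions
(1, 2, 4, 7, 11, 12, 13, 14, 15, 16, 17); X positions never count.
Parameters that matter:

* **Hydrophobic set** (`motif_spec(hydrophobic = ...)`), default
  `{A, C, F, I, L, M, P, V, W, Y}`. Family alignments show W, F, A and L at
  the Φ positions, but no authoritative enumeration of Φ exists, so the set
  is configurable. `U` (selenocysteine) and `X` never satisfy a constrained
  position, including position 2/4/13 — a deliberate conservative choice,
  since an unverified residue should not count as a cluster ligand.
* **`max_mismatch`**, default 2. Zero gives the strict scan (and the strict
  scan is exactly the relaxed scan filtered to zero mismatches — a tested
  invariant). Two suffices to recover the degenerate motifs observed in the
  tandem families, which differ from the consensus by one or two
  substitutions.
* **Status assignment.** A hit with the histidine ligand replaced by
  cysteine — and no other ligand position touched — is `his_to_cys`; such
  motifs may still bind a cluster. Any other constrained-position
  substitution (Cys→Ser; His→Gly/Ser/Gln/Asn are the ones seen in real
  collections) marks the hit `disrupted`. A strict hit suppresses relaxed
  hits sharing its position-13 cysteine so a genuine motif is never also
  reported as its own degenerate shadow.

Positions are always reported in ungapped coordinates, so scanning an
aligned record gives the same hits as scanning its ungapped sequence.

## Classification

`assign_type()` applies rules in a fixed order, with architecture taking
precedence over taxonomy (a tandem-motif archaeal sequence is type 6, not
type 3):

1. two motifs whose spacing (motif end to next motif start) falls within
   `spacing_range` → type 6, or type 5 when an FMN-binding segment follows
   the last motif;
2. a DUF1271 segment → type 7, subtype from the D/C segment order;
3. a single motif → type by taxon (1/2/3/4), optionally refined by
   homology;
4. otherwise orphan (including the no-motif case, flagged `no_motif`).

Design choices where the problem statement is genuinely open:

* **Tandem spacing default `(5, 40)`.** The family description says only
  "about 20 residues"; a generous window tolerates real variation while
  staying far below the ≥ 50-residue separations seen between motifs of
  distinct domains (e.g. the two CISDs of a type 7 DCC protein).
* **Motif evidence** is the union of scanner hits (`strict`,
  `his_to_cys`) and annotated `CISD_motif` segments. About 17 % of tandem
  proteins carry one degenerate motif, sometimes degenerate beyond what a
  2-mismatch scan recovers; their tandem architecture is then carried by
  the annotation, which in real use comes from curation or homology and in
  testing comes from the generator's truth table.
* **2a vs 2b and bacterial type 3** have no published quantitative
  criterion; both splits rest on "overall homology". The package uses
  nearest-seed ungapped identity with winner-takes-all and an explicit
  `seed_identity_unresolved` flag on ties, and records the rule that fired
  in the evidence trail of every call, so the stand-in is auditable.

`column_conservation()` computes the fraction of non-gap rows carrying a
residue from a given set at an alignment column — the quantity behind
statements like "conserved as Lys/Arg in more than 90 % of type 4
sequences at the position after the histidine ligand".

## Phylogenetic profiling

`dedup_species()` collapses records to species — multiple same-type
sequences and multiple strains count once; a species' type set is the
union over its records. The species key is the case-insensitive triple
(phylum abbreviation, genus initial, species epithet); since record names
carry only the genus initial, cross-genus initial collisions within a
phylum are accepted (and are rare at the family's scale).
`tabulate_profile()` then counts species per taxon row and type column,
with `Any` (≥ 1 CISD), `CISDpos` (membership in a user-supplied
sequenced-genome set), `Total` and `percent`. Genome totals are
user-supplied snapshot constants, never recomputed, because they refer to
a dated genome-project census.

`genus_loss_stat()` measures repeated gene loss: among genera with at
least `min_genomes = 5` sequenced genomes and at least one CISD-positive
species, it reports the mean ± SD of the per-genus positive fraction. The
headline SD is the population SD (divisor *n*); the sample SD is also
returned, since the original statistic does not state which was used.

## Structural measurements

* **Cluster detection** takes `FES`/`FE2` het-groups, or assembles
  Fe + inorganic S within 3.5 Å when the component is unnamed; a valid
  cluster has exactly 2 Fe + 2 S with all pairwise distances < 5 Å.
* **Ligand assignment** uses a 3.0 Å Fe-to-heavy-atom cutoff against Cys
  Sγ and His Nδ1/Nε2 — comfortably above typical Fe–Sγ (≈ 2.3 Å) and Fe–N
  (≈ 2.1 Å) bonds, below the next coordination shell.
* **Module extraction** anchors on the first cysteine ligand as motif
  position 2 and takes Cα of residues `C2−1 … C2+15` (positions 1–17).
  Residue numbering is author numbering throughout, because every residue
  reference in the literature (Cys25, His40, Lys64 …) is an author number.
* **Superposition** is the Kabsch least-squares fit with the determinant
  correction (always a proper rotation). The test suite checks it against
  an independent quaternion-eigenvalue implementation to 10⁻⁹ and against
  random rigid transforms for optimality.
* **Inter-module shift angle.** When two dual-module structures are
  aligned on one module, the second cluster "swings" by a characteristic
  angle (≈ 26° for the tandem type against the type 1 reference, ≈ 20° for
  types 3/4). No published definition fixes the vertex of that angle; the
  package measures it *at the aligned cluster centroid*, between the
  vectors to the reference partner's and the transformed target partner's
  cluster centroids, choosing the module pairing with the lowest anchor
  RMSD. The generator constructs dimers that realize a requested angle
  under exactly this definition, so construction and measurement are
  mutually consistent and the published figures are treated as
  approximate, not exact, targets.
* **SASA** is Shrake–Rupley quadrature: golden-section spiral points
  (default 960) on each solvent-expanded sphere, Bondi radii (Fe 2.00 Å),
  probe 1.4 Å, waters excluded, het-groups included. Quadrature makes the
  result exactly correct for an isolated sphere and accurate to well under
  1 % elsewhere, but very slightly orientation-dependent — two rigidly
  rotated copies of a model agree to quadrature accuracy (≈ 0.1–0.5 % at
  default settings), not to machine precision. Buried area per chain is
  isolated-chain SASA minus in-complex SASA. Published buried areas for
  this family come from an unnamed program, so a ±10 % band is the
  appropriate comparison, and that is what the acceptance checks use.
* **Hydrogen bonds** use the pragmatic heavy-atom criterion (N/O pairs
  ≤ 3.5 Å, different residues, beyond covalent range); donor/acceptor
  chemistry is not resolved because hydrogens are stripped on read.
* **Crystallographic mates.** For crystals with one molecule per
  asymmetric unit, `best_crystal_mate()` rebuilds the physiological dimer
  from the `REMARK 290 SMTRY` operators plus lattice shifts in
  `{-1,0,1}³`, keeping the mate with the most contacts and logging the
  operator used.
* **Pseudo-dyad** superposes module 1 (17 Cα + 4 cluster atoms) onto
  module 2 and reports the residual and the rotation angle of the fitted
  transform (180° for a true dyad).

Degenerate inputs are handled explicitly: empty sequences scan to empty
hit lists; a chain break inside a module window is an error naming the
missing residues; an isolated cluster yields an empty ligand list with a
warning; ties in altloc occupancy keep the first conformer.

## What the generator emulates — and what it does not

`gen_sequences()` plants consensus instances (Φ/X positions randomized) in
i.i.d. background sequence — uniform amino-acid frequencies by default,
since no claim here depends on background composition — with per-type
architecture: tandem spacing uniform over the configured range, an
FMN-binding segment after type 5 motifs, DUF1271 segments with ≥ 50-residue
padding for type 7. Degenerate motifs (default rate 0.17, the fraction
observed in the tandem families) use the substitutions seen in real
collections, half of them His→Cys. Record names follow the underscore
convention, so the parser, profiler and generator exercise one another.

`gen_dimer()` builds a second copy of an idealized module template — an
analytically constructed helical 17-Cα trace around a planar Fe₂S₂
rhombus, not copied from any deposited model — by an exact dyad (180°
rotation about an axis through the cluster-centroid midpoint), then
rotates it about the first cluster centroid by the requested shift angle;
both operations preserve the centre distance, so distance, angle and dyad
measurements recover the construction parameters to numerical precision at
zero noise, and degrade proportionally to added Gaussian noise.

Passing on generated data therefore demonstrates the *bookkeeping and
geometry* of the pipeline — coordinates, statuses, rule order, measurement
definitions — under known truth. It does not demonstrate performance on
real data, where motifs drift beyond two mismatches, domain annotations
are imperfect, species names collide, B-factors and disorder blur
coordination distances, and background composition is far from uniform.
Checks against deposited structures and the published sequence collections
(see the README on reproducing results) cover that ground, and require a
one-time download of those inputs.

## Problem sizes and tolerances

The shipped tests run entirely from generated data: 1,000 random point-set
pairs for the superposition oracle, 1,000 random sequences for the
scanner/brute-force comparison, 200–500 generated records for recall,
accuracy and rate recovery, and dimers at a handful of noise levels.
Numerical tolerances follow the measurement: 10⁻⁹ for algebraic identities
(Kabsch vs quaternion, rigid-motion invariance of distances), 10⁻⁶ for
constructed-geometry recovery, 1 % for SASA quadrature against closed
forms, and binomial confidence bounds for stochastic rates.

## Known limitations

* No profile-HMM or PSSM scoring: the consensus pattern, not a trained
  model, defines the motif, so retrieval-style sensitivity is out of
  scope.
* DUF1271/FMN annotations are consumed, not predicted; the package ships
  no domain-HMM engine.
* The 2a/2b and bacterial-type-3 homology rule is a documented stand-in
  (flagged in evidence), not a validated classifier.
* SASA values are method-dependent at the percent level; comparisons
  tighter than a few percent should use a single method throughout.
* The inter-module angle depends on the documented vertex definition;
  published angle figures are treated as approximate checks only.
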