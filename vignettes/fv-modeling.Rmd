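---
title: "Modeling immunoglobulin and T-cell receptor variable domains with FvModeler"
author: "FvModeler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling immunoglobulin and T-cell receptor variable domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

FvModeler builds backbone models of paired immunoglobulin (heavy +
kappa/lambda) and T-cell receptor (alpha + beta) variable domains from
amino-acid sequence alone, by the canonical-structure method: conserved
framework scaffolds are copied from the closest solved templates, and the
hypervariable CDR loops are kept or grafted according to their predicted
main-chain conformation class. This vignette explains the model behind
each stage, the parameters that matter, the numerical choices, and what
the shipped synthetic fixtures do and do not establish about behavior on
real structures.

```{r setup, eval = FALSE}
library(FvModeler)
```

## Chain identification and numbering

Each chain type is described by a sequence profile: a position-specific
scoring model over the *match states* of a numbering scheme. A profile is
built from a multiple sequence alignment whose columns are mapped to
scheme positions (`buildProfile()`); a column becomes a match state when
it is mapped and occupied in at least `occupancy` of the sequences
(default 0.5 — a column present in half the chains is part of the shared
architecture, anything rarer is an insertion). Emissions are log2-odds of
background-weighted pseudocounted column frequencies; an ambiguity
character (X) scores its expectation under the background. Alignment uses
dynamic programming with position-specific gap costs (in bits): framework
insertions/deletions are expensive (open 8, extend 2, delete 8), gaps
inside or spanning a CDR window are cheap (open 1, extend 0.25, delete
0.75), and terminal overhangs are free. The intent is that all length
variation is pushed into the CDRs, which is where the immunoglobulin fold
actually absorbs it.

`identifyChain()` scores a sequence against all profiles and accepts the
argmax if it reaches the profile's acceptance threshold (default 0 bits:
the sequence must beat the background model; under this default more than
99% of uniformly random 120-mers are rejected while every fixture chain
scores hundreds of bits). `enrichProfile()` grows a profile's training
alignment with sequences longer than 100 residues whose E-value is below
1e-50; since the profile engine produces bit scores rather than
database-calibrated statistics, E is defined as `N * 2^-score` for a
candidate set of size N, which preserves the intent of the filter (only
essentially certain homologs are merged).

Numbering follows a Chothia-style scheme. The exact historical table of
positions and insertion points is not reproduced here; the shipped
`"chothia"` table is a reconstruction with the standard window geometry
and is explicitly marked editable (`loadScheme()` accepts any scheme
JSON). Within each CDR the loop is *right-aligned*: every CDR has a
single re-entry position; a loop longer than its window places the
surplus as insertion-coded positions (A, B, ...) immediately after the
re-entry position while C-terminal residues keep canonical numbers, and a
shorter loop vacates the N-terminal-most window positions. A chain whose
framework windows cannot be filled to at least `frTolerance` (default
0.5) is rejected with an "incomplete framework" error rather than
numbered wrongly — the one failure mode a template-based pipeline should
refuse loudly.

## Canonical structures

Two same-length loops are compared by the periodic metric

$$d(a,b) = \sum_i D(\phi_{a,i}, \phi_{b,i}) + D(\psi_{a,i}, \psi_{b,i}),
\qquad D(\theta_1,\theta_2) = 2\,(1 - \cos(\theta_1 - \theta_2)),$$

which is symmetric, zero on identical loops, bounded by 8 per residue,
and insensitive to the 2π wrap-around — but not a metric in the triangle
sense, which nothing here requires. Within each chain type × CDR × length
group, classes are found by affinity propagation on similarity
`-d`, implemented in the package (damping 0.9, at most 1000 iterations,
deterministic symmetry-breaking noise from a fixed seed, so clustering is
reproducible and invariant to input order). The exemplar *preference*
controls how many classes appear. The common defaults (median or minimum
of the similarities) over-partition a single noise-scale cloud, which is
wrong for this application: a CDR whose conformations form one basin has
one canonical structure. The default rule is therefore adaptive,
`p = min(4 n · median(nearest-neighbour similarity), min(S))`: its
magnitude scales with the group size times the noise scale (so splitting
a homogeneous cloud never pays) while staying far above the separation of
genuinely distinct conformational classes (so true classes never merge).
On fixtures with 1–3 centroids at von Mises concentration κ = 50 this
recovers the generating partition exactly; the classical rules remain
available through the `preference` argument.

Each class carries a per-position log-odds sequence model with Laplace
pseudocounts (α = 1) against a background distribution (uniform by
default). `predictCS()` assigns a query loop to the best-scoring class of
its length, provided the score beats the class's *null score* — the
expected score of a background-random sequence under that model. The
minimum member self-score is also stored for inspection, but it is a
biased threshold: it is an order statistic of the training set, and
held-out members of the same class routinely score below it. Scoring
above background is the operational meaning of "this loop looks like the
class", and on held-out fixtures it yields ≥ 95% accuracy while still
rejecting sequences drawn from a disjoint alphabet. TCR beta CDR3 is
categorically never assigned a class: its conformational diversity does
not form clear canonical structures, and the selection stage always uses
the length rule there. Solved templates are labeled by their *observed*
conformation — nearest exemplar under the loop metric — never by sequence
prediction.

## Template selection

For a numbered target and each same-chain-type template,
`scoreTemplate()` computes five scores with BLOSUM62: the full-sequence
score over scheme positions occupied in both chains; three per-CDR scores
defined only when loop lengths match (`-Inf` sentinel otherwise — a loop
of different length cannot be scored positionally and can never be kept);
and the combined score, the full-sequence score plus exactly those CDR
scores whose template canonical-structure label equals the target's
prediction. Combined-score additivity (`combined - fullseq` equals the
sum of CS-matched CDR scores) is asserted on every fixture scoring event
in the test suite.

`selectFramework()` forms, per chain, the 20 templates with the highest
combined score among those with at least 60% sequence identity (identity
is computed over shared numbered positions, i.e. the variable domain
only). Among cross-chain candidate pairs sharing a crystal, the pair with
the highest overall identity — the mean of the two chains' identities —
wins; favoring same-crystal pairs avoids inventing a chain-packing
geometry. If no candidate pair shares a crystal, the fallback selects per
chain the template maximizing the *combined loop score*, read as the sum
of the defined per-CDR scores, which minimizes the number of loops that
must be grafted (the alternative reading — the combined score itself — is
available via `fallback = "combined"`). When nothing reaches the identity
gate the pipeline proceeds best-effort over all templates with a logged
low-identity warning; `strict = TRUE` refuses instead. All tie-breaks are
deterministic: higher combined score, then better (lower) resolution,
then lexicographic identifier — so selection is a pure function of
(target, database view, configuration), which the tests assert by
equality against exhaustive enumeration.

`selectLoops()` then works per CDR: keep the framework's loop when its
canonical-structure label equals the target's prediction; otherwise take
the eligible donor with the same canonical structure and the highest
CDR-specific score; otherwise (no prediction, blacklisted donors) the
best donor of the target loop's length. Beta CDR3 always uses the length
rule. A CDR for which no loop of the required length exists anywhere is a
hard error naming the CDR.

## Assembly

Same-crystal frameworks keep their coordinates bit-identical. Frameworks
from different crystals are positioned by `packChains()`: the targets'
interface pseudo-sequence (the residues at a fixed set of interface
scheme positions, shipped as an editable JSON table or derivable from a
database with `computeInterface()`, default contact cutoff 4.5 Å in at
least half of the paired templates) selects the crystal pair with the
highest BLOSUM62 pseudo-sequence similarity as a packing scaffold, and
each framework chain is superposed onto its scaffold chain over the
interface backbone atoms.

Loop grafting (`graftLoop()`) superposes the donor's 2+2 anchor residues
— the two residues before the loop's N-terminus and the two after its
C-terminus, backbone atoms N, CA, C and O, 16 atoms in total — onto the
model's anchors, places the transformed donor loop, and leaves the
anchors themselves untouched. Superposition is a Kabsch least-squares fit
(SVD with reflection correction, proper rotation guaranteed), verified in
the tests against an independent closed-form quaternion implementation to
1e-9 Å. An anchor RMSD above 1.5 Å triggers a "strained graft" warning —
a report, not a rejection, since the repacking/refinement downstream of
this package is where strain is resolved. `markRepack()` flags every CDR3
residue and every residue whose target amino acid differs from its source
template; the emitted pre-repack PDB strips flagged side chains beyond
CB (CB is kept when the template had one and the target is not glycine).
Inter-chain atom pairs closer than 0.5 Å are counted and reported as
clashes, again without rejection. Models are emitted non-minimized,
always, and the PDB header says so; side-chain repacking is an external
hook (`emitModel(..., repackHook = "cmd {in} {out}")`), not a claim this
package makes.

One ordering choice was genuinely open: whether to pack the two chains
before or after grafting loops. The package packs first. Grafting is
defined entirely relative to each chain's own framework anchors, so the
placement of a loop relative to its chain is identical either way; the
tests assert graft rigidity and anchor invariance directly.

## The synthetic fixture world

`makeTemplateDb()` generates a fully synthetic template database from a
`fixtureSpec()`, a pure function of its seed. Defaults define the
standard study conditions: 12 structures (half paired crystals, half
single chains) of TCR alpha + beta chains; CDR loops of lengths 6/5/6
drawn from 2 dihedral centroids per CDR, separated by 2.2 rad per angle,
with von Mises noise at κ = 50 (≈ 8° s.d. — crystallographic-quality
conformational tightness); framework point mutations at 5% per position
(typical of close germline relatives); resolutions cycling over 1.5–2.4 Å
so tie-breaks are exercised. Sequences encode the truth: each centroid
draws its loop residues from one of three disjoint 6-letter alphabets,
which is what makes sequence-based class prediction learnable, and every
generating label (centroid, lengths, mutations, pairing, docking
transform) is recorded in `truth.json`. Chains are built by
internal-coordinate (NeRF) construction with standard bond geometry;
`computeDihedrals()` recovers the generating angles to 1e-6 rad, and
torsion signs follow the standard convention (verified against
independent implementations). Paired chains share one fixed docking
transform, so "same crystal" has a consistent geometric meaning across
the database. Fixture profiles are framework-only: the hypervariable
columns are left as gaps so the occupancy rule drops them, and chain
identification and framework anchoring are driven entirely by the
conserved scaffold — loop composition can then never corrupt the
numbering of a boundary residue.

What the fixtures deliberately do **not** emulate: sterics and
Ramachandran favorability (loops are geometrically consistent, not
physically relaxed); and — most importantly — the rigidity of a real
β-sandwich. Because each chain is one continuous internal-coordinate
construction, noise in the loop dihedrals reorients entire downstream
framework segments, so absolute RMSDs between different fixture
structures are tens of Å where real Fv frameworks differ by ~1 Å.
Passing tests therefore establish the *machinery* — numbering, class
recovery, selection-rule fidelity, rigid-body bookkeeping, provenance,
determinism, and exact self- and sibling-recovery — not accuracy in
Å on real receptors, which depends on a curated template database the
user must supply. The leave-one-out properties are phrased accordingly:
modeling a pair from its own database returns it at 0 Å exactly, and
with the self template excluded, a sibling template with identical
coordinates but diverged sequence (built by `addSiblingStructure()`)
bounds the framework RMSD at the sibling's own divergence — grafting
never degrades the framework below its template.

## Numerical choices and degenerate inputs

* Angles are radians in (−π, π] internally; degrees appear only at I/O
  boundaries. Torsions of collinear atoms are undefined markers, never
  crashes; chain termini leave phi/psi undefined on the missing side.
* Superposition refuses fewer than 3 points or collinear/coincident point
  sets with a typed degenerate-geometry error; `det(R) = +1` to 1e-9 is
  enforced by construction.
* Affinity propagation short-circuits two degenerate cases: a singleton
  group, and a group whose pairwise distances are all numerically zero
  (identical loops), both yielding one class.
* Alternate PDB locations resolve to the highest-occupancy conformer,
  first on ties. A CDR with missing backbone atoms makes that loop
  donor-ineligible but leaves the framework usable.
* All tie-breaks (selection, scaffold choice, class labels) are total
  orders ending in lexicographic identifier, making every pipeline stage
  a deterministic pure function; repeated runs emit byte-identical files.
* Problem sizes in the tests and the acceptance script — 12-structure
  databases, 40–100 loops per clustering, 1000-case oracle sweeps —
  were chosen as the smallest sets that exercise every rule (top-20
  truncation, identity gate, pairing fallbacks) while keeping any single
  check near-instant.

## Limitations

* The numbering tables are reconstructions; users aligning to the
  historical Chothia/Kabat literature position-by-position should supply
  their own scheme JSON.
* The canonical-structure sequence predictor is a per-position log-odds
  scorer behind a fixed interface; richer classifiers can replace it
  without touching the selection stage.
* No mmCIF ingestion; no nucleotide input; no germline assignment; no
  antigen or constant domains; no refinement. The package's guarantee
  ends at the pre-repack model plus its provenance.
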