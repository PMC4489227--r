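# FvModeler

Automated template-based modeling of B- and T-cell receptor variable
domains (Fv) from paired amino-acid sequences.

Antibodies (BCRs) and T-cell receptors (TCRs) recognize their targets
through six hypervariable loops — the complementarity determining regions
(CDRs) — presented on a conserved β-sandwich framework. Although CDR
sequences are extraordinarily diverse, their main-chain conformations fall
into a limited set of *canonical structures* that can be predicted from
sequence. FvModeler exploits this: given the two chain sequences of a
receptor (heavy + kappa/lambda for a BCR, alpha + beta for a TCR), it
builds a full backbone model with per-residue provenance, ready for
side-chain repacking.

## The method

1. **Chain identification and numbering.** Each input sequence is scored
   against per-chain-type sequence profiles (position-specific scoring
   models with affine, position-dependent gap costs). The best-scoring
   profile assigns the receptor and chain type and the alignment onto a
   Chothia-style numbering scheme. CDR insertions are right-aligned: each
   CDR has a single re-entry position, surplus residues receive insertion
   codes there, and C-terminal loop residues keep canonical numbers.
2. **Canonical structures.** CDR loops from solved structures are grouped
   by chain type, CDR and length, and clustered on backbone dihedrals with
   affinity propagation. The distance between two same-length loops is

       d(a, b) = sum_i [ D(phi_a,i, phi_b,i) + D(psi_a,i, psi_b,i) ],
       D(theta1, theta2) = 2 (1 - cos(theta1 - theta2)).

   A per-position log-odds sequence model per class predicts the canonical
   structure of a query loop; TCR beta CDR3 is never assigned a class (no
   clear canonical structures exist for it).
3. **Template selection.** For every template the package computes five
   BLOSUM62 scores — full sequence, one per CDR (defined only at equal
   loop length), and a *combined* score: the full-sequence score plus the
   scores of the template CDRs whose canonical structure matches the
   query's prediction. Per chain, the 20 highest-combined templates with
   at least 60% sequence identity form the candidate list; among candidate
   pairs sharing a crystal the pair with the highest overall identity is
   chosen (avoiding chain-packing errors), with a per-chain fallback that
   maximizes the combined loop score when no such pair exists. Each CDR
   then keeps the framework loop if its canonical structure matches,
   otherwise the best-scoring donor loop with the same canonical structure
   (or, failing that and always for beta CDR3, the same length).
4. **Assembly.** Same-crystal frameworks keep their crystal coordinates.
   Frameworks from different crystals are packed by superposing each chain
   onto a scaffold pair selected by interface pseudo-sequence similarity.
   Donor loops are grafted by superposing the backbone atoms (N, CA, C, O)
   of the two residues flanking each loop end — 16 anchor atoms — and
   every CDR3 residue plus every residue not conserved between target and
   template is flagged for side-chain repacking. The emitted "pre-repack"
   PDB contains the backbone plus only template-conserved side chains; an
   external repacker can be attached as a hook. Models are never energy
   minimized.

Everything is testable offline: a synthetic fixture generator emits
numbered chains, paired crystals with a known relative orientation, and
CDR loops drawn from known dihedral centroids, with every generating label
recorded in a truth file.

## Worked example

Model a receptor against a synthetic template database, excluding its own
crystal structure so the pipeline must fall back to homologous templates:

```r
library(FvModeler)

scheme <- loadScheme("mini")
world  <- buildFixtureWorld(fixtureSpec(seed = 1, nTemplates = 12))
db     <- world$db
db
#> TemplateDatabase: 18 records, 6 crystal pairs (scheme mini-v1)
#>   chains: alpha=9 beta=9

pair   <- crystalPairs(db)[1, ]
truth1 <- templates(db)[[pair$id1]]   # alpha chain of F001
truth2 <- templates(db)[[pair$id2]]   # beta chain of F001

model <- modelReceptor(chainSequence(truth1), chainSequence(truth2),
                       db, world$profiles, world$classes, scheme,
                       world$iface, blacklist = "F001")
model
#> AssembledModel: chains A+B (60+60 residues), 37 repack-flagged, non-minimized

sel <- model@meta$framework
sprintf("framework: %s + %s (%s)", sel@chain1Id, sel@chain2Id, sel@rationale)
#> "framework: F006_A + F006_B (paired)"

model@meta$loops$chain2@choices
#>         cdr templateId                mode score
#> F002_B CDR1     F002_B          cs_matched    -1
#> 1      CDR2     F006_B kept_from_framework    NA
#> F009_A CDR3     F009_A      length_matched     7

round(evaluateModel(model, setNames(list(truth1, truth2),
                                    names(model@chains))), 2)
#>       global    framework binding_site          FR1          FR2  ...
#>        33.39        31.01        39.51        23.49        29.15  ...
```

Reading the output: the same-crystal rule selected the F006 pair as the
framework; the beta chain kept its CDR2 (canonical structure already
matching), replaced CDR1 with a canonical-structure-matched donor, and
used the length rule for CDR3 as it always does on beta chains. The RMSD
table compares the model to the blacklisted true structure. Absolute
values are large *by construction* in this synthetic world — chains are
built by internal-coordinate geometry, so loop noise reorients whole
framework segments (see the methods vignette) — what matters is the
bookkeeping: modeling the same sequences *without* the blacklist returns
the original pair at 0.0 Å.

`emitModel(model, "out/")` writes the pre-repack PDB (with provenance
REMARK records), plus JSON and CSV summaries. A command-line front end
with `build-profiles`, `build-db`, `cluster-cs`, `model`, `evaluate` and
`fixtures` subcommands ships in `inst/cli/fvmodeler.R`.

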