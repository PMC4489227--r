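Package: FvModeler
Title: Template-Based Structural Modeling of B- and T-Cell Receptor
    Variable Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated homology modeling of paired immunoglobulin and
    T-cell receptor variable domains (Fv) from amino-acid sequence alone.
    Chains are identified and renumbered onto a Chothia-style scheme with
    sequence profiles, canonical structures of the CDR loops are clustered
    from backbone dihedrals (affinity propagation on a periodic angle
    metric) and predicted from sequence, framework and loop templates are
    selected from a curated, renumbered structure database with
    BLOSUM62-based scores, and models are assembled by rigid-body packing
    and anchor-based loop grafting, with side-chain repack marking.
    Includes a fully synthetic fixture generator so the whole pipeline is
    testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'scheme.R'
    'geometry.R'
    'profiles.R'
    'canonical.R'
    'pdbio.R'
    'templatedb.R'
    'selection.R'
    'assembly.R'
    'fixtures.R'
    'pipeline.R'
    'zzz.R'
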