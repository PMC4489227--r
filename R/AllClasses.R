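#' @import methods
NULL

#' Numbering scheme for immunoglobulin-fold variable domains
#'
#' Holds, per chain type, the ordered scheme positions, the FR/CDR region
#' windows, and the single re-entry position per CDR after which insertion
#' codes are placed.  Two schemes ship with the package: a reconstructed
#' Chothia-style table (`"chothia"`, marked editable) and a miniature scheme
#' (`"mini"`) used by the synthetic fixtures; both go through identical code
#' paths.
#'
#' @slot id scheme identifier string.
#' @slot insertionOrder single string giving the ordering of insertion codes.
#' @slot chains named list (per chain type) with elements `positions`
#'   (integer vector), `regions` (named list of `c(start, end)` scheme
#'   numbers) and `reentry` (named integer vector, one per CDR).
#' @export
setClass("NumberingScheme", representation(
  id = "character",
  insertionOrder = "character",
  chains = "list"
))

setValidity("NumberingScheme", function(object) {
  for (ch in names(object@chains)) {
    if (!ch %in% CHAIN_TYPES) return(sprintf("unknown chain type '%s'", ch))
    info <- object@chains[[ch]]
    if (is.unsorted(info$positions, strictly = TRUE))
      return("scheme positions must be strictly increasing")
    for (cdr in CDR_NAMES) {
      w <- info$regions[[cdr]]
      if (is.null(w)) return(sprintf("missing %s window for %s", cdr, ch))
      re <- info$reentry[[cdr]]
      if (is.null(re) || re < w[1] || re > w[2])
        return(sprintf("re-entry position for %s/%s outside its window", ch, cdr))
    }
  }
  TRUE
})

#' Sequence profile for one receptor chain type
#'
#' A position-specific scoring model over the scheme match states, built from
#' a column-mapped multiple sequence alignment, with position-specific
#' insertion/deletion costs that concentrate length variation in the CDR
#' windows.
#'
#' @slot chain chain type.
#' @slot schemeId identifier of the numbering scheme the states live on.
#' @slot states data.frame with columns `number` and `region`, one row per
#'   match state, in scheme order.
#' @slot emissions numeric matrix (states x 21): log2-odds per residue,
#'   column 21 the expected score of an ambiguous residue.
#' @slot background length-20 background frequencies.
#' @slot insOpen,insExtend numeric length `nstates+1` gap costs per slot.
#' @slot delCost numeric length `nstates` deletion costs.
#' @slot msa character matrix of the (match-state columns of the) training
#'   alignment, kept so the profile can be enriched and rebuilt.
#' @slot acceptThreshold minimum alignment score (bits) for a sequence to be
#'   accepted as this chain type.
#' @slot nAdded number of sequences merged in by the last enrichment.
#' @export
setClass("ChainProfile", representation(
  chain = "character",
  schemeId = "character",
  states = "data.frame",
  emissions = "matrix",
  background = "numeric",
  insOpen = "numeric",
  insExtend = "numeric",
  delCost = "numeric",
  msa = "matrix",
  acceptThreshold = "numeric",
  nAdded = "integer"
))

setValidity("ChainProfile", function(object) {
  n <- nrow(object@states)
  if (nrow(object@emissions) != n) return("emissions rows != number of states")
  if (ncol(object@emissions) != 21) return("emissions must have 21 columns")
  if (is.unsorted(object@states$number, strictly = TRUE))
    return("match states must be strictly increasing")
  if (length(object@insOpen) != n + 1 || length(object@delCost) != n)
    return("gap cost vectors have wrong length")
  TRUE
})

#' A receptor chain renumbered onto the scheme
#'
#' @slot chain chain type.
#' @slot schemeId scheme identifier.
#' @slot residues data.frame with columns `number` (integer), `ins`
#'   (insertion code or ""), `aa` (one-letter residue) and `region`
#'   (FR1..FR4, CDR1..CDR3), in chain order.
#' @slot score profile alignment score in bits.
#' @export
setClass("NumberedChain", representation(
  chain = "character",
  schemeId = "character",
  residues = "data.frame",
  score = "numeric"
))

setValidity("NumberedChain", function(object) {
  r <- object@residues
  if (!all(c("number", "ins", "aa", "region") %in% names(r)))
    return("residues must have number/ins/aa/region columns")
  key <- posKey(r$number, r$ins)
  if (anyDuplicated(key)) return("duplicated scheme positions")
  ord <- order(r$number, r$ins, method = "radix")
  if (!identical(ord, seq_len(nrow(r))))
    return("residue positions must be strictly increasing")
  if (!all(r$region %in% c(FR_NAMES, CDR_NAMES)))
    return("unknown region label")
  TRUE
})

#' A CDR loop with backbone dihedrals
#'
#' @slot chain chain type.
#' @slot cdr integer 1, 2 or 3.
#' @slot sequence loop amino-acid sequence.
#' @slot phi,psi numeric vectors of dihedrals in radians, (-pi, pi], one per
#'   loop residue.
#' @slot source identifier of the structure the loop came from.
#' @export
setClass("DihedralLoop", representation(
  chain = "character",
  cdr = "integer",
  sequence = "character",
  phi = "numeric",
  psi = "numeric",
  source = "character"
))

setValidity("DihedralLoop", function(object) {
  L <- nchar(object@sequence)
  if (length(object@phi) != L || length(object@psi) != L)
    return("phi/psi length must equal sequence length")
  ang <- c(object@phi, object@psi)
  ok <- is.na(ang) | (ang > -pi - 1e-9 & ang <= pi + 1e-9)
  if (!all(ok)) return("angles must lie in (-pi, pi]")
  TRUE
})

#' A canonical-structure class of same-length CDR loops
#'
#' @slot chain,cdr,loopLength the group the class belongs to.
#' @slot classId deterministic class label.
#' @slot exemplar the [DihedralLoop-class] exemplar chosen by affinity
#'   propagation.
#' @slot members source identifiers of member loops.
#' @slot memberSeqs member loop sequences (parallel to `members`).
#' @slot seqModel per-position log-odds matrix (loopLength x 20) or a 0-row
#'   matrix before [fitSequenceModel()] has run.
#' @slot selfScoreMin minimum sequence-model score over the class's own
#'   members.
#' @slot nullScore expected model score of a background-random sequence;
#'   the default prediction confidence threshold is the midpoint
#'   `(selfScoreMin + nullScore) / 2`.
#' @export
setClass("CanonicalClass", representation(
  chain = "character",
  cdr = "integer",
  loopLength = "integer",
  classId = "character",
  exemplar = "DihedralLoop",
  members = "character",
  memberSeqs = "character",
  seqModel = "matrix",
  selfScoreMin = "numeric",
  nullScore = "numeric"
))

setValidity("CanonicalClass", function(object) {
  if (!object@exemplar@source %in% object@members)
    return("exemplar must be a member")
  if (length(object@memberSeqs) != length(object@members))
    return("memberSeqs must parallel members")
  if (any(nchar(object@memberSeqs) != object@loopLength))
    return("all members must share the class loop length")
  TRUE
})

#' One solved chain renumbered as a modeling template
#'
#' @slot sourceId structure identifier + chain letter, e.g. `"F001_A"`.
#' @slot structId crystal structure identifier.
#' @slot chain chain type.
#' @slot numbered the chain as a [NumberedChain-class].
#' @slot atoms data.frame `resIdx`, `atom`, `x`, `y`, `z` (Angstrom); resIdx
#'   indexes rows of `numbered@residues`.
#' @slot phi,psi per-residue backbone dihedrals (NA where undefined).
#' @slot csLabels named character (cdr1..cdr3): observed canonical-structure
#'   label by nearest exemplar, NA when unassigned.
#' @slot loopEligible named logical (cdr1..cdr3): loop plus 2+2 anchors have
#'   complete backbone, so the CDR can donate a loop.
#' @slot partnerId sourceId of the paired chain in the same crystal, or NA.
#' @slot resolution crystal resolution in Angstrom (NA if unknown).
#' @export
setClass("TemplateRecord", representation(
  sourceId = "character",
  structId = "character",
  chain = "character",
  numbered = "NumberedChain",
  atoms = "data.frame",
  phi = "numeric",
  psi = "numeric",
  csLabels = "character",
  loopEligible = "logical",
  partnerId = "character",
  resolution = "numeric"
))

setValidity("TemplateRecord", function(object) {
  n <- nrow(object@numbered@residues)
  if (length(object@phi) != n || length(object@psi) != n)
    return("phi/psi must have one entry per numbered residue")
  if (any(object@atoms$resIdx < 1 | object@atoms$resIdx > n))
    return("atom resIdx out of range")
  TRUE
})

#' A curated set of templates with crystal pairings
#'
#' @slot records named list of [TemplateRecord-class] objects (by sourceId).
#' @slot pairs data.frame `id1`, `id2` listing receptor pairs sharing a
#'   crystal.
#' @slot redundancyThreshold percent identity used when the set was culled
#'   (NA if never culled).
#' @slot schemeId numbering scheme identifier.
#' @export
setClass("TemplateDatabase", representation(
  records = "list",
  pairs = "data.frame",
  redundancyThreshold = "numeric",
  schemeId = "character"
))

setValidity("TemplateDatabase", function(object) {
  ids <- names(object@records)
  p <- object@pairs
  if (nrow(p) > 0) {
    if (!all(c(p$id1, p$id2) %in% ids)) return("pair entry not in records")
    for (k in seq_len(nrow(p))) {
      r1 <- object@records[[p$id1[k]]]; r2 <- object@records[[p$id2[k]]]
      if (!identical(r1@partnerId, r2@sourceId) ||
          !identical(r2@partnerId, r1@sourceId))
        return("pair entry without matching partner links")
    }
  }
  TRUE
})

#' The five per-template scores plus identity
#'
#' @slot templateId the scored template.
#' @slot fullseq BLOSUM62 score over all shared scheme positions.
#' @slot cdr numeric length 3; per-CDR scores, `-Inf` when the loop lengths
#'   differ (score undefined).
#' @slot csMatch logical length 3: template CDR canonical structure equals
#'   the target's predicted one.
#' @slot combined `fullseq` plus the CS-matched CDR scores.
#' @slot identity percent sequence identity over shared positions.
#' @export
setClass("ScoreSet", representation(
  templateId = "character",
  fullseq = "numeric",
  cdr = "numeric",
  csMatch = "logical",
  combined = "numeric",
  identity = "numeric"
))

setValidity("ScoreSet", function(object) {
  if (length(object@cdr) != 3 || length(object@csMatch) != 3)
    return("cdr/csMatch must have length 3")
  add <- sum(object@cdr[object@csMatch & is.finite(object@cdr)])
  if (abs(object@combined - (object@fullseq + add)) > 1e-9)
    return("combined must equal fullseq + CS-matched CDR scores")
  if (object@identity < 0 || object@identity > 100)
    return("identity must be a percentage")
  TRUE
})

#' Framework template choice for a receptor pair
#' @slot chain1Id,chain2Id selected template sourceIds (chain1 = heavy/alpha).
#' @slot sameCrystal TRUE when both come from one crystal.
#' @slot rationale `"paired"` or `"fallback_per_chain"`.
#' @slot candidates list of two data.frames: the top-20 candidate tables.
#' @export
setClass("FrameworkSelection", representation(
  chain1Id = "character",
  chain2Id = "character",
  sameCrystal = "logical",
  rationale = "character",
  candidates = "list"
))

#' Loop template choices for one chain
#' @slot choices data.frame `cdr`, `templateId`, `mode`, `score`; mode is one
#'   of `kept_from_framework`, `cs_matched`, `length_matched`.
#' @export
setClass("LoopSelection", representation(choices = "data.frame"))

#' Optimal rigid-body superposition result
#' @slot rotation 3x3 proper rotation (row-vector convention:
#'   `x' = x \%*\% rotation + translation`).
#' @slot translation length-3 numeric (Angstrom).
#' @slot rmsd attained minimum RMSD (Angstrom).
#' @slot nAtoms number of atom pairs fitted.
#' @export
setClass("SuperpositionResult", representation(
  rotation = "matrix",
  translation = "numeric",
  rmsd = "numeric",
  nAtoms = "integer"
))

setValidity("SuperpositionResult", function(object) {
  if (abs(det(object@rotation) - 1) > 1e-9)
    return("rotation must be proper (det = +1)")
  if (object@rmsd < -1e-12) return("rmsd must be non-negative")
  TRUE
})

#' An assembled two-chain model
#'
#' @slot chains named list (chain id, e.g. H/L or A/B) of data.frames with
#'   columns `number`, `ins`, `aa`, `region`, `atom`, `x`, `y`, `z`,
#'   `source` (template sourceId), `sourceAa` (template residue) and
#'   `repack` (logical).
#' @slot meta list with the selection report (chain types, CS assignments,
#'   framework/loop choices, scores, clash count, warnings).
#' @slot minimized always `FALSE`: models are emitted non-minimized.
#' @export
setClass("AssembledModel", representation(
  chains = "list",
  meta = "list",
  minimized = "logical"
))

setValidity("AssembledModel", function(object) {
  if (isTRUE(object@minimized)) return("models are never minimized here")
  TRUE
})

#' Specification for the synthetic fixture world
#'
#' @slot seed integer master seed; all generation is a pure function of the
#'   spec.
#' @slot nTemplates number of template structures to emit.
#' @slot chainTypes chain types to generate (a valid receptor pairing).
#' @slot loopLengths named list per CDR of `c(min, max)` loop lengths.
#' @slot nCentroids integer length 3: canonical-structure centroids per CDR.
#' @slot kappa von Mises concentration of dihedral noise about centroids.
#' @slot mutationRate per-position framework mutation rate.
#' @slot fractionPaired fraction of structures emitted as paired crystals.
#' @export
setClass("FixtureSpec", representation(
  seed = "integer",
  nTemplates = "integer",
  chainTypes = "character",
  loopLengths = "list",
  nCentroids = "integer",
  kappa = "numeric",
  mutationRate = "numeric",
  fractionPaired = "numeric"
))

setValidity("FixtureSpec", function(object) {
  if (object@nTemplates < 1) return("nTemplates must be positive")
  if (object@mutationRate < 0 || object@mutationRate > 0.5)
    return("mutationRate must be in [0, 0.5]")
  if (object@fractionPaired < 0 || object@fractionPaired > 1)
    return("fractionPaired must be in [0, 1]")
  if (!all(object@chainTypes %in% CHAIN_TYPES))
    return("unknown chain type")
  TRUE
})
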