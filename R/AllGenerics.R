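#' @include AllClasses.R
NULL

#' Chain type accessor
#' @param x an object with a chain type.
#' @return character chain type, one of `heavy`, `kappa`, `lambda`,
#'   `alpha`, `beta`.
#' @export
setGeneric("chainType", function(x) standardGeneric("chainType"))

#' @rdname chainType
#' @export
setMethod("chainType", "NumberedChain", function(x) x@chain)
#' @rdname chainType
#' @export
setMethod("chainType", "ChainProfile", function(x) x@chain)
#' @rdname chainType
#' @export
setMethod("chainType", "TemplateRecord", function(x) x@chain)
#' @rdname chainType
#' @export
setMethod("chainType", "DihedralLoop", function(x) x@chain)

#' Residue table accessor
#' @param x a [NumberedChain-class] or [TemplateRecord-class].
#' @return data.frame with `number`, `ins`, `aa`, `region`.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname residues
#' @export
setMethod("residues", "NumberedChain", function(x) x@residues)
#' @rdname residues
#' @export
setMethod("residues", "TemplateRecord", function(x) x@numbered@residues)

#' Amino-acid sequence accessor
#' @param x object carrying a sequence.
#' @return single character string.
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))
#' @rdname chainSequence
#' @export
setMethod("chainSequence", "NumberedChain",
          function(x) paste(x@residues$aa, collapse = ""))
#' @rdname chainSequence
#' @export
setMethod("chainSequence", "TemplateRecord",
          function(x) chainSequence(x@numbered))
#' @rdname chainSequence
#' @export
setMethod("chainSequence", "DihedralLoop", function(x) x@sequence)

#' Region index ranges of a numbered chain
#' @param x a [NumberedChain-class].
#' @return named list of integer residue-index vectors, one per region.
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))
#' @rdname regionMap
#' @export
setMethod("regionMap", "NumberedChain", function(x) {
  split(seq_len(nrow(x@residues)), x@residues$region)
})

#' Template records accessor
#' @param x a [TemplateDatabase-class].
#' @return named list of [TemplateRecord-class] objects.
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))
#' @rdname templates
#' @export
setMethod("templates", "TemplateDatabase", function(x) x@records)

#' Crystal pair table accessor
#' @param x a [TemplateDatabase-class].
#' @return data.frame with columns `id1`, `id2`.
#' @export
setGeneric("crystalPairs", function(x) standardGeneric("crystalPairs"))
#' @rdname crystalPairs
#' @export
setMethod("crystalPairs", "TemplateDatabase", function(x) x@pairs)

setMethod("length", "TemplateDatabase", function(x) length(x@records))

setMethod("show", "NumberedChain", function(object) {
  r <- object@residues
  cat(sprintf("NumberedChain: %s (%s), %d residues, score %.1f bits\n",
              object@chain, receptorOf(object@chain), nrow(r), object@score))
  cnt <- table(factor(r$region, levels = c(FR_NAMES, CDR_NAMES)))
  cat("  regions:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "),
      "\n")
})

setMethod("show", "ChainProfile", function(object) {
  cat(sprintf("ChainProfile: %s chain, %d match states, %d sequences (%s)\n",
              object@chain, nrow(object@states), nrow(object@msa),
              object@schemeId))
})

setMethod("show", "TemplateRecord", function(object) {
  cat(sprintf("TemplateRecord %s: %s chain, %d residues, partner %s\n",
              object@sourceId, object@chain, nrow(object@numbered@residues),
              ifelse(is.na(object@partnerId), "none", object@partnerId)))
  cat(sprintf("  CS labels: %s | loop-donor eligible: %s\n",
              paste(ifelse(is.na(object@csLabels), "-", object@csLabels),
                    collapse = ", "),
              paste(ifelse(object@loopEligible, "yes", "no"), collapse = ", ")))
})

setMethod("show", "TemplateDatabase", function(object) {
  cat(sprintf("TemplateDatabase: %d records, %d crystal pairs (scheme %s)\n",
              length(object@records), nrow(object@pairs), object@schemeId))
  cnt <- table(vapply(object@records, function(r) r@chain, character(1)))
  if (length(cnt)) cat("  chains:",
                       paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "),
                       "\n")
})

setMethod("show", "CanonicalClass", function(object) {
  cat(sprintf("CanonicalClass %s: %s CDR%d length %d, %d members%s\n",
              object@classId, object@chain, object@cdr, object@loopLength,
              length(object@members),
              if (nrow(object@seqModel)) ", sequence model fitted" else ""))
})

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf(
    "ScoreSet vs %s: full %.0f, CDR %s, combined %.0f, identity %.1f%%\n",
    object@templateId, object@fullseq,
    paste(ifelse(is.finite(object@cdr), sprintf("%.0f", object@cdr), "-"),
          collapse = "/"),
    object@combined, object@identity))
})

setMethod("show", "AssembledModel", function(object) {
  n <- vapply(object@chains,
              function(ch) length(unique(posKey(ch$number, ch$ins))),
              integer(1))
  cat(sprintf("AssembledModel: chains %s (%s residues), %d repack-flagged, %s\n",
              paste(names(object@chains), collapse = "+"),
              paste(n, collapse = "+"),
              sum(vapply(object@chains, function(ch) {
                sum(ch$repack[!duplicated(posKey(ch$number, ch$ins))])
              }, numeric(1))),
              "non-minimized"))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("Superposition: %d atoms, rmsd %.4f A\n",
              object@nAtoms, object@rmsd))
})
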