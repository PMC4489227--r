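## End-to-end orchestration: identify -> number -> predict CS -> select
## framework -> select loops -> pack -> graft -> mark repack, plus the
## leave-one-out evaluation harness.

#' Model a receptor from its two chain sequences
#'
#' Runs the full pipeline.  The two sequences must form a valid receptor
#' pair (heavy + kappa/lambda, or alpha + beta); chain order in the input is
#' free, chain 1 of the model is always the heavy/alpha chain.
#'
#' @param seq1,seq2 amino-acid sequences (raw strings).
#' @param db a [TemplateDatabase-class].
#' @param profiles named list of [ChainProfile-class] objects.
#' @param classes list of fitted [CanonicalClass-class] objects.
#' @param scheme the [NumberingScheme-class].
#' @param iface interface definition from [loadInterface()].
#' @param blacklist structure identifiers to exclude as templates.
#' @param excludeSimilar when non-NULL, exclude templates with at least this
#'   percent identity to either query (leave-one-out filter).
#' @param forceFramework optional character(2) of template sourceIds forcing
#'   the framework selection (chain1, chain2).
#' @param strict refuse when no template passes the identity gate.
#' @return An [AssembledModel-class]; its `meta` slot carries the full
#'   selection report.
#' @export
modelReceptor <- function(seq1, seq2, db, profiles, classes, scheme, iface,
                          blacklist = character(0), excludeSimilar = NULL,
                          forceFramework = NULL, strict = FALSE) {
  ids <- lapply(c(seq1, seq2), function(s) identifyChain(s, profiles))
  for (i in 1:2) {
    if (!ids[[i]]$accepted)
      fvError("fv_chain_rejected",
              sprintf("chain %d rejected: best profile score %.1f below threshold",
                      i, ids[[i]]$score))
  }
  types <- c(ids[[1]]$chain, ids[[2]]$chain)
  pairingOk <- any(vapply(validPairings, function(p) setequal(p, types),
                          logical(1)))
  if (!pairingOk)
    fvError("fv_invalid_pairing",
            sprintf("invalid pairing: %s + %s is not a receptor", types[1],
                    types[2]))
  # normalize order: chain1 = heavy/alpha
  seqs <- c(seq1, seq2)
  if (types[1] %in% c("kappa", "lambda", "beta")) {
    seqs <- rev(seqs); types <- rev(types)
  }
  n1 <- alignAndNumber(seqs[1], profiles[[types[1]]], scheme)
  n2 <- alignAndNumber(seqs[2], profiles[[types[2]]], scheme)

  dbv <- excludeTemplates(db, blacklist)
  if (!is.null(excludeSimilar))
    dbv <- excludeSimilarTemplates(dbv, list(n1, n2), excludeSimilar)
  if (length(dbv@records) == 0)
    fvError("fv_empty_db", "no templates remain after filtering")

  cs1 <- assignCS(n1, classes)
  cs2 <- assignCS(n2, classes)

  if (!is.null(forceFramework)) {
    stopifnot(length(forceFramework) == 2,
              all(forceFramework %in% names(dbv@records)))
    r1 <- dbv@records[[forceFramework[1]]]
    r2 <- dbv@records[[forceFramework[2]]]
    same <- identical(r1@partnerId, r2@sourceId) &&
      identical(r2@partnerId, r1@sourceId)
    fwSel <- new("FrameworkSelection", chain1Id = r1@sourceId,
                 chain2Id = r2@sourceId, sameCrystal = same,
                 rationale = if (same) "paired" else "fallback_per_chain",
                 candidates = list())
  } else {
    fwSel <- selectFramework(n1, n2, cs1, cs2, dbv, strict = strict)
  }
  fw1 <- dbv@records[[fwSel@chain1Id]]
  fw2 <- dbv@records[[fwSel@chain2Id]]
  loops1 <- selectLoops(n1, cs1, fw1, dbv)
  loops2 <- selectLoops(n2, cs2, fw2, dbv)

  pk <- packChains(fw1, fw2, fwSel, dbv, iface, n1, n2)
  a1 <- assembleChain(n1, fw1, pk$atoms1, loops1, dbv)
  a2 <- assembleChain(n2, fw2, pk$atoms2, loops2, dbv)

  cid <- if (receptorOf(types[1]) == "BCR") c("H", "L") else c("A", "B")
  model <- new("AssembledModel",
    chains = stats::setNames(list(a1$chain, a2$chain), cid),
    meta = list(
      receptor = receptorOf(types[1]),
      chainTypes = stats::setNames(as.list(types), cid),
      targets = list(n1, n2),
      cs = list(chain1 = cs1, chain2 = cs2),
      framework = fwSel,
      loops = list(chain1 = loops1, chain2 = loops2),
      scaffold = pk$scaffold,
      packRmsd = pk$packRmsd,
      anchorRmsd = list(chain1 = a1$anchorRmsd, chain2 = a2$anchorRmsd),
      scores = list(
        chain1 = unclass(summaryScores(n1, cs1, fw1)),
        chain2 = unclass(summaryScores(n2, cs2, fw2))),
      warnings = c(a1$warnings, a2$warnings)),
    minimized = FALSE)
  model <- markRepack(model)
  model@meta$clashes <- countClashes(model)
  model
}

# Compact score record of the chosen framework template.
summaryScores <- function(target, targetCS, fw) {
  s <- scoreTemplate(target, targetCS, fw)
  list(template = s@templateId, fullseq = s@fullseq,
       cdr = ifelse(is.finite(s@cdr), s@cdr, NA_real_),
       combined = s@combined, identity = s@identity)
}

# Matched backbone coordinates of a model against reference records, by
# (chain, scheme position, atom).  refs: named list (model chain id ->
# TemplateRecord).  Returns matrices `model`, `ref` and the region labels.
matchBackbone <- function(model, refs) {
  mrows <- list(); rrows <- list(); regions <- character(0)
  for (cid in names(model@chains)) {
    ch <- model@chains[[cid]]
    ref <- refs[[cid]]
    res <- ref@numbered@residues
    refKey <- posKey(res$number, res$ins)
    bb <- ch[ch$atom %in% BACKBONE_ATOMS, , drop = FALSE]
    for (i in seq_len(nrow(bb))) {
      r <- match(posKey(bb$number[i], bb$ins[i]), refKey)
      if (is.na(r)) next
      hit <- ref@atoms[ref@atoms$resIdx == r &
                         ref@atoms$atom == bb$atom[i], , drop = FALSE]
      if (nrow(hit) == 0) next
      mrows[[length(mrows) + 1]] <- c(bb$x[i], bb$y[i], bb$z[i])
      rrows[[length(rrows) + 1]] <- c(hit$x[1], hit$y[1], hit$z[1])
      regions <- c(regions, bb$region[i])
    }
  }
  list(model = do.call(rbind, mrows), ref = do.call(rbind, rrows),
       regions = regions)
}

#' Backbone accuracy of a model against reference structures
#'
#' Reports the global backbone RMSD (after superposing all matched backbone
#' atoms), the framework RMSD and binding-site (all-CDR) RMSD after
#' framework superposition, and a per-region breakdown.
#'
#' @param model an [AssembledModel-class].
#' @param refs named list (model chain id -> [TemplateRecord-class]) of
#'   reference chains.
#' @return named numeric vector of RMSDs in Angstrom.
#' @export
evaluateModel <- function(model, refs) {
  mb <- matchBackbone(model, refs)
  spAll <- superpose(mb$model, mb$ref)
  isFr <- mb$regions %in% FR_NAMES
  spFr <- superpose(mb$model[isFr, , drop = FALSE],
                    mb$ref[isFr, , drop = FALSE])
  fitted <- applyTransform(mb$model, spFr)
  dev <- rowSums((fitted - mb$ref)^2)
  rmsdOf <- function(mask)
    if (any(mask)) sqrt(mean(dev[mask])) else NA_real_
  out <- c(global = spAll@rmsd,
           framework = rmsdOf(isFr),
           binding_site = rmsdOf(!isFr))
  for (rg in c(FR_NAMES, CDR_NAMES)) out[rg] <- rmsdOf(mb$regions == rg)
  out
}

#' Leave-one-out evaluation over a template database
#'
#' For each crystal pair, the pair's own sequences are re-modeled after
#' excluding the pair (and every template at or above `maxIdentity` percent
#' identity to either chain), and backbone RMSDs to the solved structure
#' are recorded per region.
#'
#' @param db a [TemplateDatabase-class].
#' @param profiles,classes,scheme,iface pipeline inputs as in
#'   [modelReceptor()].
#' @param maxIdentity leave-one-out identity filter (default 90).
#' @param pairs optional subset of pair indices.
#' @return data.frame: one row per modeled pair, RMSD columns per region;
#'   failed runs carry the error message in `error`.
#' @export
leaveOneOut <- function(db, profiles, classes, scheme, iface,
                        maxIdentity = 90, pairs = NULL) {
  pr <- db@pairs
  idx <- pairs %||% seq_len(nrow(pr))
  rows <- lapply(idx, function(i) {
    r1 <- db@records[[pr$id1[i]]]; r2 <- db@records[[pr$id2[i]]]
    if (r1@chain %in% c("kappa", "lambda", "beta")) { tmp <- r1; r1 <- r2; r2 <- tmp }
    out <- data.frame(structId = r1@structId, stringsAsFactors = FALSE)
    for (nm in c("global", "framework", "binding_site", FR_NAMES, CDR_NAMES))
      out[[nm]] <- NA_real_
    out$error <- NA_character_
    tryCatch({
      model <- modelReceptor(chainSequence(r1), chainSequence(r2), db,
                             profiles, classes, scheme, iface,
                             excludeSimilar = maxIdentity)
      refs <- stats::setNames(list(r1, r2), names(model@chains))
      ev <- evaluateModel(model, refs)
      for (nm in names(ev)) out[[nm]] <- ev[[nm]]
    }, error = function(e) {
      out$error <<- conditionMessage(e)
    })
    out
  })
  do.call(rbind, rows)
}
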