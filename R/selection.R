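## Template selection: the five per-template scores, the top-20 / >=60%
## identity framework pipeline with same-crystal preference, and per-CDR
## loop selection with the beta-CDR3 length rule.

#' Score a template against a numbered target
#'
#' Five scores per template: a full-sequence BLOSUM62 similarity over the
#' scheme positions occupied in both chains, one BLOSUM62 score per CDR
#' (defined only when the loop lengths match; `-Inf` otherwise), and a
#' combined score equal to the full-sequence score plus the scores of the
#' template CDRs whose canonical-structure label equals the target's
#' predicted one.  Sequence identity over shared positions is carried along.
#'
#' @param target a [NumberedChain-class].
#' @param targetCS CS assignment for the target as returned by [assignCS()].
#' @param template a [TemplateRecord-class] of the same chain type.
#' @param matrix substitution matrix (default BLOSUM62).
#' @return A [ScoreSet-class].
#' @export
scoreTemplate <- function(target, targetCS, template, matrix = blosum62()) {
  if (!identical(target@chain, template@chain))
    fvError("fv_input", sprintf("chain type mismatch: %s vs %s",
                                target@chain, template@chain))
  tr <- target@residues
  mr <- template@numbered@residues
  keyT <- posKey(tr$number, tr$ins)
  keyM <- posKey(mr$number, mr$ins)
  shared <- intersect(keyT, keyM)
  iT <- match(shared, keyT); iM <- match(shared, keyM)
  okT <- tr$aa[iT] %in% rownames(matrix)
  okM <- mr$aa[iM] %in% rownames(matrix)
  ok <- okT & okM
  fullseq <- sum(matrix[cbind(tr$aa[iT][ok], mr$aa[iM][ok])])
  identity <- if (length(shared)) 100 * mean(tr$aa[iT] == mr$aa[iM]) else 0

  cdr <- rep(-Inf, 3)
  csMatch <- rep(FALSE, 3)
  for (k in 1:3) {
    lt <- which(tr$region == CDR_NAMES[k])
    lm <- which(mr$region == CDR_NAMES[k])
    if (length(lt) == length(lm) && length(lt) > 0) {
      # same length => identical right-aligned numbering; score in loop order
      okk <- tr$aa[lt] %in% rownames(matrix) & mr$aa[lm] %in% rownames(matrix)
      cdr[k] <- sum(matrix[cbind(tr$aa[lt][okk], mr$aa[lm][okk])])
    }
    tcs <- targetCS[[paste0("cdr", k)]]$class
    mcs <- template@csLabels[[paste0("cdr", k)]]
    csMatch[k] <- !is.na(tcs) && !is.na(mcs) && identical(tcs, mcs)
  }
  combined <- fullseq + sum(cdr[csMatch & is.finite(cdr)])
  new("ScoreSet", templateId = template@sourceId, fullseq = fullseq,
      cdr = cdr, csMatch = csMatch, combined = combined,
      identity = identity)
}

# Score every same-chain-type template in the database; returns a data.frame
# (one row per template) plus the ScoreSet list.
scoreAllTemplates <- function(target, targetCS, db, matrix = blosum62()) {
  recs <- Filter(function(r) r@chain == target@chain, db@records)
  sets <- lapply(recs, function(r) scoreTemplate(target, targetCS, r, matrix))
  df <- data.frame(
    templateId = vapply(sets, function(s) s@templateId, character(1)),
    fullseq = vapply(sets, function(s) s@fullseq, numeric(1)),
    cdr1 = vapply(sets, function(s) s@cdr[1], numeric(1)),
    cdr2 = vapply(sets, function(s) s@cdr[2], numeric(1)),
    cdr3 = vapply(sets, function(s) s@cdr[3], numeric(1)),
    combined = vapply(sets, function(s) s@combined, numeric(1)),
    identity = vapply(sets, function(s) s@identity, numeric(1)),
    resolution = vapply(recs, function(r) r@resolution, numeric(1)),
    partnerId = vapply(recs, function(r) r@partnerId, character(1)),
    structId = vapply(recs, function(r) r@structId, character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  list(table = df, sets = sets)
}

# Deterministic tie-break ordering: primary desc, then combined desc, then
# resolution asc (NA last), then sourceId lexicographic.
tieOrder <- function(primary, combined, resolution, id) {
  resolution[is.na(resolution)] <- Inf
  order(-primary, -combined, resolution, id, method = "radix")
}

#' Select framework templates for a receptor pair
#'
#' Per chain, the 20 templates with the highest combined score among those
#' with at least `minIdentity` percent sequence identity form the candidate
#' list.  Among cross-chain candidate pairs sharing a crystal, the pair with
#' the highest overall identity (mean of the two chains) is selected.  When
#' no same-crystal pair exists, the selection falls back to choosing, per
#' chain, the template with the highest combined loop score (the sum of the
#' defined per-CDR scores), which minimizes the number of loops that must be
#' grafted.  When no template reaches the identity gate the fallback runs
#' over all templates with a warning (or refuses when `strict`).
#'
#' @param target1,target2 [NumberedChain-class] targets (chain1 =
#'   heavy/alpha).
#' @param cs1,cs2 CS assignments from [assignCS()].
#' @param db a [TemplateDatabase-class] (blacklist already applied).
#' @param topN candidate list size (default 20).
#' @param minIdentity identity gate in percent (default 60).
#' @param strict refuse instead of warning when nothing passes the gate.
#' @param fallback `"cdrsum"` (default: sum of defined CDR scores) or
#'   `"combined"` for the fallback ranking.
#' @return A [FrameworkSelection-class].
#' @export
selectFramework <- function(target1, target2, cs1, cs2, db,
                            topN = 20, minIdentity = 60, strict = FALSE,
                            fallback = c("cdrsum", "combined")) {
  fallback <- match.arg(fallback)
  if (length(db@records) == 0) fvError("fv_empty_db", "empty template database")
  sc1 <- scoreAllTemplates(target1, cs1, db)
  sc2 <- scoreAllTemplates(target2, cs2, db)
  if (nrow(sc1$table) == 0 || nrow(sc2$table) == 0)
    fvError("fv_empty_db", "no template of the required chain type")

  candidates <- function(tab) {
    pass <- tab[tab$identity >= minIdentity, , drop = FALSE]
    if (nrow(pass) == 0) {
      if (strict)
        fvError("fv_low_identity",
                sprintf("no template reaches %g%% identity", minIdentity))
      warning(sprintf("low-identity: no template reaches %g%% identity",
                      minIdentity))
      return(pass)   # empty: paired search skipped, fallback over all
    }
    ord <- tieOrder(pass$combined, pass$combined, pass$resolution,
                    pass$templateId)
    pass[ord[seq_len(min(topN, nrow(pass)))], , drop = FALSE]
  }
  cand1 <- candidates(sc1$table)
  cand2 <- candidates(sc2$table)

  # same-crystal pairs among the candidate lists
  best <- NULL
  if (nrow(cand1) > 0 && nrow(cand2) > 0) {
    a <- cand1[!is.na(cand1$partnerId),
               c("templateId", "partnerId", "identity", "combined",
                 "resolution")]
    b <- cand2[, c("templateId", "identity", "combined")]
    hits <- merge(a, b, by.x = "partnerId", by.y = "templateId",
                  suffixes = c(".1", ".2"))
    if (nrow(hits) > 0) {
      meanId <- (hits$identity.1 + hits$identity.2) / 2
      comb <- hits$combined.1 + hits$combined.2
      ord <- tieOrder(meanId, comb, hits$resolution, hits$templateId)
      best <- hits[ord[1], ]
    }
  }
  if (!is.null(best)) {
    return(new("FrameworkSelection",
               chain1Id = best$templateId, chain2Id = best$partnerId,
               sameCrystal = TRUE, rationale = "paired",
               candidates = list(cand1, cand2)))
  }
  # per-chain fallback
  pick <- function(tab) {
    loopScore <- if (fallback == "cdrsum") {
      sapply(seq_len(nrow(tab)), function(i) {
        v <- c(tab$cdr1[i], tab$cdr2[i], tab$cdr3[i])
        sum(v[is.finite(v)])
      })
    } else tab$combined
    ord <- tieOrder(loopScore, tab$combined, tab$resolution, tab$templateId)
    tab$templateId[ord[1]]
  }
  new("FrameworkSelection",
      chain1Id = pick(sc1$table), chain2Id = pick(sc2$table),
      sameCrystal = FALSE, rationale = "fallback_per_chain",
      candidates = list(cand1, cand2))
}

#' Select loop templates for one chain
#'
#' Per CDR: the framework's own loop is kept when its canonical-structure
#' label equals the target's predicted CS; otherwise the eligible donor loop
#' with the same CS and the highest CDR-specific score is chosen; when no CS
#' is predicted (or no CS-matching donor exists) the donor with the target
#' loop's length and the highest CDR score is chosen.  The length rule is
#' always used for beta CDR3.  No loop of the required length anywhere in
#' the database is a hard error naming the CDR.
#'
#' @param target a [NumberedChain-class].
#' @param targetCS CS assignment from [assignCS()].
#' @param framework the selected framework [TemplateRecord-class].
#' @param db a [TemplateDatabase-class] (blacklist already applied).
#' @param matrix substitution matrix.
#' @return A [LoopSelection-class].
#' @export
selectLoops <- function(target, targetCS, framework, db,
                        matrix = blosum62()) {
  tr <- target@residues
  recs <- Filter(function(r) r@chain == target@chain, db@records)
  rows <- lapply(1:3, function(k) {
    cdrName <- CDR_NAMES[k]
    tLen <- sum(tr$region == cdrName)
    tcs <- targetCS[[paste0("cdr", k)]]$class
    fcs <- framework@csLabels[[paste0("cdr", k)]]
    lengthRule <- (target@chain == "beta" && k == 3)
    if (!lengthRule && !is.na(tcs) && !is.na(fcs) && identical(tcs, fcs)) {
      return(data.frame(cdr = cdrName, templateId = framework@sourceId,
                        mode = "kept_from_framework", score = NA_real_,
                        stringsAsFactors = FALSE))
    }
    cdrScore <- function(r) {
      lt <- which(tr$region == cdrName)
      lm <- which(r@numbered@residues$region == cdrName)
      if (length(lm) != length(lt)) return(-Inf)
      aaT <- tr$aa[lt]; aaM <- r@numbered@residues$aa[lm]
      ok <- aaT %in% rownames(matrix) & aaM %in% rownames(matrix)
      sum(matrix[cbind(aaT[ok], aaM[ok])])
    }
    chooseBest <- function(pool, mode) {
      sc <- vapply(pool, cdrScore, numeric(1))
      keep <- is.finite(sc)
      pool <- pool[keep]; sc <- sc[keep]
      if (length(pool) == 0) return(NULL)
      ids <- vapply(pool, function(r) r@sourceId, character(1))
      resol <- vapply(pool, function(r) r@resolution, numeric(1))
      ord <- tieOrder(sc, sc, resol, ids)
      data.frame(cdr = cdrName, templateId = ids[ord[1]], mode = mode,
                 score = sc[ord[1]], stringsAsFactors = FALSE)
    }
    eligible <- Filter(function(r) r@loopEligible[k], recs)
    if (!lengthRule && !is.na(tcs)) {
      csPool <- Filter(function(r)
        identical(r@csLabels[[paste0("cdr", k)]], tcs), eligible)
      hit <- chooseBest(csPool, "cs_matched")
      if (!is.null(hit)) return(hit)
    }
    lenPool <- Filter(function(r)
      sum(r@numbered@residues$region == cdrName) == tLen, eligible)
    hit <- chooseBest(lenPool, "length_matched")
    if (is.null(hit))
      fvError("fv_no_loop_template",
              sprintf("no loop template of length %d for %s", tLen, cdrName))
    hit
  })
  new("LoopSelection", choices = do.call(rbind, rows))
}
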