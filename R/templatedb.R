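## Template database: ingestion of PDB-format structures, renumbering,
## observed CS labeling, redundancy culling, blacklisting and persistence.

# Percent sequence identity over the scheme positions occupied in both
# chains (positions missing in either are skipped).
seqIdentityPct <- function(resA, resB) {
  keyA <- posKey(resA$number, resA$ins)
  keyB <- posKey(resB$number, resB$ins)
  shared <- intersect(keyA, keyB)
  if (length(shared) == 0) return(0)
  100 * mean(resA$aa[match(shared, keyA)] == resB$aa[match(shared, keyB)])
}

#' Ingest a PDB-format structure into template records
#'
#' Every chain accepted by [identifyChain()] is renumbered onto the scheme,
#' its backbone extracted, its dihedrals computed, and its CDRs labeled with
#' the nearest canonical-structure exemplar (observed from dihedrals, not
#' predicted from sequence).  Chains in the same file forming a recognized
#' receptor pair (heavy+kappa, heavy+lambda or alpha+beta) are linked as
#' crystal partners.  A CDR with missing backbone atoms is flagged
#' loop-donor ineligible; the framework remains usable.
#'
#' @param path PDB-format file.
#' @param profiles named list of [ChainProfile-class] objects.
#' @param scheme the [NumberingScheme-class].
#' @param classes list of [CanonicalClass-class] objects for observed CS
#'   labels (optional).
#' @param frTolerance framework completeness tolerance for
#'   [alignAndNumber()].
#' @return list of [TemplateRecord-class] objects (empty, with a warning,
#'   when no chain is acceptable).
#' @export
ingestStructure <- function(path, profiles, scheme, classes = list(),
                            frTolerance = 0.5) {
  at <- readPdbAtoms(path)
  resol <- readPdbResolution(path)
  structId <- toupper(sub("\\.[^.]*$", "", basename(path)))
  records <- list()
  for (cid in unique(at$chain)) {
    ca <- at[at$chain == cid, , drop = FALSE]
    resKey <- paste(ca$resno, ca$insert, sep = "|")
    resOrder <- unique(resKey)
    aa1 <- vapply(resOrder, function(k) {
      resid <- ca$resid[resKey == k][1]
      a <- suppressWarnings(bio3d::aa321(resid))
      if (is.na(a) || !a %in% AA20) "X" else a
    }, character(1))
    seq <- paste(aa1, collapse = "")
    idc <- tryCatch(identifyChain(seq, profiles), error = function(e) NULL)
    if (is.null(idc) || !idc$accepted) next
    numbered <- tryCatch(
      alignAndNumber(seq, profiles[[idc$chain]], scheme, frTolerance),
      error = function(e) NULL)
    if (is.null(numbered)) next
    res <- numbered@residues
    # map numbered residues back to structural residues and pull atoms
    atomRows <- list()
    for (i in seq_len(nrow(res))) {
      k <- resOrder[res$seqIdx[i]]
      rows <- ca[resKey == k & !grepl("^H", ca$elety), , drop = FALSE]
      if (nrow(rows) == 0) next
      atomRows[[length(atomRows) + 1]] <- data.frame(
        resIdx = i, atom = rows$elety,
        x = rows$x, y = rows$y, z = rows$z, stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, atomRows)
    dih <- computeDihedrals(atoms, nres = nrow(res))
    sourceId <- paste0(structId, "_", cid)
    csLabels <- c(cdr1 = NA_character_, cdr2 = NA_character_,
                  cdr3 = NA_character_)
    loopEligible <- c(cdr1 = FALSE, cdr2 = FALSE, cdr3 = FALSE)
    for (k in 1:3) {
      rows <- which(res$region == CDR_NAMES[k])
      if (length(rows) == 0) next
      flank <- c(min(rows) - 2L, min(rows) - 1L,
                 max(rows) + 1L, max(rows) + 2L)
      needed <- c(rows, flank)
      haveBB <- all(vapply(needed, function(i) {
        i >= 1 && i <= nrow(res) &&
          all(BACKBONE_ATOMS %in% atoms$atom[atoms$resIdx == i])
      }, logical(1)))
      angOk <- !anyNA(dih$phi[rows]) && !anyNA(dih$psi[rows])
      loopEligible[k] <- haveBB && angOk
      if (angOk && !(numbered@chain == "beta" && k == 3) &&
          length(classes) > 0) {
        loop <- new("DihedralLoop", chain = numbered@chain, cdr = as.integer(k),
                    sequence = paste(res$aa[rows], collapse = ""),
                    phi = dih$phi[rows], psi = dih$psi[rows],
                    source = sourceId)
        csLabels[k] <- assignObservedCS(loop, classes)
      }
    }
    records[[sourceId]] <- new("TemplateRecord",
      sourceId = sourceId, structId = structId, chain = numbered@chain,
      numbered = numbered, atoms = atoms,
      phi = dih$phi, psi = dih$psi,
      csLabels = csLabels, loopEligible = loopEligible,
      partnerId = NA_character_, resolution = resol)
  }
  if (length(records) == 0) {
    warning(sprintf("no acceptable receptor chain in %s", basename(path)))
    return(list())
  }
  # reciprocal partner links for recognized pairings within the file
  types <- vapply(records, function(r) r@chain, character(1))
  for (pairing in validPairings) {
    i1 <- which(types == pairing[1]); i2 <- which(types == pairing[2])
    if (length(i1) == 1 && length(i2) == 1) {
      records[[i1]]@partnerId <- records[[i2]]@sourceId
      records[[i2]]@partnerId <- records[[i1]]@sourceId
    }
  }
  records
}

#' Extract the CDR dihedral loops of a template record
#' @param record a [TemplateRecord-class].
#' @param cdrs which CDRs (default all whose dihedrals are defined).
#' @return list of [DihedralLoop-class] objects.
#' @export
templateLoops <- function(record, cdrs = 1:3) {
  res <- record@numbered@residues
  out <- list()
  for (k in cdrs) {
    rows <- which(res$region == CDR_NAMES[k])
    if (length(rows) == 0) next
    if (anyNA(record@phi[rows]) || anyNA(record@psi[rows])) next
    out[[length(out) + 1]] <- new("DihedralLoop",
      chain = record@chain, cdr = as.integer(k),
      sequence = paste(res$aa[rows], collapse = ""),
      phi = record@phi[rows], psi = record@psi[rows],
      source = record@sourceId)
  }
  out
}

# Build the pairs table from partner links among a record set.
pairsFromRecords <- function(records) {
  ids <- names(records)
  out <- data.frame(id1 = character(0), id2 = character(0),
                    stringsAsFactors = FALSE)
  seen <- character(0)
  for (id in ids) {
    p <- records[[id]]@partnerId
    if (!is.na(p) && p %in% ids && !(id %in% seen)) {
      out <- rbind(out, data.frame(id1 = id, id2 = p,
                                   stringsAsFactors = FALSE))
      seen <- c(seen, id, p)
    }
  }
  out
}

# Drop partner links pointing outside the record set.
pruneBrokenPartners <- function(records) {
  ids <- names(records)
  for (id in ids) {
    p <- records[[id]]@partnerId
    if (!is.na(p) && !(p %in% ids)) records[[id]]@partnerId <- NA_character_
  }
  records
}

#' Cull redundant templates
#'
#' Greedy culling by pairwise sequence identity over shared numbered
#' positions, visiting records by resolution (ascending, unknown last) then
#' identifier: a record is kept when its identity to every kept record of
#' the same chain type is below the threshold.  A paired structure is
#' retained whole when at least one of its chains survives, and partner
#' links are kept.
#'
#' @param records list of [TemplateRecord-class] objects (or a
#'   [TemplateDatabase-class]).
#' @param threshold percent identity in (0, 100].
#' @param schemeId scheme identifier recorded on the database.
#' @return A [TemplateDatabase-class].
#' @export
cullRedundancy <- function(records, threshold = 90, schemeId = NA_character_) {
  stopifnot(threshold > 0, threshold <= 100)
  if (is(records, "TemplateDatabase")) {
    schemeId <- records@schemeId
    records <- records@records
  }
  resol <- vapply(records, function(r)
    ifelse(is.na(r@resolution), Inf, r@resolution), numeric(1))
  ids <- names(records)
  ord <- order(resol, ids, method = "radix")
  kept <- character(0)
  for (i in ord) {
    r <- records[[i]]
    redundant <- FALSE
    for (kid in kept) {
      kr <- records[[kid]]
      if (kr@chain != r@chain) next
      if (seqIdentityPct(r@numbered@residues, kr@numbered@residues) >=
          threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, ids[i])
  }
  # retain whole pairs when one chain survives
  partners <- vapply(records[kept], function(r) r@partnerId, character(1))
  keepAll <- union(kept, partners[!is.na(partners)])
  keepAll <- keepAll[keepAll %in% ids]
  keepAll <- ids[ids %in% keepAll]   # original order
  out <- pruneBrokenPartners(records[keepAll])
  new("TemplateDatabase", records = out, pairs = pairsFromRecords(out),
      redundancyThreshold = threshold, schemeId = schemeId)
}

#' Assemble a database from records without culling
#' @param records list of [TemplateRecord-class] objects.
#' @param schemeId scheme identifier.
#' @return A [TemplateDatabase-class].
#' @export
templateDatabase <- function(records, schemeId = NA_character_) {
  records <- pruneBrokenPartners(records)
  new("TemplateDatabase", records = records,
      pairs = pairsFromRecords(records),
      redundancyThreshold = NA_real_, schemeId = schemeId)
}

#' Blacklist structures from a database
#'
#' Returns a view of the database hiding every record (and pair entry) whose
#' structure identifier matches the blacklist, case-insensitively.  Unknown
#' identifiers produce a warning.
#'
#' @param db a [TemplateDatabase-class].
#' @param blacklist character vector of structure identifiers.
#' @return A filtered [TemplateDatabase-class].
#' @export
excludeTemplates <- function(db, blacklist) {
  if (length(blacklist) == 0) return(db)
  bl <- toupper(blacklist)
  structIds <- vapply(db@records, function(r) toupper(r@structId),
                      character(1))
  unknown <- setdiff(bl, structIds)
  if (length(unknown))
    warning(sprintf("blacklist identifiers not in database: %s",
                    paste(unknown, collapse = ", ")))
  keep <- !(structIds %in% bl)
  recs <- pruneBrokenPartners(db@records[keep])
  new("TemplateDatabase", records = recs, pairs = pairsFromRecords(recs),
      redundancyThreshold = db@redundancyThreshold, schemeId = db@schemeId)
}

#' Exclude templates similar to a query (leave-one-out filter)
#'
#' Hides every record whose sequence identity to the query chain of the same
#' chain type is at or above `maxIdentity` percent, mirroring a
#' leave-one-out evaluation where near-identical templates are removed.
#'
#' @param db a [TemplateDatabase-class].
#' @param queries list of [NumberedChain-class] query chains.
#' @param maxIdentity percent identity cutoff (default 90).
#' @return A filtered [TemplateDatabase-class].
#' @export
excludeSimilarTemplates <- function(db, queries, maxIdentity = 90) {
  drop <- vapply(db@records, function(r) {
    any(vapply(queries, function(q) {
      q@chain == r@chain &&
        seqIdentityPct(q@residues, r@numbered@residues) >= maxIdentity
    }, logical(1)))
  }, logical(1))
  recs <- pruneBrokenPartners(db@records[!drop])
  new("TemplateDatabase", records = recs, pairs = pairsFromRecords(recs),
      redundancyThreshold = db@redundancyThreshold, schemeId = db@schemeId)
}

#' Persist a template database to a directory
#'
#' Writes `records.json` (all fields except coordinates) plus one renumbered
#' PDB-format coordinate file per record.
#'
#' @param db a [TemplateDatabase-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTemplateDatabase <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- lapply(db@records, function(r) list(
    source_id = r@sourceId, struct_id = r@structId, chain = r@chain,
    score = r@numbered@score,
    residues = r@numbered@residues[c("number", "ins", "aa", "region")],
    phi = r@phi, psi = r@psi,
    cs_labels = as.list(r@csLabels),
    loop_eligible = as.list(r@loopEligible),
    partner_id = r@partnerId, resolution = r@resolution))
  jsonlite::write_json(
    list(scheme_id = db@schemeId,
         redundancy_threshold = db@redundancyThreshold,
         records = payload),
    file.path(dir, "records.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  for (r in db@records) {
    res <- r@numbered@residues
    ch <- merge(data.frame(resIdx = seq_len(nrow(res)),
                           number = res$number, ins = res$ins, aa = res$aa),
                r@atoms, by = "resIdx")
    ch <- ch[order(ch$resIdx), ]
    writePdbFile(stats::setNames(list(ch), "A"),
                 file.path(dir, paste0(r@sourceId, ".pdb")),
                 resolution = r@resolution)
  }
  invisible(dir)
}

#' Load a template database written by [writeTemplateDatabase()]
#' @param dir database directory.
#' @param scheme the [NumberingScheme-class] named in `records.json`.
#' @return A [TemplateDatabase-class].
#' @export
loadTemplateDatabase <- function(dir, scheme) {
  meta <- jsonlite::read_json(file.path(dir, "records.json"),
                              simplifyVector = FALSE)
  stopifnot(identical(meta$scheme_id, scheme@id))
  num1 <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  chr1 <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  recs <- list()
  for (p in meta$records) {
    res <- data.frame(
      number = vapply(p$residues, function(r) as.integer(r$number),
                      integer(1)),
      ins = vapply(p$residues, function(r) chr1(r$ins), character(1)),
      aa = vapply(p$residues, function(r) r$aa, character(1)),
      region = vapply(p$residues, function(r) r$region, character(1)),
      stringsAsFactors = FALSE)
    res$ins[is.na(res$ins)] <- ""
    res$seqIdx <- seq_len(nrow(res))
    numbered <- new("NumberedChain", chain = p$chain, schemeId = scheme@id,
                    residues = res, score = num1(p$score))
    at <- readPdbAtoms(file.path(dir, paste0(p$source_id, ".pdb")))
    key <- posKey(at$resno, at$insert)
    resKey <- posKey(res$number, res$ins)
    atoms <- data.frame(resIdx = match(key, resKey), atom = at$elety,
                        x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
    atoms <- atoms[!is.na(atoms$resIdx), ]
    cs <- vapply(c("cdr1", "cdr2", "cdr3"), function(k)
      chr1(p$cs_labels[[k]]), character(1))
    le <- vapply(c("cdr1", "cdr2", "cdr3"), function(k)
      isTRUE(p$loop_eligible[[k]]), logical(1))
    recs[[p$source_id]] <- new("TemplateRecord",
      sourceId = p$source_id, structId = p$struct_id,
      chain = p$chain, numbered = numbered, atoms = atoms,
      phi = vapply(p$phi, num1, numeric(1)),
      psi = vapply(p$psi, num1, numeric(1)),
      csLabels = cs, loopEligible = le,
      partnerId = chr1(p$partner_id),
      resolution = num1(p$resolution))
  }
  new("TemplateDatabase", records = recs, pairs = pairsFromRecords(recs),
      redundancyThreshold = num1(meta$redundancy_threshold),
      schemeId = meta$scheme_id)
}
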