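## Model assembly: rigid-body packing of the two framework chains,
## 2+2-anchor loop grafting, repack marking, and model emission.

#' Load an interface packing definition
#'
#' Scheme positions forming the two-chain packing interface, per chain type.
#' Shipped tables: `"chothia"` (reconstructed, editable) and `"mini"` (for
#' the fixture scheme); or compute one from a database with
#' [computeInterface()].
#'
#' @param name `"chothia"`, `"mini"`, or a path to an interface JSON file.
#' @return named list: chain type -> integer vector of scheme numbers.
#' @export
loadInterface <- function(name = "chothia") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("interface_", name, ".json"),
                package = "FvModeler")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("no such interface definition: '%s'", name))
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.integer)
}

#' Derive an interface definition from paired templates
#'
#' A scheme position joins the interface of a chain type when, in at least
#' `minFrac` of the database's paired structures, one of its residue's heavy
#' atoms lies within `cutoff` Angstrom of the partner chain.
#'
#' @param db a [TemplateDatabase-class] with crystal pairs.
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @param minFrac minimum fraction of pairs showing the contact.
#' @return named list: chain type -> integer vector of scheme numbers.
#' @export
computeInterface <- function(db, cutoff = 4.5, minFrac = 0.5) {
  pairs <- db@pairs
  if (nrow(pairs) == 0) fvError("fv_input", "database has no pairs")
  tally <- list()
  npairs <- list()
  for (i in seq_len(nrow(pairs))) {
    for (ids in list(c(pairs$id1[i], pairs$id2[i]),
                     c(pairs$id2[i], pairs$id1[i]))) {
      r <- db@records[[ids[1]]]; p <- db@records[[ids[2]]]
      xyzP <- as.matrix(p@atoms[, c("x", "y", "z")])
      res <- r@numbered@residues
      npairs[[r@chain]] <- (npairs[[r@chain]] %||% 0) + 1
      for (j in seq_len(nrow(res))) {
        a <- as.matrix(r@atoms[r@atoms$resIdx == j, c("x", "y", "z")])
        if (nrow(a) == 0) next
        d2 <- outer(rowSums(a^2), rowSums(xyzP^2), `+`) -
          2 * a %*% t(xyzP)
        if (min(d2) <= cutoff^2) {
          k <- as.character(res$number[j])
          tally[[r@chain]][[k]] <- (tally[[r@chain]][[k]] %||% 0) + 1
        }
      }
    }
  }
  out <- lapply(names(tally), function(ch) {
    cnt <- unlist(tally[[ch]])
    sort(as.integer(names(cnt)[cnt / npairs[[ch]] >= minFrac]))
  })
  stats::setNames(out, names(tally))
}

# Backbone coordinates (N, CA, C, O in residue order) of a record at the
# given residue rows; NULL when any atom is missing.
backboneXyz <- function(record, rows) {
  out <- matrix(NA_real_, length(rows) * 4, 3)
  for (i in seq_along(rows)) {
    for (k in 1:4) {
      hit <- record@atoms[record@atoms$resIdx == rows[i] &
                            record@atoms$atom == BACKBONE_ATOMS[k], ,
                          drop = FALSE]
      if (nrow(hit) == 0) return(NULL)
      out[(i - 1) * 4 + k, ] <- c(hit$x[1], hit$y[1], hit$z[1])
    }
  }
  out
}

# Interface pseudo-sequence of a residue table: residues at the interface
# scheme numbers (insertion-free positions), named by number.
pseudoSequence <- function(res, ifaceNumbers) {
  hit <- res[res$ins == "" & res$number %in% ifaceNumbers, , drop = FALSE]
  stats::setNames(hit$aa, hit$number)
}

#' Position the two framework chains
#'
#' Same-crystal selections keep the crystal coordinates untouched.  For
#' frameworks from different crystals, the targets' interface
#' pseudo-sequence picks the database crystal pair with the highest BLOSUM62
#' pseudo-sequence similarity as a packing scaffold, and each framework
#' chain is superposed onto the corresponding scaffold chain over the
#' interface backbone atoms.
#'
#' @param fw1,fw2 framework [TemplateRecord-class] objects (chain1 =
#'   heavy/alpha).
#' @param selection the [FrameworkSelection-class].
#' @param db a [TemplateDatabase-class] (for scaffold pairs).
#' @param iface interface definition from [loadInterface()].
#' @param target1,target2 the numbered targets.
#' @param matrix substitution matrix for the pseudo-sequence score.
#' @return list with `atoms1`, `atoms2` (positioned atom tables),
#'   `scaffold` (pair ids or NULL) and `packRmsd` (per-chain interface
#'   RMSD to the scaffold, NA for same-crystal).
#' @export
packChains <- function(fw1, fw2, selection, db, iface, target1, target2,
                       matrix = blosum62()) {
  if (isTRUE(selection@sameCrystal)) {
    return(list(atoms1 = fw1@atoms, atoms2 = fw2@atoms, scaffold = NULL,
                packRmsd = c(NA_real_, NA_real_)))
  }
  pairs <- db@pairs
  if (nrow(pairs) == 0)
    fvError("fv_no_scaffold", "no packing scaffold: database has no pairs")
  # orient each pair as (chain1-type, chain2-type)
  targetPseudo <- c(pseudoSequence(target1@residues, iface[[target1@chain]]),
                    pseudoSequence(target2@residues, iface[[target2@chain]]))
  best <- NULL
  for (i in seq_len(nrow(pairs))) {
    ra <- db@records[[pairs$id1[i]]]; rb <- db@records[[pairs$id2[i]]]
    if (ra@chain == target2@chain) { tmp <- ra; ra <- rb; rb <- tmp }
    if (ra@chain != target1@chain || rb@chain != target2@chain) next
    scafPseudo <- c(pseudoSequence(ra@numbered@residues, iface[[ra@chain]]),
                    pseudoSequence(rb@numbered@residues, iface[[rb@chain]]))
    # positions shared between target and scaffold pseudo-sequences
    n1 <- length(pseudoSequence(target1@residues, iface[[target1@chain]]))
    sc <- 0
    for (part in 1:2) {
      tp <- if (part == 1) targetPseudo[seq_len(n1)]
            else targetPseudo[-seq_len(n1)]
      na1 <- length(pseudoSequence(ra@numbered@residues, iface[[ra@chain]]))
      sp <- if (part == 1) scafPseudo[seq_len(na1)]
            else scafPseudo[-seq_len(na1)]
      shared <- intersect(names(tp), names(sp))
      ok <- tp[shared] %in% rownames(matrix) & sp[shared] %in% rownames(matrix)
      if (any(ok)) sc <- sc + sum(matrix[cbind(tp[shared][ok],
                                               sp[shared][ok])])
    }
    key <- paste(ra@sourceId, rb@sourceId)
    if (is.null(best) || sc > best$score ||
        (sc == best$score && key < best$key))
      best <- list(score = sc, a = ra, b = rb, key = key)
  }
  if (is.null(best))
    fvError("fv_no_scaffold",
            "no packing scaffold pair matches the target chain types")
  fit <- function(fw, scaf) {
    nums <- iface[[fw@chain]]
    res <- fw@numbered@residues
    sres <- scaf@numbered@residues
    shared <- intersect(res$number[res$ins == "" & res$number %in% nums],
                        sres$number[sres$ins == "" & sres$number %in% nums])
    rowsF <- match(shared, res$number)
    rowsS <- match(shared, sres$number)
    xf <- backboneXyz(fw, rowsF); xs <- backboneXyz(scaf, rowsS)
    if (is.null(xf) || is.null(xs) || length(shared) < 3)
      fvError("fv_no_scaffold",
              "interface backbone incomplete for packing superposition")
    sp <- superpose(xf, xs)
    atoms <- fw@atoms
    atoms[, c("x", "y", "z")] <-
      applyTransform(as.matrix(atoms[, c("x", "y", "z")]), sp)
    list(atoms = atoms, rmsd = sp@rmsd)
  }
  f1 <- fit(fw1, best$a); f2 <- fit(fw2, best$b)
  list(atoms1 = f1$atoms, atoms2 = f2$atoms,
       scaffold = c(best$a@sourceId, best$b@sourceId),
       packRmsd = c(f1$rmsd, f2$rmsd))
}

# Atom table (number, ins, aa, region, atom, x, y, z, source, sourceAa) for
# the residues of `record` (with positioned coordinates `atoms`) at rows.
residueAtoms <- function(record, atoms, rows, targetRes = NULL) {
  res <- record@numbered@residues
  out <- list()
  for (i in seq_along(rows)) {
    r <- rows[i]
    a <- atoms[atoms$resIdx == r, , drop = FALSE]
    if (nrow(a) == 0) next
    tgt <- if (is.null(targetRes)) res[r, ] else targetRes[i, ]
    out[[length(out) + 1]] <- data.frame(
      number = tgt$number, ins = tgt$ins, aa = tgt$aa, region = tgt$region,
      atom = a$atom, x = a$x, y = a$y, z = a$z,
      source = record@sourceId, sourceAa = res$aa[r],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Graft a donor loop onto an assembled chain
#'
#' The donor loop is placed by the rigid transform that superposes the
#' backbone atoms (N, CA, C, O) of the two residues before the loop's
#' N-terminus and the two residues after its C-terminus onto the
#' corresponding model anchors; the model's loop residues are replaced by
#' the transformed donor residues, while the anchors themselves remain the
#' framework's.  An anchor RMSD above `sanityBound` produces a "strained
#' graft" warning.
#'
#' @param chainDf partially assembled chain atom table (framework placed).
#' @param donor donor [TemplateRecord-class].
#' @param cdr CDR index 1..3.
#' @param targetRes residue table (number/ins/aa/region) the grafted loop
#'   must adopt (the target's CDR residues).
#' @param sanityBound anchor-RMSD warning threshold in Angstrom.
#' @return list `chain` (updated atom table) and `anchorRmsd`.
#' @export
graftLoop <- function(chainDf, donor, cdr, targetRes, sanityBound = 1.5) {
  cdrName <- CDR_NAMES[cdr]
  dres <- donor@numbered@residues
  dRows <- which(dres$region == cdrName)
  if (length(dRows) == 0)
    fvError("fv_input", sprintf("donor has no %s residues", cdrName))
  dAnchor <- c(min(dRows) - 2L, min(dRows) - 1L,
               max(dRows) + 1L, max(dRows) + 2L)
  if (any(dAnchor < 1) || any(dAnchor > nrow(dres)))
    fvError("fv_input", "donor anchor residues missing")
  dx <- backboneXyz(donor, dAnchor)
  if (is.null(dx)) fvError("fv_input", "donor anchor backbone incomplete")

  # model anchors: the 2 residues at scheme positions before the loop window
  # and the 2 after it (loop window numbers are contiguous)
  keys <- posKey(chainDf$number, chainDf$ins)
  firstAt <- !duplicated(keys)
  resKeys <- keys[firstAt]
  resNums <- chainDf$number[firstAt]
  loopKeys <- posKey(targetRes$number, targetRes$ins)
  before <- resKeys[resNums < min(targetRes$number) & !resKeys %in% loopKeys]
  after <- resKeys[resNums > max(targetRes$number) & !resKeys %in% loopKeys]
  if (length(before) < 2 || length(after) < 2)
    fvError("fv_input", "model anchor residues missing")
  anchorKeys <- c(utils::tail(before, 2), utils::head(after, 2))
  mx <- matrix(NA_real_, 16, 3)
  for (i in seq_along(anchorKeys)) {
    for (k in 1:4) {
      hit <- chainDf[keys == anchorKeys[i] &
                       chainDf$atom == BACKBONE_ATOMS[k], , drop = FALSE]
      if (nrow(hit) == 0)
        fvError("fv_input", "model anchor backbone incomplete")
      mx[(i - 1) * 4 + k, ] <- c(hit$x[1], hit$y[1], hit$z[1])
    }
  }
  sp <- superpose(dx, mx)
  if (sp@rmsd > sanityBound)
    warning(sprintf("strained graft: %s anchor rmsd %.2f A", cdrName,
                    sp@rmsd))
  if (length(dRows) != nrow(targetRes))
    fvError("fv_input", "donor loop length does not match the target loop")
  donorAtoms <- donor@atoms
  donorAtoms[, c("x", "y", "z")] <-
    applyTransform(as.matrix(donorAtoms[, c("x", "y", "z")]), sp)
  loopDf <- residueAtoms(donor, donorAtoms, dRows, targetRes)
  out <- rbind(chainDf[!keys %in% loopKeys, , drop = FALSE], loopDf)
  ordKeys <- order(out$number,
                   match(out$ins, c("", strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ",
                                                 "")[[1]])),
                   method = "radix")
  list(chain = out[ordKeys, , drop = FALSE], anchorRmsd = sp@rmsd)
}

# Assemble one chain: framework residues (and kept loops) from the
# positioned framework record, grafted loops from their donors.
assembleChain <- function(target, fwRecord, fwAtoms, loopSel, db) {
  tres <- target@residues
  fres <- fwRecord@numbered@residues
  fKey <- posKey(fres$number, fres$ins)
  tKey <- posKey(tres$number, tres$ins)

  grafted <- loopSel@choices$cdr[loopSel@choices$mode != "kept_from_framework"]
  fromFw <- !(tres$region %in% grafted)
  rowsT <- which(fromFw)
  rowsF <- match(tKey[rowsT], fKey)
  present <- !is.na(rowsF)
  missing <- tKey[rowsT][!present]
  chainDf <- residueAtoms(fwRecord, fwAtoms, rowsF[present],
                          tres[rowsT[present], , drop = FALSE])
  warnings <- character(0)
  if (length(missing))
    warnings <- sprintf("positions missing in framework template: %s",
                        paste(missing, collapse = ","))
  anchorRmsd <- c(CDR1 = NA_real_, CDR2 = NA_real_, CDR3 = NA_real_)
  for (i in seq_len(nrow(loopSel@choices))) {
    ch <- loopSel@choices[i, ]
    if (ch$mode == "kept_from_framework") next
    donor <- db@records[[ch$templateId]]
    targetLoop <- tres[tres$region == ch$cdr, , drop = FALSE]
    g <- graftLoop(chainDf, donor, match(ch$cdr, CDR_NAMES), targetLoop)
    chainDf <- g$chain
    anchorRmsd[ch$cdr] <- g$anchorRmsd
  }
  list(chain = chainDf, warnings = warnings, anchorRmsd = anchorRmsd)
}

#' Mark residues for side-chain repacking
#'
#' Flags every CDR3 residue and every residue whose target amino acid
#' differs from the source template's; flagged residues lose side-chain
#' atoms beyond CB in the emitted pre-repack file.
#'
#' @param model an [AssembledModel-class].
#' @return the model with `repack` flags set.
#' @export
markRepack <- function(model) {
  model@chains <- lapply(model@chains, function(ch) {
    ch$repack <- ch$region == "CDR3" | ch$aa != ch$sourceAa
    ch
  })
  model
}

# Count atom pairs closer than `cutoff` between the two chains.
countClashes <- function(model, cutoff = 0.5) {
  if (length(model@chains) < 2) return(0L)
  a <- as.matrix(model@chains[[1]][, c("x", "y", "z")])
  b <- as.matrix(model@chains[[2]][, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sum(d2 < cutoff^2)
}

# Strip side-chain atoms beyond CB from repack-flagged residues; CB is kept
# only when the template had one and the target residue is not glycine.
preRepackChains <- function(model) {
  lapply(model@chains, function(ch) {
    keepCB <- ch$atom == "CB" & ch$aa != "G"
    keep <- !ch$repack | ch$atom %in% c("N", "CA", "C", "O") | keepCB
    ch[keep, , drop = FALSE]
  })
}

#' Emit an assembled model to disk
#'
#' Writes the pre-repack PDB (repack-flagged side chains stripped), the
#' JSON and CSV modeling summaries, and -- when an external side-chain
#' repacking hook is configured -- the full repacked, non-minimized model.
#' PDB REMARK records carry the per-region template provenance and the
#' non-minimized status.
#'
#' @param model an [AssembledModel-class].
#' @param dir output directory.
#' @param name file stem (default `"model"`).
#' @param repackHook `NULL`, or a command template containing `{in}` and
#'   `{out}` placeholders for an external repacker.
#' @return named character vector of the files written.
#' @export
emitModel <- function(model, dir, name = "model", repackHook = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenanceTriples(model)
  remarks <- c(
    sprintf("REMARK 300 %s", "FV MODEL (NON-MINIMIZED)"),
    "REMARK 300 MINIMIZED FALSE",
    sprintf("REMARK 300 PROVENANCE %s %s %s",
            prov$chain, prov$region, prov$template))
  files <- c()
  pre <- file.path(dir, paste0(name, "_pre_repack.pdb"))
  writePdbFile(preRepackChains(model), pre, remarks = remarks)
  files["pre_repack"] <- pre

  summaryJson <- file.path(dir, paste0(name, "_summary.json"))
  jsonlite::write_json(modelSummary(model), summaryJson,
                       auto_unbox = TRUE, digits = NA, na = "null")
  files["summary_json"] <- summaryJson
  summaryCsv <- file.path(dir, paste0(name, "_summary.csv"))
  utils::write.csv(prov, summaryCsv, row.names = FALSE)
  files["summary_csv"] <- summaryCsv

  if (!is.null(repackHook)) {
    full <- file.path(dir, paste0(name, ".pdb"))
    cmd <- gsub("{out}", full, gsub("{in}", pre, repackHook, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status == 0 && file.exists(full)) files["model"] <- full
    else warning("repack hook failed; only the pre-repack model was written")
  }
  invisible(files)
}

# Distinct (chain, region, template) provenance triples of a model.
provenanceTriples <- function(model) {
  rows <- lapply(names(model@chains), function(cid) {
    ch <- model@chains[[cid]]
    u <- unique(ch[, c("region", "source")])
    data.frame(chain = cid, region = u$region, template = u$source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$chain, out$region, out$template), , drop = FALSE]
}

# Structured modeling summary (written as JSON; see
# inst/extdata/model_summary.schema.json).
modelSummary <- function(model) {
  m <- model@meta
  list(
    receptor = m$receptor,
    chains = lapply(names(model@chains), function(cid) {
      ch <- model@chains[[cid]]
      resKeys <- !duplicated(posKey(ch$number, ch$ins))
      list(id = cid, chain_type = m$chainTypes[[cid]],
           n_residues = sum(resKeys),
           n_repack = sum(ch$repack[resKeys]))
    }),
    cs_assignments = m$cs,
    framework = list(chain1 = m$framework@chain1Id,
                     chain2 = m$framework@chain2Id,
                     same_crystal = m$framework@sameCrystal,
                     rationale = m$framework@rationale),
    candidates = lapply(m$framework@candidates, function(df) {
      if (is.null(df) || nrow(df) == 0) return(list())
      df <- df[c("templateId", "fullseq", "cdr1", "cdr2", "cdr3",
                 "combined", "identity")]
      for (k in c("cdr1", "cdr2", "cdr3"))  # length-mismatch sentinel
        df[[k]][!is.finite(df[[k]])] <- NA_real_
      df
    }),
    loops = lapply(m$loops, function(ls) {
      lapply(seq_len(nrow(ls@choices)), function(i)
        as.list(ls@choices[i, ]))
    }),
    scores = m$scores,
    pack_scaffold = m$scaffold,
    clashes = m$clashes,
    warnings = m$warnings,
    minimized = FALSE)
}

#' Validate a model summary against the shipped schema
#'
#' Structural validation (required keys and types) of a summary JSON file
#' against `inst/extdata/model_summary.schema.json`.
#'
#' @param path summary JSON file.
#' @return `TRUE` (invisibly) or an error describing the first violation.
#' @export
validateSummary <- function(path) {
  s <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(
    system.file("extdata", "model_summary.schema.json",
                package = "FvModeler"))
  for (key in schema$required) {
    if (!key %in% names(s)) stop(sprintf("summary lacks required key '%s'",
                                         key))
  }
  if (!identical(s$minimized, FALSE)) stop("minimized must be false")
  if (!is.list(s$chains) || length(s$chains) != 2)
    stop("summary must describe exactly two chains")
  for (ch in s$chains) {
    for (key in c("id", "chain_type", "n_residues", "n_repack"))
      if (!key %in% names(ch)) stop(sprintf("chain entry lacks '%s'", key))
  }
  invisible(TRUE)
}
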