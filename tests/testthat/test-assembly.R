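sch <- loadScheme("mini")

test_that("same-crystal packing keeps the crystal coordinates untouched", {
  w <- getWorld()
  id1 <- crystalPairs(w$db)$id1[1]; id2 <- crystalPairs(w$db)$id2[1]
  fw1 <- templates(w$db)[[id1]]; fw2 <- templates(w$db)[[id2]]
  sel <- new("FrameworkSelection", chain1Id = id1, chain2Id = id2,
             sameCrystal = TRUE, rationale = "paired", candidates = list())
  pk <- packChains(fw1, fw2, sel, w$db, w$iface,
                   fw1@numbered, fw2@numbered)
  expect_identical(pk$atoms1, fw1@atoms)
  expect_identical(pk$atoms2, fw2@atoms)
  expect_null(pk$scaffold)
})

test_that("cross-crystal packing picks the best pseudo-sequence scaffold", {
  w <- getWorld()
  pairs <- crystalPairs(w$db)
  fw1 <- templates(w$db)[[pairs$id1[1]]]
  fw2 <- templates(w$db)[[pairs$id2[2]]]   # different crystals
  sel <- new("FrameworkSelection", chain1Id = fw1@sourceId,
             chain2Id = fw2@sourceId, sameCrystal = FALSE,
             rationale = "fallback_per_chain", candidates = list())
  t1 <- fw1@numbered; t2 <- fw2@numbered
  pk <- packChains(fw1, fw2, sel, w$db, w$iface, t1, t2)
  expect_length(pk$scaffold, 2)
  # hand-score every scaffold pair's pseudo-sequence and check the argmax
  B <- blosum62()
  pseudo <- function(res, nums) {
    hit <- res[res$ins == "" & res$number %in% nums, ]
    setNames(hit$aa, hit$number)
  }
  scoreScaffold <- function(ra, rb) {
    tot <- 0
    for (pair in list(list(t1, ra), list(t2, rb))) {
      tp <- pseudo(pair[[1]]@residues, w$iface[[chainType(pair[[1]])]])
      spz <- pseudo(residues(pair[[2]]), w$iface[[chainType(pair[[2]])]])
      shared <- intersect(names(tp), names(spz))
      tot <- tot + sum(B[cbind(tp[shared], spz[shared])])
    }
    tot
  }
  best <- -Inf; bestPair <- NULL
  for (i in seq_len(nrow(pairs))) {
    ra <- templates(w$db)[[pairs$id1[i]]]; rb <- templates(w$db)[[pairs$id2[i]]]
    if (chainType(ra) != chainType(t1)) { tmp <- ra; ra <- rb; rb <- tmp }
    sc <- scoreScaffold(ra, rb)
    if (sc > best) { best <- sc; bestPair <- c(ra@sourceId, rb@sourceId) }
  }
  expect_identical(pk$scaffold, bestPair)
  # each chain's interface backbone RMSD to the scaffold equals superpose()
  expect_true(all(pk$packRmsd >= 0))
})

test_that("self-grafting a framework's own loop is a no-op", {
  w <- getWorld()
  id1 <- crystalPairs(w$db)$id1[1]
  fw <- templates(w$db)[[id1]]
  t1 <- fw@numbered
  loopSel <- new("LoopSelection", choices = data.frame(
    cdr = c("CDR1", "CDR2", "CDR3"), templateId = id1,
    mode = c("kept_from_framework", "kept_from_framework", "cs_matched"),
    score = NA_real_, stringsAsFactors = FALSE))
  a <- FvModeler:::assembleChain(t1, fw, fw@atoms, loopSel, w$db)
  # CDR3 was "grafted" from the framework itself: coordinates unchanged
  ch <- a$chain
  for (i in seq_len(nrow(ch))) {
    res <- residues(fw)
    key <- paste0(res$number, res$ins)
    j <- match(paste0(ch$number[i], ch$ins[i]), key)
    orig <- fw@atoms[fw@atoms$resIdx == j & fw@atoms$atom == ch$atom[i], ]
    expect_equal(c(ch$x[i], ch$y[i], ch$z[i]),
                 c(orig$x[1], orig$y[1], orig$z[1]), tolerance = 1e-9)
  }
  expect_lt(a$anchorRmsd[["CDR3"]], 1e-9)
})

test_that("grafting is rigid and equals the independent anchor superposition", {
  w <- getWorld()
  id1 <- crystalPairs(w$db)$id1[1]
  fw <- templates(w$db)[[id1]]
  donorId <- setdiff(names(which(vapply(templates(w$db), function(r)
    r@chain == "alpha" && r@loopEligible["cdr3"], logical(1)))), id1)[1]
  donor <- templates(w$db)[[donorId]]
  t1 <- fw@numbered
  # donor loop must match the target CDR3 length for a graft
  dLen <- sum(residues(donor)$region == "CDR3")
  tLen <- sum(residues(fw)$region == "CDR3")
  if (dLen != tLen) {
    donors <- Filter(function(r) r@chain == "alpha" &&
                       r@sourceId != id1 && r@loopEligible["cdr3"] &&
                       sum(residues(r)$region == "CDR3") == tLen,
                     templates(w$db))
    donor <- donors[[1]]
  }
  chainDf <- FvModeler:::residueAtoms(fw, fw@atoms,
                                      seq_len(nrow(residues(fw))))
  targetLoop <- t1@residues[t1@residues$region == "CDR3", ]
  g <- suppressWarnings(graftLoop(chainDf, donor, 3L, targetLoop))
  # rigidity: donor-loop internal CA-CA distances preserved exactly
  dres <- residues(donor)
  dRows <- which(dres$region == "CDR3")
  donorCa <- do.call(rbind, lapply(dRows, function(r) {
    a <- donor@atoms[donor@atoms$resIdx == r & donor@atoms$atom == "CA", ]
    c(a$x[1], a$y[1], a$z[1])
  }))
  new <- g$chain[g$chain$region == "CDR3" & g$chain$atom == "CA", ]
  newCa <- as.matrix(new[, c("x", "y", "z")])
  expect_equal(as.numeric(dist(newCa)), as.numeric(dist(donorCa)),
               tolerance = 1e-9)
  # the applied transform equals superpose() on the 16 anchor atoms
  dAnchor <- c(min(dRows) - 2L, min(dRows) - 1L,
               max(dRows) + 1L, max(dRows) + 2L)
  dx <- FvModeler:::backboneXyz(donor, dAnchor)
  fres <- residues(fw)
  fRows <- which(fres$region == "CDR3")
  fAnchor <- c(min(fRows) - 2L, min(fRows) - 1L,
               max(fRows) + 1L, max(fRows) + 2L)
  mx <- FvModeler:::backboneXyz(fw, fAnchor)
  sp <- superpose(dx, mx)
  expect_equal(g$anchorRmsd, sp@rmsd, tolerance = 1e-9)
  moved <- applyTransform(donorCa, sp)
  expect_equal(newCa, moved, tolerance = 1e-9, ignore_attr = TRUE)
  # anchors themselves remain the framework's
  anchorNum <- fres$number[fAnchor]
  for (nm in anchorNum) {
    got <- g$chain[g$chain$number == nm & g$chain$atom == "CA", ]
    j <- which(fres$number == nm & fres$ins == "")
    orig <- fw@atoms[fw@atoms$resIdx == j & fw@atoms$atom == "CA", ]
    expect_equal(c(got$x[1], got$y[1], got$z[1]),
                 c(orig$x[1], orig$y[1], orig$z[1]), tolerance = 1e-12)
  }
})

test_that("repack marking flags CDR3 plus every non-conserved residue", {
  w <- getWorld()
  pairs <- crystalPairs(w$db)
  r1 <- templates(w$db)[[pairs$id1[1]]]; r2 <- templates(w$db)[[pairs$id2[1]]]
  m <- modelReceptor(chainSequence(r1), chainSequence(r2), w$db,
                     w$profiles, w$classes, sch, w$iface)
  # target identical to all templates: only CDR3 residues flagged
  for (ch in m@chains) {
    resFlags <- ch[!duplicated(paste0(ch$number, ch$ins)), ]
    expect_identical(resFlags$repack, resFlags$region == "CDR3")
  }
  # a point mutation adds exactly that residue
  s1 <- chainSequence(r1)
  res1 <- residues(r1)
  pos <- which(res1$region == "FR2")[3]
  mutAa <- setdiff(FvModeler:::AA20, substr(s1, pos, pos))[5]
  s1m <- paste0(substr(s1, 1, pos - 1), mutAa,
                substr(s1, pos + 1, nchar(s1)))
  m2 <- modelReceptor(s1m, chainSequence(r2), w$db, w$profiles, w$classes,
                      sch, w$iface)
  fl1 <- m2@chains[[1]][!duplicated(paste0(m2@chains[[1]]$number,
                                           m2@chains[[1]]$ins)), ]
  extra <- fl1[fl1$repack & fl1$region != "CDR3", ]
  expect_identical(nrow(extra), 1L)
  expect_identical(extra$number, res1$number[pos])
  # flag count equals an independent position-by-position oracle
  for (trial in 1:5) {
    set.seed(trial)
    sM <- s1
    idx <- sample(nchar(s1), 3)
    for (i in idx) {
      sM <- paste0(substr(sM, 1, i - 1),
                   sample(setdiff(FvModeler:::AA20,
                                  substr(sM, i, i)), 1),
                   substr(sM, i + 1, nchar(sM)))
    }
    mt <- modelReceptor(sM, chainSequence(r2), w$db, w$profiles, w$classes,
                        sch, w$iface)
    fl <- mt@chains[[1]][!duplicated(paste0(mt@chains[[1]]$number,
                                            mt@chains[[1]]$ins)), ]
    oracle <- fl$region == "CDR3" | fl$aa != fl$sourceAa
    expect_identical(fl$repack, oracle)
  }
})

test_that("emitted models round-trip and carry provenance remarks", {
  w <- getWorld()
  pairs <- crystalPairs(w$db)
  r1 <- templates(w$db)[[pairs$id1[2]]]; r2 <- templates(w$db)[[pairs$id2[2]]]
  m <- modelReceptor(chainSequence(r1), chainSequence(r2), w$db,
                     w$profiles, w$classes, sch, w$iface)
  out <- tempfile("emit")
  files <- emitModel(m, out)
  expect_true(all(file.exists(files)))
  # summary validates against the shipped schema
  expect_true(validateSummary(files[["summary_json"]]))
  # REMARK provenance lines: one per distinct (chain, region, template)
  lines <- readLines(files[["pre_repack"]])
  provLines <- grep("^REMARK 300 PROVENANCE", lines, value = TRUE)
  triples <- FvModeler:::provenanceTriples(m)
  expect_length(provLines, nrow(triples))
  expect_true(any(grepl("MINIMIZED FALSE", lines)))
  # re-ingestion reproduces numbering and backbone exactly
  recs <- ingestStructure(files[["pre_repack"]], w$profiles, sch)
  expect_length(recs, 2)
  for (rec in recs) {
    cid <- sub(".*_", "", rec@sourceId)
    ch <- m@chains[[cid]]
    bb <- ch[ch$atom %in% c("N", "CA", "C", "O"), ]
    key <- paste0(residues(rec)$number, residues(rec)$ins)
    expect_setequal(unique(paste0(bb$number, bb$ins)), key)
    for (i in sample(nrow(bb), 25)) {
      j <- match(paste0(bb$number[i], bb$ins[i]), key)
      at <- rec@atoms[rec@atoms$resIdx == j & rec@atoms$atom == bb$atom[i], ]
      expect_equal(c(at$x[1], at$y[1], at$z[1]),
                   round(c(bb$x[i], bb$y[i], bb$z[i]), 3))
    }
  }
  # pre-repack strips side chains beyond CB on flagged residues
  preA <- recs[[1]]
  flagged <- m@chains[[1]][m@chains[[1]]$repack, ]
  expect_false(any(flagged$atom %in%
                     setdiff(unique(flagged$atom),
                             c("N", "CA", "C", "O", "CB")) &
                     !flagged$atom %in% c("N", "CA", "C", "O", "CB")))
})

test_that("an interface can be derived from paired templates", {
  w <- getWorld()
  # fixture chains sit ~30 A apart; a generous cutoff must find contacts and
  # the position set must be scheme positions
  iface <- computeInterface(w$db, cutoff = 40, minFrac = 0.5)
  expect_true(all(c("alpha", "beta") %in% names(iface)))
  pos <- schemePositions(sch, "alpha")$number
  expect_true(all(iface$alpha %in% pos))
  expect_gt(length(iface$alpha), 0)
})
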