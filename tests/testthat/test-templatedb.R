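sch <- loadScheme("mini")

test_that("structure ingestion renumbers chains and links crystal partners", {
  w <- getWorld()
  # paired fixture file: two records, mutually partnered
  f <- file.path(w$dir, "F001.pdb")
  recs <- ingestStructure(f, w$profiles, sch, w$classes)
  expect_length(recs, 2)
  types <- sort(unname(vapply(recs, chainType, character(1))))
  expect_identical(types, c("alpha", "beta"))
  expect_identical(recs[[1]]@partnerId, recs[[2]]@sourceId)
  expect_identical(recs[[2]]@partnerId, recs[[1]]@sourceId)
  expect_equal(recs[[1]]@resolution, w$truth$structures$F001$resolution)
  # single-chain fixture: one record, no partner
  singles <- names(which(!vapply(w$truth$structures, function(s) s$paired,
                                 logical(1))))
  recs1 <- ingestStructure(file.path(w$dir, paste0(singles[1], ".pdb")),
                           w$profiles, sch, w$classes)
  expect_length(recs1, 1)
  expect_true(is.na(recs1[[1]]@partnerId))
  # a file with no acceptable chain warns and returns nothing
  junk <- tempfile(fileext = ".pdb")
  ch <- data.frame(number = 1:5, ins = "", aa = "A",
                   atom = "CA", x = (1:5) * 3.8, y = 0.1 * (1:5)^2, z = 0)
  FvModeler:::writePdbFile(list(A = ch), junk)
  expect_warning(out <- ingestStructure(junk, w$profiles, sch),
                 "no acceptable")
  expect_length(out, 0)
})

test_that("a missing CDR backbone atom flags the loop ineligible only", {
  w <- getWorld()
  lines <- readLines(file.path(w$dir, "F001.pdb"))
  # drop the CA of one CDR2 residue of chain A (scheme numbers 27..31)
  hit <- grep("^ATOM.{8} CA .{5}A  29 ", lines)[1]
  expect_false(is.na(hit))
  tmp <- tempfile(fileext = ".pdb")
  writeLines(lines[-hit], tmp)
  recs <- ingestStructure(tmp, w$profiles, sch, w$classes)
  rec <- recs[[which(vapply(recs, chainType, character(1)) == "alpha")]]
  expect_false(rec@loopEligible["cdr2"])
  expect_true(rec@loopEligible["cdr1"])
  expect_true(rec@loopEligible["cdr3"])
  # framework is still usable: the record is present and numbered
  expect_s4_class(rec@numbered, "NumberedChain")
})

test_that("observed CS labels are the nearest exemplar under loop distance", {
  w <- getWorld()
  for (r in templates(w$db)) {
    for (loop in FvModeler:::templateLoops(r)) {
      if (chainType(r) == "beta" && loop@cdr == 3L) next
      cand <- Filter(function(c) c@chain == loop@chain &&
                       c@cdr == loop@cdr &&
                       c@loopLength == nchar(loop@sequence), w$classes)
      if (length(cand) == 0) next
      d <- vapply(cand, function(c) loopDistance(loop, c@exemplar),
                  numeric(1))
      expect_identical(r@csLabels[[paste0("cdr", loop@cdr)]],
                       cand[[which.min(d)]]@classId)
    }
  }
})

test_that("ingested dihedrals match the independent bio3d torsion oracle", {
  w <- getWorld()
  r <- templates(w$db)[[1]]
  res <- residues(r)
  bb <- r@atoms[r@atoms$atom %in% c("N", "CA", "C"), ]
  bb <- bb[order(bb$resIdx, match(bb$atom, c("N", "CA", "C"))), ]
  xyz <- as.numeric(t(as.matrix(bb[, c("x", "y", "z")])))
  tor <- bio3d::torsion.xyz(xyz, atm.inc = 1) * pi / 180
  n <- nrow(res)
  # torsion.xyz emits one angle per atom (leading NA): with N/CA/C atom
  # triples, psi(i) sits at index 3i-1 and phi(i) at index 3i-2
  phiOracle <- c(NA, vapply(2:n, function(i) tor[3 * i - 2], numeric(1)))
  psiOracle <- c(vapply(seq_len(n - 1), function(i) tor[3 * i - 1],
                        numeric(1)), NA)
  expect_equal(FvModeler:::wrapAngle(r@phi[-1] - phiOracle[-1]),
               rep(0, n - 1), tolerance = 1e-6)
  expect_equal(FvModeler:::wrapAngle(r@psi[-n] - psiOracle[-n]),
               rep(0, n - 1), tolerance = 1e-6)
})

test_that("redundancy culling keeps pairs with one non-redundant chain", {
  w <- getWorld()
  recs <- templates(w$db)
  # byte-identical duplicate of a single chain: threshold 100 keeps one
  single <- recs[[which(vapply(recs, function(r) is.na(r@partnerId),
                               logical(1)))[1]]]
  dup <- single
  dup@sourceId <- "ZZZZ_A"
  dup@structId <- "ZZZZ"
  two <- list(single, dup)
  names(two) <- c(single@sourceId, "ZZZZ_A")
  culled <- cullRedundancy(two, threshold = 100, schemeId = sch@id)
  expect_length(templates(culled), 1)
  # pair (A1,B1): A1 redundant with A2 but B1 unique -> both A1,B1 retained
  pairRec <- recs[[w$db@pairs$id1[1]]]
  partner <- recs[[w$db@pairs$id2[1]]]
  cloneA <- pairRec
  cloneA@sourceId <- "COPY_A"; cloneA@structId <- "COPY"
  cloneA@partnerId <- NA_character_
  cloneA@resolution <- pairRec@resolution - 0.5  # visited first
  three <- list(cloneA, pairRec, partner)
  names(three) <- vapply(three, function(r) r@sourceId, character(1))
  culled2 <- cullRedundancy(three, threshold = 95, schemeId = sch@id)
  expect_true(all(c(pairRec@sourceId, partner@sourceId) %in%
                    names(templates(culled2))))
  expect_identical(nrow(crystalPairs(culled2)), 1L)
  # greedy culling equals an independent all-pairs oracle on 10 chains
  ten <- recs[seq_len(10)]
  thr <- 70
  idPct <- function(a, b) FvModeler:::seqIdentityPct(residues(a), residues(b))
  ord <- order(vapply(ten, function(r) r@resolution, numeric(1)),
               names(ten), method = "radix")
  keptOracle <- character(0)
  for (i in ord) {
    ok <- all(vapply(keptOracle, function(k) {
      ten[[k]]@chain != ten[[i]]@chain || idPct(ten[[k]], ten[[i]]) < thr
    }, logical(1)))
    if (ok) keptOracle <- c(keptOracle, names(ten)[i])
  }
  partners <- vapply(ten[keptOracle], function(r) r@partnerId, character(1))
  keptOracle <- union(keptOracle,
                      intersect(partners[!is.na(partners)], names(ten)))
  culled3 <- cullRedundancy(ten, threshold = thr, schemeId = sch@id)
  expect_setequal(names(templates(culled3)), keptOracle)
})

test_that("blacklisting hides records case-insensitively", {
  w <- getWorld()
  expect_identical(names(templates(excludeTemplates(w$db, character(0)))),
                   names(templates(w$db)))
  bl <- excludeTemplates(w$db, "f001")
  expect_false(any(grepl("^F001", names(templates(bl)))))
  expect_false(any(crystalPairs(bl)$id1 == "F001_A"))
  expect_warning(excludeTemplates(w$db, "9XYZ"), "not in database")
})

test_that("the leave-one-out similarity filter hides near-identical templates", {
  w <- getWorld()
  r <- templates(w$db)[[w$db@pairs$id1[1]]]
  filtered <- excludeSimilarTemplates(w$db, list(r@numbered), 90)
  expect_false(r@sourceId %in% names(templates(filtered)))
  # the partner survives but its pair entry is gone
  partner <- r@partnerId
  expect_true(partner %in% names(templates(filtered)))
  expect_false(any(crystalPairs(filtered)$id1 == r@sourceId |
                     crystalPairs(filtered)$id2 == r@sourceId))
})

test_that("a database round-trips losslessly through its directory format", {
  w <- getWorld()
  dir <- tempfile("dbdir")
  writeTemplateDatabase(w$db, dir)
  expect_true(file.exists(file.path(dir, "records.json")))
  back <- loadTemplateDatabase(dir, sch)
  expect_identical(sort(names(templates(back))),
                   sort(names(templates(w$db))))
  for (id in names(templates(w$db))) {
    a <- templates(w$db)[[id]]; b <- templates(back)[[id]]
    expect_identical(residues(b)[c("number", "ins", "aa", "region")],
                     residues(a)[c("number", "ins", "aa", "region")])
    expect_equal(b@phi, a@phi, tolerance = 1e-9)
    expect_identical(b@csLabels, a@csLabels)
    expect_identical(b@loopEligible, a@loopEligible)
    expect_identical(b@partnerId, a@partnerId)
    expect_equal(b@resolution, a@resolution)
    # coordinates: PDB precision is 3 decimals and fixtures are written at
    # that precision, so the round trip is exact
    ka <- paste(a@atoms$resIdx, a@atoms$atom)
    kb <- paste(b@atoms$resIdx, b@atoms$atom)
    expect_setequal(kb, ka)
    m <- match(ka, kb)
    expect_equal(b@atoms$x[m], a@atoms$x)
    expect_equal(b@atoms$y[m], a@atoms$y)
    expect_equal(b@atoms$z[m], a@atoms$z)
  }
  expect_identical(nrow(crystalPairs(back)), nrow(crystalPairs(w$db)))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       9.999   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), tmp)
  at <- FvModeler:::readPdbAtoms(tmp)
  ca <- at[at$elety == "CA", ]
  expect_identical(nrow(ca), 1L)
  expect_equal(ca$x, 9.999)
})
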