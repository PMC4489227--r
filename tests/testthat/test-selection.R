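sch <- loadScheme("mini")

targetOf <- function(w, id) {
  r <- templates(w$db)[[id]]
  list(numbered = r@numbered, cs = assignCS(r@numbered, w$classes),
       record = r)
}

test_that("the five template scores follow their definitions", {
  w <- getWorld()
  t1 <- targetOf(w, "F001_A")
  B <- blosum62()
  # template == target: fullseq is the diagonal sum, identity 100, and all
  # three CDR canonical structures trivially match
  s <- scoreTemplate(t1$numbered, t1$cs, t1$record)
  diagSum <- sum(B[cbind(residues(t1$record)$aa, residues(t1$record)$aa)])
  expect_equal(s@fullseq, diagSum)
  expect_equal(s@identity, 100)
  expect_true(all(s@csMatch))
  expect_equal(s@combined, s@fullseq + sum(s@cdr))
  # hand-aligned toy pair: fullseq equals a hand-summed oracle
  other <- templates(w$db)[["F002_A"]]
  s2 <- scoreTemplate(t1$numbered, t1$cs, other)
  o <- oracleScore(t1$numbered, t1$cs, other)
  expect_equal(s2@fullseq, o$fullseq)
  expect_equal(s2@identity, o$identity)
  expect_equal(s2@cdr, o$cdr)
  expect_equal(s2@combined, o$combined)
  # chain-type mismatch refuses
  expect_error(scoreTemplate(t1$numbered, t1$cs,
                             templates(w$db)[["F001_B"]]),
               class = "fv_input")
})

test_that("a CDR length mismatch yields the -Inf sentinel, excluded from combined", {
  w <- getWorld()
  t1 <- targetOf(w, "F001_A")
  tpl <- templates(w$db)[["F002_A"]]
  # shrink the template's CDR2 by dropping its first loop residue
  res <- residues(tpl)
  drop <- which(res$region == "CDR2")[1]
  tpl@numbered@residues <- res[-drop, ]
  tpl@phi <- tpl@phi[-drop]; tpl@psi <- tpl@psi[-drop]
  tpl@atoms <- tpl@atoms[tpl@atoms$resIdx != drop, ]
  tpl@atoms$resIdx <- ifelse(tpl@atoms$resIdx > drop,
                             tpl@atoms$resIdx - 1L, tpl@atoms$resIdx)
  s <- scoreTemplate(t1$numbered, t1$cs, tpl)
  expect_identical(s@cdr[2], -Inf)
  expect_false(s@csMatch[2] && is.finite(s@cdr[2]))
  expect_equal(s@combined,
               s@fullseq + sum(s@cdr[s@csMatch & is.finite(s@cdr)]))
})

test_that("combined score additivity holds on every fixture scoring event", {
  w <- getWorld()
  for (id in names(templates(w$db))[1:6]) {
    t1 <- targetOf(w, id)
    for (tpl in templates(w$db)) {
      if (chainType(tpl) != chainType(t1$numbered)) next
      s <- scoreTemplate(t1$numbered, t1$cs, tpl)
      expect_equal(s@combined - s@fullseq,
                   sum(s@cdr[s@csMatch & is.finite(s@cdr)]))
    }
  }
})

test_that("the 60% identity gate is sharp", {
  w <- getWorld()
  t1 <- targetOf(w, "F001_A"); t2 <- targetOf(w, "F001_B")
  dbv <- excludeTemplates(w$db, "F001")
  tres <- residues(t1$numbered)
  tkey <- paste0(tres$number, tres$ins)
  # rewrite F002_A's sequence to hit an exact match count against the target
  setMatches <- function(tpl, nMatches) {
    res <- residues(tpl)
    key <- paste0(res$number, res$ins)
    shared <- intersect(key, tkey)
    for (i in seq_along(shared)) {
      j <- match(shared[i], key)
      taa <- tres$aa[match(shared[i], tkey)]
      res$aa[j] <- if (i <= nMatches) taa
                   else setdiff(FvModeler:::AA20, taa)[1]
    }
    tpl@numbered@residues <- res
    tpl
  }
  n <- length(intersect(paste0(residues(templates(dbv)[["F002_A"]])$number,
                               residues(templates(dbv)[["F002_A"]])$ins),
                        tkey))
  gate <- ceiling(0.6 * n)
  swap <- function(tpl) {
    recs <- templates(dbv)
    recs[["F002_A"]] <- tpl
    templateDatabase(recs, schemeId = sch@id)
  }
  below <- setMatches(templates(dbv)[["F002_A"]], gate - 1)
  at <- setMatches(templates(dbv)[["F002_A"]], gate)
  expect_lt(scoreTemplate(t1$numbered, t1$cs, below)@identity, 60)
  expect_gte(scoreTemplate(t1$numbered, t1$cs, at)@identity, 60)
  fsBelow <- suppressWarnings(
    selectFramework(t1$numbered, t2$numbered, t1$cs, t2$cs, swap(below)))
  fsAt <- suppressWarnings(
    selectFramework(t1$numbered, t2$numbered, t1$cs, t2$cs, swap(at)))
  expect_false("F002_A" %in% fsBelow@candidates[[1]]$templateId)
  expect_true("F002_A" %in% fsAt@candidates[[1]]$templateId)
})

test_that("framework selection equals exhaustive enumeration of the stated rule", {
  for (seed in 1:5) {
    w <- getWorld(seed = seed)
    q <- makeQueryPair(seed)
    n1 <- alignAndNumber(q[[1]], w$profiles[["alpha"]], sch)
    n2 <- alignAndNumber(q[[2]], w$profiles[["beta"]], sch)
    cs1 <- assignCS(n1, w$classes); cs2 <- assignCS(n2, w$classes)
    got <- suppressWarnings(
      selectFramework(n1, n2, cs1, cs2, w$db))
    want <- oracleSelectFramework(n1, n2, cs1, cs2, w$db)
    expect_identical(got@chain1Id, want$id1)
    expect_identical(got@chain2Id, want$id2)
    expect_identical(got@rationale, want$rationale)
    # and repeated calls are bit-identical (pure function)
    again <- suppressWarnings(selectFramework(n1, n2, cs1, cs2, w$db))
    expect_identical(got, again)
  }
})

test_that("the same-crystal pair wins even against higher per-chain identity", {
  w <- getWorld()
  t1 <- targetOf(w, "F001_A"); t2 <- targetOf(w, "F001_B")
  # hide F001 itself; among the rest the chosen pair must share a crystal,
  # while the per-chain identity argmax combination does not
  dbv <- excludeTemplates(w$db, "F001")
  fs <- selectFramework(t1$numbered, t2$numbered, t1$cs, t2$cs, dbv)
  expect_true(fs@sameCrystal)
  expect_identical(fs@rationale, "paired")
  r1 <- templates(dbv)[[fs@chain1Id]]
  expect_identical(r1@partnerId, fs@chain2Id)
  best1 <- fs@candidates[[1]]$templateId[which.max(fs@candidates[[1]]$identity)]
  best2 <- fs@candidates[[2]]$templateId[which.max(fs@candidates[[2]]$identity)]
  mixedBetter <-
    (max(fs@candidates[[1]]$identity) + max(fs@candidates[[2]]$identity)) / 2
  r1id <- fs@candidates[[1]]$identity[fs@candidates[[1]]$templateId ==
                                        fs@chain1Id]
  r2id <- fs@candidates[[2]]$identity[fs@candidates[[2]]$templateId ==
                                        fs@chain2Id]
  # the mixed-crystal combination has at least the chosen pair's identity,
  # yet the same-crystal pair is selected
  expect_gte(mixedBetter, (r1id + r2id) / 2)
})

test_that("without a shared crystal the fallback maximizes the CDR score sum", {
  w <- getWorld()
  t1 <- targetOf(w, "F001_A"); t2 <- targetOf(w, "F001_B")
  # keep only unpaired records
  singles <- Filter(function(r) is.na(r@partnerId), templates(w$db))
  dbs <- templateDatabase(singles, schemeId = sch@id)
  fs <- selectFramework(t1$numbered, t2$numbered, t1$cs, t2$cs, dbs)
  expect_identical(fs@rationale, "fallback_per_chain")
  want <- oracleSelectFramework(t1$numbered, t2$numbered, t1$cs, t2$cs, dbs)
  expect_identical(fs@chain1Id, want$id1)
  expect_identical(fs@chain2Id, want$id2)
})

test_that("loop selection follows CS-match-then-score with the beta-CDR3 length rule", {
  for (seed in c(5, 2)) {
    w <- getWorld(seed = seed)
    for (pairRow in seq_len(min(2, nrow(crystalPairs(w$db))))) {
      id1 <- crystalPairs(w$db)$id1[pairRow]
      t1 <- targetOf(w, id1)
      fw <- templates(w$db)[[id1]]
      got <- selectLoops(t1$numbered, t1$cs, fw, w$db)
      want <- oracleSelectLoops(t1$numbered, t1$cs, fw, w$db)
      for (k in 1:3) {
        rg <- paste0("CDR", k)
        expect_identical(got@choices$templateId[got@choices$cdr == rg],
                         want[[rg]]$id)
        expect_identical(got@choices$mode[got@choices$cdr == rg],
                         want[[rg]]$mode)
      }
    }
    # framework CS matches everywhere -> all loops kept (self as framework)
    id1 <- crystalPairs(w$db)$id1[1]
    t1 <- targetOf(w, id1)
    got <- selectLoops(t1$numbered, t1$cs, templates(w$db)[[id1]], w$db)
    expect_true(all(got@choices$mode[got@choices$cdr != "CDR3" |
                                       chainType(t1$numbered) != "beta"] ==
                      "kept_from_framework"))
    # beta chains: CDR3 is always length-matched
    idb <- crystalPairs(w$db)$id2[1]
    tb <- targetOf(w, idb)
    gotb <- selectLoops(tb$numbered, tb$cs, templates(w$db)[[idb]], w$db)
    expect_identical(gotb@choices$mode[gotb@choices$cdr == "CDR3"],
                     "length_matched")
  }
})

test_that("a CS mismatch picks the best-scoring donor, ties broken deterministically", {
  w <- getWorld()
  id1 <- crystalPairs(w$db)$id1[1]
  t1 <- targetOf(w, id1)
  fw <- templates(w$db)[[id1]]
  # force a CDR1 mismatch on the framework
  other <- setdiff(unique(vapply(w$classes, function(c) c@classId,
                                 character(1))), fw@csLabels["cdr1"])
  fw@csLabels["cdr1"] <- other[1]
  got <- selectLoops(t1$numbered, t1$cs, fw, w$db)
  ch1 <- got@choices[got@choices$cdr == "CDR1", ]
  expect_identical(ch1$mode, "cs_matched")
  want <- oracleSelectLoops(t1$numbered, t1$cs, fw, w$db)
  expect_identical(ch1$templateId, want$CDR1$id)
  # no loop of the required length anywhere -> hard error naming the CDR
  t1mod <- t1$numbered
  res <- t1mod@residues
  keep <- res$region != "CDR2"
  res2 <- rbind(res[keep, ],
                transform(res[res$region == "CDR2", ][1:2, ],
                          number = c(30, 31), ins = ""))
  t1mod@residues <- res2[order(res2$number,
                               match(res2$ins, c("", LETTERS))), ]
  cs <- t1$cs; cs$cdr2 <- list(class = NA_character_, score = NA_real_)
  expect_error(selectLoops(t1mod, cs, fw, w$db),
               regexp = "CDR2", class = "fv_no_loop_template")
})
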