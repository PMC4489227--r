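# Shared fixtures and independent oracles for the test suite.  Fixture
# worlds are pure functions of their seed and are cached per session.

.worldCache <- new.env(parent = emptyenv())

getWorld <- function(seed = 5, nTemplates = 12, ...) {
  key <- paste0("w", seed, "n", nTemplates)
  if (is.null(.worldCache[[key]])) {
    .worldCache[[key]] <- buildFixtureWorld(
      fixtureSpec(seed = seed, nTemplates = nTemplates, ...))
  }
  .worldCache[[key]]
}

miniScheme <- function() {
  if (is.null(.worldCache$scheme)) .worldCache$scheme <- loadScheme("mini")
  .worldCache$scheme
}

# Random dihedral loops around shifted centroids (generating labels kept).
makeLoopSet <- function(k, n = 40, len = 6, kappa = 50, seed = 3,
                        delta = 2.2, chain = "alpha", cdr = 1L) {
  set.seed(seed)
  base <- list(phi = runif(len, -pi, pi), psi = runif(len, -pi, pi))
  lab <- sample(rep(seq_len(k), length.out = n))
  alph <- list(c("A", "D", "E", "F", "H", "I"),
               c("K", "L", "M", "N", "P", "Q"),
               c("R", "S", "T", "V", "W", "Y"))
  loops <- lapply(seq_len(n), function(i) {
    mu_phi <- FvModeler:::wrapAngle(base$phi + (lab[i] - 1) * delta)
    mu_psi <- FvModeler:::wrapAngle(base$psi + (lab[i] - 1) * delta)
    new("DihedralLoop", chain = chain, cdr = cdr,
        sequence = paste(sample(alph[[(lab[i] - 1) %% 3 + 1]], len,
                                replace = TRUE), collapse = ""),
        phi = vapply(mu_phi, function(m) FvModeler:::rvonmises(1, m, kappa),
                     numeric(1)),
        psi = vapply(mu_psi, function(m) FvModeler:::rvonmises(1, m, kappa),
                     numeric(1)),
        source = sprintf("S%03d", i))
  })
  list(loops = loops, labels = lab)
}

# Cluster membership labels aligned to loop indices S001..Snnn.
classMembership <- function(classes, n) {
  memb <- rep(NA_integer_, n)
  for (ci in seq_along(classes)) {
    for (m in classes[[ci]]@members)
      memb[as.integer(substr(m, 2, 4))] <- ci
  }
  memb
}

# Adjusted Rand index (independent of the clustering code path).
ariIndex <- function(a, b) mclust::adjustedRandIndex(a, b)

# --- independent superposition oracle: Horn's closed-form quaternion fit ---
quatSuperpose <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  M <- t(mc) %*% rc
  N <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
    M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3],
    M[1, 2] + M[2, 1], M[3, 1] + M[1, 3],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1],
    -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[3, 1] + M[1, 3],
    M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x),
    w^2 - x^2 - y^2 + z^2), 3, 3, byrow = TRUE)
  fitted <- mc %*% t(R)
  list(rmsd = sqrt(mean(rowSums((fitted - rc)^2))), rotation = t(R))
}

# --- independent template scoring + framework selection oracle ------------
oracleScore <- function(target, targetCS, template, B = blosum62()) {
  tr <- residues(target)
  mr <- residues(template)
  kT <- paste0(tr$number, tr$ins); kM <- paste0(mr$number, mr$ins)
  shared <- intersect(kT, kM)
  aaT <- tr$aa[match(shared, kT)]; aaM <- mr$aa[match(shared, kM)]
  fullseq <- sum(vapply(seq_along(shared),
                        function(i) B[aaT[i], aaM[i]], numeric(1)))
  identity <- 100 * mean(aaT == aaM)
  cdr <- rep(-Inf, 3); match_cs <- rep(FALSE, 3)
  for (k in 1:3) {
    rg <- paste0("CDR", k)
    sT <- tr$aa[tr$region == rg]; sM <- mr$aa[mr$region == rg]
    if (length(sT) == length(sM) && length(sT) > 0)
      cdr[k] <- sum(vapply(seq_along(sT),
                           function(i) B[sT[i], sM[i]], numeric(1)))
    tcs <- targetCS[[paste0("cdr", k)]]$class
    mcs <- template@csLabels[[paste0("cdr", k)]]
    match_cs[k] <- !is.na(tcs) && !is.na(mcs) && tcs == mcs
  }
  list(fullseq = fullseq,
       cdr = cdr,
       combined = fullseq + sum(cdr[match_cs & is.finite(cdr)]),
       identity = identity,
       match_cs = match_cs)
}

# Exhaustive enumeration of the framework-selection rule: top-20 combined
# among identity >= 60 per chain; same-crystal pair maximizing mean
# identity; per-chain fallback maximizing the sum of defined CDR scores.
oracleSelectFramework <- function(t1, t2, cs1, cs2, db,
                                  topN = 20, minId = 60) {
  tieRank <- function(primary, combined, resol, id) {
    resol[is.na(resol)] <- Inf
    order(-primary, -combined, resol, id, method = "radix")
  }
  scoreChain <- function(target, cs) {
    recs <- Filter(function(r) r@chain == chainType(target), db@records)
    rows <- lapply(recs, function(r) {
      s <- oracleScore(target, cs, r)
      data.frame(id = r@sourceId, combined = s$combined,
                 identity = s$identity,
                 cdrsum = sum(s$cdr[is.finite(s$cdr)]),
                 resol = r@resolution,
                 partner = r@partnerId, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  s1 <- scoreChain(t1, cs1); s2 <- scoreChain(t2, cs2)
  cand <- function(s) {
    p <- s[s$identity >= minId, , drop = FALSE]
    p[tieRank(p$combined, p$combined, p$resol, p$id)[
      seq_len(min(topN, nrow(p)))], , drop = FALSE]
  }
  c1 <- cand(s1); c2 <- cand(s2)
  best <- NULL
  for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
    if (is.na(c1$partner[i]) || c1$partner[i] != c2$id[j]) next
    cand_pair <- list(id1 = c1$id[i], id2 = c2$id[j],
                      meanId = (c1$identity[i] + c2$identity[j]) / 2,
                      comb = c1$combined[i] + c2$combined[j],
                      resol = c1$resol[i])
    r_new <- ifelse(is.na(cand_pair$resol), Inf, cand_pair$resol)
    r_old <- if (is.null(best)) Inf else ifelse(is.na(best$resol), Inf,
                                                best$resol)
    if (is.null(best) || cand_pair$meanId > best$meanId ||
        (cand_pair$meanId == best$meanId && cand_pair$comb > best$comb) ||
        (cand_pair$meanId == best$meanId && cand_pair$comb == best$comb &&
           r_new < r_old) ||
        (cand_pair$meanId == best$meanId && cand_pair$comb == best$comb &&
           r_new == r_old && cand_pair$id1 < best$id1))
      best <- cand_pair
  }
  if (!is.null(best))
    return(list(id1 = best$id1, id2 = best$id2, rationale = "paired"))
  pick <- function(s) {
    unname(s$id[tieRank(s$cdrsum, s$combined, s$resol, s$id)[1]])
  }
  list(id1 = pick(s1), id2 = pick(s2), rationale = "fallback_per_chain")
}

# Exhaustive per-CDR loop selection oracle.
oracleSelectLoops <- function(target, targetCS, fw, db, B = blosum62()) {
  tr <- residues(target)
  recs <- Filter(function(r) r@chain == chainType(target), db@records)
  out <- list()
  for (k in 1:3) {
    rg <- paste0("CDR", k)
    tLen <- sum(tr$region == rg)
    tcs <- targetCS[[paste0("cdr", k)]]$class
    fcs <- fw@csLabels[[paste0("cdr", k)]]
    lenRule <- chainType(target) == "beta" && k == 3
    if (!lenRule && !is.na(tcs) && !is.na(fcs) && tcs == fcs) {
      out[[rg]] <- list(id = fw@sourceId, mode = "kept_from_framework")
      next
    }
    score1 <- function(r) {
      sM <- residues(r)$aa[residues(r)$region == rg]
      sT <- tr$aa[tr$region == rg]
      if (length(sM) != tLen) return(-Inf)
      sum(vapply(seq_len(tLen), function(i) B[sT[i], sM[i]], numeric(1)))
    }
    bestOf <- function(pool, mode) {
      if (length(pool) == 0) return(NULL)
      sc <- vapply(pool, score1, numeric(1))
      ids <- vapply(pool, function(r) r@sourceId, character(1))
      resol <- vapply(pool, function(r) r@resolution, numeric(1))
      keep <- is.finite(sc)
      if (!any(keep)) return(NULL)
      sc <- sc[keep]; ids <- ids[keep]; resol <- resol[keep]
      resol[is.na(resol)] <- Inf
      ord <- order(-sc, -sc, resol, ids, method = "radix")
      list(id = unname(ids[ord[1]]), mode = mode)
    }
    elig <- Filter(function(r) r@loopEligible[k], recs)
    hit <- NULL
    if (!lenRule && !is.na(tcs)) {
      pool <- Filter(function(r)
        !is.na(r@csLabels[k]) && r@csLabels[k] == tcs, elig)
      hit <- bestOf(pool, "cs_matched")
    }
    if (is.null(hit)) {
      pool <- Filter(function(r)
        sum(residues(r)$region == rg) == tLen, elig)
      hit <- bestOf(pool, "length_matched")
    }
    out[[rg]] <- hit
  }
  out
}

# Synthetic query pair (not in any database), drawn from the fixture chain
# model under a fixed seed.
makeQueryPair <- function(seed, scheme = miniScheme(),
                          chains = c("alpha", "beta")) {
  spec <- fixtureSpec(seed = seed)
  FvModeler:::withSeed(seed * 1000 + 7, {
    lapply(chains, function(ch) {
      sc <- FvModeler:::synthChain(ch, scheme, spec)
      paste(sc$residues$aa, collapse = "")
    })
  })
}
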