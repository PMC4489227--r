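## Fully synthetic fixtures: numbered chains with framework + CDR regions,
## paired crystal structures with a known relative orientation, and CDR
## loops drawn from known dihedral centroids.  Everything is a pure function
## of the FixtureSpec seed, and a truth file records every generating label.

# Residue alphabets: glycine is excluded so every fixture residue carries a
# CB stub; the three disjoint 6-letter groups give each canonical-structure
# centroid a distinguishable sequence signature.
FIXTURE_AA <- setdiff(AA20, c("G", "C"))
CENTROID_ALPHABETS <- list(c("A", "D", "E", "F", "H", "I"),
                           c("K", "L", "M", "N", "P", "Q"),
                           c("R", "S", "T", "V", "W", "Y"))

#' Construct a fixture specification
#'
#' Defaults describe the standard synthetic study conditions: a TCR
#' (alpha + beta) template set with two dihedral centroids per CDR, von
#' Mises noise of concentration 50 about them, 5\% framework mutations and
#' half the structures paired.
#'
#' @param seed master seed.
#' @param nTemplates number of structures.
#' @param chainTypes the receptor pairing to generate.
#' @param loopLengths named list per CDR of `c(min, max)` lengths.
#' @param nCentroids integer length 3, centroids per CDR.
#' @param kappa von Mises concentration of the dihedral noise.
#' @param mutationRate framework point-mutation rate.
#' @param fractionPaired fraction of structures emitted as crystal pairs.
#' @return A [FixtureSpec-class].
#' @export
fixtureSpec <- function(seed = 1, nTemplates = 12,
                        chainTypes = c("alpha", "beta"),
                        loopLengths = list(CDR1 = c(6, 6), CDR2 = c(5, 5),
                                           CDR3 = c(6, 6)),
                        nCentroids = c(2, 2, 2), kappa = 50,
                        mutationRate = 0.05, fractionPaired = 0.5) {
  new("FixtureSpec", seed = as.integer(seed),
      nTemplates = as.integer(nTemplates), chainTypes = chainTypes,
      loopLengths = loopLengths, nCentroids = as.integer(nCentroids),
      kappa = kappa, mutationRate = mutationRate,
      fractionPaired = fractionPaired)
}

# Master framework of a chain type: per-position phi/psi (a perturbed
# beta-strand basin) and a master sequence.  Fixed per chain type,
# independent of the FixtureSpec seed, so profiles and templates agree.
masterFramework <- function(chain, scheme) {
  pos <- schemePositions(scheme, chain)
  n <- nrow(pos)
  withSeed(7000 + match(chain, CHAIN_TYPES), {
    list(pos = pos,
         phi = wrapAngle(-2.1 + stats::runif(n, -0.15, 0.15)),
         psi = wrapAngle(2.27 + stats::runif(n, -0.15, 0.15)),
         seq = sample(FIXTURE_AA, n, replace = TRUE))
  })
}

# Dihedral centroid k for a chain/CDR/length group: a fixed base curve plus
# a 2.2 rad offset per centroid index (well separated under the loop
# metric).
centroidAngles <- function(chain, cdr, len, k) {
  base <- withSeed(8000 + 97 * match(chain, CHAIN_TYPES) + 13 * cdr + len, {
    list(phi = stats::runif(len, -pi, pi), psi = stats::runif(len, -pi, pi))
  })
  list(phi = wrapAngle(base$phi + (k - 1) * 2.2),
       psi = wrapAngle(base$psi + (k - 1) * 2.2))
}

# Master full-length sequence of a chain type at the scheme's default
# (window-width) CDR lengths; rows of the profile MSAs derive from it.
masterChainSequence <- function(chain, scheme) {
  mf <- masterFramework(chain, scheme)
  mf$seq
}

#' Build the fixture chain profiles
#'
#' One profile per chain type from a synthetic MSA: the chain's master
#' sequence mutated independently per row, with the hypervariable CDR
#' columns left as gaps.  The occupancy rule therefore drops the CDR
#' columns, giving framework-only profiles that treat loops as unscored
#' insertions: chain identification and framework anchoring are driven by
#' the conserved scaffold, never by the synthetic loop composition.
#'
#' @param scheme the [NumberingScheme-class] (normally the mini scheme).
#' @param chains chain types to build.
#' @param nSeqs rows per MSA.
#' @param mutationRate per-position mutation rate of the MSA rows.
#' @param seed RNG seed.
#' @return named list of [ChainProfile-class] objects.
#' @export
makeFixtureProfiles <- function(scheme, chains = CHAIN_TYPES, nSeqs = 8,
                                mutationRate = 0.08, seed = 101) {
  out <- lapply(chains, function(ch) {
    mf <- masterFramework(ch, scheme)
    isCdr <- mf$pos$region %in% CDR_NAMES
    msa <- withSeed(seed + match(ch, CHAIN_TYPES), {
      t(vapply(seq_len(nSeqs), function(i) {
        s <- mf$seq
        hit <- stats::runif(length(s)) < mutationRate
        s[hit] <- sample(FIXTURE_AA, sum(hit), replace = TRUE)
        s[isCdr] <- "-"
        s
      }, character(nrow(mf$pos))))
    })
    buildProfile(msa, mf$pos$number, ch, scheme)
  })
  stats::setNames(out, chains)
}

# One synthetic chain: residue table (number/ins/aa/region), phi/psi, and
# the generating labels.  CDR loops are sampled from their centroid with von
# Mises noise; the framework keeps the master backbone exactly.
synthChain <- function(chain, scheme, spec) {
  mf <- masterFramework(chain, scheme)
  windows <- cdrWindows(scheme, chain)
  resRows <- list(); truth <- list(centroids = c(NA, NA, NA),
                                   lengths = c(NA, NA, NA),
                                   mutations = integer(0))
  frMask <- mf$pos$region %in% FR_NAMES
  # framework mutations
  aa <- mf$seq
  mut <- which(stats::runif(nrow(mf$pos)) < spec@mutationRate & frMask)
  for (i in mut) aa[i] <- sample(setdiff(FIXTURE_AA, aa[i]), 1)
  truth$mutations <- mf$pos$number[mut]

  segments <- list()
  for (rg in c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")) {
    if (rg %in% FR_NAMES) {
      rows <- which(mf$pos$region == rg)
      segments[[rg]] <- data.frame(
        number = mf$pos$number[rows], ins = "", aa = aa[rows], region = rg,
        phi = mf$phi[rows], psi = mf$psi[rows], stringsAsFactors = FALSE)
    } else {
      k <- match(rg, CDR_NAMES)
      rng <- spec@loopLengths[[rg]]
      len <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
      cen <- sample.int(spec@nCentroids[k], 1)
      truth$centroids[k] <- cen
      truth$lengths[k] <- len
      ca <- centroidAngles(chain, k, len, cen)
      alph <- CENTROID_ALPHABETS[[(cen - 1) %% 3 + 1]]
      ren <- cdrRenumber(len, windows[[rg]]$numbers, windows[[rg]]$reentry,
                         scheme@insertionOrder)
      segments[[rg]] <- data.frame(
        number = ren$number, ins = ren$ins,
        aa = sample(alph, len, replace = TRUE), region = rg,
        phi = vapply(seq_len(len), function(i)
          rvonmises(1, ca$phi[i], spec@kappa), numeric(1)),
        psi = vapply(seq_len(len), function(i)
          rvonmises(1, ca$psi[i], spec@kappa), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segments)
  rownames(out) <- NULL
  out$chain <- chain
  list(residues = out, truth = truth)
}

# Fixed docking transform placing the second chain of a paired fixture
# relative to the first (known relative orientation, shared by all pairs).
dockingTransform <- function() {
  ang <- 120 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0,
                -sin(ang), cos(ang), 0,
                0, 0, 1), 3, 3)
  list(R = R, t = c(30, 6, 4))
}

#' Generate a synthetic template database on disk
#'
#' Emits `nTemplates` PDB-format structures (paired first, then singles,
#' alternating chain types) plus `truth.json` recording every generating
#' label: chain types, sequences, CDR centroid indices and lengths,
#' framework mutations, pairing and the docking transform.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir output directory (created if needed).
#' @param scheme the [NumberingScheme-class].
#' @return the truth list, invisibly; files are written under `dir`.
#' @export
makeTemplateDb <- function(spec, dir, scheme) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nPaired <- round(spec@nTemplates * spec@fractionPaired)
  dock <- dockingTransform()
  truth <- list(scheme_id = scheme@id, seed = spec@seed,
                structures = list())
  withSeed(spec@seed, {
    for (t in seq_len(spec@nTemplates)) {
      structId <- sprintf("F%03d", t)
      paired <- t <= nPaired
      chains <- if (paired) spec@chainTypes
                else spec@chainTypes[(t %% length(spec@chainTypes)) + 1]
      chainIds <- c("A", "B")[seq_along(chains)]
      resolution <- 1.5 + 0.1 * (t %% 10)
      pdbChains <- list()
      chTruth <- list()
      for (ci in seq_along(chains)) {
        sc <- synthChain(chains[ci], scheme, spec)
        bb <- makeBackbone(sc$residues$phi, sc$residues$psi,
                           sequence = paste(sc$residues$aa, collapse = ""))
        if (ci == 2) {
          xyz <- as.matrix(bb[, c("x", "y", "z")])
          bb[, c("x", "y", "z")] <- sweep(xyz %*% dock$R, 2, dock$t, `+`)
        }
        ch <- merge(data.frame(resIdx = seq_len(nrow(sc$residues)),
                               number = sc$residues$number,
                               ins = sc$residues$ins,
                               aa = sc$residues$aa),
                    bb, by = "resIdx")
        ch <- ch[order(ch$resIdx), ]
        pdbChains[[chainIds[ci]]] <- ch
        chTruth[[chainIds[ci]]] <- list(
          chain_type = chains[ci],
          sequence = paste(sc$residues$aa, collapse = ""),
          numbers = sc$residues$number, ins = sc$residues$ins,
          regions = sc$residues$region,
          cs_centroids = sc$truth$centroids,
          loop_lengths = sc$truth$lengths,
          fr_mutations = sc$truth$mutations)
      }
      writePdbFile(pdbChains, file.path(dir, paste0(structId, ".pdb")),
                   resolution = resolution)
      truth$structures[[structId]] <- list(
        id = structId, paired = paired, resolution = resolution,
        chains = chTruth)
    }
  })
  truth$docking <- list(rotation = dock$R, translation = dock$t)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(truth)
}

#' Add a near-identical sibling of a fixture structure
#'
#' Writes a copy of an existing fixture structure under a new identifier
#' with bit-identical coordinates but a diverged sequence: framework
#' positions carry point mutations at `mutationRate` (leaving the framework
#' ~95\% identical), and all but the first `keepCdrMatches` CDR residues per
#' chain are shifted deterministically within their centroid alphabet.  The
#' sibling's whole-chain identity therefore drops below typical
#' leave-one-out filters while staying clearly above every unrelated
#' template, and its backbone divergence from the original is exactly zero.
#'
#' @param dir fixture database directory.
#' @param sourceId structure identifier to copy (e.g. `"F001"`).
#' @param newId identifier of the sibling.
#' @param mutationRate per-position framework mutation rate.
#' @param keepCdrMatches CDR residues (per chain, in chain order) left
#'   unchanged.
#' @param seed RNG seed.
#' @param scheme the [NumberingScheme-class].
#' @return path of the new PDB file, invisibly.
#' @export
addSiblingStructure <- function(dir, sourceId, newId, mutationRate = 0.05,
                                keepCdrMatches = 8, seed = 99,
                                scheme = loadScheme("mini")) {
  at <- readPdbAtoms(file.path(dir, paste0(sourceId, ".pdb")))
  resol <- readPdbResolution(file.path(dir, paste0(sourceId, ".pdb")))
  chains <- list()
  withSeed(seed, {
    for (cid in unique(at$chain)) {
      ca <- at[at$chain == cid, , drop = FALSE]
      ch <- data.frame(number = ca$resno, ins = ca$insert,
                       aa = vapply(ca$resid, function(r)
                         suppressWarnings(bio3d::aa321(r)), character(1)),
                       atom = ca$elety, x = ca$x, y = ca$y, z = ca$z,
                       stringsAsFactors = FALSE)
      # all chain types share the windows in the fixture scheme
      rg <- regionOfNumber(scheme, "alpha", ch$number)
      resKey <- posKey(ch$number, ch$ins)
      for (k in unique(resKey[rg %in% FR_NAMES])) {
        if (stats::runif(1) < mutationRate) {
          old <- ch$aa[resKey == k][1]
          ch$aa[resKey == k] <- sample(setdiff(FIXTURE_AA, old), 1)
        }
      }
      cdrKeys <- unique(resKey[rg %in% CDR_NAMES])
      for (ki in seq_along(cdrKeys)) {
        if (ki <= keepCdrMatches) next
        k <- cdrKeys[ki]
        old <- ch$aa[resKey == k][1]
        grp <- Filter(function(a) old %in% a, CENTROID_ALPHABETS)
        alph <- if (length(grp)) grp[[1]] else FIXTURE_AA
        ch$aa[resKey == k] <- alph[(match(old, alph) %% length(alph)) + 1]
      }
      chains[[cid]] <- ch
    }
  })
  path <- file.path(dir, paste0(newId, ".pdb"))
  writePdbFile(chains, path, resolution = resol)
  invisible(path)
}

# Fill observed CS labels of ingested records from fitted classes
# (beta CDR3 is never labeled: no canonical structures are defined for it).
labelTemplates <- function(records, classes) {
  lapply(records, function(r) {
    for (loop in templateLoops(r)) {
      if (r@chain == "beta" && loop@cdr == 3L) next
      r@csLabels[paste0("cdr", loop@cdr)] <- assignObservedCS(loop, classes)
    }
    r
  })
}

#' Build the complete fixture world
#'
#' Generates the synthetic structures, builds the chain profiles, ingests
#' every structure, clusters the ingested CDR loops into canonical classes,
#' fits their sequence models, labels the templates, and assembles the
#' template database.  Pure function of the spec.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir working directory for the structure files.
#' @param scheme the [NumberingScheme-class] (default: mini).
#' @return list with `profiles`, `classes`, `db`, `truth`, `scheme`,
#'   `iface`, `dir`.
#' @export
buildFixtureWorld <- function(spec, dir = tempfile("fixdb"),
                              scheme = loadScheme("mini")) {
  truth <- makeTemplateDb(spec, dir, scheme)
  profiles <- makeFixtureProfiles(scheme,
                                  chains = unique(c(spec@chainTypes,
                                                    CHAIN_TYPES)))
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  records <- list()
  for (f in files)
    records <- c(records, ingestStructure(f, profiles, scheme))
  loops <- unlist(lapply(records, templateLoops))
  loops <- Filter(function(l) !(l@chain == "beta" && l@cdr == 3L), loops)
  classes <- clusterLoops(loops)
  classes <- lapply(classes, fitSequenceModel)
  records <- labelTemplates(records, classes)
  db <- templateDatabase(records, schemeId = scheme@id)
  list(profiles = profiles, classes = classes, db = db, truth = truth,
       scheme = scheme, iface = loadInterface("mini"), dir = dir)
}
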