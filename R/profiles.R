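## Sequence profiles: build from column-mapped MSAs, enrich with filtered
## sequence sets, identify chain types, and align/renumber sequences onto the
## scheme with right-aligned CDR insertions.

# Emission matrix from an MSA over the match states: log2-odds with
# background-weighted pseudocounts; column 21 holds the expected score of an
# ambiguous residue (X) under the background.
profileEmissions <- function(msa, background, pseudocount = 1) {
  nstates <- ncol(msa)
  emis <- matrix(0, nstates, 21,
                 dimnames = list(NULL, c(AA20, "X")))
  for (j in seq_len(nstates)) {
    col <- msa[, j]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    p <- (as.numeric(cnt) + pseudocount * background) /
      (length(col) + pseudocount)
    emis[j, 1:20] <- log2(p / background)
    emis[j, 21] <- sum(background * emis[j, 1:20])
  }
  emis
}

# Position-specific gap costs (bits).  Length variation belongs in the CDRs:
# insertions and deletions there are cheap, framework gaps expensive, and the
# sequence may overhang the profile freely at either end.
profileGapCosts <- function(stateNumbers, scheme, chain,
                            frInsOpen = 8, frInsExtend = 2,
                            cdrInsOpen = 1, cdrInsExtend = 0.25,
                            frDel = 8, cdrDel = 0.75) {
  region <- regionOfNumber(scheme, chain, stateNumbers)
  isCdr <- region %in% CDR_NAMES
  n <- length(stateNumbers)
  # a slot is cheap when its state is inside a CDR window, or when the gap
  # to the next state spans one (CDR columns dropped by the occupancy rule)
  allPos <- schemePositions(scheme, chain)
  cdrNums <- allPos$number[allPos$region %in% CDR_NAMES]
  spansCdr <- vapply(seq_len(n), function(j) {
    if (j == n) return(FALSE)
    any(cdrNums > stateNumbers[j] & cdrNums < stateNumbers[j + 1])
  }, logical(1))
  cheap <- isCdr | spansCdr
  insOpen <- c(0, ifelse(cheap, cdrInsOpen, frInsOpen))
  insExtend <- c(0, ifelse(cheap, cdrInsExtend, frInsExtend))
  insOpen[n + 1] <- 0
  insExtend[n + 1] <- 0
  delCost <- ifelse(isCdr, cdrDel, frDel)
  list(insOpen = insOpen, insExtend = insExtend, delCost = delCost)
}

# Normalise MSA input to a character matrix of single residues.
asMsaMatrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (inherits(msa, "AAStringSet") || inherits(msa, "XStringSet"))
    msa <- as.character(msa)
  if (is.character(msa)) {
    if (length(msa) == 0) return(matrix(character(0), 0, 0))
    if (length(unique(nchar(msa))) != 1)
      fvError("fv_input", "aligned sequences must have equal length")
    return(do.call(rbind, strsplit(toupper(msa), "")))
  }
  fvError("fv_input", "unsupported MSA representation")
}

#' Build a chain profile from a column-mapped alignment
#'
#' Every alignment column that is mapped to a scheme position and occupied in
#' at least `occupancy` of the sequences becomes a match state; emission
#' scores are background-weighted log2-odds of the column residue
#' frequencies.
#'
#' @param msa aligned sequences: character matrix, character vector of
#'   equal-length strings, or an `AAStringSet`; gaps are `-` or `.`.
#' @param columnMap integer vector, one scheme number per alignment column
#'   (`NA` only for columns with no residues).
#' @param chain chain type the profile models.
#' @param scheme the [NumberingScheme-class] the columns are mapped to.
#' @param occupancy minimum non-gap fraction for a column to be retained as a
#'   match state (default 0.5).
#' @param pseudocount pseudocount mass added per state.
#' @param background length-20 background frequencies (default uniform).
#' @param acceptThreshold minimum alignment score in bits for
#'   [identifyChain()] acceptance (default 0: a sequence must beat the
#'   background model).
#' @return A [ChainProfile-class].
#' @export
buildProfile <- function(msa, columnMap, chain, scheme,
                         occupancy = 0.5, pseudocount = 1,
                         background = NULL, acceptThreshold = 0) {
  m <- asMsaMatrix(msa)
  if (nrow(m) == 0) fvError("fv_input", "empty MSA")
  if (nrow(m) < 2) fvError("fv_input", "a profile needs at least 2 sequences")
  if (length(columnMap) != ncol(m))
    fvError("fv_config", "columnMap length must equal MSA width")
  isGap <- m == "-" | m == "."
  occ <- colMeans(!isGap)
  if (any(occ > 0 & is.na(columnMap)))
    fvError("fv_config", sprintf("unmapped occupied column: %d",
                                 which(occ > 0 & is.na(columnMap))[1]))
  keep <- !is.na(columnMap) & occ >= occupancy
  if (!any(keep)) fvError("fv_config", "no columns pass the occupancy filter")
  nums <- as.integer(columnMap[keep])
  if (is.unsorted(nums, strictly = TRUE))
    fvError("fv_config", "mapped scheme numbers must be strictly increasing")
  if (!all(nums %in% scheme@chains[[chain]]$positions))
    fvError("fv_config", "columnMap contains numbers absent from the scheme")
  background <- background %||% rep(1 / 20, 20)
  mm <- m[, keep, drop = FALSE]
  gaps <- profileGapCosts(nums, scheme, chain)
  new("ChainProfile",
      chain = chain, schemeId = scheme@id,
      states = data.frame(number = nums,
                          region = regionOfNumber(scheme, chain, nums),
                          stringsAsFactors = FALSE),
      emissions = profileEmissions(mm, background, pseudocount),
      background = background,
      insOpen = gaps$insOpen, insExtend = gaps$insExtend,
      delCost = gaps$delCost,
      msa = mm, acceptThreshold = acceptThreshold, nAdded = 0L)
}

# Core alignment call.
alignToProfile <- function(sequence, profile, traceback = FALSE) {
  enc <- aaEncode(sequence)
  .profileAlignCpp(enc, profile@emissions, profile@insOpen,
                   profile@insExtend, profile@delCost, traceback)
}

#' Score a sequence against a profile
#' @param sequence amino-acid string.
#' @param profile a [ChainProfile-class].
#' @return alignment score in bits.
#' @export
scoreSequence <- function(sequence, profile) {
  alignToProfile(sequence, profile)$score
}

#' Enrich a profile with a filtered sequence set
#'
#' Candidate sequences longer than `minLength` residues and with an E-value
#' below `evalueCutoff` are aligned to the seed profile, their match-state
#' residues merged into the training alignment, and the emission model is
#' rebuilt; the match states themselves are unchanged.  The E-value of a
#' candidate scoring `s` bits against the seed is `N * 2^-s` with `N` the
#' candidate-set size.
#'
#' @param seed a [ChainProfile-class].
#' @param sequences character vector (or `AAStringSet`) of candidates.
#' @param evalueCutoff E-value filter (default `1e-50`).
#' @param minLength sequences must be strictly longer than this (default 100).
#' @return A rebuilt [ChainProfile-class]; slot `nAdded` reports how many
#'   sequences passed both filters (0 returns the seed unchanged).
#' @export
enrichProfile <- function(seed, sequences, evalueCutoff = 1e-50,
                          minLength = 100) {
  stopifnot(evalueCutoff > 0, minLength > 0)
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (length(sequences) == 0) {
    seed@nAdded <- 0L
    return(seed)
  }
  scores <- vapply(sequences, function(s) alignToProfile(s, seed)$score,
                   numeric(1))
  evalue <- length(sequences) * 2^(-scores)
  pass <- evalue < evalueCutoff & nchar(sequences) > minLength
  if (!any(pass)) {
    seed@nAdded <- 0L
    return(seed)
  }
  rows <- lapply(sequences[pass], function(s) {
    aln <- alignToProfile(s, seed, traceback = TRUE)
    chars <- strsplit(toupper(s), "")[[1]]
    row <- rep("-", nrow(seed@states))
    matched <- aln$assign > 0
    row[aln$assign[matched]] <- chars[matched]
    row
  })
  out <- seed
  out@msa <- rbind(seed@msa, do.call(rbind, rows))
  out@emissions <- profileEmissions(out@msa, seed@background)
  out@nAdded <- as.integer(sum(pass))
  out
}

#' Identify the chain type of a sequence
#'
#' Scores the sequence against all supplied profiles; the best-scoring
#' profile's chain type is returned, or a rejection when the best score is
#' below the acceptance threshold.
#'
#' @param sequence amino-acid string (X allowed).
#' @param profiles named list of [ChainProfile-class] objects.
#' @param threshold acceptance threshold in bits; defaults to each profile's
#'   own `acceptThreshold`.
#' @return list with `chain` (NA when rejected), `receptor`, `score`,
#'   `accepted`, and the named vector `scores` of all profile scores.
#' @export
identifyChain <- function(sequence, profiles, threshold = NULL) {
  if (!nzchar(sequence)) fvError("fv_input", "empty sequence")
  scores <- vapply(profiles, function(p) alignToProfile(sequence, p)$score,
                   numeric(1))
  best <- which.max(scores)
  thr <- threshold %||% profiles[[best]]@acceptThreshold
  accepted <- scores[best] >= thr
  list(chain = if (accepted) profiles[[best]]@chain else NA_character_,
       receptor = if (accepted) receptorOf(profiles[[best]]@chain)
                  else NA_character_,
       score = unname(scores[best]), accepted = accepted, scores = scores)
}

#' Align a sequence to a profile and renumber it onto the scheme
#'
#' Framework residues take their match-state numbers (framework insertions
#' get insertion codes in place).  Within each CDR the residues falling
#' between the flanking framework anchors are renumbered right-aligned:
#' C-terminal residues keep canonical numbers, short loops vacate the
#' N-terminal-most window positions, and surplus residues become
#' insertion-coded positions immediately after the CDR's single re-entry
#' position.  Residues overhanging the profile at either terminus are
#' trimmed.
#'
#' @param sequence amino-acid string accepted by [identifyChain()] for this
#'   profile.
#' @param profile a [ChainProfile-class].
#' @param scheme the [NumberingScheme-class] named by the profile.
#' @param frTolerance minimum occupied fraction required of every framework
#'   window (default 0.5); below it an "incomplete framework" error is
#'   raised.
#' @return A [NumberedChain-class].
#' @export
alignAndNumber <- function(sequence, profile, scheme, frTolerance = 0.5) {
  stopifnot(identical(profile@schemeId, scheme@id))
  aln <- alignToProfile(sequence, profile, traceback = TRUE)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  assign <- aln$assign
  insAfter <- aln$insAfter
  stateNum <- profile@states$number

  number <- ifelse(assign > 0, stateNum[pmax(assign, 1L)], NA_integer_)
  ins <- rep("", L)
  keep <- rep(TRUE, L)

  # trim terminal overhangs (insertions in slot 0 / slot nstates)
  keep[assign == 0 & !is.na(insAfter) & insAfter == 0] <- FALSE
  keep[assign == 0 & !is.na(insAfter) & insAfter == nrow(profile@states)] <-
    FALSE

  windows <- cdrWindows(scheme, profile@chain)
  inLoop <- rep(FALSE, L)
  for (cdr in CDR_NAMES) {
    w <- windows[[cdr]]
    lastBefore <- which(assign > 0 & number < min(w$numbers))
    firstAfter <- which(assign > 0 & number > max(w$numbers))
    lo <- if (length(lastBefore)) max(lastBefore) else 0L
    hi <- if (length(firstAfter)) min(firstAfter) else L + 1L
    idx <- seq_len(L)
    span <- idx > lo & idx < hi & keep
    if (!any(span)) next
    ren <- cdrRenumber(sum(span), w$numbers, w$reentry,
                       scheme@insertionOrder)
    number[span] <- ren$number
    ins[span] <- ren$ins
    inLoop[span] <- TRUE
  }

  # framework insertion codes: consecutive run after state j -> nA, nB, ...
  codes <- strsplit(scheme@insertionOrder, "")[[1]]
  i <- 1L
  while (i <= L) {
    if (keep[i] && !inLoop[i] && assign[i] == 0) {
      j <- insAfter[i]
      run <- i
      while (run < L && keep[run + 1L] && !inLoop[run + 1L] &&
             assign[run + 1L] == 0 && identical(insAfter[run + 1L], j))
        run <- run + 1L
      if (j < 1 || run - i + 1L > length(codes))
        fvError("fv_numbering", "unplaceable framework insertion")
      number[i:run] <- stateNum[j]
      ins[i:run] <- codes[seq_len(run - i + 1L)]
      i <- run + 1L
    } else i <- i + 1L
  }

  res <- data.frame(number = number[keep], ins = ins[keep],
                    aa = chars[keep], seqIdx = which(keep),
                    stringsAsFactors = FALSE)
  res$region <- regionOfNumber(scheme, profile@chain, res$number)

  # framework completeness check per FR window
  allPos <- schemePositions(scheme, profile@chain)
  for (fr in FR_NAMES) {
    want <- allPos$number[allPos$region == fr]
    got <- sum(want %in% res$number[res$ins == ""])
    if (got / length(want) < frTolerance)
      fvError("fv_incomplete_framework",
              sprintf("incomplete framework: %s has %d of %d positions",
                      fr, got, length(want)))
  }

  new("NumberedChain", chain = profile@chain, schemeId = scheme@id,
      residues = res, score = aln$score)
}

#' Serialize profiles to JSON
#' @param profiles named list of [ChainProfile-class] objects.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  payload <- lapply(profiles, function(p) list(
    chain = p@chain, scheme_id = p@schemeId,
    state_numbers = p@states$number,
    emissions = unname(p@emissions),
    background = p@background,
    ins_open = p@insOpen, ins_extend = p@insExtend, del_cost = p@delCost,
    msa = apply(p@msa, 1, paste, collapse = ""),
    accept_threshold = p@acceptThreshold))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read profiles from JSON written by [writeProfiles()]
#' @param path JSON file.
#' @param scheme the [NumberingScheme-class] the profiles were built on.
#' @return named list of [ChainProfile-class] objects.
#' @export
readProfiles <- function(path, scheme) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(p) {
    emis <- matrix(unlist(p$emissions), ncol = 21, byrow = FALSE)
    if (is.matrix(p$emissions)) emis <- p$emissions
    colnames(emis) <- c(AA20, "X")
    nums <- as.integer(p$state_numbers)
    new("ChainProfile", chain = p$chain, schemeId = p$scheme_id,
        states = data.frame(number = nums,
                            region = regionOfNumber(scheme, p$chain, nums),
                            stringsAsFactors = FALSE),
        emissions = emis, background = p$background,
        insOpen = p$ins_open, insExtend = p$ins_extend,
        delCost = p$del_cost,
        msa = do.call(rbind, strsplit(p$msa, "")),
        acceptThreshold = p$accept_threshold, nAdded = 0L)
  })
  names(out) <- vapply(out, function(p) p@chain, character(1))
  out
}

#' Read sequences from FASTA or raw text
#'
#' Accepts FASTA (possibly multi-record) or raw single-sequence text with no
#' header or special characters; whitespace is stripped.
#'
#' @param path file to read.
#' @return character vector of sequences (named for FASTA input).
#' @export
readSequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(lines, ">"))) {
    set <- Biostrings::readAAStringSet(path)
    out <- as.character(set)
    names(out) <- names(set)
    out
  } else {
    gsub("[[:space:]]", "", paste(lines, collapse = ""))
  }
}
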