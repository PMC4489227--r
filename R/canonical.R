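## Canonical structures: periodic dihedral metric, per-length clustering by
## affinity propagation, and sequence-based class prediction.

#' Periodic distance between two dihedral angles
#'
#' `D(theta1, theta2) = 2 * (1 - cos(theta1 - theta2))`: zero for equal
#' angles, maximal (4) for angles pi apart, periodic with period 2*pi.
#'
#' @param theta1,theta2 angles in radians (vectorized).
#' @return numeric distances in `[0, 4]`.
#' @export
angleDistance <- function(theta1, theta2) {
  stopifnot(all(is.finite(theta1)), all(is.finite(theta2)))
  2 * (1 - cos(theta1 - theta2))
}

#' Distance between two same-length CDR loops
#'
#' Sum over residues of the [angleDistance()] of the phi angles plus that of
#' the psi angles.  Loops are only comparable within one chain type, CDR and
#' length group.
#'
#' @param a,b [DihedralLoop-class] objects of equal length, same chain type
#'   and CDR.
#' @return non-negative numeric.
#' @export
loopDistance <- function(a, b) {
  if (length(a@phi) != length(b@phi))
    fvError("fv_input", "loops of different length cannot be compared")
  if (!identical(a@chain, b@chain) || !identical(a@cdr, b@cdr))
    fvError("fv_input", "loops must share chain type and CDR")
  sum(angleDistance(a@phi, b@phi)) + sum(angleDistance(a@psi, b@psi))
}

# Dense distance matrix for one group of loops.
loopDistanceMatrix <- function(loops) {
  n <- length(loops)
  phi <- do.call(rbind, lapply(loops, function(l) l@phi))
  psi <- do.call(rbind, lapply(loops, function(l) l@psi))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dp <- 2 * (1 - cos(sweep(phi, 2, phi[i, ])))
    ds <- 2 * (1 - cos(sweep(psi, 2, psi[i, ])))
    d[, i] <- rowSums(dp) + rowSums(ds)
  }
  d
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering on a similarity matrix by responsibility /
#' availability message passing, with damping and a deterministic
#' symmetry-breaking perturbation so results are reproducible and invariant
#' to input order.
#'
#' @param S square similarity matrix (larger = more similar).
#' @param preference exemplar preference: a number, or one of
#'   `"adaptive"` (default: `4 * n * median(nearest-neighbour similarity)`,
#'   which keeps a single noise-scale cloud in one class while leaving
#'   well-separated classes intact), `"median"`, `"min"`, or `"min-range"`
#'   (minimum off-diagonal similarity minus the off-diagonal range).
#' @param damping message damping factor in `[0.5, 1)`.
#' @param maxit maximum iterations.
#' @param convits stop after this many iterations without exemplar changes.
#' @param noiseSeed seed of the deterministic tie-breaking noise.
#' @return list with `exemplars` (indices) and `labels` (exemplar index per
#'   point).
#' @export
affinityPropagation <- function(S, preference = "adaptive", damping = 0.9,
                                maxit = 1000, convits = 50, noiseSeed = 42) {
  n <- nrow(S)
  if (n == 1) return(list(exemplars = 1L, labels = 1L))
  off <- S[row(S) != col(S)]
  if (max(off) - min(off) < 1e-12) {
    # fully degenerate group (e.g. identical loops): one cluster
    return(list(exemplars = 1L, labels = rep(1L, n)))
  }
  if (is.character(preference)) {
    diag(S) <- NA
    nn <- apply(S, 1, max, na.rm = TRUE)   # nearest-neighbour similarity
    preference <- switch(preference,
      "median" = stats::median(off),
      "min" = min(off),
      "min-range" = min(off) - (max(off) - min(off)),
      "adaptive" = min(4 * n * stats::median(nn), min(off)),
      stop("unknown preference rule"))
  }
  diag(S) <- preference
  eps <- (max(S) - min(S)) * 1e-9
  S <- S + withSeed(noiseSeed, matrix(stats::runif(n * n), n, n)) * eps

  R <- A <- matrix(0, n, n)
  lastEx <- NULL
  stable <- 0L
  for (it in seq_len(maxit)) {
    AS <- A + S
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a + s)(i,k')
    top1 <- apply(AS, 1, which.max)
    m1 <- AS[cbind(seq_len(n), top1)]
    AS2 <- AS
    AS2[cbind(seq_len(n), top1)] <- -Inf
    m2 <- apply(AS2, 1, max)
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), top1)] <- S[cbind(seq_len(n), top1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colS <- colSums(Rp)
    Anew <- matrix(colS, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, lastEx)) stable <- stable + 1L else stable <- 0L
    lastEx <- ex
    if (stable >= convits && length(ex) > 0) break
  }
  ex <- lastEx
  if (length(ex) == 0) ex <- which.max(diag(R) + diag(A))
  labels <- ex[apply(S[, ex, drop = FALSE], 1, which.max)]
  labels[ex] <- ex
  list(exemplars = ex, labels = labels)
}

#' Cluster CDR loops into canonical-structure classes
#'
#' Loops are grouped by chain type, CDR and loop length; within each group
#' affinity propagation is run on similarity = `-loopDistance`.  Singleton
#' groups yield a single class.  Class labels are deterministic for a given
#' configuration.
#'
#' @param loops list of [DihedralLoop-class] objects.
#' @param preference,damping,maxit,noiseSeed passed to
#'   [affinityPropagation()].
#' @return list of [CanonicalClass-class] objects (sequence models unfitted;
#'   see [fitSequenceModel()]).
#' @export
clusterLoops <- function(loops, preference = "adaptive", damping = 0.9,
                         maxit = 1000, noiseSeed = 42) {
  if (length(loops) == 0) return(list())
  key <- vapply(loops, function(l)
    sprintf("%s.%d.L%d", l@chain, l@cdr, nchar(l@sequence)), character(1))
  # deterministic internal order regardless of input order
  srcOrder <- order(key, vapply(loops, function(l) l@source, character(1)),
                    method = "radix")
  loops <- loops[srcOrder]
  key <- key[srcOrder]
  out <- list()
  for (g in sort(unique(key))) {
    grp <- loops[key == g]
    lens <- vapply(grp, function(l) length(l@phi), integer(1))
    if (length(unique(lens)) != 1)
      fvError("fv_input", "mixed loop lengths within one group")
    d <- loopDistanceMatrix(grp)
    cl <- affinityPropagation(-d, preference = preference, damping = damping,
                              maxit = maxit, noiseSeed = noiseSeed)
    exIdx <- sort(unique(cl$labels))
    # order classes by exemplar source id for stable labels
    exSrc <- vapply(grp[exIdx], function(l) l@source, character(1))
    exIdx <- exIdx[orderLex(exSrc)]
    for (k in seq_along(exIdx)) {
      memberIdx <- which(cl$labels == exIdx[k])
      cls <- new("CanonicalClass",
                 chain = grp[[1]]@chain, cdr = grp[[1]]@cdr,
                 loopLength = lens[1],
                 classId = sprintf("%s.%02d", g, k),
                 exemplar = grp[[exIdx[k]]],
                 members = vapply(grp[memberIdx], function(l) l@source,
                                  character(1)),
                 memberSeqs = vapply(grp[memberIdx], function(l) l@sequence,
                                     character(1)),
                 seqModel = matrix(numeric(0), 0, 20),
                 selfScoreMin = NA_real_, nullScore = NA_real_)
      out[[cls@classId]] <- cls
    }
  }
  out
}

#' Fit the per-position sequence model of a canonical class
#'
#' Laplace-smoothed per-position log-odds of the member residues against a
#' background distribution (natural log; uniform background when `background`
#' is empty or `NULL`).  Also records the minimum member self-score
#' (informational) and the expected score of a background-random sequence:
#' that null score is the default prediction confidence threshold, so a
#' class is only assigned to loops that look more like its members than
#' like background.
#'
#' @param cls a [CanonicalClass-class] with at least one member sequence.
#' @param background length-20 amino-acid frequencies or `NULL`.
#' @param alpha Laplace pseudocount (default 1).
#' @return the class with `seqModel` and `selfScoreMin` filled in.
#' @export
fitSequenceModel <- function(cls, background = NULL, alpha = 1) {
  if (length(cls@memberSeqs) == 0)
    fvError("fv_input", "class has no member sequences")
  if (is.null(background) || length(background) == 0 ||
      any(!is.finite(background)))
    background <- rep(1 / 20, 20)
  background <- background / sum(background)
  L <- cls@loopLength
  chars <- do.call(rbind, strsplit(cls@memberSeqs, ""))
  n <- nrow(chars)
  model <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(L)) {
    cnt <- table(factor(chars[, i], levels = AA20))
    p <- (as.numeric(cnt) + alpha) / (n + 20 * alpha)
    model[i, ] <- log(p / background)
  }
  cls@seqModel <- model
  selfScores <- vapply(cls@memberSeqs, function(s)
    scoreLoopSequence(s, model), numeric(1))
  cls@selfScoreMin <- min(selfScores)
  cls@nullScore <- sum(model %*% background)
  cls
}

scoreLoopSequence <- function(sequence, model) {
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (anyNA(idx)) return(-Inf)
  sum(model[cbind(seq_along(idx), idx)])
}

#' Predict the canonical structure of a CDR loop from sequence
#'
#' Among the classes of the loop's chain type, CDR and length, returns the
#' class whose sequence model scores the loop highest, provided the score
#' reaches the class's confidence threshold (default: the class's background
#' null score, the expected score of a background-random sequence);
#' otherwise no class.  TCR beta CDR3 always returns no class: no clear
#' canonical structures exist for it.
#'
#' @param loopSequence amino-acid string of the loop.
#' @param chain chain type.
#' @param cdr CDR index 1..3.
#' @param classes list of [CanonicalClass-class] objects (sequence models
#'   fitted).
#' @param threshold confidence threshold; default each class's
#'   `nullScore`.
#' @return list `class` (class id or `NA`) and `score`.
#' @export
predictCS <- function(loopSequence, chain, cdr, classes, threshold = NULL) {
  if (identical(chain, "beta") && cdr == 3L)
    return(list(class = NA_character_, score = NA_real_))
  cand <- Filter(function(c)
    c@chain == chain && c@cdr == cdr &&
      c@loopLength == nchar(loopSequence) && nrow(c@seqModel) > 0, classes)
  if (length(cand) == 0) return(list(class = NA_character_, score = NA_real_))
  scores <- vapply(cand, function(c)
    scoreLoopSequence(loopSequence, c@seqModel), numeric(1))
  best <- which.max(scores)
  thr <- threshold %||% cand[[best]]@nullScore
  if (is.na(thr)) thr <- -Inf
  if (scores[best] >= thr)
    list(class = cand[[best]]@classId, score = unname(scores[best]))
  else list(class = NA_character_, score = unname(scores[best]))
}

#' Predict canonical structures for all CDRs of a numbered chain
#'
#' @param numbered a [NumberedChain-class].
#' @param classes list of fitted [CanonicalClass-class] objects.
#' @param threshold optional confidence threshold override.
#' @return named list `cdr1`..`cdr3` of `list(class, score)`; `cdr3` of a
#'   beta chain is always unassigned.
#' @export
assignCS <- function(numbered, classes, threshold = NULL) {
  r <- numbered@residues
  out <- lapply(1:3, function(k) {
    seqk <- paste(r$aa[r$region == CDR_NAMES[k]], collapse = "")
    predictCS(seqk, numbered@chain, as.integer(k), classes, threshold)
  })
  names(out) <- c("cdr1", "cdr2", "cdr3")
  out
}

#' Assign the observed canonical structure of a loop
#'
#' Nearest exemplar under [loopDistance()] among classes of the loop's
#' group; used when ingesting solved structures (observed, not predicted).
#'
#' @param loop a [DihedralLoop-class] with defined angles.
#' @param classes list of [CanonicalClass-class] objects.
#' @return class id, or `NA` when no class covers the group.
#' @export
assignObservedCS <- function(loop, classes) {
  cand <- Filter(function(c)
    c@chain == loop@chain && c@cdr == loop@cdr &&
      c@loopLength == length(loop@phi), classes)
  if (length(cand) == 0) return(NA_character_)
  d <- vapply(cand, function(c) loopDistance(loop, c@exemplar), numeric(1))
  cand[[which.min(d)]]@classId
}

#' Serialize canonical classes to JSON
#' @param classes list of [CanonicalClass-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCanonicalClasses <- function(classes, path) {
  payload <- lapply(classes, function(c) list(
    chain = c@chain, cdr = c@cdr, loop_length = c@loopLength,
    class_id = c@classId,
    exemplar = list(source = c@exemplar@source,
                    sequence = c@exemplar@sequence,
                    phi = c@exemplar@phi, psi = c@exemplar@psi),
    members = c@members, member_seqs = c@memberSeqs,
    seq_model = if (nrow(c@seqModel)) unname(c@seqModel) else NULL,
    self_score_min = if (is.na(c@selfScoreMin)) NULL else c@selfScoreMin,
    null_score = if (is.na(c@nullScore)) NULL else c@nullScore))
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read canonical classes from JSON written by [writeCanonicalClasses()]
#' @param path JSON file.
#' @return named list of [CanonicalClass-class] objects.
#' @export
readCanonicalClasses <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(payload)), function(i) {
    p <- payload[i, ]
    sm <- p$seq_model[[1]]
    if (is.null(sm)) sm <- matrix(numeric(0), 0, 20) else {
      sm <- matrix(unlist(sm), ncol = 20, byrow = FALSE)
      if (is.matrix(p$seq_model[[1]])) sm <- p$seq_model[[1]]
      colnames(sm) <- AA20
    }
    ex <- p$exemplar
    new("CanonicalClass", chain = p$chain, cdr = as.integer(p$cdr),
        loopLength = as.integer(p$loop_length), classId = p$class_id,
        exemplar = new("DihedralLoop", chain = p$chain,
                       cdr = as.integer(p$cdr),
                       sequence = ex$sequence, phi = unlist(ex$phi),
                       psi = unlist(ex$psi), source = ex$source),
        members = unlist(p$members), memberSeqs = unlist(p$member_seqs),
        seqModel = sm,
        selfScoreMin = if (is.null(p$self_score_min[[1]])) NA_real_
                       else as.numeric(p$self_score_min),
        nullScore = if (is.null(p$null_score[[1]])) NA_real_
                    else as.numeric(p$null_score))
  })
  names(out) <- vapply(out, function(c) c@classId, character(1))
  out
}

#' Export a loop distance matrix as TSV
#' @param loops list of same-group [DihedralLoop-class] objects.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(loops, path) {
  d <- loopDistanceMatrix(loops)
  ids <- vapply(loops, function(l) l@source, character(1))
  dimnames(d) <- list(ids, ids)
  utils::write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
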