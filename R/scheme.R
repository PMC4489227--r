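## Numbering scheme tables and the CDR right-alignment renumbering rule.

#' Load a numbering scheme
#'
#' Reads a scheme table from JSON.  Two tables ship with the package:
#' `"chothia"`, a reconstructed Chothia-style Kabat-Chothia table with
#' per-CDR insertion re-entry positions (marked editable -- the exact
#' historical insertion table is not reproduced verbatim), and `"mini"`, a
#' miniature ~60-position scheme used by the synthetic fixtures so tests run
#' fast.  Both are processed by identical code paths.
#'
#' @param name `"chothia"`, `"mini"`, or a path to a scheme JSON file.
#' @return A [NumberingScheme-class] object.
#' @export
loadScheme <- function(name = "chothia") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("scheme_", name, ".json"),
                package = "FvModeler")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("no such scheme: '%s'", name))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  chains <- lapply(raw$chains, function(info) {
    list(positions = as.integer(info$positions),
         regions = lapply(info$regions, as.integer),
         reentry = vapply(info$reentry, as.integer, integer(1)))
  })
  new("NumberingScheme", id = raw$scheme_id,
      insertionOrder = raw$insertion_order, chains = chains)
}

#' Scheme positions for a chain type
#' @param scheme a [NumberingScheme-class].
#' @param chain chain type.
#' @return data.frame `number`, `region` in scheme order.
#' @export
schemePositions <- function(scheme, chain) {
  info <- scheme@chains[[chain]]
  if (is.null(info)) stop(sprintf("scheme has no chain '%s'", chain))
  data.frame(number = info$positions,
             region = regionOfNumber(scheme, chain, info$positions),
             stringsAsFactors = FALSE)
}

# Region label of scheme numbers for a chain type.
regionOfNumber <- function(scheme, chain, number) {
  info <- scheme@chains[[chain]]
  out <- rep(NA_character_, length(number))
  for (rg in names(info$regions)) {
    w <- info$regions[[rg]]
    out[number >= w[1] & number <= w[2]] <- rg
  }
  out
}

#' CDR windows of a chain type
#' @param scheme a [NumberingScheme-class].
#' @param chain chain type.
#' @return named list per CDR with `numbers` (window scheme numbers) and
#'   `reentry` (the single insertion re-entry number).
#' @export
cdrWindows <- function(scheme, chain) {
  info <- scheme@chains[[chain]]
  out <- lapply(CDR_NAMES, function(cdr) {
    w <- info$regions[[cdr]]
    list(numbers = info$positions[info$positions >= w[1] &
                                    info$positions <= w[2]],
         reentry = info$reentry[[cdr]])
  })
  names(out) <- CDR_NAMES
  out
}

# Renumber L loop residues onto a CDR window.  The loop is right-aligned:
# C-terminal residues always keep their canonical numbers.  A loop shorter
# than the window vacates the N-terminal-most window positions; a longer loop
# places the extra residues as insertion-coded positions immediately after
# the single re-entry position.
cdrRenumber <- function(L, window, reentry, insertionOrder) {
  w <- length(window)
  if (L == 0) {
    return(data.frame(number = integer(0), ins = character(0),
                      stringsAsFactors = FALSE))
  }
  if (L <= w) {
    data.frame(number = window[(w - L + 1):w], ins = "",
               stringsAsFactors = FALSE)
  } else {
    r <- match(reentry, window)
    nIns <- L - w
    codes <- strsplit(insertionOrder, "")[[1]]
    if (nIns > length(codes)) stop("loop too long for insertion-code order")
    data.frame(
      number = c(window[seq_len(r)], rep(reentry, nIns),
                 window[(r + 1):w]),
      ins = c(rep("", r), codes[seq_len(nIns)], rep("", w - r)),
      stringsAsFactors = FALSE)
  }
}

# Total order of positions under a scheme: number ascending, then "" before
# insertion codes in insertionOrder sequence.  Returns an ordering index.
orderPositions <- function(number, ins, insertionOrder) {
  codes <- strsplit(insertionOrder, "")[[1]]
  rank <- match(ins, codes)
  rank[is.na(rank)] <- 0L   # "" sorts first
  order(number, rank)
}
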