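## Shared constants and small helpers.

# Canonical amino-acid alphabet used throughout (order fixed: emission matrix
# columns, sequence models and BLOSUM lookups all index into this vector).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CHAIN_TYPES <- c("heavy", "kappa", "lambda", "alpha", "beta")
CDR_NAMES <- c("CDR1", "CDR2", "CDR3")
FR_NAMES <- c("FR1", "FR2", "FR3", "FR4")
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Receptor type of a chain
#'
#' Heavy, kappa and lambda chains belong to B-cell receptors (antibodies);
#' alpha and beta chains to T-cell receptors.
#'
#' @param chain Character, one of `"heavy"`, `"kappa"`, `"lambda"`,
#'   `"alpha"`, `"beta"`.
#' @return `"BCR"` or `"TCR"`.
#' @export
receptorOf <- function(chain) {
  stopifnot(all(chain %in% CHAIN_TYPES))
  ifelse(chain %in% c("heavy", "kappa", "lambda"), "BCR", "TCR")
}

# Valid light-chain partner sets for a receptor pair.
validPairings <- list(
  c("heavy", "kappa"), c("heavy", "lambda"), c("alpha", "beta")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return angles mapped into the half-open interval (-pi, pi].
#' @export
wrapAngle <- function(theta) {
  out <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # floor() maps exact pi to -pi; keep the +pi representative
  out[out <= -pi + 1e-15] <- pi
  out
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream (the global .Random.seed is saved and restored).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draws from a von Mises distribution centred at mu with concentration kappa
# (Best & Fisher 1979 rejection sampler).  Used by the fixture generator for
# dihedral noise around cluster centroids.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(wrapAngle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- wrapAngle(sign(u[3] - 0.5) * acos(f) + mu)
      i <- i + 1L
    }
  }
  out
}

# Encode an amino-acid string as integer codes into AA20 (X and other
# ambiguity characters -> 21, scored as expectation over the background).
aaEncode <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(chars, c(AA20, "X"))
  if (length(bad) > 0) {
    stop(sprintf("non-amino-acid character in sequence: '%s'", bad[1]),
         call. = FALSE)
  }
  idx <- match(chars, AA20)
  idx[is.na(idx)] <- 21L
  idx
}

# Position key: scheme number + insertion code, e.g. "52" or "52A".
posKey <- function(number, ins) paste0(number, ifelse(is.na(ins) | ins == "", "", ins))

# Deterministic lexicographic ordering used by every tie-break in the
# selection machinery (C collation so results do not depend on locale).
orderLex <- function(x) order(x, method = "radix")

# BLOSUM62 from Biostrings, cached per session.
.pkgCache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix (from \pkg{Biostrings}), restricted to the
#' 20 canonical residues, used by all template and pseudo-sequence scores.
#' @return A 20x20 integer matrix with dimnames in the canonical alphabet.
#' @export
blosum62 <- function() {
  if (is.null(.pkgCache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .pkgCache$blosum62 <- env$BLOSUM62[AA20, AA20]
  }
  .pkgCache$blosum62
}

# Typed condition helper so pipeline callers can distinguish failure modes.
fvError <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fvError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
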