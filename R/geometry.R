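## Backbone geometry: torsion angles, internal-coordinate chain construction,
## and least-squares rigid-body superposition.

# Torsion angle about b2 for the atom quadruple p1-p2-p3-p4, radians in
# (-pi, pi].  Returns NA for degenerate (collinear) geometry.
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  ang <- atan2(-y, x)   # IUPAC sign convention
  if (ang <= -pi) ang <- pi
  ang
}

#' Backbone phi/psi dihedrals of a chain
#'
#' Standard torsions: phi(i) about C(i-1)-N(i)-CA(i)-C(i), psi(i) about
#' N(i)-CA(i)-C(i)-N(i+1), radians in (-pi, pi].  Angles whose defining
#' atoms are missing (chain termini, incomplete residues) or degenerate
#' (collinear) are `NA`.
#'
#' @param atoms data.frame with columns `resIdx`, `atom`, `x`, `y`, `z`
#'   covering backbone atoms N/CA/C for consecutive residues.
#' @param nres number of residues (default `max(resIdx)`).
#' @return list with numeric vectors `phi` and `psi` of length `nres`.
#' @export
computeDihedrals <- function(atoms, nres = max(atoms$resIdx)) {
  get <- function(i, name) {
    row <- atoms[atoms$resIdx == i & atoms$atom == name, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  phi <- psi <- rep(NA_real_, nres)
  for (i in seq_len(nres)) {
    Cm <- if (i > 1) get(i - 1, "C") else NULL
    N <- get(i, "N"); CA <- get(i, "CA"); C <- get(i, "C")
    Np <- if (i < nres) get(i + 1, "N") else NULL
    if (!is.null(Cm) && !is.null(N) && !is.null(CA) && !is.null(C))
      phi[i] <- torsionAngle(Cm, N, CA, C)
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Np))
      psi[i] <- torsionAngle(N, CA, C, Np)
  }
  list(phi = phi, psi = psi)
}

# Place atom D given A-B-C, bond |C-D|, angle B-C-D and torsion A-B-C-D
# (natural extension reference frame).
placeAtom <- function(a, b, c0, bond, angle, torsion) {
  bc <- c0 - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c0 + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Standard backbone geometry constants (Angstrom / radians).
BB_GEOM <- list(
  bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231, bCACB = 1.521,
  aNCAC = 111.2 * pi / 180, aCACN = 116.2 * pi / 180,
  aCNCA = 121.7 * pi / 180, aCACO = 120.8 * pi / 180,
  aNCACB = 110.5 * pi / 180)

#' Build a backbone from phi/psi angles
#'
#' Internal-coordinate (NeRF-style) construction with standard bond lengths
#' and angles and trans peptide bonds.  `phi[1]` and `psi[length]` are not
#' used (undefined at the termini).  Carbonyl O atoms are placed anti to the
#' next residue's N; a CB is added (except for glycine) from the standard
#' tetrahedral geometry, so grafting and repack marking have a side-chain
#' stub to work with.
#'
#' @param phi,psi numeric vectors of equal length (radians).
#' @param sequence optional amino-acid string (controls glycine CB
#'   omission); defaults to alanines.
#' @param omega peptide-bond torsions, default all trans (pi).
#' @return data.frame `resIdx`, `atom`, `x`, `y`, `z`.
#' @export
makeBackbone <- function(phi, psi, sequence = NULL, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  if (is.null(omega)) omega <- rep(pi, n)
  aa <- if (is.null(sequence)) rep("A", n) else strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n)
  g <- BB_GEOM
  N <- CA <- C <- matrix(NA_real_, n, 3)
  # first residue in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  C[1, ] <- CA[1, ] + g$bCAC *
    c(-cos(g$aNCAC), sin(g$aNCAC), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      # N(i) from CA(i-1), C(i-1) with torsion psi(i-1)
      N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$bCN, g$aCACN, psi[i - 1])
      CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           g$bNCA, g$aCNCA, omega[i - 1])
      C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                          g$bCAC, g$aNCAC, phi[i])
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <-
      data.frame(resIdx = i, atom = c("N", "CA", "C"),
                 x = c(N[i, 1], CA[i, 1], C[i, 1]),
                 y = c(N[i, 2], CA[i, 2], C[i, 2]),
                 z = c(N[i, 3], CA[i, 3], C[i, 3]),
                 stringsAsFactors = FALSE)
    # carbonyl O: anti to N(i+1) (or a fixed torsion at the C terminus)
    oTor <- if (i < n) wrapAngle(psi[i] + pi) else -pi / 3
    O <- placeAtom(N[i, ], CA[i, ], C[i, ], g$bCO, g$aCACO, oTor)
    rows[[length(rows) + 1]] <-
      data.frame(resIdx = i, atom = "O", x = O[1], y = O[2], z = O[3],
                 stringsAsFactors = FALSE)
    if (aa[i] != "G") {
      # CB from the standard tetrahedral frame about CA
      CB <- placeAtom(C[i, ], N[i, ], CA[i, ], g$bCACB, g$aNCACB,
                      -122.6 * pi / 180)
      rows[[length(rows) + 1]] <-
        data.frame(resIdx = i, atom = "CB", x = CB[1], y = CB[2], z = CB[3],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over proper rotations and
#' translations, via SVD of the covariance with a reflection correction.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3,
#'   non-collinear).
#' @return A [SuperpositionResult-class]; apply with [applyTransform()]
#'   (`x' = x \%*\% rotation + translation`).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    fvError("fv_input", "coordinate sets must have equal size")
  if (nrow(mobile) < 3)
    fvError("fv_degenerate", "superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  mc <- sweep(mobile, 2, cm); rc <- sweep(reference, 2, cr)
  if (svd(mc)$d[2] < 1e-8 || svd(rc)$d[2] < 1e-8)
    fvError("fv_degenerate",
            "degenerate geometry: points are collinear or coincident")
  H <- t(mc) %*% rc
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- mc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cr - cm %*% R), rmsd = rmsd,
      nAtoms = nrow(mobile))
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param sp a [SuperpositionResult-class].
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp@rotation, 2, sp@translation, `+`)
}
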