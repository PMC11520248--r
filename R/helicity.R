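## Dihedral-window secondary-structure statistics for coarse-grained
## trajectories: phi/psi computation from backbone coordinates, the helical
## dihedral window, triplet alpha-helix assignment, per-residue propensities,
## region aggregation, and the backbone H-bond potential.

# torsion angle (degrees) for four points given as rows of a matrix
.dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1 * n1) < 1e-12 || sum(n2 * n2) < 1e-12) return(NA_real_)  # colinear
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone dihedral angles from backbone coordinates
#'
#' Computes phi(i) from C'(i-1)-N(i)-Ca(i)-C'(i) and psi(i) from
#' N(i)-Ca(i)-C'(i)-N(i+1). Angles undefined at chain termini, and angles
#' whose defining atoms are missing (`NA` coordinates) or degenerate
#' (colinear), are reported as `NA` rather than dropped.
#'
#' @param coords a 4-dimensional array `[frames, residues, atom, xyz]` with
#'   the atom dimension ordered N, Ca, C'; or a single-frame array
#'   `[residues, atom, xyz]`.
#' @param residueIds optional integer residue labels.
#' @return a [DihedralSeries-class].
#' @export
computeDihedrals <- function(coords, residueIds = NULL) {
  if (length(dim(coords)) == 3L)
    coords <- array(coords, c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 4L, dim(coords)[3] == 3L, dim(coords)[4] == 3L)
  nf <- dim(coords)[1]; nr <- dim(coords)[2]
  if (nr < 3L) stop("need at least 3 consecutive residues", call. = FALSE)
  phi <- matrix(NA_real_, nf, nr)
  psi <- matrix(NA_real_, nf, nr)
  for (f in seq_len(nf)) {
    N  <- coords[f, , 1L, , drop = TRUE]
    CA <- coords[f, , 2L, , drop = TRUE]
    CP <- coords[f, , 3L, , drop = TRUE]
    for (i in seq_len(nr)) {
      if (i > 1L) {
        pts <- rbind(CP[i - 1L, ], N[i, ], CA[i, ], CP[i, ])
        if (!anyNA(pts)) phi[f, i] <- .dihedral4(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      }
      if (i < nr) {
        pts <- rbind(N[i, ], CA[i, ], CP[i, ], N[i + 1L, ])
        if (!anyNA(pts)) psi[f, i] <- .dihedral4(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      }
    }
  }
  if (is.null(residueIds)) residueIds <- seq_len(nr)
  DihedralSeries(phi, psi, residueIds)
}

#' Read a long-format dihedral table
#'
#' Expects a delimited text file with columns `frame`, `residue`, `phi`,
#' `psi` (header required). Missing (frame, residue) combinations become
#' `NA` angles.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return a [DihedralSeries-class].
#' @export
readDihedralTable <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("frame", "residue", "phi", "psi") %in% names(tab)))
  frames <- sort(unique(tab$frame))
  resid <- sort(unique(tab$residue))
  phi <- matrix(NA_real_, length(frames), length(resid))
  psi <- matrix(NA_real_, length(frames), length(resid))
  fi <- match(tab$frame, frames); ri <- match(tab$residue, resid)
  phi[cbind(fi, ri)] <- tab$phi
  psi[cbind(fi, ri)] <- tab$psi
  DihedralSeries(phi, psi, resid)
}

#' Helical-form test on backbone dihedral angles
#'
#' A residue is in helical form iff its phi angle lies strictly between -160
#' and -20 degrees and its psi angle strictly between -120 and 50 degrees.
#' Undefined (`NA`) angles are never helical.
#'
#' @param phi,psi numeric angles in degrees (vectorized).
#' @return logical vector.
#' @export
isHelicalForm <- function(phi, psi) {
  ok <- !is.na(phi) & !is.na(psi) &
    phi > -160 & phi < -20 & psi > -120 & psi < 50
  ok
}

#' Triplet alpha-helix assignment
#'
#' A residue is part of an alpha-helix iff it and both its neighbours are in
#' helical form; terminal residues are never alpha-helical.
#'
#' @param formFlags logical per-residue helical-form flags for one frame.
#' @return logical vector, same length.
#' @export
assignAlphaHelix <- function(formFlags) {
  flags <- !is.na(formFlags) & formFlags
  n <- length(flags)
  if (n < 3L) return(rep(FALSE, n))
  flags & c(FALSE, flags[-n]) & c(flags[-1L], FALSE)
}

#' Per-residue helical propensity over trajectory frames
#'
#' The fraction of frames in which each residue is part of an alpha-helix
#' (triplet rule). Missing dihedrals count as non-helical; the denominator is
#' always the total number of frames.
#'
#' @param series a [DihedralSeries-class].
#' @return a [HelicityProfile-class].
#' @export
helicalPropensityProfile <- function(series) {
  stopifnot(is(series, "DihedralSeries"))
  nf <- nrow(series@phi)
  if (nf < 1L) stop("need at least one frame", call. = FALSE)
  form <- matrix(isHelicalForm(series@phi, series@psi), nf)
  alpha <- t(apply(form, 1L, assignAlphaHelix))
  if (nf == 1L) alpha <- matrix(alpha, 1L)  # apply drops dims for one row
  new("HelicityProfile", propensity = colMeans(alpha),
      nFrames = as.integer(nf), residueIds = series@residueIds)
}

#' Mean helical propensity per named region
#'
#' @param profile a [HelicityProfile-class].
#' @param regions named list of length-2 numeric ranges of residue ids, e.g.
#'   `list(a0_3 = c(1, 156), a4_6 = c(157, 267))`.
#' @return named numeric vector of unweighted per-region mean propensities.
#' @export
regionHelicity <- function(profile, regions) {
  stopifnot(is(profile, "HelicityProfile"), is.list(regions))
  vapply(regions, function(rg) {
    inRegion <- profile@residueIds >= rg[1] & profile@residueIds <= rg[2]
    if (!any(inRegion))
      stop("region [", rg[1], ", ", rg[2], "] contains no residues", call. = FALSE)
    if (rg[2] > max(profile@residueIds) || rg[1] < min(profile@residueIds))
      stop("region [", rg[1], ", ", rg[2], "] extends beyond the chain", call. = FALSE)
    mean(profile@propensity[inRegion])
  }, numeric(1))
}

#' Coarse-grained backbone hydrogen-bond potential
#'
#' V(r, thetaN, thetaC) = lambda * eps * (5 (sigma/r)^12 - 6 (sigma/r)^10) *
#' cos^2(thetaN) * cos^2(thetaC) for |thetaN|, |thetaC| < 90 degrees and 0
#' otherwise. At r = sigma and aligned angles the minimum is -lambda * eps;
#' `lambda < 1` mimics urea-weakened hydrogen bonds.
#'
#' @param r donor-acceptor distance(s), > 0 (same units as `sigmaHb`).
#' @param params an [HBondParams-class].
#' @param thetaN,thetaC angles in degrees.
#' @return numeric potential energy, vectorized over `r`.
#' @export
hbondPotential <- function(r, params, thetaN = 0, thetaC = 0) {
  stopifnot(is(params, "HBondParams"))
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (abs(thetaN) >= 90 || abs(thetaC) >= 90) return(rep(0, length(r)))
  sr <- params@sigmaHb / r
  ang <- cos(thetaN * pi / 180)^2 * cos(thetaC * pi / 180)^2
  params@lambda * params@epsilonHb * (5 * sr^12 - 6 * sr^10) * ang
}

#' Ideal alpha-helix backbone coordinates
#'
#' Builds N/Ca/C' backbone coordinates for a chain with constant canonical
#' dihedrals (phi = -57, psi = -47, omega = 180 by default) using standard
#' bond lengths and angles, replicated over `nFrames` identical frames.
#' Useful as a geometric ground truth: [computeDihedrals()] on the result
#' returns the requested angles for interior residues.
#'
#' @param nRes number of residues.
#' @param phi,psi,omega backbone dihedrals in degrees (scalars or per-residue
#'   vectors).
#' @param nFrames number of identical frames.
#' @return array `[nFrames, nRes, 3 (N, Ca, C'), 3 (xyz)]`.
#' @export
idealHelixCoords <- function(nRes, phi = -57, psi = -47, omega = 180,
                             nFrames = 1L) {
  phi <- rep_len(phi, nRes); psi <- rep_len(psi, nRes); omega <- rep_len(omega, nRes)
  ## internal coordinates: bond lengths (A) and angles (deg) of the backbone
  bNC <- 1.329; bNCa <- 1.458; bCaC <- 1.525
  aCNCa <- 121.7; aNCaC <- 111.2; aCaCN <- 116.2
  place <- function(a, b, c, bond, angle, torsion) {
    ## natural extension: position d given three previous atoms
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
  }
  atoms <- matrix(NA_real_, nRes * 3L, 3L)  # N, Ca, C' per residue
  atoms[1L, ] <- c(0, 0, 0)
  atoms[2L, ] <- c(bNCa, 0, 0)
  a <- aNCaC * pi / 180
  atoms[3L, ] <- atoms[2L, ] + bCaC * c(-cos(a), sin(a), 0)
  idx <- function(res, atom) (res - 1L) * 3L + atom
  for (i in 2L:nRes) {
    atoms[idx(i, 1L), ] <- place(atoms[idx(i - 1L, 1L), ], atoms[idx(i - 1L, 2L), ],
                                 atoms[idx(i - 1L, 3L), ], bNC, aCaCN, psi[i - 1L])
    atoms[idx(i, 2L), ] <- place(atoms[idx(i - 1L, 2L), ], atoms[idx(i - 1L, 3L), ],
                                 atoms[idx(i, 1L), ], bNCa, aCNCa, omega[i - 1L])
    atoms[idx(i, 3L), ] <- place(atoms[idx(i - 1L, 3L), ], atoms[idx(i, 1L), ],
                                 atoms[idx(i, 2L), ], bCaC, aNCaC, phi[i])
  }
  out <- array(NA_real_, c(nFrames, nRes, 3L, 3L))
  for (f in seq_len(nFrames))
    for (i in seq_len(nRes))
      for (at in 1:3) out[f, i, at, ] <- atoms[idx(i, at), ]
  out
}
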