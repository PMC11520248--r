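## Shrake-Rupley solvent-accessible surface area and the Trp-indole context
## comparison (full assembly vs isolated coiled-coil vs single helix), plus
## a programmatically built synthetic Trp-pocket structure used when the
## deposited barrel structure is unavailable.

# deterministic quasi-uniform unit-sphere points (golden spiral)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Read heavy atoms from a PDB file
#'
#' Parses a PDB file with `bio3d` and returns the heavy (non-hydrogen) atoms
#' as an [AtomSet-class].
#'
#' @param path PDB file path.
#' @param radii named vdW radii; defaults to [defaultVdwRadii()].
#' @return an [AtomSet-class].
#' @export
readAtomSet <- function(path, radii = defaultVdwRadii()) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- elem != "H"
  AtomSet(data.frame(
    element = elem[keep], name = trimws(at$elety)[keep],
    resid = at$resno[keep], resname = trimws(at$resid)[keep],
    chain = at$chain[keep], x = at$x[keep], y = at$y[keep], z = at$z[keep],
    stringsAsFactors = FALSE), radii = radii)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by sampling `nPoints`
#' quasi-uniform points on each atom's solvent-accessible sphere (radius =
#' vdW radius + probe radius) and counting points not inside any other
#' atom's accessible sphere. Points exactly on a neighbour's surface count as
#' accessible, so coincident identical atoms are well defined (each keeps
#' the points it owns).
#'
#' @param atoms an [AtomSet-class].
#' @param probeRadius solvent probe radius in Angstrom (default 1.4, water).
#' @param nPoints sample points per atom (default 960).
#' @return numeric per-atom areas in Angstrom^2 (named by atom name), in the
#'   row order of `atomTable(atoms)`.
#' @export
shrakeRupley <- function(atoms, probeRadius = 1.4, nPoints = 960L) {
  stopifnot(is(atoms, "AtomSet"), nrow(atoms@atoms) >= 1L)
  tab <- atoms@atoms
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  rad <- unname(atoms@radii[tab$element]) + probeRadius
  n <- nrow(xyz)
  sph <- .spherePoints(nPoints)
  areas <- numeric(n)
  maxR <- max(rad)
  ## deterministic per-atom orientation of the point sphere: decorrelates
  ## the sampling error across atoms so sums over atom groups converge
  ## faster than the per-atom error
  ga <- pi * (3 - sqrt(5))
  rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  for (i in seq_len(n)) {
    sphI <- sph %*% (rotZ(i * ga) %*% rotX(i * ga * 0.7))
    ## neighbour candidates within the maximal occlusion distance
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    pts <- sweep(sphI * rad[i], 2L, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
               (pts[, 3] - xyz[j, 3])^2
        free <- free & dj2 >= rad[j]^2
        if (!any(free)) break
      }
      acc <- sum(free)
    } else acc <- nPoints
    areas[i] <- 4 * pi * rad[i]^2 * acc / nPoints
  }
  names(areas) <- tab$name
  areas
}

.indoleAtoms <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")

#' Tryptophan indole SASA in a structural context
#'
#' Sums the Shrake-Rupley areas of the nine indole-ring atoms (CG, CD1, CD2,
#' NE1, CE2, CE3, CZ2, CZ3, CH2) of one Trp residue, computed within one of
#' three atomic contexts: the full assembly, the isolated chain restricted to
#' its coiled-coil hairpin, or the single helix carrying the Trp. Shrinking
#' the context can only expose the indole further, so areas are ordered
#' full_assembly <= coiled_coil_chain <= single_helix.
#'
#' @param structure an [AtomSet-class] containing at least the Trp residue.
#' @param chain chain id of the Trp.
#' @param resid residue id of the Trp.
#' @param context `"full_assembly"`, `"coiled_coil_chain"` or
#'   `"single_helix"`.
#' @param coiledCoilRange residue-id range kept in the coiled-coil context
#'   (default 26-156, the helical-hairpin construct boundaries).
#' @param helixRange residue-id range kept in the single-helix context; must
#'   contain `resid`.
#' @param probeRadius,nPoints passed to [shrakeRupley()].
#' @return indole SASA in Angstrom^2.
#' @export
trpIndoleSasa <- function(structure, chain, resid,
                          context = c("full_assembly", "coiled_coil_chain",
                                      "single_helix"),
                          coiledCoilRange = c(26, 156),
                          helixRange = c(26, 95),
                          probeRadius = 1.4, nPoints = 960L) {
  context <- match.arg(context)
  stopifnot(is(structure, "AtomSet"))
  tab <- structure@atoms
  isTrp <- tab$chain == chain & tab$resid == resid
  if (!any(isTrp)) stop("residue not found", call. = FALSE)
  if (!all(tab$resname[isTrp] == "TRP"))
    stop("residue ", resid, " of chain ", chain, " is not Trp", call. = FALSE)
  if (!all(.indoleAtoms %in% tab$name[isTrp]))
    stop("Trp side chain incomplete: missing ",
         paste(setdiff(.indoleAtoms, tab$name[isTrp]), collapse = ", "),
         call. = FALSE)
  keep <- switch(context,
    full_assembly = rep(TRUE, nrow(tab)),
    coiled_coil_chain = tab$chain == chain &
      tab$resid >= coiledCoilRange[1] & tab$resid <= coiledCoilRange[2],
    single_helix = tab$chain == chain &
      tab$resid >= helixRange[1] & tab$resid <= helixRange[2])
  if (!all(which(isTrp) %in% which(keep)))
    stop("context does not contain the Trp residue", call. = FALSE)
  sub <- AtomSet(tab[keep, , drop = FALSE], radii = structure@radii)
  areas <- shrakeRupley(sub, probeRadius = probeRadius, nPoints = nPoints)
  stab <- sub@atoms
  sel <- stab$chain == chain & stab$resid == resid & stab$name %in% .indoleAtoms
  sum(areas[sel])
}

#' SASA of a free tryptophan indole ring
#'
#' Builds a lone Trp residue (backbone plus full side chain) in free space
#' and returns its indole SASA: the maximal reference exposure against which
#' context values can be compared.
#'
#' @param probeRadius,nPoints passed to [shrakeRupley()].
#' @return indole SASA in Angstrom^2.
#' @export
freeIndoleSasa <- function(probeRadius = 1.4, nPoints = 960L) {
  trp <- .trpTemplate()
  atoms <- AtomSet(data.frame(
    element = trp$element, name = trp$name, resid = 1L, resname = "TRP",
    chain = "A", x = trp$x, y = trp$y, z = trp$z, stringsAsFactors = FALSE))
  areas <- shrakeRupley(atoms, probeRadius = probeRadius, nPoints = nPoints)
  sum(areas[atoms@atoms$name %in% .indoleAtoms])
}

## Trp residue template in a local frame: CA at the origin, side chain
## reaching into +x (and slightly +z). The indole is an idealized planar
## fused pentagon/hexagon with 1.40 A aromatic bonds; the ring plane
## contains the x and z axes.
.trpTemplate <- function() {
  hex <- t(vapply(0:5, function(k) {
    a <- pi / 3 * k
    1.40 * c(cos(a), sin(a))
  }, numeric(2)))
  ## hexagon vertices in order: CD2, CE2, CZ2, CH2, CZ3, CE3
  hex <- sweep(hex, 2L, hex[1, ])             # CD2 at the 2D origin
  e1 <- (hex[2, ] - hex[1, ]) / 1.40          # CD2 -> CE2 unit vector
  mid <- (hex[1, ] + hex[2, ]) / 2
  perp <- c(e1[2], -e1[1])
  if (sum((mid + perp - colMeans(hex))^2) < sum((mid - perp - colMeans(hex))^2))
    perp <- -perp                             # point away from the hexagon
  ## pentagon on the shared CD2-CE2 edge: CG (next to CD2), NE1 (next to
  ## CE2), CD1 at the apex; regular pentagon with side 1.40
  cg  <- hex[1, ] - e1 * 1.40 * cos(2 * pi / 5) + perp * 1.40 * sin(2 * pi / 5)
  ne1 <- hex[2, ] + e1 * 1.40 * cos(2 * pi / 5) + perp * 1.40 * sin(2 * pi / 5)
  ## apex at base midpoint + (apothem + circumradius) along perp
  cd1 <- mid + perp * (1.40 / (2 * tan(pi / 5)) + 1.40 / (2 * sin(pi / 5)))
  ring <- rbind(hex, cg, cd1, ne1)
  nm <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3", "CG", "CD1", "NE1")
  ## orient in 2D: put CG at the origin with the ring centroid along +u
  ring <- sweep(ring, 2L, ring[7, ])
  u <- colMeans(ring); u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1])
  ring2 <- cbind(ring %*% u, ring %*% v)      # (along-ring, across-ring)
  ## 3D frame: CA origin, CB up +z, CG out at (0.85, 0, 2.35); ring plane
  ## spanned by e1 = (outward+up) and e2 = z x e1 rotated into the xz-plane
  cg3 <- c(0.85, 0, 2.35)
  a1 <- c(0.92, 0, 0.39); a1 <- a1 / sqrt(sum(a1^2))   # mostly +x
  a2 <- c(-0.39, 0, 0.92)                              # in-plane, +z
  xyz <- t(apply(ring2, 1L, function(p) cg3 + p[1] * a1 + p[2] * a2))
  data.frame(
    name = c(nm, "CB", "CA", "N", "C", "O"),
    element = c(substr(nm, 1, 1), "C", "C", "N", "C", "O"),
    x = c(xyz[, 1], 0.45, 0, -1.20, 0.50, 1.55),
    y = c(xyz[, 2], 0.05, 0, 0.75, -1.25, -1.40),
    z = c(xyz[, 3], 1.45, 0, -0.45, -0.55, -0.15),
    stringsAsFactors = FALSE)
}

#' Synthetic Trp-pocket structure (stand-in, not a deposited structure)
#'
#' Programmatically builds an idealized structure emulating the three
#' contexts of the Trp71 indole: a two-helix hairpin (chain `"A"`, the
#' "coiled-coil") whose first helix carries a full-atom Trp pointing into
#' the inter-helix groove, surrounded by four neighbour helices (chains
#' `"B"`-`"E"`) that close a pocket around the indole as neighbouring
#' protomers do in the oligomeric barrel. All coordinates are generated from
#' ideal helix geometry; this object is explicitly synthetic and is used for
#' method validation when no deposited structure is available.
#'
#' Context conventions for [trpIndoleSasa()] on this structure: the Trp sits
#' at residue 15 of chain `"A"`; `helixRange = c(1, 30)` selects the
#' Trp-carrying helix alone and `coiledCoilRange = c(1, 60)` the hairpin.
#'
#' @return an [AtomSet-class].
#' @export
syntheticTrpPocket <- function() {
  mkHelix <- function(nRes, chain, residOffset = 0L, origin = c(0, 0, 0),
                      axis = c(0, 0, 1), flip = FALSE) {
    co <- idealHelixCoords(nRes)[1, , , ]
    ## backbone frame: helix axis is roughly z after centering; rotate to axis
    ctr <- colMeans(co[, 2, ])
    xyz <- NULL
    nm <- NULL; el <- NULL; rs <- NULL
    ## fit the helix axis from Ca positions (first principal component)
    cas <- co[, 2, ]
    pc <- prcomp(cas)$rotation[, 1]
    if (pc[3] < 0) pc <- -pc
    rotTo <- function(v, w) {   # rotation matrix taking unit v to unit w
      v <- v / sqrt(sum(v^2)); w <- w / sqrt(sum(w^2))
      cr <- c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3],
              v[1] * w[2] - v[2] * w[1])
      cc <- sum(v * w)
      if (sum(cr^2) < 1e-12) {
        if (cc > 0) return(diag(3))
        ## 180 degree flip about any perpendicular axis
        p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        p <- p - sum(p * v) * v; p <- p / sqrt(sum(p^2))
        return(2 * outer(p, p) - diag(3))
      }
      K <- matrix(c(0, cr[3], -cr[2], -cr[3], 0, cr[1], cr[2], -cr[1], 0), 3, 3)
      diag(3) + K + K %*% K / (1 + cc)
    }
    ax <- if (flip) -axis else axis
    R <- rotTo(pc, ax)
    for (i in seq_len(nRes)) {
      for (at in 1:3) {
        xyz <- rbind(xyz, as.numeric(R %*% (co[i, at, ] - ctr)) + origin)
        nm <- c(nm, c("N", "CA", "C")[at])
        el <- c(el, c("N", "C", "C")[at])
        rs <- c(rs, i + residOffset)
      }
    }
    data.frame(element = el, name = nm, resid = as.integer(rs),
               resname = "ALA", chain = chain,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }

  h1 <- mkHelix(30L, "A", 0L, origin = c(0, 0, 0))

  ## radial (outward) direction of the Trp CA, in the helix cross-section
  caRow <- which(h1$resid == 15L & h1$name == "CA")
  ca <- as.numeric(h1[caRow, c("x", "y", "z")])
  rhat <- c(ca[1], ca[2], 0); rhat <- rhat / sqrt(sum(rhat^2))
  that <- c(-rhat[2], rhat[1], 0)             # tangential direction

  ## graft the Trp side chain: template +x (side-chain reach) onto rhat
  trp <- .trpTemplate()
  Rz <- cbind(rhat, that, c(0, 0, 1))         # maps ex->rhat, ey->that
  side <- trp$name %in% c(.indoleAtoms, "CB")
  tpl <- as.matrix(trp[side, c("x", "y", "z")])
  grafted <- t(Rz %*% t(tpl)) + matrix(ca, sum(side), 3, byrow = TRUE)
  trpRows <- data.frame(
    element = trp$element[side], name = trp$name[side], resid = 15L,
    resname = "TRP", chain = "A",
    x = grafted[, 1], y = grafted[, 2], z = grafted[, 3],
    stringsAsFactors = FALSE)
  indoleCtr <- colMeans(grafted[trp$name[side] %in% .indoleAtoms, ])

  ## partner helix of the hairpin: across the groove from the indole
  h2 <- mkHelix(30L, "A", 30L,
                origin = c(ca[1:2] + rhat[1:2] * 9.5, 0), flip = TRUE)
  ## neighbour helices of other protomers closing the pocket sides
  nb <- rbind(
    mkHelix(26L, "B", 0L, origin = c(ca[1:2] + rhat[1:2] * 4.6 + that[1:2] * 7.2, 0)),
    mkHelix(26L, "C", 0L, origin = c(ca[1:2] + rhat[1:2] * 4.6 - that[1:2] * 7.2, 0),
            flip = TRUE),
    mkHelix(26L, "D", 0L, origin = c(ca[1:2] + rhat[1:2] * 9.8 + that[1:2] * 6.8, 0)),
    mkHelix(26L, "E", 0L, origin = c(ca[1:2] + rhat[1:2] * 9.8 - that[1:2] * 6.8, 0),
            flip = TRUE))

  allAtoms <- rbind(h1, trpRows, h2, nb)
  allAtoms$resname[allAtoms$chain == "A" & allAtoms$resid == 15L] <- "TRP"
  AtomSet(allAtoms)
}
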