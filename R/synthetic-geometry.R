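# Synthetic geometry fixtures: idealized sp2 groups at controlled
# separations and orientations, plus random group fields for property tests.

# Ideal aromatic six-ring (C-C 1.39 angstrom) in the z = 0 plane, centered at
# the origin. Atom order follows ring adjacency.
idealRingCoords <- function() {
  ang <- c(CG = 180, CD1 = 120, CD2 = -120, CE1 = 60, CE2 = -60, CZ = 0)
  r <- 1.39
  m <- cbind(r * cos(ang * pi / 180), r * sin(ang * pi / 180), 0)
  rownames(m) <- names(ang)
  m
}

# Planar trans peptide unit (C-N 1.33 angstrom) in the z = 0 plane, centered
# on the amide bond midpoint.
idealPeptideCoords <- function() {
  m <- rbind(
    CA_i = c(-0.62, -1.39, 0),
    C_i = c(0, 0, 0),
    O_i = c(-0.67, 1.03, 0),
    N_ip1 = c(1.33, 0, 0),
    CA_ip1 = c(2.10, 1.24, 0))
  sweep(m, 2, c(0.665, 0, 0))  # center on the C-N bond midpoint
}

# Planar guanidinium group (Arg) in the z = 0 plane, centered on CZ.
idealGuanidiniumCoords <- function() {
  ang <- c(NE = 90, NH1 = 210, NH2 = 330)
  m <- rbind(c(0, 0, 0),
             1.33 * cbind(cos(ang * pi / 180), sin(ang * pi / 180), 0))
  rownames(m) <- c("CZ", "NE", "NH1", "NH2")
  m
}

groupTemplate <- function(identity) {
  switch(identity,
    F = , Y = list(coords = idealRingCoords(), triple = c("CG", "CD1", "CD2"),
                   category = "sidechain", aromatic = TRUE, carbonCount = 6L,
                   resid = if (identity == "F") "PHE" else "TYR"),
    R = list(coords = idealGuanidiniumCoords(),
             triple = c("NE", "CZ", "NH1"), category = "sidechain",
             aromatic = FALSE, carbonCount = 1L, resid = "ARG"),
    PEPTIDE = list(coords = idealPeptideCoords(),
                   triple = c("O_i", "C_i", "N_ip1"), category = "backbone",
                   aromatic = FALSE, carbonCount = 3L, resid = "GLY"),
    stop("unsupported fixture identity: ", identity)
  )
}

#' Build a stacked pair of planar groups at controlled geometry
#'
#' Places two idealized planar groups with the plane of the second lifted
#' \code{gap} angstrom along the first group's normal, displaced \code{offset}
#' angstrom in-plane, and tilted \code{tilt} degrees about an in-plane axis.
#' The geometry parameters are reproduced exactly in the returned
#' coordinates.
#'
#' @param identityA,identityB group identities ("F", "Y", "R" or "PEPTIDE").
#' @param gap inter-plane separation along the first normal, angstrom
#'   (must be non-negative).
#' @param offset in-plane centroid displacement, angstrom.
#' @param tilt rotation of the second group about the in-plane x axis,
#'   degrees; the absolute normal dot product is cos(tilt).
#' @param sameChain place both groups in one chain (sequence separation 20)
#'   or in chains A and B.
#' @param unitCell optional numeric(6) cell written into the model.
#' @param symOpsXyz optional fractional symmetry operator strings stored as
#'   orthogonal-frame operators on the model.
#' @return a \linkS4class{StructureModel} containing only the group atoms.
#' @examples
#' makeStackedPair(gap = 3.5)                 # accepted contact geometry
#' makeStackedPair(gap = 3.5, tilt = 40)      # fails the |dot| >= 0.8 test
#' @export
makeStackedPair <- function(identityA = "F", identityB = "F", gap = 3.5,
                            offset = 0, tilt = 0, sameChain = TRUE,
                            unitCell = numeric(0), symOpsXyz = NULL) {
  if (gap < 0) stop("impossible geometry: negative inter-plane gap")
  ta <- groupTemplate(identityA)
  tb <- groupTemplate(identityB)
  coA <- ta$coords
  R <- axisRotation(c(1, 0, 0), tilt * pi / 180)
  coB <- tb$coords %*% t(R)
  coB <- sweep(coB, 2, c(offset, 0, gap), "+")
  rownames(coB) <- rownames(tb$coords)

  fixName <- function(nm) sub("_(i|ip1)$", "", nm)
  chainB <- if (sameChain) "A" else "B"
  resnoA <- if (ta$category == "backbone") rep(c(10L, 11L),
    c(3L, 2L)) else rep(10L, nrow(coA))
  baseB <- if (sameChain) 30L else 10L
  resnoB <- if (tb$category == "backbone") rep(c(baseB, baseB + 1L),
    c(3L, 2L)) else rep(baseB, nrow(coB))

  ops <- list()
  if (length(unitCell)) {
    if (is.null(symOpsXyz)) symOpsXyz <- "X,Y,Z"
    M <- cellOrthMatrix(unitCell)
    Minv <- solve(M)
    ops <- lapply(symOpsXyz, function(s) {
      fo <- parseSymopXyz(s)
      list(R = M %*% fo$R %*% Minv, t = as.numeric(M %*% fo$t))
    })
  }
  structureFromAtoms(
    elety = c(fixName(rownames(coA)), fixName(rownames(coB))),
    resid = c(rep(ta$resid, nrow(coA)), rep(tb$resid, nrow(coB))),
    chain = c(rep("A", nrow(coA)), rep(chainB, nrow(coB))),
    resno = c(resnoA, resnoB),
    xyz = rbind(coA, coB),
    unitCell = unitCell, symmetryOps = ops,
    source = sprintf("stacked_%s_%s_gap%.2f_off%.2f_tilt%.1f",
                     identityA, identityB, gap, offset, tilt))
}

#' Build an idealized tripeptide fixture
#'
#' An extended idealized backbone with optional sp2/sp3 sidechain groups and
#' a C-terminal OXT, used to test group extraction and involvement counting.
#' Only atoms that participate in group definitions are placed.
#'
#' @param seq one-letter sequence (supported sidechains: F, Y, L, A, G and
#'   any residue treated as glycine-like otherwise).
#' @param withOXT add the C-terminal carboxyl OXT.
#' @param dropAtoms character vector of "resno:atomname" entries to omit
#'   (e.g. \code{"2:CZ"}), for incomplete-group tests.
#' @param chainBreakAfter optional residue position after which the remainder
#'   of the chain is translated far away (breaks peptide connectivity).
#' @return a \linkS4class{StructureModel}.
#' @export
makeIdealPeptide <- function(seq = "GFG", withOXT = TRUE,
                             dropAtoms = character(0),
                             chainBreakAfter = NA_integer_) {
  aas <- strsplit(seq, "")[[1]]
  n <- length(aas)
  elety <- character(0); resid <- character(0); resno <- integer(0)
  xyz <- NULL
  add <- function(names, res3, k, co) {
    keep <- !(paste0(k, ":", names) %in% dropAtoms)
    elety <<- c(elety, names[keep])
    resid <<- c(resid, rep(res3, sum(keep)))
    resno <<- c(resno, rep(k, sum(keep)))
    xyz <<- rbind(xyz, co[keep, , drop = FALSE])
  }
  for (k in seq_len(n)) {
    shift <- c(3.8 * (k - 1) +
                 if (!is.na(chainBreakAfter) && k > chainBreakAfter) 50 else 0,
               0, 0)
    bb <- rbind(N = c(-1.3, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0),
                O = c(1.2, 2.03, 0))
    bb <- sweep(bb, 2, shift, "+")
    res3 <- if (aas[k] %in% names(aaThree)) aaThree[aas[k]] else "GLY"
    add(rownames(bb), res3, k, bb)
    if (aas[k] %in% c("F", "Y")) {
      ring <- sweep(idealRingCoords(), 2, shift + c(0, 0, 2.8), "+")
      add(rownames(ring), res3, k, ring)
    } else if (aas[k] == "L") {
      sc <- rbind(CG = c(0, -1.0, 1.0), CD1 = c(-1.2, -1.6, 1.6),
                  CD2 = c(1.2, -1.6, 1.6))
      add(rownames(sc), res3, k, sweep(sc, 2, shift, "+"))
    } else if (aas[k] == "K") {
      sc <- rbind(CD = c(0, -1.0, 1.0), CE = c(0, -1.8, 2.2),
                  NZ = c(1.1, -2.5, 2.8))
      add(rownames(sc), res3, k, sweep(sc, 2, shift, "+"))
    }
    if (withOXT && k == n) {
      add("OXT", res3, k,
          matrix(c(2.3, 0.2, 0) + shift, 1, 3,
                 dimnames = list("OXT", NULL)))
    }
  }
  structureFromAtoms(elety, resid, chain = rep("A", length(elety)),
                     resno = resno, xyz = xyz,
                     source = paste0("peptide_", seq))
}

#' Scatter waters around a structure
#'
#' Adds \code{n} water oxygens at seeded random positions between
#' \code{rmin} and \code{rmax} angstrom from a reference atom, for testing
#' water contact counting.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param n number of waters.
#' @param rmin,rmax radial placement range, angstrom.
#' @param around index of the reference atom row (default 1).
#' @param seed RNG seed.
#' @return a new \linkS4class{StructureModel} including the waters.
#' @export
addWaterShell <- function(model, n, rmin = 3, rmax = 4, around = 1L,
                          seed = 1L) {
  atoms <- model@atoms
  ref <- as.numeric(atoms[around, c("x", "y", "z")])
  withSeed(seed, {
    dir <- matrix(stats::rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- stats::runif(n, rmin, rmax)
  })
  co <- sweep(dir * r, 2, ref, "+")
  wat <- data.frame(
    elety = "O", alt = "", resid = "HOH", chain = "W",
    resno = seq_len(n) + 1000L, insert = "",
    x = co[, 1], y = co[, 2], z = co[, 3], o = 1, elesy = "O",
    isWater = TRUE, isH = FALSE, resIndex = NA_integer_,
    stringsAsFactors = FALSE)
  out <- model
  out@atoms <- rbind(atoms, wat)
  out
}

#' Random field of planar groups
#'
#' Draws \code{nGroups} idealized planar groups (aromatic rings, peptide
#' units, guanidinium groups) at seeded uniform positions and orientations in
#' a cubic box, returning them directly as a \linkS4class{Sp2GroupSet}.
#' Groups are spaced ten residue indices apart so that every intra-chain pair
#' is long-range.
#'
#' @param nGroups number of groups (at most 200 keeps tests fast).
#' @param box box edge length, angstrom.
#' @param seed RNG seed.
#' @param pSecondChain probability a group is placed in chain "B".
#' @return a \linkS4class{Sp2GroupSet}.
#' @export
makeRandomGroupField <- function(nGroups = 40, box = 30, seed = 1L,
                                 pSecondChain = 0.2) {
  ids <- c("F", "R", "PEPTIDE")
  rows <- list(); coordsL <- list(); normalsL <- list()
  withSeed(seed, {
    pick <- sample(ids, nGroups, replace = TRUE)
    chains <- ifelse(stats::runif(nGroups) < pSecondChain, "B", "A")
    for (k in seq_len(nGroups)) {
      tpl <- groupTemplate(pick[k])
      R <- randomRotation()
      co <- tpl$coords %*% t(R)
      co <- sweep(co, 2, stats::runif(3, 0, box), "+")
      rownames(co) <- rownames(tpl$coords)
      n <- planeNormal(co[tpl$triple, , drop = FALSE])
      identity <- pick[k]
      rows[[k]] <- data.frame(
        groupId = sprintf("%s:%d:%s", chains[k], k * 10L, identity),
        identity = identity,
        seqIdentity = if (identity == "PEPTIDE") "GG" else identity,
        category = tpl$category, aromatic = tpl$aromatic,
        carbonCount = tpl$carbonCount, chain = chains[k],
        resIndex = k * 10L, resno = k * 10L, stringsAsFactors = FALSE)
      coordsL[[k]] <- co
      normalsL[[k]] <- n
    }
  })
  newSp2GroupSet(rows, coordsL, normalsL, integer(0))
}
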