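# The planar pi-pi contact criterion and contact detection.

# Atom identity keys for one group (chain + residue + plain atom name);
# peptide-unit suffixes resolve to the flanking residue the atom belongs to.
groupAtomKeys <- function(memberNames, chain, resIndex) {
  res <- rep(resIndex, length(memberNames))
  res[grepl("_ip1$", memberNames)] <- resIndex + 1L
  paste(chain, res, sub("_(i|ip1)$", "", memberNames), sep = "\r")
}

# Heavy C/N/O member subset used for VDW distance measurements.
vdwAtoms <- function(coords) {
  el <- memberElement(rownames(coords))
  coords[el %in% c("C", "N", "O"), , drop = FALSE]
}

#' Count heavy-atom pairs in van der Waals contact
#'
#' Number of (atom in a, atom in b) pairs of C/N/O atoms within
#' \code{cutoff} angstrom (inclusive). Groups sharing any atom are never
#' contact candidates and return \code{NA}, the shared-atom sentinel.
#'
#' @param coordsA,coordsB member coordinate matrices with atom-name rownames.
#' @param cutoff VDW contact distance, angstrom.
#' @param keysA,keysB optional atom identity keys used to detect shared
#'   atoms (see \code{\link{detectContacts}}); when \code{NULL} the groups
#'   are assumed disjoint.
#' @return integer count, or \code{NA} when the groups share an atom.
#' @examples
#' a <- makeStackedPair(gap = 3.6)
#' g <- groupCoords(extractSp2Groups(a))
#' countVdwPairs(g[[1]], g[[2]])  # 36: all pairs of two stacked six-rings
#' @export
countVdwPairs <- function(coordsA, coordsB, cutoff = 4.9,
                          keysA = NULL, keysB = NULL) {
  if (!is.null(keysA) && !is.null(keysB) && length(intersect(keysA, keysB)))
    return(NA_integer_)
  sum(crossDist(vdwAtoms(coordsA), vdwAtoms(coordsB)) <= cutoff)
}

#' Distance between elevated planar surfaces
#'
#' For every atom of each group, points are constructed \code{elevation}
#' angstrom above and below the group plane along its unit normal; the
#' surface distance is the minimum distance between any elevated point of
#' one group and any elevated point of the other, over both normal signs.
#'
#' @param coordsA,coordsB member coordinate matrices.
#' @param normalA,normalB unit plane normals.
#' @param elevation height above the plane, angstrom.
#' @return minimum elevated-surface distance, angstrom.
#' @examples
#' m <- makeStackedPair(gap = 3.4)
#' g <- extractSp2Groups(m)
#' surfaceDistance(groupCoords(g)[[1]], groupNormals(g)[1, ],
#'                 groupCoords(g)[[2]], groupNormals(g)[2, ])  # 0
#' @export
surfaceDistance <- function(coordsA, normalA, coordsB, normalB,
                            elevation = 1.7) {
  upA <- sweep(coordsA, 2, elevation * normalA, "+")
  dnA <- sweep(coordsA, 2, elevation * normalA, "-")
  upB <- sweep(coordsB, 2, elevation * normalB, "+")
  dnB <- sweep(coordsB, 2, elevation * normalB, "-")
  min(minCrossDist(rbind(upA, dnA), rbind(upB, dnB)))
}

#' Evaluate the planar pi-pi contact criterion for one group pair
#'
#' A pair is a planar pi-pi contact when it has at least
#' \code{minAtomPairs} VDW atom pairs, elevated surfaces within
#' \code{surfaceCutoff}, and |normal dot product| at least \code{minAbsDot}
#' (all thresholds inclusive).
#'
#' @inheritParams countVdwPairs
#' @inheritParams surfaceDistance
#' @param criteria a \linkS4class{ContactCriteria}.
#' @return list with \code{contact} (logical), \code{nVdwPairs},
#'   \code{minAtomDistance}, \code{absDot}, \code{minSurfaceDistance}. The
#'   surface distance is only evaluated (non-NA) once the cheaper VDW-pair
#'   and normal-alignment criteria hold; the decision is unaffected.
#' @export
isPlanarPiContact <- function(coordsA, normalA, coordsB, normalB,
                              criteria = contactCriteria(),
                              keysA = NULL, keysB = NULL) {
  dists <- if (is.null(keysA) || is.null(keysB) ||
                 !length(intersect(keysA, keysB)))
    crossDist(vdwAtoms(coordsA), vdwAtoms(coordsB)) else NULL
  if (is.null(dists))
    return(list(contact = FALSE, nVdwPairs = NA_integer_,
                minAtomDistance = NA_real_, absDot = NA_real_,
                minSurfaceDistance = NA_real_))
  nPairs <- sum(dists <= criteria@vdwCutoff)
  absDot <- abs(sum(normalA * normalB))
  if (nPairs < criteria@minAtomPairs || absDot < criteria@minAbsDot)
    return(list(contact = FALSE, nVdwPairs = as.integer(nPairs),
                minAtomDistance = min(dists), absDot = absDot,
                minSurfaceDistance = NA_real_))
  surf <- surfaceDistance(coordsA, normalA, coordsB, normalB,
                          criteria@elevation)
  list(contact = surf <= criteria@surfaceCutoff,
       nVdwPairs = as.integer(nPairs), minAtomDistance = min(dists),
       absDot = absDot, minSurfaceDistance = surf)
}

# Contact rows between groups of set A (indices ia) and set B (indices ib).
# When B is A itself, only unordered pairs ia < ib are evaluated. A centroid
# neighbor prefilter bounds the candidate pairs; it is a strict superset of
# pairs with any atom pair within the cutoff, so results equal exhaustive
# search.
pairContacts <- function(gsA, gsB = NULL, criteria, chainClass = NULL,
                         symmetry = FALSE) {
  same <- is.null(gsB)
  if (same) gsB <- gsA
  ga <- gsA@groups; gb <- gsB@groups
  if (!nrow(ga) || !nrow(gb)) return(emptyContactDf())
  centA <- t(vapply(gsA@coords, colMeans, numeric(3)))
  centB <- t(vapply(gsB@coords, colMeans, numeric(3)))
  radA <- vapply(seq_along(gsA@coords), function(i)
    sqrt(max(rowSums(sweep(gsA@coords[[i]], 2, centA[i, ])^2))), numeric(1))
  radB <- vapply(seq_along(gsB@coords), function(i)
    sqrt(max(rowSums(sweep(gsB@coords[[i]], 2, centB[i, ])^2))), numeric(1))
  dd <- crossDist(centA, centB)
  lim <- outer(radA, radB, "+") + criteria@vdwCutoff
  cand <- which(dd <= lim, arr.ind = TRUE)
  if (same) cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (!nrow(cand)) return(emptyContactDf())

  keysA <- lapply(seq_len(nrow(ga)), function(i)
    groupAtomKeys(rownames(gsA@coords[[i]]), ga$chain[i], ga$resIndex[i]))
  keysB <- if (same) keysA else lapply(seq_len(nrow(gb)), function(i)
    groupAtomKeys(rownames(gsB@coords[[i]]), gb$chain[i], gb$resIndex[i]))

  rows <- vector("list", nrow(cand))
  nr <- 0L
  for (p in seq_len(nrow(cand))) {
    i <- cand[p, 1]; j <- cand[p, 2]
    if (same && excludedCovalentPair(ga[i, ], ga[j, ])) next
    res <- isPlanarPiContact(gsA@coords[[i]], gsA@normals[i, ],
                             gsB@coords[[j]], gsB@normals[j, ],
                             criteria, keysA[[i]], keysB[[j]])
    if (!res$contact) next
    a <- ga[i, ]; b <- gb[j, ]
    # deterministic ordering by (chain, resIndex, category); symmetry copies
    # always second
    if (same && orderKey(b) < orderKey(a)) { tmp <- a; a <- b; b <- tmp }
    sep <- if (!symmetry && a$chain == b$chain)
      abs(a$resIndex - b$resIndex) else Inf
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      idA = a$groupId, idB = b$groupId,
      identityA = a$identity, identityB = b$identity,
      seqIdentityA = a$seqIdentity, seqIdentityB = b$seqIdentity,
      categoryA = a$category, categoryB = b$category,
      aromaticA = a$aromatic, aromaticB = b$aromatic,
      chainA = a$chain, chainB = b$chain,
      resIndexA = a$resIndex, resIndexB = b$resIndex,
      nVdwPairs = res$nVdwPairs, minAtomDistance = res$minAtomDistance,
      absDot = res$absDot, minSurfaceDistance = res$minSurfaceDistance,
      seqSeparation = sep,
      rangeClass = if (is.finite(sep) && sep <= 4) "short" else "long",
      chainClass = if (symmetry) "symmetry"
      else if (a$chain == b$chain) "intra" else "inter_asu",
      stringsAsFactors = FALSE)
  }
  if (!nr) return(emptyContactDf())
  do.call(rbind, rows[seq_len(nr)])
}

orderKey <- function(g) paste(g$chain, sprintf("%09d", g$resIndex), g$category)

# Covalently bonded group pairs without shared atoms: the C-terminal carboxyl
# carbon is bonded to the CA inside the preceding peptide unit.
excludedCovalentPair <- function(a, b) {
  if (a$chain != b$chain) return(FALSE)
  (a$category == "cterm" && b$category == "backbone" &&
     b$resIndex == a$resIndex - 1L) ||
    (b$category == "cterm" && a$category == "backbone" &&
       a$resIndex == b$resIndex - 1L)
}

emptyContactDf <- function() {
  data.frame(idA = character(), idB = character(), identityA = character(),
             identityB = character(), seqIdentityA = character(),
             seqIdentityB = character(), categoryA = character(),
             categoryB = character(), aromaticA = logical(),
             aromaticB = logical(), chainA = character(),
             chainB = character(), resIndexA = integer(),
             resIndexB = integer(), nVdwPairs = integer(),
             minAtomDistance = numeric(), absDot = numeric(),
             minSurfaceDistance = numeric(), seqSeparation = numeric(),
             rangeClass = character(), chainClass = character(),
             stringsAsFactors = FALSE)
}

#' Detect planar pi-pi contacts
#'
#' For a \linkS4class{Sp2GroupSet}, evaluates the criterion over all group
#' pairs (centroid-prefiltered; results identical to exhaustive search). For
#' a \linkS4class{StructureModel}, groups are extracted first and, when
#' crystal records are present and \code{symmetry = TRUE}, contacts to
#' symmetry copies within \code{radius} angstrom are measured as well and
#' flagged \code{chainClass = "symmetry"}; symmetry atom pairs closer than
#' 1 angstrom are counted as clashes.
#'
#' @param x a \linkS4class{Sp2GroupSet} or \linkS4class{StructureModel}.
#' @param criteria a \linkS4class{ContactCriteria}.
#' @param ... passed on to methods.
#' @return a \linkS4class{PlanarContactSet}.
#' @examples
#' detectContacts(makeStackedPair(gap = 3.5))
#' @export
setGeneric("detectContacts",
           function(x, criteria = contactCriteria(), ...)
             standardGeneric("detectContacts"))

#' @rdname detectContacts
#' @export
setMethod("detectContacts", "Sp2GroupSet", function(x, criteria, ...) {
  new("PlanarContactSet", contacts = pairContacts(x, NULL, criteria),
      criteria = criteria, nGroups = nrow(x@groups), clashes = 0L)
})

#' @rdname detectContacts
#' @param symmetry also measure contacts to crystal symmetry copies.
#' @param radius symmetry neighbor inclusion radius, angstrom.
#' @param definitions group definition table.
#' @export
setMethod("detectContacts", "StructureModel",
          function(x, criteria, symmetry = TRUE, radius = 8,
                   definitions = sp2Definitions(), ...) {
  gs <- extractSp2Groups(x, definitions)
  ct <- pairContacts(gs, NULL, criteria)
  clashes <- 0L
  if (symmetry && length(x@unitCell) && length(x@symmetryOps)) {
    copies <- expandSymmetry(x, radius)
    heavy <- x@atoms[!x@atoms$isH & !x@atoms$isWater, c("x", "y", "z")]
    for (cp in copies) {
      cpModel <- x
      cpModel@atoms <- cp$atoms
      gsym <- extractSp2Groups(cpModel, definitions)
      if (nrow(gsym@groups)) {
        gsym@groups$groupId <- paste0(cp$label, ":", gsym@groups$groupId)
        gsym@groups$chain <- paste0(cp$label, ":", gsym@groups$chain)
        ct <- rbind(ct, pairContacts(gs, gsym, criteria, symmetry = TRUE))
      }
      ch <- cp$atoms[!cp$atoms$isH & !cp$atoms$isWater, c("x", "y", "z")]
      if (nrow(ch) && nrow(heavy))
        clashes <- clashes +
          sum(crossDist(as.matrix(ch), as.matrix(heavy)) < 1)
    }
  }
  rownames(ct) <- NULL
  new("PlanarContactSet", contacts = ct, criteria = criteria,
      nGroups = nrow(gs@groups), clashes = as.integer(clashes))
})

#' Count waters in contact with a residue
#'
#' Number of water oxygens (including symmetry-copy waters when crystal
#' records allow) with any distance at most \code{cutoff} angstrom to any
#' heavy atom of the residue. The boundary is inclusive.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain,resIndex residue selector.
#' @param cutoff contact distance, angstrom.
#' @param includeSymmetry include symmetry-expanded waters when available.
#' @param radius symmetry inclusion radius, angstrom.
#' @return integer count.
#' @export
waterContactCount <- function(model, chain, resIndex, cutoff = 4.9,
                              includeSymmetry = TRUE, radius = 8) {
  atoms <- model@atoms
  res <- atoms[atoms$chain == chain & !atoms$isWater & !atoms$isH &
                 atoms$resIndex == resIndex, c("x", "y", "z")]
  if (!nrow(res)) stop("no such residue: ", chain, "/", resIndex)
  watO <- atoms[atoms$isWater & atoms$elesy == "O", c("x", "y", "z")]
  if (includeSymmetry && length(model@unitCell) &&
      length(model@symmetryOps)) {
    for (cp in expandSymmetry(model, radius)) {
      w <- cp$atoms[cp$atoms$isWater & cp$atoms$elesy == "O",
                    c("x", "y", "z")]
      watO <- rbind(watO, w)
    }
  }
  if (!nrow(watO)) return(0L)
  d <- crossDist(as.matrix(watO), as.matrix(res))
  sum(apply(d, 1, min) <= cutoff)
}
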