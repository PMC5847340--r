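# Survey statistics over contact annotations: involvement frequencies,
# per-100-residue rates, resolution binning, bootstrap errors, solvation and
# secondary-structure profiles, interface breakdowns and sp3 controls.

# Unique (chainKey, resIndex) pairs involved in at least one planar contact.
# Backbone planar contacts involve both flanking residues. Contacts to
# symmetry partners are excluded from frequency statistics by default.
involvedResidues <- function(contacts, excludeSymmetry = TRUE,
                             category = c("any", "sidechain", "backbone")) {
  category <- match.arg(category)
  if (excludeSymmetry && nrow(contacts))
    contacts <- contacts[contacts$chainClass != "symmetry", , drop = FALSE]
  if (!nrow(contacts))
    return(data.frame(chainKey = character(), resIndex = integer()))
  side <- function(ck, idx, cat) {
    keep <- if (category == "any") rep(TRUE, length(cat))
    else if (category == "backbone") cat == "backbone"
    else cat %in% c("sidechain", "cterm")
    ck <- ck[keep]; idx <- idx[keep]; cat <- cat[keep]
    bb <- cat == "backbone"
    data.frame(chainKey = c(ck, ck[bb]),
               resIndex = c(idx, idx[bb] + 1L),
               stringsAsFactors = FALSE)
  }
  out <- rbind(side(contacts$chainKeyA, contacts$resIndexA,
                    contacts$categoryA),
               side(contacts$chainKeyB, contacts$resIndexB,
                    contacts$categoryB))
  unique(out)
}

#' Per-residue-type involvement frequency
#'
#' Fraction of residues of each amino-acid type contributing any atom to at
#' least one planar pi-pi contact; a residue participates through its
#' sidechain group, its C-terminal carboxyl, or either flanking backbone
#' peptide unit.
#'
#' @param ann a \linkS4class{ChainAnnotations}.
#' @param excludeSymmetry drop symmetry-partner contacts (the default
#'   convention for frequency statistics).
#' @return data.frame (aa, involved, total, frequency) with attributes
#'   \code{overall} (total involved / total residues) and \code{typeMean}
#'   (unweighted mean of per-type frequencies).
#' @export
involvementFrequency <- function(ann, excludeSymmetry = TRUE) {
  res <- ann@residues
  if (!nrow(res)) stop("insufficient data: no residues annotated")
  inv <- involvedResidues(ann@contacts, excludeSymmetry)
  hit <- paste(res$chainKey, res$resIndex) %in%
    paste(inv$chainKey, inv$resIndex)
  out <- do.call(rbind, lapply(STANDARD_AA, function(a) {
    sel <- res$aa == a
    data.frame(aa = a, involved = sum(hit & sel), total = sum(sel),
               frequency = if (sum(sel)) sum(hit & sel) / sum(sel)
               else NA_real_, stringsAsFactors = FALSE)
  }))
  attr(out, "overall") <- sum(hit) / nrow(res)
  attr(out, "typeMean") <- mean(out$frequency, na.rm = TRUE)
  out
}

# Group participations: each accepted contact contributes one participation
# per involved group. Contact classes partition by aromaticity of the two
# groups; backbone_backbone is the peptide-peptide subset.
participationCount <- function(contacts, class, excludeSymmetry = TRUE) {
  if (excludeSymmetry && nrow(contacts))
    contacts <- contacts[contacts$chainClass != "symmetry", , drop = FALSE]
  if (!nrow(contacts)) return(0L)
  keep <- switch(class,
    all = rep(TRUE, nrow(contacts)),
    aromatic_aromatic = contacts$aromaticA & contacts$aromaticB,
    aromatic_nonaromatic = xor(contacts$aromaticA, contacts$aromaticB),
    nonaromatic_nonaromatic = !contacts$aromaticA & !contacts$aromaticB,
    backbone_backbone = contacts$categoryA == "backbone" &
      contacts$categoryB == "backbone",
    stop("unknown contact class: ", class))
  2L * sum(keep)
}

#' Planar-contact participations per 100 residues
#'
#' Average number of sp2 groups involved in planar pi-pi contacts per 100
#' residues, for a contact class defined by the nature of the two groups.
#'
#' @param ann a \linkS4class{ChainAnnotations}.
#' @param class one of "all", "aromatic_aromatic", "aromatic_nonaromatic",
#'   "nonaromatic_nonaromatic", "backbone_backbone".
#' @param excludeSymmetry drop symmetry-partner contacts.
#' @param perContact count each contact once instead of one participation
#'   per involved group (a sensitivity variant; the default matches "groups
#'   involved per 100 residues").
#' @return participations (or contacts) per 100 residues.
#' @export
contactsPer100 <- function(ann, class = "all", excludeSymmetry = TRUE,
                           perContact = FALSE) {
  n <- nrow(ann@residues)
  if (!n) stop("insufficient data: no residues annotated")
  cnt <- participationCount(ann@contacts, class, excludeSymmetry)
  if (perContact) cnt <- cnt / 2
  100 * cnt / n
}

#' Bin structures by crystallographic resolution
#'
#' Sorts PDB entries into non-overlapping bins, first by exact resolution,
#' then rolling any bin with fewer than \code{minCount} entries into the next
#' bin provided the merge spans at most \code{window} angstrom. A bin that
#' cannot reach \code{minCount} within the window is kept as is.
#'
#' @param ann a \linkS4class{ChainAnnotations} with resolutions.
#' @param minCount minimum PDB entries per bin.
#' @param window maximum resolution span when rolling small bins, angstrom.
#' @param class contact class passed to \code{\link{contactsPer100}} when
#'   computing per-entry rates.
#' @return data.frame (resolution = weighted mean bin resolution, rate = mean
#'   per-entry participations per 100 residues, n = entries in bin).
#' @export
resolutionBins <- function(ann, minCount = 100, window = 0.25,
                           class = "all") {
  ch <- ann@chains
  if (all(is.na(ch$resolution)))
    stop("no resolutions present in the annotation set")
  # per-PDB rate and resolution
  pdbs <- unique(ch$pdbId[!is.na(ch$resolution)])
  perPdb <- do.call(rbind, lapply(pdbs, function(p) {
    sel <- ch$pdbId == p
    keys <- ch$chainKey[sel]
    nres <- sum(nchar(ch$sequence[sel]))
    ct <- ann@contacts[ann@contacts$chainKeyA %in% keys, , drop = FALSE]
    data.frame(pdbId = p, resolution = ch$resolution[sel][1],
               rate = 100 * participationCount(ct, class) / nres,
               stringsAsFactors = FALSE)
  }))
  perPdb <- perPdb[order(perPdb$resolution), ]
  vals <- sort(unique(perPdb$resolution))
  counts <- vapply(vals, function(v) sum(perPdb$resolution == v), integer(1))
  bins <- list(); cur <- integer(0)
  for (k in seq_along(vals)) {
    cur <- c(cur, k)
    if (sum(counts[cur]) >= minCount ||
        (k < length(vals) && vals[k + 1] - vals[cur[1]] > window) ||
        k == length(vals)) {
      bins[[length(bins) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  out <- do.call(rbind, lapply(bins, function(ix) {
    sel <- perPdb$resolution %in% vals[ix]
    data.frame(resolution = stats::weighted.mean(vals[ix], counts[ix]),
               rate = mean(perPdb$rate[sel]), n = sum(counts[ix]))
  }))
  rownames(out) <- NULL
  out
}

#' Sample-size weighted linear fit over resolution bins
#'
#' Least squares of bin mean rate on bin mean resolution, weighted by bin
#' sample size.
#'
#' @param bins data.frame from \code{\link{resolutionBins}} (columns
#'   \code{resolution}, \code{rate}, \code{n}).
#' @return list with \code{slope}, \code{intercept}, \code{r} (signed
#'   weighted correlation).
#' @export
weightedLinearFit <- function(bins) {
  if (nrow(bins) < 2) stop("need at least 2 bins for a linear fit")
  fit <- stats::lm(rate ~ resolution, data = bins, weights = bins$n)
  # collinear bins fit exactly; summary.lm's perfect-fit warning is expected
  r2 <- suppressWarnings(summary(fit)$r.squared)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r = sign(unname(co[2])) * sqrt(r2))
}

#' PDB-block bootstrap standard error
#'
#' Standard deviation of a statistic over resamples that draw whole PDB
#' entries with replacement, keeping residues of one structure together as a
#' dependent block.
#'
#' @param statistic function taking a \linkS4class{ChainAnnotations} and
#'   returning a numeric scalar.
#' @param ann the annotations.
#' @param nIter bootstrap iterations.
#' @param seed RNG seed.
#' @return bootstrap SEM (numeric scalar).
#' @export
blockBootstrapSEM <- function(statistic, ann, nIter = 10000, seed = 1L) {
  pdbs <- unique(ann@chains$pdbId)
  if (length(pdbs) < 2) {
    warning("single-PDB input: bootstrap SEM is 0")
    return(0)
  }
  chBy <- split(ann@chains, ann@chains$pdbId)
  # residues/contacts keyed by chainKey; map chainKey -> pdbId via chains
  ck2pdb <- stats::setNames(ann@chains$pdbId, ann@chains$chainKey)
  resBy <- split(ann@residues, ck2pdb[ann@residues$chainKey])
  ctBy <- split(ann@contacts, ck2pdb[ann@contacts$chainKeyA])
  emptyCt <- ann@contacts[0, , drop = FALSE]
  vals <- withSeed(seed, vapply(seq_len(nIter), function(it) {
    take <- sample(pdbs, length(pdbs), replace = TRUE)
    suffix <- make.unique(take, sep = "\rdup")
    chs <- list(); ress <- list(); cts <- list()
    for (q in seq_along(take)) {
      p <- take[q]; sfx <- suffix[q]
      b <- chBy[[p]]
      b$chainKey <- paste0(sfx, "\r", b$chainKey)
      b$pdbId <- sfx
      chs[[q]] <- b
      r <- resBy[[p]]
      if (!is.null(r)) {
        r$chainKey <- paste0(sfx, "\r", r$chainKey)
        ress[[q]] <- r
      }
      cc <- ctBy[[p]]
      if (!is.null(cc) && nrow(cc)) {
        cc$chainKeyA <- paste0(sfx, "\r", cc$chainKeyA)
        cc$chainKeyB <- paste0(sfx, "\r", cc$chainKeyB)
        cts[[q]] <- cc
      }
    }
    boot <- new("ChainAnnotations", chains = do.call(rbind, chs),
                residues = do.call(rbind, ress),
                contacts = if (length(cts)) do.call(rbind, cts) else emptyCt)
    statistic(boot)
  }, numeric(1)))
  stats::sd(vals)
}

#' Contact frequency versus solvation
#'
#' Involvement frequency as a function of the number of solved waters in VDW
#' contact with each residue, computed separately for sidechain-group and
#' backbone participation. Only structures with more than
#' \code{minWaterPerResidue} water contacts per residue on average qualify.
#'
#' @param ann annotations with per-residue water counts.
#' @param minWaterPerResidue structure-level inclusion threshold.
#' @return data.frame (waterCount, sidechainFreq, backboneFreq, anyFreq, n).
#' @export
solvationProfile <- function(ann, minWaterPerResidue = 1) {
  res <- ann@residues
  ck2pdb <- stats::setNames(ann@chains$pdbId, ann@chains$chainKey)
  perPdbMean <- tapply(res$waterCount, ck2pdb[res$chainKey],
                       function(w) mean(w, na.rm = TRUE))
  ok <- names(perPdbMean)[!is.na(perPdbMean) &
                            perPdbMean > minWaterPerResidue]
  if (!length(ok)) stop("no structures exceed the water threshold")
  res <- res[ck2pdb[res$chainKey] %in% ok & !is.na(res$waterCount), ,
             drop = FALSE]
  keys <- paste(res$chainKey, res$resIndex)
  invSc <- keys %in% with(involvedResidues(ann@contacts,
                                           category = "sidechain"),
                          paste(chainKey, resIndex))
  invBb <- keys %in% with(involvedResidues(ann@contacts,
                                           category = "backbone"),
                          paste(chainKey, resIndex))
  invAny <- keys %in% with(involvedResidues(ann@contacts),
                           paste(chainKey, resIndex))
  out <- do.call(rbind, lapply(sort(unique(res$waterCount)), function(w) {
    sel <- res$waterCount == w
    data.frame(waterCount = w, sidechainFreq = mean(invSc[sel]),
               backboneFreq = mean(invBb[sel]), anyFreq = mean(invAny[sel]),
               n = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

# Signed sequence position relative to regular secondary structure for one
# assignment string: negative inside H/G/E (distance to the nearest
# loop/turn), positive in loops (distance to the nearest H/G/E), capped at
# +/- (cap + 1) to pool positions beyond the cap.
ssSignedPositions <- function(ss, cap = 7L) {
  ordered <- ss %in% c("H", "G", "E")
  n <- length(ss)
  nearestDist <- function(targets) {
    # distance from every position to the nearest TRUE in targets
    if (!any(targets)) return(rep(Inf, n))
    idx <- which(targets)
    vapply(seq_len(n), function(i) min(abs(i - idx)), numeric(1))
  }
  dOrd <- nearestDist(ordered)
  dLoop <- nearestDist(!ordered)
  pos <- ifelse(ordered, -pmin(dLoop, cap + 1), pmin(dOrd, cap + 1))
  pos
}

#' Contact frequency versus distance from regular secondary structure
#'
#' Mean involvement frequency at each signed sequence distance from regular
#' secondary structure (H/G/E, negative positions are inside it, measured to
#' the nearest loop/turn) and from loop/turn regions (positive positions,
#' measured to the nearest H/G/E). Distances beyond \code{cap} are pooled.
#'
#' @param ann annotations with secondary-structure assignments.
#' @param cap pooling distance.
#' @return data.frame (position, frequency, n); positions -(cap+1) and
#'   (cap+1) are the pooled "beyond cap" bins.
#' @export
ssDistanceProfile <- function(ann, cap = 7L) {
  res <- ann@residues
  if (all(is.na(res$ss))) stop("no secondary-structure assignments present")
  inv <- involvedResidues(ann@contacts)
  invKeys <- paste(inv$chainKey, inv$resIndex)
  pieces <- lapply(unique(res$chainKey), function(ck) {
    r <- res[res$chainKey == ck, ]
    r <- r[order(r$resIndex), ]
    if (any(is.na(r$ss))) return(NULL)
    data.frame(pos = ssSignedPositions(r$ss, cap),
               inv = paste(ck, r$resIndex) %in% invKeys)
  })
  d <- do.call(rbind, pieces)
  if (is.null(d)) stop("no chains with complete assignments")
  d <- d[is.finite(d$pos), , drop = FALSE]
  out <- do.call(rbind, lapply(sort(unique(d$pos)), function(p) {
    sel <- d$pos == p
    data.frame(position = p, frequency = mean(d$inv[sel]), n = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Sidechain contact frequencies by interface proximity
#'
#' For each of the nine sp2 sidechain types and each interface class of the
#' residue (no other chain within VDW distance of the sidechain, in contact
#' with a chain in the same asymmetric unit, or in contact with a symmetry
#' copy), splits the total sidechain contact frequency into local intrachain
#' (separation <= 4), non-local intrachain, and interchain contributions.
#'
#' @param ann a \linkS4class{ChainAnnotations}.
#' @return data.frame (identity, interfaceClass, local, nonlocalIntra,
#'   inter, total, n).
#' @export
interfaceBreakdown <- function(ann) {
  res <- ann@residues
  ct <- ann@contacts
  sp2sc <- c("W", "F", "Y", "H", "R", "Q", "N", "E", "D")
  # per-contact sidechain participations with their class
  part <- NULL
  if (nrow(ct)) {
    mk <- function(ck, idx, cat, sep, cclass) {
      sel <- cat == "sidechain"
      data.frame(key = paste(ck[sel], idx[sel]),
                 kind = ifelse(cclass[sel] != "intra", "inter",
                               ifelse(is.finite(sep[sel]) & sep[sel] <= 4,
                                      "local", "nonlocalIntra")),
                 stringsAsFactors = FALSE)
    }
    part <- rbind(mk(ct$chainKeyA, ct$resIndexA, ct$categoryA,
                     ct$seqSeparation, ct$chainClass),
                  mk(ct$chainKeyB, ct$resIndexB, ct$categoryB,
                     ct$seqSeparation, ct$chainClass))
  }
  grid <- expand.grid(identity = sp2sc,
                      interfaceClass = c("none", "inter_asu", "symmetry"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sel <- res$aa == grid$identity[g] &
      res$interfaceClass == grid$interfaceClass[g]
    n <- sum(sel)
    keys <- paste(res$chainKey[sel], res$resIndex[sel])
    cnt <- c(local = 0, nonlocalIntra = 0, inter = 0)
    if (n && !is.null(part) && nrow(part)) {
      p <- part[part$key %in% keys, , drop = FALSE]
      tb <- table(factor(p$kind, levels = names(cnt)))
      cnt <- as.numeric(tb)
      names(cnt) <- c("local", "nonlocalIntra", "inter")
    }
    data.frame(identity = grid$identity[g],
               interfaceClass = grid$interfaceClass[g],
               local = if (n) cnt["local"] / n else NA_real_,
               nonlocalIntra = if (n) cnt["nonlocalIntra"] / n else NA_real_,
               inter = if (n) cnt["inter"] / n else NA_real_,
               total = if (n) sum(cnt) / n else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Planar fraction of backbone VDW contacts, sp2 versus sp3
#'
#' For every sp2 sidechain group and sp3 control plane in a structure, finds
#' VDW contacts to backbone peptide units (at least \code{minAtomPairs} atom
#' pairs within the cutoff) and reports how many of them also satisfy the
#' full planar criterion.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param criteria a \linkS4class{ContactCriteria}.
#' @param definitions group definition table.
#' @return data.frame (identity, class = "sp2"/"sp3", nVdw, nPlanar).
#' @export
backbonePlanarFractions <- function(model, criteria = contactCriteria(),
                                    definitions = sp2Definitions()) {
  sc <- extractSp2Groups(model, definitions)
  scOnly <- sc@groups$category == "sidechain"
  pep <- sc@groups$category == "backbone"
  sp3 <- extractSp3Controls(model, definitions)
  tally <- list()
  count <- function(gsA, selA, classLabel) {
    ga <- gsA@groups[selA, , drop = FALSE]
    co <- gsA@coords[selA]
    no <- gsA@normals[selA, , drop = FALSE]
    pg <- sc@groups[pep, , drop = FALSE]
    pco <- sc@coords[pep]
    pno <- sc@normals[pep, , drop = FALSE]
    for (i in seq_len(nrow(ga))) {
      kA <- groupAtomKeys(rownames(co[[i]]), ga$chain[i], ga$resIndex[i])
      for (j in seq_len(nrow(pg))) {
        kB <- groupAtomKeys(rownames(pco[[j]]), pg$chain[j], pg$resIndex[j])
        nv <- countVdwPairs(co[[i]], pco[[j]], criteria@vdwCutoff, kA, kB)
        if (is.na(nv) || nv < criteria@minAtomPairs) next
        res <- isPlanarPiContact(co[[i]], no[i, ], pco[[j]], pno[j, ],
                                 criteria, kA, kB)
        key <- paste0(classLabel, "\r", ga$identity[i])
        prev <- tally[[key]]
        if (is.null(prev)) prev <- c(nVdw = 0L, nPlanar = 0L)
        prev["nVdw"] <- prev["nVdw"] + 1L
        prev["nPlanar"] <- prev["nPlanar"] + as.integer(res$contact)
        tally[[key]] <<- prev
      }
    }
  }
  count(sc, scOnly, "sp2")
  count(sp3, rep(TRUE, nrow(sp3@groups)), "sp3")
  if (!length(tally))
    return(data.frame(identity = character(), class = character(),
                      nVdw = integer(), nPlanar = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(names(tally), "\r", fixed = TRUE)
  out <- data.frame(
    identity = vapply(parts, `[`, "", 2),
    class = vapply(parts, `[`, "", 1),
    nVdw = vapply(tally, `[[`, 0L, "nVdw"),
    nPlanar = vapply(tally, `[[`, 0L, "nPlanar"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sp3-control enrichment of planar stacking
#'
#' Conditional fraction P(planar | VDW contact to a peptide unit) per group
#' identity, comparing sp2 sidechain groups to sp3 control planes.
#' Identities with no VDW contacts are omitted with a warning.
#'
#' @param fractions data.frame from \code{\link{backbonePlanarFractions}}
#'   (possibly summed over structures).
#' @return data.frame (identity, class, nVdw, nPlanar, fraction).
#' @export
sp3ControlEnrichment <- function(fractions) {
  zero <- fractions$nVdw == 0
  if (any(zero)) {
    warning("omitting identities with zero VDW denominators: ",
            paste(fractions$identity[zero], collapse = ", "))
    fractions <- fractions[!zero, , drop = FALSE]
  }
  fractions$fraction <- fractions$nPlanar / fractions$nVdw
  fractions
}
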