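# Stage-1 predictor: expected pi-contact frequencies per sp2 group from
# sequence alone, via an empirical frequency table keyed by group identity,
# partner residue type, separation class and contacted category, followed by
# percentile calibration against same-identity groups.

SP2_SIDECHAINS <- c("W", "F", "Y", "H", "R", "Q", "N", "E", "D")
AROMATIC_AA <- c("W", "F", "Y", "H")
SEP_CLASSES <- c("short", "long")
CATEGORIES <- c("sidechain", "backbone")
CONTEXT_WINDOW <- 40L

# All sequence identities: nine sp2 sidechains plus 400 ordered backbone
# dipeptides.
tableIdentities <- function() {
  dip <- as.vector(outer(STANDARD_AA, STANDARD_AA,
                         function(a, b) paste0(a, b)))
  c(SP2_SIDECHAINS, dip)
}

identityIndex <- function(id) {
  idx <- match(id, SP2_SIDECHAINS)
  two <- nchar(id) == 2
  a <- match(substr(id[two], 1, 1), STANDARD_AA)
  b <- match(substr(id[two], 2, 2), STANDARD_AA)
  # column-major over (first, second), matching tableIdentities()
  idx[two] <- 9L + a + (b - 1L) * 20L
  idx
}

# Sp2 groups of one sequence: sidechain groups at sp2 residues, one backbone
# peptide unit anchored at each position 1..L-1 (identity = the ordered
# dipeptide). Non-standard letters never form groups.
enumerateGroups <- function(seqChars) {
  L <- length(seqChars)
  typeIdx <- match(seqChars, STANDARD_AA)
  scPos <- which(seqChars %in% SP2_SIDECHAINS)
  bbPos <- if (L >= 2)
    which(!is.na(typeIdx[-L]) & !is.na(typeIdx[-1])) else integer(0)
  n <- length(scPos) + length(bbPos)
  data.frame(
    gid = seq_len(n),
    pos = c(scPos, bbPos),
    cat = rep(c("sidechain", "backbone"),
              c(length(scPos), length(bbPos))),
    identity = c(seqChars[scPos],
                 paste0(seqChars[bbPos], seqChars[bbPos + 1L])),
    typeIdx = c(typeIdx[scPos], typeIdx[bbPos]),
    aromatic = c(seqChars[scPos] %in% AROMATIC_AA,
                 rep(FALSE, length(bbPos))),
    stringsAsFactors = FALSE)
}

# Canonical contact opportunities of one chain: unordered group pairs with
# anchor offset 1..window; adjacent backbone units (which share an atom in a
# structure) are excluded. The same enumeration backs the synthetic corpus
# generator, the table builder and the context expectation, so frequencies
# are proper conditional rates on a single opportunity definition.
enumerateOpportunities <- function(groups, L, window = CONTEXT_WINDOW) {
  scAt <- rep(NA_integer_, L); bbAt <- rep(NA_integer_, L)
  sc <- groups$cat == "sidechain"
  scAt[groups$pos[sc]] <- groups$gid[sc]
  bbAt[groups$pos[!sc]] <- groups$gid[!sc]
  res <- vector("list", window * 4L)
  k <- 0L
  for (off in seq_len(min(window, L - 1L))) {
    ij <- seq_len(L - off)
    for (ca in c("sc", "bb")) for (cb in c("sc", "bb")) {
      if (ca == "bb" && cb == "bb" && off == 1L) next
      aRow <- (if (ca == "sc") scAt else bbAt)[ij]
      bRow <- (if (cb == "sc") scAt else bbAt)[ij + off]
      ok <- !is.na(aRow) & !is.na(bRow)
      if (!any(ok)) next
      k <- k + 1L
      res[[k]] <- data.frame(a = aRow[ok], b = bRow[ok], offset = off)
    }
  }
  if (!k) return(data.frame(a = integer(), b = integer(),
                            offset = integer(), sep = character()))
  out <- do.call(rbind, res[seq_len(k)])
  out$sep <- ifelse(out$offset <= 4L, "short", "long")
  out
}

# 4-d cell index helpers: [identity(409), partnerType(20), sep(2), cat(2)].
cellDims <- function() c(length(tableIdentities()), 20L, 2L, 2L)

cellIndex <- function(idIdx, typeIdx, sepIdx, catIdx) {
  d <- cellDims()
  ((catIdx - 1L) * d[3] + (sepIdx - 1L)) * d[2] * d[1] +
    (typeIdx - 1L) * d[1] + idIdx
}

# Directed (group -> partner) observation indices for one chain's
# opportunities; each unordered opportunity yields one observation per
# direction.
directedCells <- function(groups, opp) {
  idIdx <- identityIndex(groups$identity)
  typeIdx <- groups$typeIdx
  catIdx <- match(groups$cat, CATEGORIES)
  sepIdx <- match(opp$sep, SEP_CLASSES)
  c(cellIndex(idIdx[opp$a], typeIdx[opp$b], sepIdx, catIdx[opp$b]),
    cellIndex(idIdx[opp$b], typeIdx[opp$a], sepIdx, catIdx[opp$a]))
}

#' Random train/test split of annotation chains
#'
#' @param ann a \linkS4class{ChainAnnotations}.
#' @param testFrac held-out fraction of chains.
#' @param seed RNG seed.
#' @return list with \code{train} and \code{test} chainKey vectors.
#' @export
trainTestSplit <- function(ann, testFrac = 0.2, seed = 1L) {
  keys <- ann@chains$chainKey
  nTest <- round(length(keys) * testFrac)
  test <- withSeed(seed, sample(keys, nTest))
  list(train = setdiff(keys, test), test = test)
}

#' Build the empirical pi-contact frequency table
#'
#' Counts, for every (group identity, partner residue type, separation
#' class, contacted category) cell, the contact opportunities present in the
#' annotated chains and how many of them are realized contacts. Both
#' directions of every contact are counted once each.
#'
#' @param ann a \linkS4class{ChainAnnotations} whose contacts carry anchor
#'   positions (\code{resIndexA/B}) and categories.
#' @param chainKeys optional chain subset (e.g. the training side of
#'   \code{\link{trainTestSplit}}).
#' @param smoothing list(priorContacts): strength, in pseudo-contacts, of
#'   the hierarchical shrinkage applied by \code{\link{tableFrequencies}}.
#'   Denominating the prior in contacts rather than opportunities makes the
#'   shrinkage self-scaling: a cell is trusted once it has seen enough
#'   contacts for its rate to be measurable, regardless of how rare contacts
#'   are.
#' @return a \linkS4class{ContactFrequencyTable}.
#' @export
buildContactTable <- function(ann, chainKeys = NULL,
                              smoothing = list(priorContacts = 10)) {
  ch <- ann@chains
  if (!is.null(chainKeys)) ch <- ch[ch$chainKey %in% chainKeys, , drop = FALSE]
  if (!nrow(ch)) stop("no chains to build a table from")
  d <- cellDims()
  nCells <- prod(d)
  oppCnt <- numeric(nCells)
  ctCnt <- numeric(nCells)
  ct <- ann@contacts
  ct <- ct[ct$chainClass == "intra" & ct$chainKeyA %in% ch$chainKey, ,
           drop = FALSE]
  for (i in seq_len(nrow(ch))) {
    seqChars <- strsplit(ch$sequence[i], "")[[1]]
    groups <- enumerateGroups(seqChars)
    if (!nrow(groups)) next
    opp <- enumerateOpportunities(groups, length(seqChars))
    if (nrow(opp)) {
      cells <- directedCells(groups, opp)
      tb <- tabulate(cells, nCells)
      oppCnt <- oppCnt + tb
    }
    cci <- ct[ct$chainKeyA == ch$chainKey[i], , drop = FALSE]
    if (nrow(cci)) {
      key <- paste(groups$pos, groups$cat)
      a <- match(paste(cci$resIndexA, cci$categoryA), key)
      b <- match(paste(cci$resIndexB, cci$categoryB), key)
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        oc <- data.frame(a = a[ok], b = b[ok],
                         sep = cci$rangeClass[ok])
        cells <- directedCells(groups, oc)
        ctCnt <- ctCnt + tabulate(cells, nCells)
      }
    }
  }
  dn <- list(identity = tableIdentities(), partner = STANDARD_AA,
             sep = SEP_CLASSES, category = CATEGORIES)
  new("ContactFrequencyTable",
      counts = array(ctCnt, d, dimnames = dn),
      opportunities = array(oppCnt, d, dimnames = dn),
      smoothing = smoothing,
      provenance = list(nChains = nrow(ch), chainKeys = ch$chainKey))
}

#' Smoothed frequencies of a contact table
#'
#' Hierarchical empirical-Bayes estimate of the conditional contact rates.
#' Within each (separation, category) slice the cell rate is modeled
#' multiplicatively as global rate x group-identity effect x partner-type
#' effect, with each factor estimated at its own level of aggregation and a
#' cell-specific residual on top. Backbone dipeptide identities are pooled
#' through their anchor residue (the first flanking residue) before the
#' identity-specific residual is applied. Every level is shrunk toward its
#' parent with a Gamma-Poisson prior worth \code{smoothing$priorContacts}
#' pseudo-contacts at the parent rate, so estimates follow the data exactly
#' where the data can support a rate and fall back smoothly where they
#' cannot. At survey scale (millions of opportunities per cell) the
#' shrinkage weights approach one and the table reproduces the empirical
#' rates.
#'
#' @param table a \linkS4class{ContactFrequencyTable}.
#' @return 4-d array of frequencies in [0, 1].
#' @export
tableFrequencies <- function(table) {
  k <- table@smoothing$priorContacts
  cnt <- table@counts; opp <- table@opportunities
  d <- dim(cnt)
  ids <- dimnames(cnt)[[1]]
  anchor <- substr(ids, 1, 1)  # sidechains are their own pool
  anchor[nchar(ids) == 2] <- paste0("bb", anchor[nchar(ids) == 2])
  out <- array(0, d, dimnames = dimnames(cnt))
  shrink <- function(c0, n0, target) {
    pr <- k / pmax(target, 1e-12)  # prior worth k contacts at the target
    (c0 + pr * target) / (n0 + pr)
  }
  for (s in seq_len(d[3])) for (cc in seq_len(d[4])) {
    C <- cnt[, , s, cc]; O <- opp[, , s, cc]
    g <- (sum(C) + 0.5) / (sum(O) + 1)  # guarded global rate
    # partner-type effect, estimated over all identities
    pRate <- shrink(colSums(C), colSums(O), g)
    P <- pRate / g
    # anchor-residue rate, pooled over identities sharing the anchor
    aCnt <- rowsum(rowSums(C), anchor)
    aOpp <- rowsum(rowSums(O), anchor)
    aRate <- shrink(aCnt[, 1], aOpp[, 1], g)[anchor]
    # identity residual, shrunk toward its anchor rate
    iRate <- shrink(rowSums(C), rowSums(O), aRate)
    # cell estimate around the multiplicative target
    target <- outer(iRate, P)
    out[, , s, cc] <- shrink(C, O, target)
  }
  out
}

# Raw context expectations for every group of a sequence: per group and
# (sep, cat) channel, the mean table frequency over that group's
# opportunities. Cells with no opportunity fall back to the identity
# marginal.
rawExpectations <- function(seqChars, freq, groups = NULL, opp = NULL) {
  if (is.null(groups)) groups <- enumerateGroups(seqChars)
  if (!nrow(groups))
    return(list(groups = groups,
                raw = matrix(numeric(0), 0, 4,
                             dimnames = list(NULL, rawChannelNames()))))
  if (is.null(opp)) opp <- enumerateOpportunities(groups, length(seqChars))
  idIdx <- identityIndex(groups$identity)
  typeIdx <- groups$typeIdx
  catIdx <- match(groups$cat, CATEGORIES)
  sepIdx <- match(opp$sep, SEP_CLASSES)
  g <- c(opp$a, opp$b)
  vals <- freq[c(cellIndex(idIdx[opp$a], typeIdx[opp$b], sepIdx,
                           catIdx[opp$b]),
                 cellIndex(idIdx[opp$b], typeIdx[opp$a], sepIdx,
                           catIdx[opp$a]))]
  chan <- c((match(opp$sep, SEP_CLASSES) - 1L) * 2L + catIdx[opp$b],
            (match(opp$sep, SEP_CLASSES) - 1L) * 2L + catIdx[opp$a])
  raw <- matrix(NA_real_, nrow(groups), 4,
                dimnames = list(NULL, rawChannelNames()))
  sums <- rowsum(vals, paste(g, chan))
  ns <- rowsum(rep(1, length(vals)), paste(g, chan))
  parts <- strsplit(rownames(sums), " ")
  gi <- as.integer(vapply(parts, `[`, "", 1))
  ci <- as.integer(vapply(parts, `[`, "", 2))
  raw[cbind(gi, ci)] <- sums / ns
  # identity-marginal fallback for channels with no opportunities
  if (anyNA(raw)) {
    for (ci in 1:4) {
      sel <- is.na(raw[, ci])
      if (!any(sel)) next
      s <- (ci - 1L) %/% 2L + 1L
      cc <- (ci - 1L) %% 2L + 1L
      raw[sel, ci] <- rowMeans(freq[idIdx[sel], , s, cc, drop = FALSE],
                               dims = 1)
    }
  }
  list(groups = groups, raw = raw)
}

rawChannelNames <- function() {
  # channel index = (sep - 1) * 2 + category
  c("short_sc", "short_bb", "long_sc", "long_bb")
}

#' Raw context expectation for one sp2 group
#'
#' Mean table frequency over the residues within the context window of the
#' group, split by the separation class implied by each residue's offset and
#' by the contacted category: four absolute expected frequencies.
#'
#' @param sequence amino-acid sequence (single string).
#' @param position anchor position of the group (for backbone units, the
#'   first flanking residue).
#' @param table a \linkS4class{ContactFrequencyTable}.
#' @param category "sidechain" or "backbone".
#' @return named numeric(4): short_sc, short_bb, long_sc, long_bb.
#' @export
contextExpectation <- function(sequence, position, table,
                               category = c("sidechain", "backbone")) {
  category <- match.arg(category)
  seqChars <- strsplit(sequence, "")[[1]]
  re <- rawExpectations(seqChars, tableFrequencies(table))
  sel <- re$groups$pos == position & re$groups$cat == category
  if (!any(sel)) stop("no ", category, " group at position ", position)
  stats::setNames(re$raw[which(sel)[1], ], rawChannelNames())
}

# Per-group realized directed contact rates (contacts / opportunities per
# channel), the calibration outcomes.
observedGroupRates <- function(seqChars, groups, opp, contacts) {
  nG <- nrow(groups)
  oppN <- matrix(0, nG, 4)
  ctN <- matrix(0, nG, 4)
  catIdx <- match(groups$cat, CATEGORIES)
  if (nrow(opp)) {
    chanA <- (match(opp$sep, SEP_CLASSES) - 1L) * 2L + catIdx[opp$b]
    chanB <- (match(opp$sep, SEP_CLASSES) - 1L) * 2L + catIdx[opp$a]
    tb <- rowsum(rep(1, 2 * nrow(opp)),
                 paste(c(opp$a, opp$b), c(chanA, chanB)))
    parts <- strsplit(rownames(tb), " ")
    oppN[cbind(as.integer(vapply(parts, `[`, "", 1)),
               as.integer(vapply(parts, `[`, "", 2)))] <- tb
  }
  if (nrow(contacts)) {
    key <- paste(groups$pos, groups$cat)
    a <- match(paste(contacts$resIndexA, contacts$categoryA), key)
    b <- match(paste(contacts$resIndexB, contacts$categoryB), key)
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      sep <- contacts$rangeClass[ok]
      a <- a[ok]; b <- b[ok]
      chanA <- (match(sep, SEP_CLASSES) - 1L) * 2L + catIdx[b]
      chanB <- (match(sep, SEP_CLASSES) - 1L) * 2L + catIdx[a]
      tb <- rowsum(rep(1, 2 * length(a)), paste(c(a, b), c(chanA, chanB)))
      parts <- strsplit(rownames(tb), " ")
      ctN[cbind(as.integer(vapply(parts, `[`, "", 1)),
                as.integer(vapply(parts, `[`, "", 2)))] <- tb
    }
  }
  rate <- ctN / pmax(oppN, 1)
  rate[oppN == 0] <- NA
  attr(rate, "opportunities") <- oppN
  rate
}

#' Calibrate raw expectations against same-identity groups
#'
#' Builds, per sequence identity and channel, the percentile map from raw
#' context expectation to mean observed contact frequency over
#' equal-population bins, smoothed by isotonic regression so the map is
#' monotone. Identities with too few training groups share a pooled map per
#' category.
#'
#' @param table the training \linkS4class{ContactFrequencyTable}.
#' @param ann annotations supplying training chains and contacts.
#' @param chainKeys training chain subset (defaults to the table's chains).
#' @param nBins number of equal-population percentile bins.
#' @param minPerIdentity minimum training groups for an identity-specific
#'   percentile map; identities below it share the pooled per-category map.
#'   At the tiny per-group contact rates of folded proteins, percentile maps
#'   fit on few groups memorize noise, so the floor is deliberately high.
#' @param meanFloor minimum training groups for an identity-specific mean
#'   (used by the relative channels).
#' @return a \linkS4class{ContactCalibration}.
#' @export
calibrateContactPredictor <- function(table, ann, chainKeys = NULL,
                                      nBins = 20L, minPerIdentity = 2000L,
                                      meanFloor = 50L) {
  if (is.null(chainKeys)) chainKeys <- table@provenance$chainKeys
  ch <- ann@chains[ann@chains$chainKey %in% chainKeys, , drop = FALSE]
  freq <- tableFrequencies(table)
  ct <- ann@contacts
  ct <- ct[ct$chainClass == "intra", , drop = FALSE]
  rawL <- list(); obsL <- list(); idL <- list()
  for (i in seq_len(nrow(ch))) {
    seqChars <- strsplit(ch$sequence[i], "")[[1]]
    groups <- enumerateGroups(seqChars)
    if (!nrow(groups)) next
    opp <- enumerateOpportunities(groups, length(seqChars))
    re <- rawExpectations(seqChars, freq, groups, opp)
    obs <- observedGroupRates(
      seqChars, groups, opp,
      ct[ct$chainKeyA == ch$chainKey[i], , drop = FALSE])
    rawL[[length(rawL) + 1L]] <- re$raw
    obsL[[length(obsL) + 1L]] <- obs
    idL[[length(idL) + 1L]] <- groups$identity
  }
  if (!length(rawL)) stop("no training groups for calibration")
  raw <- do.call(rbind, rawL)
  obs <- do.call(rbind, obsL)
  ids <- unlist(idL)

  fitMap <- function(r, o, nb) {
    ok <- !is.na(r) & !is.na(o)
    r <- r[ok]; o <- o[ok]
    if (length(r) < 2 * nb) nb <- max(1L, length(r) %/% 4L)
    if (!length(r)) return(NULL)
    br <- unique(stats::quantile(r, probs = seq(0, 1, length.out = nb + 1),
                                 names = FALSE))
    bin <- findInterval(r, br, rightmost.closed = TRUE, all.inside = TRUE)
    means <- tapply(o, factor(bin, levels = seq_len(length(br) - 1)), mean)
    means[is.na(means)] <- mean(o)
    means <- stats::isoreg(seq_along(means), as.numeric(means))$yf
    list(breaks = br, means = means, mean = mean(o))
  }

  bins <- list(); identityMeans <- list()
  for (id in unique(ids)) {
    sel <- ids == id
    if (sum(sel) < meanFloor) next
    identityMeans[[id]] <- vapply(1:4, function(ci) {
      o <- obs[sel, ci]
      if (all(is.na(o))) NA_real_ else mean(o, na.rm = TRUE)
    }, numeric(1))
    if (sum(sel) < minPerIdentity) next
    maps <- lapply(1:4, function(ci)
      fitMap(raw[sel, ci], obs[sel, ci], nBins))
    names(maps) <- rawChannelNames()
    bins[[id]] <- maps
  }
  pooled <- list()
  for (cat in CATEGORIES) {
    sel <- if (cat == "sidechain") nchar(ids) == 1 else nchar(ids) == 2
    maps <- lapply(1:4, function(ci)
      fitMap(raw[sel, ci], obs[sel, ci], nBins))
    names(maps) <- rawChannelNames()
    pooled[[cat]] <- maps
  }
  new("ContactCalibration", bins = bins, identityMeans = identityMeans,
      pooled = pooled, nBins = as.integer(nBins))
}

applyCalibration <- function(calibration, ids, cats, raw) {
  n <- length(ids)
  absv <- matrix(NA_real_, n, 4)
  relv <- matrix(NA_real_, n, 4)
  seen <- names(calibration@bins)
  unseenSc <- unique(ids[!(ids %in% seen) & nchar(ids) == 1])
  if (length(unseenSc))
    warning(warningCondition(
      paste("unseen identities use the pooled calibration:",
            paste(unseenSc, collapse = ", ")),
      class = "pipiUnseenIdentity"))
  for (i in seq_len(n)) {
    maps <- calibration@bins[[ids[i]]]
    if (is.null(maps)) maps <- calibration@pooled[[cats[i]]]
    im <- calibration@identityMeans[[ids[i]]]
    for (ci in 1:4) {
      m <- maps[[ci]]
      if (is.null(m) || is.na(raw[i, ci])) next
      b <- findInterval(raw[i, ci], m$breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
      absv[i, ci] <- m$means[b]
      base <- if (!is.null(im) && !is.na(im[ci])) im[ci] else m$mean
      relv[i, ci] <- absv[i, ci] - base
    }
  }
  list(absolute = absv, relative = relv)
}

#' Predict the pi-contact profile of a sequence
#'
#' One 8-vector per sp2 group: the calibrated absolute expected contact
#' frequency and the relative difference from same-identity groups, for
#' \{short, long\} separation x \{sidechain, backbone\} contacted category.
#'
#' @param sequence amino-acid sequence (single string, length >= 2).
#' @param table a \linkS4class{ContactFrequencyTable}.
#' @param calibration a \linkS4class{ContactCalibration}.
#' @return a \linkS4class{ContactProfile}.
#' @export
predictProfile <- function(sequence, table, calibration) {
  seqChars <- strsplit(sequence, "")[[1]]
  if (length(seqChars) < 2) stop("sequence must have length >= 2")
  re <- rawExpectations(seqChars, tableFrequencies(table))
  groups <- re$groups
  cal <- applyCalibration(calibration, groups$identity, groups$cat, re$raw)
  defs <- sp2Definitions()
  cc <- integer(nrow(groups))
  sel <- groups$cat == "sidechain"
  cc[sel] <- defs$carbonCount[match(groups$identity[sel], defs$identity)]
  cc[!sel] <- defs$carbonCount[match("PEPTIDE", defs$identity)]
  prof <- data.frame(position = groups$pos, identity = groups$identity,
                     category = groups$cat, carbonCount = cc,
                     stringsAsFactors = FALSE)
  ab <- cal$absolute; rl <- cal$relative
  colnames(ab) <- paste0(rawChannelNames(), "_abs")
  colnames(rl) <- paste0(rawChannelNames(), "_rel")
  prof <- cbind(prof, ab, rl)
  new("ContactProfile", sequence = sequence, profile = prof)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a sequence-based pi-contact predictor
#'
#' One-call training of the stage-1 predictor with an honest split: the
#' chains are divided into a held-out test set, a table subset (frequency
#' counting) and a calibration subset (percentile maps). Fitting the
#' calibration on chains that did not feed the table keeps the percentile
#' maps free of resubstitution bias, so held-out reliability slopes are
#' centered on one.
#'
#' @param ann a \linkS4class{ChainAnnotations}.
#' @param testFrac fraction of chains held out entirely.
#' @param tableFrac fraction of the remaining training chains used for the
#'   frequency table (the rest feed the calibration).
#' @param seed RNG seed for the splits.
#' @param smoothing passed to \code{\link{buildContactTable}}.
#' @param nBins,minPerIdentity,meanFloor passed to
#'   \code{\link{calibrateContactPredictor}}.
#' @return list with \code{table}, \code{calibration} and \code{split}
#'   (chainKey vectors \code{table}, \code{calibration}, \code{test}).
#' @export
trainContactPredictor <- function(ann, testFrac = 0.2, tableFrac = 2 / 3,
                                  seed = 1L,
                                  smoothing = list(priorContacts = 10),
                                  nBins = 20L, minPerIdentity = 2000L,
                                  meanFloor = 50L) {
  outer <- trainTestSplit(ann, testFrac, seed)
  nTab <- round(length(outer$train) * tableFrac)
  tableKeys <- withSeed(seed + 1L, sample(outer$train, nTab))
  calKeys <- setdiff(outer$train, tableKeys)
  table <- buildContactTable(ann, tableKeys, smoothing)
  calibration <- calibrateContactPredictor(
    table, ann, chainKeys = calKeys, nBins = nBins,
    minPerIdentity = minPerIdentity, meanFloor = meanFloor)
  list(table = table, calibration = calibration,
       split = list(table = tableKeys, calibration = calKeys,
                    test = outer$test))
}

#' Reliability of calibrated predictions on held-out chains
#'
#' Bins held-out groups into equal-population percentile bins of their
#' calibrated absolute prediction for one channel and reports the mean
#' prediction and mean realized contact rate per bin, plus the
#' size-weighted least-squares slope of realized on predicted.
#'
#' @param ann annotations with contacts.
#' @param chainKeys held-out chain subset.
#' @param table,calibration the trained stage-1 predictor.
#' @param channel one of "short_sc", "short_bb", "long_sc", "long_bb", or
#'   "total" for the per-group overall contact rate (each channel's
#'   calibrated prediction weighted by the group's share of opportunities in
#'   that channel — the reliability-plot construct).
#' @param nBins percentile bins.
#' @return data.frame (predicted, observed, n) with attribute \code{slope}.
#' @export
calibrationReliability <- function(ann, chainKeys, table, calibration,
                                   channel = "total", nBins = 20L) {
  ci <- if (identical(channel, "total")) 0L
  else match(channel, rawChannelNames())
  if (is.na(ci)) stop("unknown channel: ", channel)
  ch <- ann@chains[ann@chains$chainKey %in% chainKeys, , drop = FALSE]
  freq <- tableFrequencies(table)
  ct <- ann@contacts[ann@contacts$chainClass == "intra", , drop = FALSE]
  predL <- list(); obsL <- list()
  for (i in seq_len(nrow(ch))) {
    seqChars <- strsplit(ch$sequence[i], "")[[1]]
    groups <- enumerateGroups(seqChars)
    if (!nrow(groups)) next
    opp <- enumerateOpportunities(groups, length(seqChars))
    re <- rawExpectations(seqChars, freq, groups, opp)
    cal <- quietCalibrationFallback(
      applyCalibration(calibration, groups$identity, groups$cat, re$raw))
    obs <- observedGroupRates(
      seqChars, groups, opp,
      ct[ct$chainKeyA == ch$chainKey[i], , drop = FALSE])
    if (ci == 0L) {
      oppN <- attr(obs, "opportunities")
      w <- oppN / pmax(rowSums(oppN), 1)
      predL[[length(predL) + 1L]] <- rowSums(cal$absolute * w,
                                             na.rm = TRUE)
      obsL[[length(obsL) + 1L]] <- rowSums(obs * w, na.rm = TRUE)
    } else {
      predL[[length(predL) + 1L]] <- cal$absolute[, ci]
      obsL[[length(obsL) + 1L]] <- obs[, ci]
    }
  }
  pred <- unlist(predL); obs <- unlist(obsL)
  ok <- !is.na(pred) & !is.na(obs)
  pred <- pred[ok]; obs <- obs[ok]
  if (length(pred) < 2 * nBins) stop("too few held-out groups")
  br <- unique(stats::quantile(pred, seq(0, 1, length.out = nBins + 1),
                               names = FALSE))
  bin <- findInterval(pred, br, rightmost.closed = TRUE, all.inside = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(predicted = mean(pred[sel]), observed = mean(obs[sel]),
               n = sum(sel))
  }))
  fit <- stats::lm(observed ~ predicted, data = out, weights = out$n)
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  out
}

# --- serialization ----------------------------------------------------------

#' Write / read a contact frequency table as versioned TSV
#'
#' Long-format TSV of cells with nonzero opportunities, preceded by header
#' metadata lines (\code{#key=value}).
#'
#' @param table a \linkS4class{ContactFrequencyTable}.
#' @param path file path.
#' @return the path (write) or a \linkS4class{ContactFrequencyTable} (read).
#' @export
writeContactTable <- function(table, path) {
  idx <- which(table@opportunities > 0)
  ai <- arrayInd(idx, dim(table@opportunities))
  dn <- dimnames(table@opportunities)
  df <- data.frame(identity = dn[[1]][ai[, 1]], partner = dn[[2]][ai[, 2]],
                   sep = dn[[3]][ai[, 3]], category = dn[[4]][ai[, 4]],
                   count = table@counts[idx],
                   opportunities = table@opportunities[idx])
  hdr <- c("#format=pipi-contact-table-1",
           sprintf("#smoothing_prior_contacts=%g",
                   table@smoothing$priorContacts),
           sprintf("#n_chains=%d", table@provenance$nChains %||% NA_integer_))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeContactTable
#' @export
readContactTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^#", "", hdr), "=")
  metaV <- stats::setNames(vapply(meta, `[`, "", 2),
                           vapply(meta, `[`, "", 1))
  df <- utils::read.delim(
    text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE,
    na.strings = character(0),
    colClasses = c(identity = "character", partner = "character",
                   sep = "character", category = "character"))
  d <- cellDims()
  dn <- list(identity = tableIdentities(), partner = STANDARD_AA,
             sep = SEP_CLASSES, category = CATEGORIES)
  cnt <- array(0, d, dimnames = dn)
  opp <- array(0, d, dimnames = dn)
  idx <- cellIndex(identityIndex(df$identity),
                   match(df$partner, STANDARD_AA),
                   match(df$sep, SEP_CLASSES),
                   match(df$category, CATEGORIES))
  cnt[idx] <- df$count
  opp[idx] <- df$opportunities
  new("ContactFrequencyTable", counts = cnt, opportunities = opp,
      smoothing = list(priorContacts =
                         as.numeric(metaV[["smoothing_prior_contacts"]])),
      provenance = list(nChains = as.integer(metaV[["n_chains"]])))
}

#' Write / read a contact calibration as structured text
#'
#' @param calibration a \linkS4class{ContactCalibration}.
#' @param path YAML file path.
#' @return the path (write) or a \linkS4class{ContactCalibration} (read).
#' @export
writeCalibration <- function(calibration, path) {
  yaml::write_yaml(list(
    format = "pipi-calibration-1",
    nBins = calibration@nBins,
    identityMeans = lapply(calibration@identityMeans, as.list),
    bins = calibration@bins,
    pooled = calibration@pooled), path, precision = 17)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  y <- yaml::read_yaml(path)
  fix <- function(maps) lapply(maps, function(m) {
    if (is.null(m)) return(NULL)
    list(breaks = as.numeric(unlist(m$breaks)),
         means = as.numeric(unlist(m$means)), mean = as.numeric(m$mean))
  })
  new("ContactCalibration",
      bins = lapply(y$bins, fix),
      identityMeans = lapply(y$identityMeans,
                             function(v) as.numeric(unlist(v))),
      pooled = lapply(y$pooled, fix),
      nBins = as.integer(y$nBins))
}
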