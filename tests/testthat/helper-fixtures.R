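# Shared test fixtures and independent oracles.

# Brute-force all-pairs evaluation of the planar contact criterion: a plain
# double loop over group pairs, independent of the neighbor-prefiltered
# detection path. Returns a sorted "i:j" pair key vector.
bruteForceContactPairs <- function(gs, criteria = contactCriteria()) {
  g <- groupTable(gs)
  co <- groupCoords(gs)
  no <- groupNormals(gs)
  n <- nrow(g)
  if (n < 2) return(character(0))
  keys <- lapply(seq_len(n), function(i)
    PiPiContacts:::groupAtomKeys(rownames(co[[i]]), g$chain[i],
                                 g$resIndex[i]))
  chain <- g$chain; cat <- g$category; ridx <- g$resIndex
  ids <- g$groupId
  out <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # covalently bonded cterm/backbone neighbors are not candidates
    if (chain[i] == chain[j] &&
        ((cat[i] == "cterm" && cat[j] == "backbone" &&
            ridx[j] == ridx[i] - 1L) ||
           (cat[j] == "cterm" && cat[i] == "backbone" &&
              ridx[i] == ridx[j] - 1L))) next
    res <- isPlanarPiContact(co[[i]], no[i, ], co[[j]], no[j, ],
                             criteria, keys[[i]], keys[[j]])
    if (res$contact)
      out <- c(out, paste(sort(c(ids[i], ids[j])), collapse = "|"))
  }
  sort(out)
}

# Pair keys of a PlanarContactSet in the same sorted form (the detector
# orders each pair deterministically; re-sort per pair for comparability).
detectedContactPairs <- function(ct) {
  df <- contactTable(ct)
  if (!nrow(df)) return(character(0))
  sort(vapply(seq_len(nrow(df)), function(k)
    paste(sort(c(df$idA[k], df$idB[k])), collapse = "|"), character(1)))
}

applyRigidMotion <- function(gs, R, t) {
  co <- lapply(groupCoords(gs), function(m)
    sweep(m %*% t(R), 2, t, "+"))
  no <- groupNormals(gs) %*% t(R)
  new("Sp2GroupSet", groups = groupTable(gs), coords = co,
      normals = no, skipped = skippedGroups(gs))
}

# Expensive shared fixture: a synthetic corpus with its trained stage-1
# predictor, built once per test run.
.shared <- new.env(parent = emptyenv())

sharedPredictor <- function() {
  if (is.null(.shared$predictor)) {
    corpus <- makeAnnotationCorpus(nChains = 400, lengthRange = c(150, 300),
                                   seed = 42L)
    pr <- suppressWarnings(trainContactPredictor(corpus$annotations,
                                                 seed = 43L))
    .shared$predictor <- list(
      corpus = corpus, ann = corpus$annotations,
      split = list(train = c(pr$split$table, pr$split$calibration),
                   test = pr$split$test, parts = pr$split),
      table = pr$table, calibration = pr$calibration)
  }
  .shared$predictor
}

# Small hand-built annotation set: one chain, explicit contacts.
tinyAnnotations <- function(sequence = "GAFGAGAGFG", contacts = NULL) {
  chains <- data.frame(chainKey = "T1_A", sequence = sequence,
                       resolution = NA_real_, rFactor = NA_real_,
                       pdbId = "T1", stringsAsFactors = FALSE)
  if (is.null(contacts)) contacts <- PiPiContacts:::emptyAnnotationContacts()
  chainAnnotations(chains, contacts)
}

tinyContactRow <- function(iA, iB, catA = "sidechain", catB = "sidechain",
                           typeA = "F", typeB = "F", chainClass = "intra",
                           key = "T1_A", keyB = key) {
  sep <- if (chainClass == "intra") abs(iA - iB) else Inf
  data.frame(chainKeyA = key, chainKeyB = keyB, typeA = typeA, typeB = typeB,
             categoryA = catA, categoryB = catB,
             aromaticA = typeA %in% c("W", "F", "Y", "H"),
             aromaticB = typeB %in% c("W", "F", "Y", "H"),
             resIndexA = iA, resIndexB = iB, seqSeparation = sep,
             rangeClass = if (is.finite(sep) && sep <= 4) "short" else "long",
             chainClass = chainClass, stringsAsFactors = FALSE)
}
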