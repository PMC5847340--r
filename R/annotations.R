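# Per-chain contact annotations: construction from structures, the
# tab-separated annotation dialect, and DSSP consumption.

#' Construct a ChainAnnotations object
#'
#' @param chains data.frame with at least \code{chainKey} and
#'   \code{sequence}; \code{resolution}, \code{rFactor} and \code{pdbId}
#'   are filled with NA / derived defaults when absent.
#' @param contacts contact data.frame (see
#'   \code{\link{writeContactAnnotations}} for columns); may be empty.
#' @param residues optional residue table; derived from the sequences when
#'   omitted.
#' @return a \linkS4class{ChainAnnotations}.
#' @export
chainAnnotations <- function(chains, contacts = emptyAnnotationContacts(),
                             residues = NULL) {
  if (!"resolution" %in% names(chains)) chains$resolution <- NA_real_
  if (!"rFactor" %in% names(chains)) chains$rFactor <- NA_real_
  if (!"pdbId" %in% names(chains))
    chains$pdbId <- sub("_.*$", "", chains$chainKey)
  if (is.null(residues)) {
    residues <- do.call(rbind, lapply(seq_len(nrow(chains)), function(i) {
      aa <- strsplit(chains$sequence[i], "")[[1]]
      data.frame(chainKey = chains$chainKey[i], resIndex = seq_along(aa),
                 aa = aa, waterCount = NA_integer_, ss = NA_character_,
                 interfaceClass = "none", stringsAsFactors = FALSE)
    }))
    if (is.null(residues))
      residues <- data.frame(chainKey = character(), resIndex = integer(),
                             aa = character(), waterCount = integer(),
                             ss = character(), interfaceClass = character(),
                             stringsAsFactors = FALSE)
  }
  for (col in c("waterCount", "ss", "interfaceClass"))
    if (!col %in% names(residues))
      residues[[col]] <- if (col == "interfaceClass") "none" else NA
  rownames(chains) <- rownames(residues) <- rownames(contacts) <- NULL
  new("ChainAnnotations", chains = chains, residues = residues,
      contacts = contacts)
}

emptyAnnotationContacts <- function() {
  data.frame(chainKeyA = character(), chainKeyB = character(),
             typeA = character(), typeB = character(),
             categoryA = character(), categoryB = character(),
             aromaticA = logical(), aromaticB = logical(),
             resIndexA = integer(), resIndexB = integer(),
             seqSeparation = numeric(), rangeClass = character(),
             chainClass = character(), stringsAsFactors = FALSE)
}

#' Annotate a structure with its contacts and residue context
#'
#' Runs contact detection and assembles the tabular survey form: chain
#' sequences, per-residue water contact counts (optional), interface classes
#' (any sidechain atom within the VDW cutoff of another chain, or of a
#' symmetry copy), and the contact list.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param criteria a \linkS4class{ContactCriteria}.
#' @param pdbId identifier used as the annotation block key (defaults to the
#'   file basename).
#' @param symmetry measure symmetry contacts/interfaces when crystal records
#'   permit.
#' @param waters compute per-residue water contact counts.
#' @param radius symmetry inclusion radius, angstrom.
#' @return a \linkS4class{ChainAnnotations}.
#' @export
annotateStructure <- function(model, criteria = contactCriteria(),
                              pdbId = NULL, symmetry = TRUE, waters = FALSE,
                              radius = 8) {
  if (is.null(pdbId))
    pdbId <- sub("\\.[^.]*$", "", basename(model@source))
  ct <- detectContacts(model, criteria, symmetry = symmetry, radius = radius)
  atoms <- model@atoms
  prot <- atoms[!atoms$isWater & !atoms$isH, , drop = FALSE]
  chains <- unique(prot$chain)
  key <- function(ch) paste0(pdbId, "_", ch)

  chainDf <- do.call(rbind, lapply(chains, function(ch) {
    sel <- prot[prot$chain == ch, ]
    idx <- sort(unique(sel$resIndex))
    aa <- vapply(idx, function(i) {
      r3 <- sel$resid[sel$resIndex == i][1]
      if (r3 %in% names(aaOne)) aaOne[[r3]] else "X"
    }, character(1))
    seqv <- rep("X", max(idx))
    seqv[idx] <- aa
    data.frame(chainKey = key(ch), sequence = paste(seqv, collapse = ""),
               resolution = model@resolution, rFactor = model@rFactor,
               pdbId = pdbId, stringsAsFactors = FALSE)
  }))

  # Interface classes from any-sidechain-atom VDW proximity to other chains
  # (inter_asu takes precedence) or to symmetry copies.
  resDf <- do.call(rbind, lapply(chains, function(ch) {
    sel <- prot[prot$chain == ch, ]
    idx <- sort(unique(sel$resIndex))
    other <- prot[prot$chain != ch, c("x", "y", "z")]
    symAtoms <- NULL
    if (symmetry && length(model@unitCell) && length(model@symmetryOps)) {
      cps <- expandSymmetry(model, radius)
      if (length(cps))
        symAtoms <- do.call(rbind, lapply(cps, function(cp)
          cp$atoms[!cp$atoms$isH & !cp$atoms$isWater, c("x", "y", "z")]))
    }
    data.frame(
      chainKey = key(ch), resIndex = idx,
      aa = vapply(idx, function(i) {
        r3 <- sel$resid[sel$resIndex == i][1]
        if (r3 %in% names(aaOne)) aaOne[[r3]] else "X"
      }, character(1)),
      waterCount = if (waters) vapply(idx, function(i)
        waterContactCount(model, ch, i, criteria@vdwCutoff,
                          includeSymmetry = symmetry, radius = radius),
        integer(1)) else NA_integer_,
      ss = NA_character_,
      interfaceClass = vapply(idx, function(i) {
        sc <- sel[sel$resIndex == i &
                    !sel$elety %in% c("N", "CA", "C", "O", "OXT"),
                  c("x", "y", "z")]
        if (!nrow(sc)) return("none")
        if (nrow(other) &&
            min(crossDist(as.matrix(sc), as.matrix(other))) <=
              criteria@vdwCutoff) return("inter_asu")
        if (!is.null(symAtoms) && nrow(symAtoms) &&
            min(crossDist(as.matrix(sc), as.matrix(symAtoms))) <=
              criteria@vdwCutoff) return("symmetry")
        "none"
      }, character(1)),
      stringsAsFactors = FALSE)
  }))

  cd <- ct@contacts
  if (nrow(cd) == 0)
    return(chainAnnotations(chainDf, emptyAnnotationContacts(), resDf))
  contacts <- data.frame(
    chainKeyA = paste0(pdbId, "_", cd$chainA),
    chainKeyB = paste0(pdbId, "_", cd$chainB),
    typeA = cd$seqIdentityA, typeB = cd$seqIdentityB,
    categoryA = cd$categoryA, categoryB = cd$categoryB,
    aromaticA = cd$aromaticA, aromaticB = cd$aromaticB,
    resIndexA = cd$resIndexA, resIndexB = cd$resIndexB,
    seqSeparation = cd$seqSeparation, rangeClass = cd$rangeClass,
    chainClass = cd$chainClass, stringsAsFactors = FALSE)
  chainAnnotations(chainDf, contacts, resDf)
}

#' Write / read contact annotations
#'
#' The contact file has one contact per line with sp2 group types named by
#' single amino acid letters for sidechains and by the flanking residue pair
#' (i, i+1) for backbone peptide units; the chains file lists each chain's
#' sequence, resolution and R-factor and carries the residue counts used as
#' frequency denominators.
#'
#' @param ann a \linkS4class{ChainAnnotations}.
#' @param contactsPath,chainsPath output/input TSV paths.
#' @return \code{writeContactAnnotations} returns the paths invisibly;
#'   \code{readContactAnnotations} returns a \linkS4class{ChainAnnotations}.
#' @export
writeContactAnnotations <- function(ann, contactsPath, chainsPath) {
  utils::write.table(ann@contacts, contactsPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ch <- ann@chains
  counts <- t(vapply(ch$sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    vapply(STANDARD_AA, function(a) sum(aa == a), integer(1))
  }, integer(length(STANDARD_AA))))
  colnames(counts) <- paste0("n", STANDARD_AA)
  utils::write.table(cbind(ch, counts), chainsPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(contactsPath, chainsPath))
}

#' @rdname writeContactAnnotations
#' @export
readContactAnnotations <- function(contactsPath, chainsPath) {
  # single-letter amino-acid types ("F") and dipeptides ("NA") must never be
  # coerced to logicals or missing values
  contacts <- utils::read.delim(
    contactsPath, stringsAsFactors = FALSE, na.strings = character(0),
    colClasses = c(typeA = "character", typeB = "character",
                   chainKeyA = "character", chainKeyB = "character"))
  chains <- utils::read.delim(chainsPath, stringsAsFactors = FALSE,
                              na.strings = "NA")
  chains <- chains[, setdiff(names(chains), paste0("n", STANDARD_AA))]
  chainAnnotations(chains, contacts)
}

#' Read a DSSP assignment file
#'
#' Extracts per-residue simplified one-letter secondary-structure codes from
#' DSSP output; blank assignments become "-".
#'
#' @param path DSSP output file.
#' @return named character vector, one assignment string per chain.
#' @export
readDssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("not a DSSP file (missing residue table): ", path)
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  chain <- substr(body, 12, 12)
  aa <- substr(body, 14, 14)
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  keep <- aa != "!"  # chain-break records carry no residue
  chain <- chain[keep]; ss <- ss[keep]
  vapply(unique(chain), function(ch) paste(ss[chain == ch], collapse = ""),
         character(1))
}

#' Attach secondary-structure assignments to annotations
#'
#' @param ann a \linkS4class{ChainAnnotations}.
#' @param ss named character vector (chainKey -> assignment string, one
#'   letter per residue in the chain's sequence).
#' @return the updated \linkS4class{ChainAnnotations}.
#' @export
assignSecondaryStructure <- function(ann, ss) {
  for (ck in names(ss)) {
    i <- match(ck, ann@chains$chainKey)
    if (is.na(i)) stop("unknown chain: ", ck)
    if (nchar(ss[[ck]]) != nchar(ann@chains$sequence[i]))
      stop("assignment length differs from sequence length for ", ck)
    letters1 <- strsplit(ss[[ck]], "")[[1]]
    sel <- ann@residues$chainKey == ck
    ann@residues$ss[sel] <- letters1[ann@residues$resIndex[sel]]
  }
  ann
}
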