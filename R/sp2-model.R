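# Definition and extraction of planar sp2 groups (and sp3 control planes).

#' Load planar group definitions
#'
#' Reads the atom-name tables defining each planar group: the nine sp2
#' sidechain groups (W, F, Y, H, R, Q, N, E, D), the backbone peptide unit,
#' the C-terminal carboxyl, and the sp3 control planes (L, V, M, I, C, S, T,
#' K). The shipped table can be replaced to test alternative atom
#' memberships.
#'
#' @param path path to a definitions TSV; default uses the table shipped with
#'   the package.
#' @return data.frame with columns \code{identity}, \code{kind},
#'   \code{aromatic}, \code{members} (list of atom-name vectors),
#'   \code{triple} (list of 3 atom names), \code{carbonCount}.
#' @examples
#' defs <- sp2Definitions()
#' defs[defs$identity == "F", "carbonCount"]
#' @export
sp2Definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sp2_definitions.tsv",
                        package = "PiPiContacts")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$members <- strsplit(df$members, ",", fixed = TRUE)
  df$triple <- strsplit(df$triple, ",", fixed = TRUE)
  bad <- !vapply(seq_len(nrow(df)),
                 function(i) all(df$triple[[i]] %in% df$members[[i]]),
                 logical(1))
  if (any(bad))
    stop("plane triple not a subset of member atoms for: ",
         paste(df$identity[bad], collapse = ", "))
  # Carbon count by element inferred from PDB atom-name conventions: a name
  # starting with C is carbon unless it is CL; suffixed peptide names are
  # stripped first.
  df$carbonCount <- vapply(df$members, function(m) {
    nm <- sub("_(i|ip1)$", "", m)
    sum(substr(nm, 1, 1) == "C" & nm != "CL")
  }, integer(1))
  df
}

# Element of a (suffix-stripped) member atom name: first character for the
# standard protein atoms used here (C, N, O, S).
memberElement <- function(names) substr(sub("_(i|ip1)$", "", names), 1, 1)

#' Unit normal of a plane through three points
#'
#' The normal is the normalized cross product (p2 - p1) x (p3 - p1); its sign
#' is arbitrary but deterministic in the point order.
#'
#' @param pts 3 x 3 numeric matrix, one point per row, angstrom.
#' @return unit 3-vector.
#' @examples
#' planeNormal(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))  # (0, 0, 1)
#' @export
planeNormal <- function(pts) {
  stopifnot(is.matrix(pts), nrow(pts) == 3, ncol(pts) == 3)
  n <- cross3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
  len <- sqrt(sum(n^2))
  if (len < 1e-6)
    stop("degenerate plane: the three points are collinear")
  n / len
}

# Internal: assemble a group set from accumulated lists.
newSp2GroupSet <- function(rows, coords, normals, skipped) {
  groups <- if (length(rows)) do.call(rbind, rows) else
    data.frame(groupId = character(), identity = character(),
               seqIdentity = character(), category = character(),
               aromatic = logical(), carbonCount = integer(),
               chain = character(), resIndex = integer(),
               resno = integer(), stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  normals <- if (length(normals)) do.call(rbind, normals) else
    matrix(numeric(0), ncol = 3)
  new("Sp2GroupSet", groups = groups, coords = coords, normals = normals,
      skipped = skipped)
}

# Per-residue atom lookup for one chain: list of coordinate matrices with
# atom-name rownames, ordered by resIndex.
chainResidueAtoms <- function(atoms) {
  atoms <- atoms[!atoms$isWater & !atoms$isH, , drop = FALSE]
  split(atoms, atoms$resIndex)
}

residueCoordMatrix <- function(res) {
  m <- as.matrix(res[, c("x", "y", "z")])
  rownames(m) <- res$elety
  m
}

# Extract one defined group from a residue's atoms; NULL when incomplete or
# degenerate.
takeGroup <- function(coordMat, members, triple) {
  if (!all(members %in% rownames(coordMat))) return(NULL)
  co <- coordMat[members, , drop = FALSE]
  n <- tryCatch(planeNormal(co[triple, , drop = FALSE]),
                error = function(e) NULL)
  if (is.null(n)) return(NULL)
  list(coords = co, normal = n)
}

#' Extract planar sp2 groups from a structure
#'
#' Instantiates one group per complete sp2 sidechain group, one backbone
#' peptide unit per bonded pair of consecutive residues (C(i)-N(i+1)
#' distance at most 1.8 angstrom, same chain), and one C-terminal carboxyl
#' per residue carrying an OXT atom. Groups missing any expected heavy atom
#' are skipped and counted, mirroring the survey's filtering of incomplete
#' sp2 systems.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param definitions group definition table from \code{\link{sp2Definitions}}.
#' @param chains optional chain subset.
#' @return a \linkS4class{Sp2GroupSet}.
#' @examples
#' mod <- makeStackedPair(gap = 3.5)
#' extractSp2Groups(mod)
#' @export
extractSp2Groups <- function(model, definitions = sp2Definitions(),
                             chains = NULL) {
  extractGroupsByKind(model, definitions,
                      kinds = c("sidechain", "backbone", "cterm"),
                      chains = chains)
}

#' Extract sp3 control planes from a structure
#'
#' Terminal three-atom planar surfaces on fully sp3-hybridized sidechains
#' (L, V, M, I, C, S, T, K), used as the null expectation when measuring
#' planar stacking enrichment.
#'
#' @inheritParams extractSp2Groups
#' @return a \linkS4class{Sp2GroupSet} with category "sp3".
#' @export
extractSp3Controls <- function(model, definitions = sp2Definitions(),
                               chains = NULL) {
  extractGroupsByKind(model, definitions, kinds = "sp3", chains = chains)
}

extractGroupsByKind <- function(model, definitions, kinds, chains = NULL) {
  atoms <- model@atoms
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  defs <- definitions[definitions$kind %in% kinds, , drop = FALSE]
  scDefs <- defs[defs$kind %in% c("sidechain", "sp3"), , drop = FALSE]
  doPeptide <- "backbone" %in% defs$kind
  doCterm <- "cterm" %in% defs$kind

  rows <- list(); coordsL <- list(); normalsL <- list()
  skipped <- integer(0)
  bump <- function(id) {
    skipped[id] <<- (if (id %in% names(skipped)) skipped[id] else 0L) + 1L
  }

  for (ch in unique(atoms$chain[!atoms$isWater])) {
    resList <- chainResidueAtoms(atoms[atoms$chain == ch, , drop = FALSE])
    if (!length(resList)) next
    idx <- as.integer(names(resList))
    mats <- lapply(resList, residueCoordMatrix)
    resids <- vapply(resList, function(r) r$resid[1], character(1))
    resnos <- vapply(resList, function(r) r$resno[1], numeric(1))
    oneLetter <- unname(aaOne[resids])

    addRow <- function(def, grp, resIndex, resno, seqId) {
      rows[[length(rows) + 1L]] <<- data.frame(
        groupId = sprintf("%s:%d:%s", ch, resIndex, def$identity),
        identity = def$identity, seqIdentity = seqId,
        category = def$kind, aromatic = def$aromatic,
        carbonCount = def$carbonCount, chain = ch,
        resIndex = resIndex, resno = resno, stringsAsFactors = FALSE)
      coordsL[[length(coordsL) + 1L]] <<- grp$coords
      normalsL[[length(normalsL) + 1L]] <<- grp$normal
    }

    # Sidechain sp2 groups and sp3 control planes.
    if (nrow(scDefs)) {
      for (k in seq_along(idx)) {
        aa <- oneLetter[k]
        if (is.na(aa)) next
        j <- match(aa, scDefs$identity)
        if (is.na(j)) next
        def <- scDefs[j, ]
        grp <- takeGroup(mats[[k]], def$members[[1]], def$triple[[1]])
        if (is.null(grp)) { bump(def$identity); next }
        addRow(def, grp, idx[k], resnos[k], aa)
      }
    }

    # Backbone peptide units between bonded consecutive residues.
    if (doPeptide && length(idx) >= 2) {
      def <- defs[defs$kind == "backbone", ][1, ]
      for (k in seq_len(length(idx) - 1L)) {
        if (idx[k + 1L] != idx[k] + 1L) next
        mi <- mats[[k]]; mj <- mats[[k + 1L]]
        need_i <- c("CA", "C", "O"); need_j <- c("N", "CA")
        if (!all(need_i %in% rownames(mi)) || !all(need_j %in% rownames(mj))) {
          bump("PEPTIDE"); next
        }
        if (sqrt(sum((mi["C", ] - mj["N", ])^2)) > 1.8) next  # chain break
        co <- rbind(mi[need_i, , drop = FALSE], mj[need_j, , drop = FALSE])
        rownames(co) <- c("CA_i", "C_i", "O_i", "N_ip1", "CA_ip1")
        n <- tryCatch(
          planeNormal(co[c("O_i", "C_i", "N_ip1"), , drop = FALSE]),
          error = function(e) NULL)
        if (is.null(n)) { bump("PEPTIDE"); next }
        seqId <- paste0(
          if (is.na(oneLetter[k])) "X" else oneLetter[k],
          if (is.na(oneLetter[k + 1L])) "X" else oneLetter[k + 1L])
        addRow(def, list(coords = co, normal = n), idx[k], resnos[k], seqId)
      }
    }

    # C-terminal carboxyl groups (any residue carrying OXT).
    if (doCterm) {
      def <- defs[defs$kind == "cterm", ][1, ]
      for (k in seq_along(idx)) {
        if (!"OXT" %in% rownames(mats[[k]])) next
        grp <- takeGroup(mats[[k]], def$members[[1]], def$triple[[1]])
        if (is.null(grp)) { bump("CTERM"); next }
        aa <- if (is.na(oneLetter[k])) "X" else oneLetter[k]
        addRow(def, grp, idx[k], resnos[k], aa)
      }
    }
  }
  newSp2GroupSet(rows, coordsL, normalsL, skipped)
}
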