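# Reading PDB/mmCIF structures, normalizing them to the survey conventions,
# and expanding crystallographic symmetry neighbors.

#' Parse a protein structure file
#'
#' Reads a PDB or mmCIF file (through bio3d) and normalizes it: only the
#' first-encountered altloc variant of each atom is kept, MSE is mapped to
#' MET, other non-standard non-water residues are dropped with a message,
#' waters are retained and flagged, and hydrogens are retained but flagged so
#' heavy-atom distance computations ignore them. Crystallographic metadata
#' (unit cell, symmetry operators, resolution, R-factor) is extracted from
#' the header when present.
#'
#' @param path file path.
#' @param format "pdb", "cif" or "auto" (by file extension).
#' @return a \linkS4class{StructureModel}.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeStructureFixture(makeStackedPair(gap = 3.5), f)
#' parseStructure(f)
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  parsed <- tryCatch(suppressWarnings(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  atoms <- parsed$atom
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("empty structure: no atom records in ", path)
  hdr <- if (format == "pdb") parsePdbHeader(path) else parseCifHeader(path)
  normalizeStructure(atoms, source = path, resolution = hdr$resolution,
                     rFactor = hdr$rFactor, unitCell = hdr$unitCell,
                     symmetryOps = hdr$symmetryOps)
}

# Build a normalized StructureModel from a bio3d-style atom data.frame.
normalizeStructure <- function(atoms, source = "", resolution = NA_real_,
                               rFactor = NA_real_, unitCell = numeric(0),
                               symmetryOps = list()) {
  keep <- c("elety", "alt", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "elesy")
  for (col in setdiff(keep, names(atoms))) atoms[[col]] <- NA
  atoms <- atoms[, keep]
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$alt[is.na(atoms$alt)] <- ""

  # Map non-standard residues with a standard parent; drop the rest
  # (waters excepted).
  mse <- atoms$resid == "MSE"
  if (any(mse)) {
    atoms$resid[mse] <- "MET"
    atoms$elety[mse & atoms$elety == "SE"] <- "SD"
    atoms$elesy[mse & atoms$elesy == "SE"] <- "S"
  }
  isWater <- atoms$resid %in% WATER_RESID
  known <- atoms$resid %in% names(aaOne)
  if (any(!known & !isWater)) {
    dropped <- unique(atoms$resid[!known & !isWater])
    message("dropping non-standard residues without a mapping: ",
            paste(dropped, collapse = ", "))
    sel <- known | isWater
    atoms <- atoms[sel, , drop = FALSE]
    isWater <- isWater[sel]
  }
  if (nrow(atoms) == 0) stop("empty structure after normalization")

  # First set of coordinates when represented by multiple conformations:
  # keep the first-encountered altloc per (chain, residue, atom name).
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "\r")
  sel <- !duplicated(key)
  atoms <- atoms[sel, , drop = FALSE]
  isWater <- isWater[sel]

  elesy <- atoms$elesy
  guess <- substr(gsub("[0-9' ]", "", atoms$elety), 1, 1)
  elesy[is.na(elesy) | elesy == ""] <- guess[is.na(elesy) | elesy == ""]
  atoms$elesy <- elesy
  atoms$isWater <- isWater
  atoms$isH <- elesy %in% c("H", "D")

  # Contiguous per-chain residue index over non-water residues, file order;
  # insertion codes are distinct residues.
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  atoms$resIndex <- NA_integer_
  for (ch in unique(atoms$chain[!isWater])) {
    sel <- atoms$chain == ch & !isWater
    u <- unique(rkey[sel])
    atoms$resIndex[sel] <- match(rkey[sel], u)
  }
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, resolution = resolution,
      rFactor = rFactor, unitCell = unitCell, symmetryOps = symmetryOps,
      source = source)
}

# --- header readers ---------------------------------------------------------

parsePdbHeader <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(resolution = NA_real_, rFactor = NA_real_,
              unitCell = numeric(0), symmetryOps = list())
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    f <- strsplit(trimws(substr(cr[1], 7, 54)), "\\s+")[[1]]
    if (length(f) >= 6) out$unitCell <- as.numeric(f[1:6])
  }
  res <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(res)) {
    tail0 <- sub(".*RESOLUTION\\.?", "", res[1])
    m <- regmatches(tail0, regexpr("[0-9]+\\.?[0-9]*", tail0))
    if (length(m)) out$resolution <- as.numeric(m)
  }
  rv <- grep("^REMARK   3   R VALUE", lines, value = TRUE)
  rv <- grep("WORKING SET", rv, value = TRUE)
  if (length(rv)) {
    m <- regmatches(rv[1], regexpr("[0-9]\\.[0-9]+", rv[1]))
    if (length(m)) out$rFactor <- as.numeric(m)
  }
  sm <- grep("^REMARK 290 +SMTRY", lines, value = TRUE)
  if (length(sm)) {
    tok <- lapply(strsplit(trimws(sm), "\\s+"), function(x) x)
    rowNo <- as.integer(sub("SMTRY", "", vapply(tok, `[`, "", 3)))
    opNo <- as.integer(vapply(tok, `[`, "", 4))
    vals <- t(vapply(tok, function(x) as.numeric(x[5:8]), numeric(4)))
    ops <- list()
    for (k in sort(unique(opNo))) {
      sel <- opNo == k
      R <- matrix(0, 3, 3); t <- numeric(3)
      R[rowNo[sel], ] <- vals[sel, 1:3]
      t[rowNo[sel]] <- vals[sel, 4]
      ops[[k]] <- list(R = R, t = t)
    }
    out$symmetryOps <- ops
  } else if (length(out$unitCell)) {
    out$symmetryOps <- list(list(R = diag(3), t = numeric(3)))
  }
  out
}

parseCifHeader <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(resolution = NA_real_, rFactor = NA_real_,
              unitCell = numeric(0), symmetryOps = list())
  val <- function(tag) {
    hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][2]))
  }
  cell <- c(val("_cell.length_a"), val("_cell.length_b"),
            val("_cell.length_c"), val("_cell.angle_alpha"),
            val("_cell.angle_beta"), val("_cell.angle_gamma"))
  if (all(is.finite(cell))) out$unitCell <- cell
  out$resolution <- val("_refine.ls_d_res_high")
  if (is.na(out$resolution)) out$resolution <- val("_reflns.d_resolution_high")
  out$rFactor <- val("_refine.ls_R_factor_R_work")

  # Symmetry operator strings, fractional frame, converted to orthogonal.
  si <- grep("_symmetry_equiv\\.pos_as_xyz|_symmetry_equiv_pos_as_xyz|_space_group_symop\\.operation_xyz",
             lines)
  if (length(si) && length(out$unitCell)) {
    xyz <- character(0)
    for (i in seq(si[1] + 1, length(lines))) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "_") || startsWith(ln, "loop_") ||
          startsWith(ln, "#") || startsWith(ln, "data_")) break
      ln <- sub("^[0-9]+\\s+", "", ln)  # optional op id column
      xyz <- c(xyz, gsub("'", "", ln))
    }
    M <- cellOrthMatrix(out$unitCell)
    Minv <- solve(M)
    out$symmetryOps <- lapply(xyz, function(s) {
      fo <- parseSymopXyz(s)
      list(R = M %*% fo$R %*% Minv, t = as.numeric(M %*% fo$t))
    })
  } else if (length(out$unitCell)) {
    out$symmetryOps <- list(list(R = diag(3), t = numeric(3)))
  }
  out
}

# Parse a fractional symmetry-operator string such as "-X,Y+1/2,-Z".
parseSymopXyz <- function(s) {
  comps <- strsplit(toupper(gsub("\\s", "", s)), ",")[[1]]
  if (length(comps) != 3) stop("malformed symmetry operator: ", s)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    c0 <- comps[i]
    for (j in 1:3) {
      ax <- c("X", "Y", "Z")[j]
      if (grepl(paste0("-", ax), c0, fixed = TRUE)) R[i, j] <- -1
      else if (grepl(ax, c0, fixed = TRUE)) R[i, j] <- 1
      c0 <- gsub(paste0("[+-]?", ax), "", c0)
    }
    if (nchar(c0)) {
      if (!grepl("^[0-9+/.-]+$", c0))
        stop("malformed symmetry operator: ", s)
      t[i] <- eval(parse(text = c0)[[1]])
    }
  }
  list(R = R, t = t)
}

# --- symmetry expansion -----------------------------------------------------

#' Expand crystallographic symmetry neighbors
#'
#' Applies every symmetry operator combined with lattice translations of
#' -1..1 cells along each axis, and returns every copy that places any atom
#' within \code{radius} angstrom of the primary model. The identity copy
#' (identity operator, zero shift) is excluded.
#'
#' @param model a \linkS4class{StructureModel} with crystal records.
#' @param radius inclusion radius in angstrom.
#' @return list of \code{list(label, atoms)} where \code{atoms} is the
#'   transformed atom data.frame of one copy.
#' @export
expandSymmetry <- function(model, radius) {
  if (!length(model@unitCell) || !length(model@symmetryOps))
    stop("symmetry unavailable: structure has no crystal records")
  if (radius <= 0) return(list())
  atoms <- model@atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  heavy <- !atoms$isH
  prim <- xyz[heavy, , drop = FALSE]
  lo <- apply(prim, 2, min) - radius
  hi <- apply(prim, 2, max) + radius
  M <- cellOrthMatrix(model@unitCell)
  shifts <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  out <- list()
  for (k in seq_along(model@symmetryOps)) {
    op <- model@symmetryOps[[k]]
    isIdent <- max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t)) < 1e-9
    base <- xyz %*% t(op$R) + matrix(op$t, nrow(xyz), 3, byrow = TRUE)
    for (s in seq_len(nrow(shifts))) {
      sh <- as.numeric(M %*% shifts[s, ])
      if (isIdent && all(shifts[s, ] == 0)) next
      co <- base + matrix(sh, nrow(xyz), 3, byrow = TRUE)
      ch <- co[heavy, , drop = FALSE]
      inBox <- ch[, 1] >= lo[1] & ch[, 1] <= hi[1] &
        ch[, 2] >= lo[2] & ch[, 2] <= hi[2] &
        ch[, 3] >= lo[3] & ch[, 3] <= hi[3]
      if (!any(inBox)) next
      if (min(crossDist(ch[inBox, , drop = FALSE], prim)) > radius) next
      cp <- atoms
      cp$x <- co[, 1]; cp$y <- co[, 2]; cp$z <- co[, 3]
      out[[length(out) + 1L]] <- list(
        label = sprintf("sym%d_%d_%d_%d", k, shifts[s, 1], shifts[s, 2],
                        shifts[s, 3]),
        atoms = cp)
    }
  }
  out
}

# --- fixture writers --------------------------------------------------------

#' Write a minimal structure fixture file
#'
#' Emits a valid single-model PDB (CRYST1 + REMARK 290 + ATOM/HETATM) or a
#' minimal mmCIF carrying the same records, suitable for exercising the
#' parser and symmetry expansion in tests.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output path.
#' @param format "pdb" or "cif".
#' @param symOpsXyz optional character vector of fractional operator strings
#'   (e.g. \code{c("X,Y,Z", "-X,Y+1/2,-Z")}); defaults to the identity when a
#'   unit cell is present. PDB output converts them to orthogonal-frame
#'   REMARK 290 operators.
#' @return \code{path}, invisibly.
#' @export
writeStructureFixture <- function(model, path, format = c("pdb", "cif"),
                                  symOpsXyz = NULL) {
  format <- match.arg(format)
  atoms <- model@atoms
  cell <- model@unitCell
  if (is.null(symOpsXyz)) symOpsXyz <- "X,Y,Z"
  lines <- character(0)
  if (format == "pdb") {
    if (!is.na(model@resolution))
      lines <- c(lines, sprintf(
        "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", model@resolution))
    if (!is.na(model@rFactor))
      lines <- c(lines, sprintf(
        "REMARK   3   R VALUE            (WORKING SET) : %.3f",
        model@rFactor))
    if (length(cell)) {
      M <- cellOrthMatrix(cell)
      Minv <- solve(M)
      for (k in seq_along(symOpsXyz)) {
        fo <- parseSymopXyz(symOpsXyz[k])
        R <- M %*% fo$R %*% Minv
        t <- as.numeric(M %*% fo$t)
        for (r in 1:3)
          lines <- c(lines, sprintf(
            "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
            r, k, R[r, 1], R[r, 2], R[r, 3], t[r]))
      }
      lines <- c(lines, sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        cell[1], cell[2], cell[3], cell[4], cell[5], cell[6]))
    }
    for (i in seq_len(nrow(atoms))) {
      a <- atoms[i, ]
      name <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety)
      else a$elety
      lines <- c(lines, sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (a$isWater) "HETATM" else "ATOM", i, name,
        substr(a$alt, 1, 1), a$resid, a$chain, as.integer(a$resno),
        substr(a$insert, 1, 1), a$x, a$y, a$z, a$o, 0, a$elesy))
    }
    lines <- c(lines, "END")
  } else {
    lines <- c("data_fixture")
    if (length(cell))
      lines <- c(lines,
        sprintf("_cell.length_a    %.4f", cell[1]),
        sprintf("_cell.length_b    %.4f", cell[2]),
        sprintf("_cell.length_c    %.4f", cell[3]),
        sprintf("_cell.angle_alpha %.4f", cell[4]),
        sprintf("_cell.angle_beta  %.4f", cell[5]),
        sprintf("_cell.angle_gamma %.4f", cell[6]))
    if (!is.na(model@resolution))
      lines <- c(lines, sprintf("_refine.ls_d_res_high %.2f",
                                model@resolution))
    if (!is.na(model@rFactor))
      lines <- c(lines, sprintf("_refine.ls_R_factor_R_work %.3f",
                                model@rFactor))
    lines <- c(lines, "loop_", "_symmetry_equiv.pos_as_xyz",
               sprintf("'%s'", symOpsXyz))
    lines <- c(lines, "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num")
    for (i in seq_len(nrow(atoms))) {
      a <- atoms[i, ]
      alt <- if (is.na(a$alt) || a$alt == "") "." else a$alt
      ins <- if (is.na(a$insert) || a$insert == "") "?" else a$insert
      lines <- c(lines, sprintf(
        "%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
        if (a$isWater) "HETATM" else "ATOM", i, a$elesy, a$elety, alt,
        a$resid, a$chain, as.integer(a$resno), ins, a$x, a$y, a$z, a$o,
        as.integer(a$resno), a$resid, a$chain, a$elety))
    }
    lines <- c(lines, "#")
  }
  writeLines(lines, path)
  invisible(path)
}

# Assemble a StructureModel from minimal per-atom vectors (fixture builders).
structureFromAtoms <- function(elety, resid, chain, resno, xyz,
                               isWater = FALSE, alt = "", occupancy = 1,
                               resolution = NA_real_, rFactor = NA_real_,
                               unitCell = numeric(0), symmetryOps = list(),
                               source = "fixture") {
  n <- length(elety)
  atoms <- data.frame(
    elety = elety, alt = rep_len(alt, n), resid = resid, chain = chain,
    resno = resno, insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = rep_len(occupancy, n), elesy = memberElement(elety),
    stringsAsFactors = FALSE)
  atoms$isWater <- rep_len(isWater, n)
  atoms$isH <- FALSE
  # Fixture builders preserve residue-number gaps so sequence separations
  # equal the intended resno differences.
  atoms$resIndex <- NA_integer_
  for (ch in unique(atoms$chain[!atoms$isWater])) {
    sel <- atoms$chain == ch & !atoms$isWater
    atoms$resIndex[sel] <- as.integer(atoms$resno[sel]) -
      min(as.integer(atoms$resno[sel])) + 1L
  }
  new("StructureModel", atoms = atoms, resolution = resolution,
      rFactor = rFactor, unitCell = unitCell, symmetryOps = symmetryOps,
      source = source)
}
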