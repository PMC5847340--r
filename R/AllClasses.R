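#' @import methods
NULL

#' Geometric criteria defining a planar pi-pi contact
#'
#' A contact between two sp2 groups is accepted when (i) at least
#' \code{minAtomPairs} heavy-atom pairs lie within \code{vdwCutoff} angstrom,
#' (ii) surfaces elevated \code{elevation} angstrom above each sp2 plane come
#' within \code{surfaceCutoff} angstrom of one another, and (iii) the absolute
#' dot product of the two unit plane normals is at least \code{minAbsDot}.
#' All thresholds are inclusive.
#'
#' @slot vdwCutoff heavy-atom van der Waals contact distance, angstrom.
#' @slot minAtomPairs minimum number of distinct atom pairs in VDW contact.
#' @slot elevation height above the sp2 plane at which surfaces are compared,
#'   angstrom.
#' @slot surfaceCutoff maximum allowed distance between elevated surfaces,
#'   angstrom.
#' @slot minAbsDot minimum absolute dot product of unit plane normals.
#' @exportClass ContactCriteria
setClass("ContactCriteria",
  representation(
    vdwCutoff = "numeric",
    minAtomPairs = "numeric",
    elevation = "numeric",
    surfaceCutoff = "numeric",
    minAbsDot = "numeric"
  ),
  prototype(
    vdwCutoff = 4.9,
    minAtomPairs = 2,
    elevation = 1.7,
    surfaceCutoff = 1.5,
    minAbsDot = 0.8
  )
)

setValidity("ContactCriteria", function(object) {
  msgs <- character()
  for (s in c("vdwCutoff", "minAtomPairs", "elevation", "surfaceCutoff",
              "minAbsDot")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(object@minAbsDot) == 1 && is.finite(object@minAbsDot) &&
      object@minAbsDot > 1)
    msgs <- c(msgs, "'minAbsDot' must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct contact criteria
#'
#' @param vdwCutoff,minAtomPairs,elevation,surfaceCutoff,minAbsDot see
#'   \linkS4class{ContactCriteria}. Defaults are the survey values:
#'   4.9 angstrom, 2 pairs, 1.7 angstrom elevation, 1.5 angstrom surface gap,
#'   |dot| 0.8.
#' @return a \linkS4class{ContactCriteria} object.
#' @examples
#' contactCriteria()
#' contactCriteria(vdwCutoff = 4.5)
#' @export
contactCriteria <- function(vdwCutoff = 4.9, minAtomPairs = 2, elevation = 1.7,
                            surfaceCutoff = 1.5, minAbsDot = 0.8) {
  new("ContactCriteria", vdwCutoff = vdwCutoff, minAtomPairs = minAtomPairs,
      elevation = elevation, surfaceCutoff = surfaceCutoff,
      minAbsDot = minAbsDot)
}

#' A normalized macromolecular structure
#'
#' Holds the heavy-atom records of a single-model structure after
#' normalization: first-encountered altloc kept, MSE mapped to MET, waters
#' retained and flagged, hydrogens flagged so distance computations can skip
#' them. Crystallographic metadata (unit cell, symmetry operators in the
#' orthogonal frame, resolution, R-factor) is carried when present.
#'
#' @slot atoms data.frame with one row per atom: \code{elety} (atom name),
#'   \code{resid} (3-letter residue), \code{chain}, \code{resno} (author
#'   numbering), \code{insert}, \code{x,y,z} (angstrom), \code{o} (occupancy),
#'   \code{alt}, \code{elesy} (element), \code{isWater}, \code{isH},
#'   \code{resIndex} (contiguous per-chain index over non-water residues).
#' @slot resolution crystallographic resolution in angstrom, or \code{NA}.
#' @slot rFactor crystallographic R-factor, or \code{NA}.
#' @slot unitCell numeric(6) cell parameters (a, b, c, alpha, beta, gamma) or
#'   numeric(0) when absent.
#' @slot symmetryOps list of \code{list(R = 3x3, t = 3-vector)} operators in
#'   orthogonal coordinates; contains the identity when crystal records exist.
#' @slot source character label (file path or fixture name).
#' @exportClass StructureModel
setClass("StructureModel",
  representation(
    atoms = "data.frame",
    resolution = "numeric",
    rFactor = "numeric",
    unitCell = "numeric",
    symmetryOps = "list",
    source = "character"
  ),
  prototype(resolution = NA_real_, rFactor = NA_real_,
            unitCell = numeric(0), symmetryOps = list(), source = "")
)

setValidity("StructureModel", function(object) {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z",
            "isWater", "isH", "resIndex")
  miss <- setdiff(need, names(object@atoms))
  msgs <- character()
  if (length(miss))
    msgs <- c(msgs, paste("atoms lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(object@atoms) &&
      !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msgs <- c(msgs, "atom coordinates must be finite")
  if (length(object@unitCell) && length(object@unitCell) != 6)
    msgs <- c(msgs, "unitCell must have length 0 or 6")
  if (length(msgs)) msgs else TRUE
})

#' A set of extracted planar groups
#'
#' One row of \code{groups} per complete sp2 group (or sp3 control plane),
#' with per-group member coordinates and unit plane normals.
#'
#' @slot groups data.frame: \code{groupId}, \code{identity} (one-letter
#'   sidechain code, "PEPTIDE" or "CTERM"; sp3 controls use the one-letter
#'   code of their residue), \code{seqIdentity} (one-letter code, or ordered
#'   dipeptide for peptide units), \code{category} ("sidechain", "backbone",
#'   "cterm" or "sp3"), \code{aromatic}, \code{carbonCount}, \code{chain},
#'   \code{resIndex}, \code{resno}.
#' @slot coords list of per-group member coordinate matrices (rows named by
#'   atom name).
#' @slot normals numeric matrix, one unit normal per group.
#' @slot skipped named integer vector counting incomplete groups by identity.
#' @exportClass Sp2GroupSet
setClass("Sp2GroupSet",
  representation(
    groups = "data.frame",
    coords = "list",
    normals = "matrix",
    skipped = "integer"
  ),
  prototype(skipped = integer(0))
)

setValidity("Sp2GroupSet", function(object) {
  n <- nrow(object@groups)
  msgs <- character()
  if (length(object@coords) != n)
    msgs <- c(msgs, "coords must have one matrix per group")
  if (n && nrow(object@normals) != n)
    msgs <- c(msgs, "normals must have one row per group")
  if (n) {
    nrm <- sqrt(rowSums(object@normals^2))
    if (any(abs(nrm - 1) > 1e-9))
      msgs <- c(msgs, "normals must be unit vectors (|n| = 1 +/- 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Accepted planar pi-pi contacts
#'
#' @slot contacts data.frame with one row per accepted contact; columns
#'   include the two group descriptions (identity, seqIdentity, category,
#'   chain, resIndex), \code{nVdwPairs}, \code{minAtomDistance},
#'   \code{absDot}, \code{minSurfaceDistance}, \code{seqSeparation}
#'   (\code{Inf} between chains), \code{rangeClass} ("short"/"long") and
#'   \code{chainClass} ("intra"/"inter_asu"/"symmetry").
#' @slot criteria the \linkS4class{ContactCriteria} used.
#' @slot nGroups number of groups screened.
#' @slot clashes number of symmetry atom pairs closer than 1 angstrom.
#' @exportClass PlanarContactSet
setClass("PlanarContactSet",
  representation(
    contacts = "data.frame",
    criteria = "ContactCriteria",
    nGroups = "integer",
    clashes = "integer"
  ),
  prototype(nGroups = 0L, clashes = 0L)
)

#' Per-chain contact annotations
#'
#' The tabular survey form consumed by all statistics: one row per chain,
#' one row per residue, one row per contact. Produced either by annotating
#' parsed structures or by the synthetic corpus generator.
#'
#' @slot chains data.frame: \code{chainKey}, \code{sequence},
#'   \code{resolution}, \code{rFactor}, \code{pdbId}.
#' @slot residues data.frame: \code{chainKey}, \code{resIndex}, \code{aa},
#'   \code{waterCount}, \code{ss} (DSSP one-letter or NA),
#'   \code{interfaceClass} ("none"/"inter_asu"/"symmetry").
#' @slot contacts data.frame in the contact-annotation dialect (see
#'   \code{\link{writeContactAnnotations}}).
#' @exportClass ChainAnnotations
setClass("ChainAnnotations",
  representation(
    chains = "data.frame",
    residues = "data.frame",
    contacts = "data.frame"
  )
)

#' Empirical pi-contact frequency table
#'
#' Counts and opportunities keyed by (group sequence identity, partner
#' residue type, separation class, contacted group category). Group
#' identities are the nine sp2 sidechain letters plus 400 ordered backbone
#' dipeptides.
#'
#' @slot counts,opportunities 4-d arrays indexed by identity, partner type
#'   (20 letters), separation class ("short"/"long"), contacted category
#'   ("sidechain"/"backbone").
#' @slot smoothing list: \code{add} (additive pseudocount) and \code{floor}
#'   (minimum opportunity count before falling back to the partner-marginal
#'   rate).
#' @slot provenance list with \code{seed}, \code{nChains}, \code{split}.
#' @exportClass ContactFrequencyTable
setClass("ContactFrequencyTable",
  representation(
    counts = "array",
    opportunities = "array",
    smoothing = "list",
    provenance = "list"
  )
)

#' Sequence-identity calibration for pi-contact predictions
#'
#' Maps raw context expectations to their percentile within same-identity raw
#' values seen in training, and returns the mean observed contact frequency
#' in that percentile bin after isotonic smoothing.
#'
#' @slot bins named list (identity -> channel -> list(breaks, means)).
#' @slot identityMeans named list (identity -> per-channel mean observed
#'   frequency).
#' @slot pooled fallback calibration for unseen identities, same shape as one
#'   \code{bins} entry, per category.
#' @slot nBins number of equal-population percentile bins.
#' @exportClass ContactCalibration
setClass("ContactCalibration",
  representation(
    bins = "list",
    identityMeans = "list",
    pooled = "list",
    nBins = "integer"
  ),
  prototype(nBins = 20L)
)

#' Per-group predicted contact frequencies for one sequence
#'
#' Eight channels per sp2 group: \{short, long\} separation x \{sidechain,
#' backbone\} contacted category x \{absolute, relative-to-identity\}.
#'
#' @slot sequence the scored amino-acid sequence.
#' @slot profile data.frame: \code{position}, \code{identity},
#'   \code{category} ("sidechain"/"backbone"), \code{carbonCount}, and the
#'   eight channel columns (\code{short_sc_abs}, \code{long_sc_abs},
#'   \code{short_bb_abs}, \code{long_bb_abs} and their \code{_rel}
#'   counterparts).
#' @exportClass ContactProfile
setClass("ContactProfile",
  representation(sequence = "character", profile = "data.frame")
)

#' A trained phase-separation propensity model
#'
#' @slot components data.frame, one row per scored component: \code{channel},
#'   \code{weight}, \code{window} (residues), \code{mode} ("max" window mean
#'   or "topk" top-60 +/- 5 expansion), \code{carbon} (multiply channel
#'   values by the group carbon count).
#' @slot bgMean,bgSd mean and SD of raw scores over the background reference
#'   set; PScore = (raw - bgMean) / bgSd.
#' @slot trace numeric vector of accepted objective values during training
#'   (non-decreasing).
#' @slot seed integer seed used for training.
#' @slot meta list of training metadata.
#' @exportClass PScoreModel
setClass("PScoreModel",
  representation(
    components = "data.frame",
    bgMean = "numeric",
    bgSd = "numeric",
    trace = "numeric",
    seed = "integer",
    meta = "list"
  ),
  prototype(bgMean = 0, bgSd = 1, trace = numeric(0), seed = NA_integer_,
            meta = list())
)

setValidity("PScoreModel", function(object) {
  msgs <- character()
  need <- c("channel", "weight", "window", "mode", "carbon")
  miss <- setdiff(need, names(object@components))
  if (length(miss))
    msgs <- c(msgs, paste("components lacks:", paste(miss, collapse = ", ")))
  if (!is.na(object@bgSd) && object@bgSd <= 0)
    msgs <- c(msgs, "bgSd must be positive")
  if ("window" %in% names(object@components)) {
    w <- object@components$window
    if (any(w < 1 | w > 140))
      msgs <- c(msgs, "window lengths must lie in [1, 140]")
  }
  if (length(msgs)) msgs else TRUE
})
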