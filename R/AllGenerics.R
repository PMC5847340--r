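# Accessors and show methods for the core classes.

#' @rdname StructureModel-class
#' @param x,object a \linkS4class{StructureModel}.
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname StructureModel-class
#' @export
setMethod("atomRecords", "StructureModel", function(x) x@atoms)

#' @rdname StructureModel-class
#' @export
setGeneric("structureResolution",
           function(x) standardGeneric("structureResolution"))

#' @rdname StructureModel-class
#' @export
setMethod("structureResolution", "StructureModel", function(x) x@resolution)

#' @rdname StructureModel-class
#' @export
setGeneric("rFactor", function(x) standardGeneric("rFactor"))

#' @rdname StructureModel-class
#' @export
setMethod("rFactor", "StructureModel", function(x) x@rFactor)

#' @rdname StructureModel-class
#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))

#' @rdname StructureModel-class
#' @export
setMethod("unitCell", "StructureModel", function(x) x@unitCell)

#' @rdname StructureModel-class
#' @export
setGeneric("symmetryOps", function(x) standardGeneric("symmetryOps"))

#' @rdname StructureModel-class
#' @export
setMethod("symmetryOps", "StructureModel", function(x) x@symmetryOps)

#' @rdname StructureModel-class
#' @export
setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", object@source, "\n")
  cat(sprintf("  %d atoms (%d water, %d hydrogen), %d chain(s)\n",
              nrow(a), sum(a$isWater), sum(a$isH),
              length(unique(a$chain[!a$isWater]))))
  cat(sprintf("  resolution: %s  R-factor: %s  symmetry ops: %d\n",
              format(object@resolution), format(object@rFactor),
              length(object@symmetryOps)))
  invisible(NULL)
})

#' @rdname Sp2GroupSet-class
#' @param x,object a \linkS4class{Sp2GroupSet}.
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

#' @rdname Sp2GroupSet-class
#' @export
setMethod("groupTable", "Sp2GroupSet", function(x) x@groups)

#' @rdname Sp2GroupSet-class
#' @export
setGeneric("groupCoords", function(x) standardGeneric("groupCoords"))

#' @rdname Sp2GroupSet-class
#' @export
setMethod("groupCoords", "Sp2GroupSet", function(x) x@coords)

#' @rdname Sp2GroupSet-class
#' @export
setGeneric("groupNormals", function(x) standardGeneric("groupNormals"))

#' @rdname Sp2GroupSet-class
#' @export
setMethod("groupNormals", "Sp2GroupSet", function(x) x@normals)

#' @rdname Sp2GroupSet-class
#' @export
setGeneric("skippedGroups", function(x) standardGeneric("skippedGroups"))

#' @rdname Sp2GroupSet-class
#' @export
setMethod("skippedGroups", "Sp2GroupSet", function(x) x@skipped)

#' @rdname Sp2GroupSet-class
#' @export
setMethod("show", "Sp2GroupSet", function(object) {
  g <- object@groups
  cat(sprintf("Sp2GroupSet: %d group(s)", nrow(g)))
  if (nrow(g))
    cat(" [", paste(sprintf("%s:%d", names(table(g$identity)),
                            as.integer(table(g$identity))), collapse = " "),
        "]", sep = "")
  cat("\n")
  if (sum(object@skipped))
    cat("  skipped incomplete:",
        paste(sprintf("%s:%d", names(object@skipped), object@skipped),
              collapse = " "), "\n")
  invisible(NULL)
})

#' @rdname PlanarContactSet-class
#' @param x,object a \linkS4class{PlanarContactSet}.
#' @export
setGeneric("contactTable", function(x) standardGeneric("contactTable"))

#' @rdname PlanarContactSet-class
#' @export
setMethod("contactTable", "PlanarContactSet", function(x) x@contacts)

#' @rdname PlanarContactSet-class
#' @export
setGeneric("contactCriteriaOf", function(x) standardGeneric("contactCriteriaOf"))

#' @rdname PlanarContactSet-class
#' @export
setMethod("contactCriteriaOf", "PlanarContactSet", function(x) x@criteria)

#' @rdname PlanarContactSet-class
#' @export
setMethod("show", "PlanarContactSet", function(object) {
  ct <- object@contacts
  cat(sprintf("PlanarContactSet: %d contact(s) from %d group(s)\n",
              nrow(ct), object@nGroups))
  if (nrow(ct)) {
    cc <- table(ct$chainClass)
    cat("  by chain class:",
        paste(sprintf("%s:%d", names(cc), as.integer(cc)), collapse = " "),
        "\n")
  }
  if (object@clashes)
    cat("  symmetry clashes (< 1 A):", object@clashes, "\n")
  invisible(NULL)
})

#' @rdname ChainAnnotations-class
#' @param x,object a \linkS4class{ChainAnnotations}.
#' @export
setGeneric("annotationChains", function(x) standardGeneric("annotationChains"))

#' @rdname ChainAnnotations-class
#' @export
setMethod("annotationChains", "ChainAnnotations", function(x) x@chains)

#' @rdname ChainAnnotations-class
#' @export
setGeneric("annotationResidues",
           function(x) standardGeneric("annotationResidues"))

#' @rdname ChainAnnotations-class
#' @export
setMethod("annotationResidues", "ChainAnnotations", function(x) x@residues)

#' @rdname ChainAnnotations-class
#' @export
setGeneric("annotationContacts",
           function(x) standardGeneric("annotationContacts"))

#' @rdname ChainAnnotations-class
#' @export
setMethod("annotationContacts", "ChainAnnotations", function(x) x@contacts)

#' @rdname ChainAnnotations-class
#' @export
setMethod("show", "ChainAnnotations", function(object) {
  cat(sprintf("ChainAnnotations: %d chain(s), %d residue(s), %d contact(s)\n",
              nrow(object@chains), nrow(object@residues),
              nrow(object@contacts)))
  invisible(NULL)
})

#' @rdname ContactFrequencyTable-class
#' @param x,object a \linkS4class{ContactFrequencyTable}.
#' @export
setMethod("show", "ContactFrequencyTable", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "ContactFrequencyTable: %d identities x %d partner types x %d x %d\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  total contacts %d over %d opportunities\n",
              sum(object@counts), sum(object@opportunities)))
  invisible(NULL)
})

#' @rdname ContactProfile-class
#' @param x,object a \linkS4class{ContactProfile}.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname ContactProfile-class
#' @export
setMethod("profileTable", "ContactProfile", function(x) x@profile)

#' @rdname ContactProfile-class
#' @export
setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile: %d group(s) over %d residues\n",
              nrow(object@profile), nchar(object@sequence)))
  invisible(NULL)
})

#' @rdname PScoreModel-class
#' @param x,object a \linkS4class{PScoreModel}.
#' @export
setGeneric("modelComponents", function(x) standardGeneric("modelComponents"))

#' @rdname PScoreModel-class
#' @export
setMethod("modelComponents", "PScoreModel", function(x) x@components)

#' @rdname PScoreModel-class
#' @export
setGeneric("backgroundMoments",
           function(x) standardGeneric("backgroundMoments"))

#' @rdname PScoreModel-class
#' @export
setMethod("backgroundMoments", "PScoreModel",
          function(x) c(mean = x@bgMean, sd = x@bgSd))

#' @rdname PScoreModel-class
#' @export
setGeneric("trainingTrace", function(x) standardGeneric("trainingTrace"))

#' @rdname PScoreModel-class
#' @export
setMethod("trainingTrace", "PScoreModel", function(x) x@trace)

#' @rdname PScoreModel-class
#' @export
setMethod("show", "PScoreModel", function(object) {
  cat(sprintf("PScoreModel: %d component(s), background mean %.4g sd %.4g\n",
              nrow(object@components), object@bgMean, object@bgSd))
  if (length(object@trace))
    cat(sprintf("  trained: %d accepted steps, final objective %.4g\n",
                length(object@trace), object@trace[length(object@trace)]))
  invisible(NULL)
})
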