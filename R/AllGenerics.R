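# Generics and accessors for the central S4 classes.

#' @rdname ProteinStructure-class
#' @param x,object a \code{ProteinStructure}.
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("residueRecords", function(x) standardGeneric("residueRecords"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("residueSequence", function(x) standardGeneric("residueSequence"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname DesignSpec-class
#' @param x a \code{DesignSpec}.
#' @export
setGeneric("designedPositions", function(x) standardGeneric("designedPositions"))

#' @rdname DesignSpec-class
#' @export
setGeneric("allowedTypes", function(x) standardGeneric("allowedTypes"))

#' @rdname DesignSpec-class
#' @export
setGeneric("repackedPositions", function(x) standardGeneric("repackedPositions"))

#' @rdname DesignSpec-class
#' @export
setGeneric("premutations", function(x) standardGeneric("premutations"))

#' @rdname InteractionGraph-class
#' @param x an \code{InteractionGraph}.
#' @export
setGeneric("graphPositions", function(x) standardGeneric("graphPositions"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("stateCounts", function(x) standardGeneric("stateCounts"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("positionGroups", function(x) standardGeneric("positionGroups"))

#' @rdname SequenceArchive-class
#' @param x a \code{SequenceArchive}.
#' @export
setGeneric("archiveRecords", function(x) standardGeneric("archiveRecords"))

#' @rdname SequenceArchive-class
#' @export
setGeneric("archiveComponents", function(x) standardGeneric("archiveComponents"))

#' @rdname PWM-class
#' @param x a \code{PWM}.
#' @export
setGeneric("pwmProfile", function(x) standardGeneric("pwmProfile"))

#' @rdname PWM-class
#' @export
setGeneric("pwmPositions", function(x) standardGeneric("pwmPositions"))

#' @describeIn ProteinStructure-class atom table accessor.
setMethod("atomRecords", "ProteinStructure", function(x) x@atoms)

#' @describeIn ProteinStructure-class residue table accessor.
setMethod("residueRecords", "ProteinStructure", function(x) x@residues)

#' @describeIn ProteinStructure-class residue key vector.
setMethod("residueKeys", "ProteinStructure", function(x) x@residues$key)

#' @describeIn ProteinStructure-class one-letter sequence, named by key.
setMethod("residueSequence", "ProteinStructure",
  function(x) stats::setNames(x@residues$aa, x@residues$key))

#' @describeIn ProteinStructure-class number of residues.
setMethod("nResidues", "ProteinStructure", function(x) nrow(x@residues))

#' @describeIn ProteinStructure-class CA coordinate matrix (rows = residue
#'   keys).
setMethod("caCoords", "ProteinStructure", function(x) {
  at <- x@atoms
  ca <- at[at$elety == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste0(ca$chain, ca$resno, ca$icode)
  m[x@residues$key, , drop = FALSE]
})

setMethod("show", "ProteinStructure", function(object) {
  res <- object@residues
  cat(sprintf("ProteinStructure: %d residues, %d atoms, chains %s\n",
              nrow(res), nrow(object@atoms),
              paste(unique(res$chain), collapse = ",")))
  cat(sprintf("  source: %s (model %s)\n",
              object@provenance$source %||% "<memory>",
              object@provenance$model %||% 1))
})

#' @describeIn DesignSpec-class designed position keys.
setMethod("designedPositions", "DesignSpec",
  function(x) names(x@designed))

#' @describeIn DesignSpec-class named list of allowed types per designed
#'   position.
setMethod("allowedTypes", "DesignSpec", function(x) x@designed)

#' @describeIn DesignSpec-class repacked position keys.
setMethod("repackedPositions", "DesignSpec", function(x) x@repacked)

#' @describeIn DesignSpec-class premutated position -> type map.
setMethod("premutations", "DesignSpec", function(x) x@premutated)

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf(
    "DesignSpec: %d designed, %d repacked, %d premutated, %d nonmoving\n",
    length(object@designed), length(object@repacked),
    length(object@premutated), length(object@nonmoving)))
})

setMethod("show", "MoveMap", function(object) {
  cat(sprintf("MoveMap: %d chi-movable, %d backbone-movable, rigid chains: %s\n",
              length(object@chiMovable), length(object@bbMovable),
              if (length(object@rigidChains))
                paste(object@rigidChains, collapse = ",") else "none"))
})

#' @describeIn InteractionGraph-class movable position keys.
setMethod("graphPositions", "InteractionGraph", function(x) x@positions)

#' @describeIn InteractionGraph-class number of states per position.
setMethod("stateCounts", "InteractionGraph",
  function(x) stats::setNames(vapply(x@states, nrow, 0L), x@positions))

#' @describeIn InteractionGraph-class group (chain) label per position.
setMethod("positionGroups", "InteractionGraph", function(x) x@groups)

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph: %d positions, %d edges, %s states total\n",
              length(object@positions), length(object@edges),
              sum(vapply(object@states, nrow, 0L))))
})

#' @describeIn SequenceArchive-class scored-sequence record table.
setMethod("archiveRecords", "SequenceArchive", function(x) x@records)

#' @describeIn SequenceArchive-class per-record group energy components.
setMethod("archiveComponents", "SequenceArchive", function(x) x@components)

setMethod("show", "SequenceArchive", function(object) {
  rec <- object@records
  cat(sprintf(
    "SequenceArchive: %d scored slots, %d distinct sequences, %d generation(s), %d backbone(s)\n",
    nrow(rec), sum(rec$firstSeen), max(c(rec$generation, 0)),
    length(unique(rec$backbone))))
})

#' @describeIn PWM-class 20 x positions frequency matrix.
setMethod("pwmProfile", "PWM", function(x) x@profile)

#' @describeIn PWM-class position labels.
setMethod("pwmPositions", "PWM", function(x) x@positions)

setMethod("show", "PWM", function(object) {
  cat(sprintf("PWM: %d positions (%s)\n", length(object@positions),
              paste(object@positions, collapse = ", ")))
  top <- apply(object@profile, 2, function(p) AA_ALPHABET[which.max(p)])
  cat("  consensus:", paste(top, collapse = ""), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
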