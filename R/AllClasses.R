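#' ProteinStructure: chains, residues and atoms with coordinates
#'
#' Holds one model of a protein structure: an atom table (as read from the
#' source, so structures round-trip through PDB output unchanged), a residue
#' table with one-letter types and the current chi1 torsion of each side
#' chain, and provenance. Residues are keyed by `<chain><resno><icode>`
#' (e.g. "A5"), matching the 1-based numbering of the source PDB.
#'
#' @slot atoms data.frame with columns elety, x, y, z, chain, resno, icode,
#'   resid (3-letter type), occ.
#' @slot residues data.frame with columns key, chain, resno, icode, aa
#'   (one-letter type), chi1 (degrees; NA when the type has no chi1).
#' @slot provenance list with at least `source` and `model`.
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", residues = "data.frame",
                 provenance = "list"))

setValidity("ProteinStructure", function(object) {
  res <- object@residues
  at <- object@atoms
  msgs <- character()
  if (nrow(res) == 0) msgs <- c(msgs, "structure has no residues")
  if (anyDuplicated(res$key)) {
    msgs <- c(msgs, "residue (chain, number, icode) keys must be unique")
  }
  if (!all(res$aa %in% AA_ALPHABET)) {
    msgs <- c(msgs, "residue types must be canonical one-letter codes")
  }
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")])))) {
    msgs <- c(msgs, "atom coordinates must be finite")
  }
  atkey <- paste0(at$chain, at$resno, at$icode)
  for (k in res$key) {
    names <- at$elety[atkey == k]
    if (!all(c("N", "CA", "C") %in% names)) {
      msgs <- c(msgs, sprintf("residue %s lacks N/CA/C backbone atoms", k))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DesignSpec: premutated, designed, repacked and nonmoving positions
#'
#' @slot premutated named character vector: position key -> one-letter type
#'   substituted before ensemble generation.
#' @slot designed named list: position key -> character vector of allowed
#'   one-letter types sampled during sequence optimization.
#' @slot repacked character vector of position keys whose side-chain
#'   conformation (not type) may change.
#' @slot nonmoving character vector of fully fixed position keys.
#' @export
setClass("DesignSpec",
  representation(premutated = "character", designed = "list",
                 repacked = "character", nonmoving = "character"))

setValidity("DesignSpec", function(object) {
  msgs <- character()
  if (length(intersect(names(object@designed), names(object@premutated)))) {
    msgs <- c(msgs, "designed and premutated positions must be disjoint")
  }
  for (p in names(object@designed)) {
    al <- object@designed[[p]]
    if (length(al) == 0 || !all(al %in% AA_ALPHABET)) {
      msgs <- c(msgs, sprintf(
        "allowed set at %s must be a non-empty subset of the 20 types", p))
    }
  }
  if (length(object@premutated) &&
      !all(object@premutated %in% AA_ALPHABET)) {
    msgs <- c(msgs, "premutated types must be canonical")
  }
  if (length(msgs)) msgs else TRUE
})

#' MoveMap: movable degrees of freedom per position and chain
#'
#' @slot chiMovable character vector of position keys with movable chi.
#' @slot bbMovable character vector of position keys with movable phi/psi.
#' @slot rigidChains character vector of chain IDs with movable rigid-body
#'   degrees of freedom.
#' @export
setClass("MoveMap",
  representation(chiMovable = "character", bbMovable = "character",
                 rigidChains = "character"))

#' InteractionGraph: precomputed one-body and two-body energies
#'
#' Vertices are movable positions (designed: all allowed types x rotamers;
#' repacked: native type x rotamers); each vertex stores a one-body energy
#' per state, and each edge (position pairs whose CB atoms fall within the
#' interaction cutoff) stores a two-body energy matrix over state pairs.
#' Nonmoving residues are folded into the one-body terms and an additive
#' background constant.
#'
#' @slot positions character vector of movable position keys, in order.
#' @slot states list (per position) of data.frames with columns aa, chi1,
#'   rot, and the side-chain pseudo-atom coordinates sx, sy, sz.
#' @slot oneBody list (per position) of numeric one-body energy vectors.
#' @slot edges list of lists with elements i, j (position indices, i < j)
#'   and e (states_i x states_j energy matrix).
#' @slot groups named character vector: position key -> group label
#'   (chain ID).
#' @slot background numeric scalar: state-independent energy of the fixed
#'   context.
#' @slot params list: the energy-model parameters used to build the graph.
#' @export
setClass("InteractionGraph",
  representation(positions = "character", states = "list",
                 oneBody = "list", edges = "list", groups = "character",
                 background = "numeric", params = "list"))

setValidity("InteractionGraph", function(object) {
  msgs <- character()
  np <- length(object@positions)
  if (length(object@states) != np || length(object@oneBody) != np) {
    msgs <- c(msgs, "states and oneBody must align with positions")
  }
  for (k in seq_along(object@oneBody)) {
    if (!all(is.finite(object@oneBody[[k]]))) {
      msgs <- c(msgs, "one-body energies must be finite (clamped)")
    }
    if (length(object@oneBody[[k]]) != nrow(object@states[[k]])) {
      msgs <- c(msgs, "one-body vector length must match state count")
    }
  }
  for (ed in object@edges) {
    if (!(ed$i < ed$j)) msgs <- c(msgs, "edges must be stored with i < j")
    if (!all(is.finite(ed$e))) {
      msgs <- c(msgs, "two-body energies must be finite (clamped)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SequenceArchive: every sequence scored by the genetic algorithm
#'
#' One record per scored-sequence slot: the sequence over the designed
#' positions, its raw score, its reweighted fitness, the generation it was
#' produced in, the backbone index, and whether this record is the first
#' occurrence of the sequence in the archive. Per-record group energy
#' components are kept alongside so fitness can be recomputed with new
#' coefficients during post-processing.
#'
#' @slot records data.frame with columns sequence, generation, backbone,
#'   rawScore, fitness, firstSeen.
#' @slot components numeric matrix, rows aligned with records; columns are
#'   group self energies ("self:<g>") and pair interaction energies
#'   ("int:<g>:<h>").
#' @slot positions character vector of designed position keys (sequence
#'   column order).
#' @slot meta list of run metadata (GA parameters, weights, seeds).
#' @export
setClass("SequenceArchive",
  representation(records = "data.frame", components = "matrix",
                 positions = "character", meta = "list"))

setValidity("SequenceArchive", function(object) {
  msgs <- character()
  rec <- object@records
  need <- c("sequence", "generation", "backbone", "rawScore", "fitness",
            "firstSeen")
  if (!all(need %in% names(rec))) {
    msgs <- c(msgs, "records must carry sequence/generation/backbone/rawScore/fitness/firstSeen")
  } else {
    if (anyNA(rec$fitness)) msgs <- c(msgs, "fitness recorded for every record")
    if (nrow(rec) && any(rec$generation < 1)) {
      msgs <- c(msgs, "generation indices must be >= 1")
    }
  }
  if (nrow(object@components) && nrow(object@components) != nrow(rec)) {
    msgs <- c(msgs, "components must align with records")
  }
  if (length(msgs)) msgs else TRUE
})

#' PWM: position weight matrix over the 20 amino acids
#'
#' @slot profile numeric matrix, 20 rows (amino acids, alphabetical
#'   one-letter order) by one column per designed position; each column
#'   sums to 1.
#' @slot positions character vector of position labels (column order).
#' @slot metadata list: provenance (backbone count, weighting parameters).
#' @export
setClass("PWM",
  representation(profile = "matrix", positions = "character",
                 metadata = "list"))

setValidity("PWM", function(object) {
  p <- object@profile
  msgs <- character()
  if (nrow(p) != 20 || !identical(rownames(p), AA_ALPHABET)) {
    msgs <- c(msgs, "profile must have the 20 amino acids as rows")
  }
  if (ncol(p) != length(object@positions)) {
    msgs <- c(msgs, "positions must label the profile columns")
  }
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    msgs <- c(msgs, "frequencies must lie in [0, 1]")
  }
  if (ncol(p) && any(abs(colSums(p) - 1) > 1e-9)) {
    msgs <- c(msgs, "each column must sum to 1 (within 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})
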