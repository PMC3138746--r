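# Deterministic synthetic fixtures: ideal-geometry toy structures, planted
# interaction-graph landscapes small enough for exact enumeration, and
# noisy "experimental" profiles for metric testing.

#' Specification of a toy structure
#'
#' @param nres residues per chain (>= 3).
#' @param geometry "helix" (ideal alpha helix, phi -57 / psi -47) or
#'   "extended" (beta strand, phi -139 / psi 135).
#' @param sequence one-letter sequence recycled to `nres` (default a fixed
#'   mixed-composition repeat).
#' @param nchains 1 or 2; a second chain is a translated copy labelled B.
#' @param offset inter-chain translation in Angstrom (applied along z).
#' @return a `ToySpec` list.
#' @export
toySpec <- function(nres, geometry = c("helix", "extended"),
                    sequence = NULL, nchains = 1, offset = 8) {
  geometry <- match.arg(geometry)
  stopifnot(nres >= 3, nchains %in% c(1, 2), offset > 0)
  if (is.null(sequence)) {
    sequence <- paste(rep_len(c("A", "V", "L", "S", "K", "E", "F", "T",
                                "I", "D"), nres), collapse = "")
  }
  seqv <- strsplit(sequence, "")[[1]]
  stopifnot(all(seqv %in% AA_ALPHABET))
  structure(list(nres = nres, geometry = geometry,
                 sequence = rep_len(seqv, nres), nchains = nchains,
                 offset = offset), class = "ToySpec")
}

# Ideal peptide backbone by sequential NeRF placement.
.idealBackbone <- function(n, phi, psi, omega = 180) {
  N <- matrix(NA_real_, n, 3)
  CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- deg2rad(111.2)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- placeAtom(N[i, ], CA[i, ], C[i, ],
                            bond = 1.329, angle = 116.2, dihedral = psi)
    CA[i + 1, ] <- placeAtom(CA[i, ], C[i, ], N[i + 1, ],
                             bond = 1.458, angle = 121.7, dihedral = omega)
    C[i + 1, ] <- placeAtom(C[i, ], N[i + 1, ], CA[i + 1, ],
                            bond = 1.525, angle = 111.2, dihedral = phi)
    O[i, ] <- placeAtom(N[i + 1, ], CA[i, ], C[i, ],
                        bond = 1.231, angle = 120.8, dihedral = 180)
  }
  O[n, ] <- placeAtom(N[n, ], CA[n, ], C[n, ],
                      bond = 1.231, angle = 120.8, dihedral = psi - 180)
  list(N = N, CA = CA, C = C, O = O)
}

#' Build a deterministic toy structure with ideal geometry
#'
#' Backbone atoms (N, CA, C, O) are placed by ideal bond lengths/angles
#' and the geometry's phi/psi; CB is added for non-glycine residues.
#' Output is bit-identical for identical specs.
#'
#' @param spec a \code{\link{toySpec}}.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' s <- makeToyStructure(toySpec(10))
#' ca <- caCoords(s)
#' sqrt(rowSums(diff(ca)^2))  # consecutive CA-CA distances near 3.8 A
#' @export
makeToyStructure <- function(spec) {
  stopifnot(inherits(spec, "ToySpec"))
  ang <- if (spec$geometry == "helix") c(-57, -47) else c(-139, 135)
  bb <- .idealBackbone(spec$nres, phi = ang[1], psi = ang[2])
  mkChain <- function(chain, shift) {
    rows <- list()
    for (i in seq_len(spec$nres)) {
      aa <- spec$sequence[i]
      at <- rbind(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ],
                  O = bb$O[i, ])
      if (aa != "G") {
        at <- rbind(at, CB = virtualCB(bb$N[i, ], bb$CA[i, ], bb$C[i, ]))
      }
      at <- sweep(at, 2, shift, `+`)
      rows[[i]] <- data.frame(elety = rownames(at), x = at[, 1],
                              y = at[, 2], z = at[, 3], chain = chain,
                              resno = i, icode = "",
                              resid = AA_THREE[[aa]], occ = 1,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  atoms <- mkChain("A", c(0, 0, 0))
  if (spec$nchains == 2) {
    atoms <- rbind(atoms, mkChain("B", c(0, 0, spec$offset)))
  }
  rownames(atoms) <- NULL
  suppressWarnings(.structureFromAtoms(atoms, source = "toy", model = 1))
}

#' Synthetic interaction graph with a planted optimal sequence
#'
#' Builds a small \linkS4class{InteractionGraph} whose exhaustively
#' enumerated optimum is the planted sequence with an energy margin of at
#' least `gap` over every other sequence: the planted letter's one-body
#' term is 0 at each position while other letters are penalized by draws
#' from [1.5 gap, 2.5 gap], and optional edge noise is bounded so it can
#' never close the margin. All positions are designed; groups default to a
#' single chain "A".
#'
#' @param positions number of positions (<= 4 recommended for exact
#'   enumeration).
#' @param alphabet list of per-position allowed letter vectors, or a
#'   single vector recycled to all positions.
#' @param planted the planted optimal sequence (string or letter vector).
#' @param gap energy margin in score units (> 0, or 0 with `coOptimal`).
#' @param nrotamers states per letter at each position (default 1).
#' @param edgeNoise if > 0, pairwise matrices get uniform noise in
#'   [-b, b] with b = min(edgeNoise, gap / (4 (positions - 1))).
#' @param coOptimal optional second sequence given the same (zero)
#'   one-body terms, producing exact co-optima when `gap` separates the
#'   rest.
#' @param groups chain label per position (default all "A").
#' @param seed RNG seed for the penalty and noise draws.
#' @return an \linkS4class{InteractionGraph}.
#' @export
plantedLandscape <- function(positions, alphabet, planted, gap = 5,
                             nrotamers = 1, edgeNoise = 0,
                             coOptimal = NULL, groups = NULL, seed = 1) {
  if (length(planted) == 1) planted <- strsplit(planted, "")[[1]]
  if (!is.list(alphabet)) alphabet <- rep(list(alphabet), positions)
  stopifnot(length(planted) == positions, length(alphabet) == positions,
            gap >= 0)
  if (!is.null(coOptimal) && length(coOptimal) == 1) {
    coOptimal <- strsplit(coOptimal, "")[[1]]
  }
  for (i in seq_len(positions)) {
    stopifnot(planted[i] %in% alphabet[[i]])
  }
  if (is.null(groups)) groups <- rep("A", positions)
  keys <- paste0(groups, seq_len(positions))

  set.seed(seed)
  states <- vector("list", positions)
  oneBody <- vector("list", positions)
  for (i in seq_len(positions)) {
    al <- alphabet[[i]]
    st <- expand.grid(rot = seq_len(nrotamers), aa = al,
                      stringsAsFactors = FALSE)[, c("aa", "rot")]
    st$chi1 <- NA_real_
    st$prob <- 1
    st$sx <- 0; st$sy <- 0; st$sz <- 0
    rownames(st) <- NULL
    states[[i]] <- st
    best <- planted[i]
    also <- if (!is.null(coOptimal)) coOptimal[i] else NULL
    base <- if (gap > 0) gap else 1
    pen <- ifelse(st$aa %in% c(best, also), 0,
                  stats::runif(nrow(st), 1.5 * base, 2.5 * base))
    # non-optimal rotamers of the optimal letter get a small penalty so
    # the optimum state is unique
    pen <- pen + ifelse(st$aa %in% c(best, also) & st$rot > 1, 0.1, 0)
    oneBody[[i]] <- pen
  }

  edges <- list()
  if (edgeNoise > 0 && positions > 1) {
    b <- min(edgeNoise, gap / (4 * (positions - 1)))
    for (i in seq_len(positions - 1)) {
      for (j in (i + 1):positions) {
        e <- matrix(stats::runif(nrow(states[[i]]) * nrow(states[[j]]),
                                 -b, b),
                    nrow(states[[i]]), nrow(states[[j]]))
        edges[[length(edges) + 1]] <- list(i = i, j = j, e = e)
      }
    }
  }

  methods::new("InteractionGraph", positions = keys, states = states,
               oneBody = oneBody,
               edges = edges,
               groups = stats::setNames(groups, keys),
               background = stats::setNames(
                 rep(0, length(unique(groups))),
                 paste0("self:", sort(unique(groups)))),
               params = list(designed = keys, planted = planted))
}

#' Synthetic "experimental" position weight matrix
#'
#' Stands in for an experimentally measured specificity profile (e.g. from
#' phage display) when testing the evaluation metrics. With `noise = 0`
#' the normalized preferences are returned exactly; with `noise > 0` each
#' column is drawn from a Dirichlet with concentration
#' `noise * preference` (zero-preference letters stay at zero).
#'
#' @param preferences named list: position label -> named numeric letter
#'   weights (>= 0, at least one positive).
#' @param noise Dirichlet concentration (0 = exact).
#' @param seed RNG seed used when `noise > 0`.
#' @return a \linkS4class{PWM}.
#' @export
makeExperimentalPWM <- function(preferences, noise = 0, seed = 1) {
  pos <- names(preferences)
  prof <- matrix(0, 20, length(pos),
                 dimnames = list(AA_ALPHABET, pos))
  if (noise > 0) set.seed(seed)
  for (j in seq_along(pos)) {
    w <- preferences[[j]]
    stopifnot(all(w >= 0), any(w > 0), all(names(w) %in% AA_ALPHABET))
    p <- stats::setNames(rep(0, 20), AA_ALPHABET)
    p[names(w)] <- w / sum(w)
    if (noise > 0) {
      g <- stats::rgamma(20, shape = p * noise)
      p <- if (sum(g) > 0) g / sum(g) else p
    }
    prof[, j] <- p
  }
  methods::new("PWM", profile = prof, positions = pos,
               metadata = list(source = "synthetic", noise = noise))
}

#' Enumerate exact Boltzmann sequence marginals of a small graph
#'
#' Brute-force oracle: enumerates every sequence over the designed
#' positions, finds each sequence's best assignment by exhaustive state
#' enumeration, Boltzmann-weights the resulting fitnesses and returns the
#' per-position letter marginals as a PWM. Only feasible for tiny graphs.
#'
#' @param g an \linkS4class{InteractionGraph} (all positions designed).
#' @param w a `FitnessWeights` list.
#' @param kT Boltzmann factor in score units.
#' @return a \linkS4class{PWM} of exact marginals.
#' @export
enumerateBoltzmannPWM <- function(g, w, kT = 0.228) {
  en <- enumerateSequences(g, w)
  wts <- boltzmannWeights(en$fitness, kT)
  prof <- matrix(0, 20, length(g@positions),
                 dimnames = list(AA_ALPHABET, g@positions))
  seqs <- strsplit(en$sequence, "")
  for (i in seq_along(seqs)) {
    for (j in seq_along(g@positions)) {
      prof[seqs[[i]][j], j] <- prof[seqs[[i]][j], j] + wts[i]
    }
  }
  prof <- sweep(prof, 2, colSums(prof), `/`)
  methods::new("PWM", profile = prof, positions = g@positions,
               metadata = list(source = "enumeration", kT = kT))
}

#' Exhaustively score every sequence of a small graph
#'
#' For each sequence over the designed positions, enumerates all rotamer
#' assignments compatible with it and records the best raw score and its
#' reweighted fitness.
#'
#' @inheritParams enumerateBoltzmannPWM
#' @return data.frame with columns sequence, rawScore, fitness.
#' @export
enumerateSequences <- function(g, w) {
  np <- length(g@positions)
  letterSets <- lapply(g@states, function(st) unique(st$aa))
  seqGrid <- expand.grid(rev(letterSets), stringsAsFactors = FALSE)
  seqGrid <- seqGrid[, rev(seq_len(np)), drop = FALSE]
  out <- data.frame(sequence = apply(seqGrid, 1, paste, collapse = ""),
                    rawScore = NA_real_, fitness = NA_real_)
  for (r in seq_len(nrow(seqGrid))) {
    idxSets <- lapply(seq_len(np), function(i) {
      which(g@states[[i]]$aa == seqGrid[r, i])
    })
    best <- Inf
    bestA <- NULL
    assGrid <- expand.grid(rev(idxSets))
    assGrid <- assGrid[, rev(seq_len(np)), drop = FALSE]
    for (q in seq_len(nrow(assGrid))) {
      a <- as.integer(assGrid[q, ])
      sc <- rawScore(g, a)
      if (sc < best) {
        best <- sc
        bestA <- a
      }
    }
    out$rawScore[r] <- best
    out$fitness[r] <- reweightedFitness(g, bestA, w)
  }
  out
}
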