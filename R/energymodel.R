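# Pluggable residue-pairwise energy model: the reference potential places
# one side-chain pseudo-atom per residue (from CB along the chi1
# direction) and scores pairwise-additive 6-12 interactions between
# pseudo-atoms plus a repulsion-only clash term against the fixed
# backbone. Score units are arbitrary; the Boltzmann factor kT is the only
# bridge to frequencies.

#' Energy model parameters
#'
#' @param reference named numeric vector of per-type reference energies
#'   (score units); missing types default to 0.
#' @param hisReferenceOffset additive reference-energy offset for
#'   histidine (score units). The protocol default raises histidine by
#'   1.2 to correct its overprediction.
#' @param priorWeight weight on the rotamer prior term
#'   (-log p(rotamer) x priorWeight).
#' @param clamp repulsion ceiling per atom pair (score units).
#' @param cutoff interaction cutoff in Angstrom: graph edges require
#'   CB-CB distance within it, and pair terms are exactly zero beyond it.
#' @param backboneSigma,backboneEps LJ diameter/depth used for backbone
#'   heavy atoms in the clash term.
#' @param sigma,epsilon named per-type LJ diameter / well depth of the
#'   side-chain pseudo-atom; defaults are the packaged tables.
#' @return a validated list of class `EnergyModelParams`.
#' @export
energyModelParams <- function(reference = numeric(),
                              hisReferenceOffset = 1.2,
                              priorWeight = 1,
                              clamp = 10,
                              cutoff = 12,
                              backboneSigma = BACKBONE_SIGMA,
                              backboneEps = 0.2,
                              sigma = SC_SIGMA,
                              epsilon = SC_EPSILON) {
  ref <- stats::setNames(rep(0, 20), AA_ALPHABET)
  ref[names(reference)] <- reference
  ref["H"] <- ref["H"] + hisReferenceOffset
  stopifnot(clamp > 0, cutoff > 0, all(sigma > 0), all(epsilon >= 0),
            all(is.finite(ref)))
  structure(list(reference = ref, priorWeight = priorWeight,
                 clamp = clamp, cutoff = cutoff,
                 backboneSigma = backboneSigma, backboneEps = backboneEps,
                 sigma = sigma[AA_ALPHABET], epsilon = epsilon[AA_ALPHABET]),
            class = "EnergyModelParams")
}

#' Read energy-model parameters from a key-value config file
#'
#' Recognized keys (one `key: value` pair per line, `#` comments):
#' `his_reference_offset`, `prior_weight`, `clamp`, `cutoff`,
#' `backbone_sigma`, `backbone_eps`, and `reference_<X>` for per-type
#' reference energies (X a one-letter code).
#'
#' @param path config file path.
#' @return an `EnergyModelParams` list.
#' @export
readEnergyModelConfig <- function(path) {
  lines <- trimws(sub("#.*", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":")
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- as.numeric(vapply(kv, function(x) trimws(x[2]), ""))
  arg <- list()
  refs <- numeric()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (grepl("^reference_[A-Y]$", k)) {
      refs[sub("reference_", "", k)] <- vals[i]
    } else {
      nm <- switch(k, his_reference_offset = "hisReferenceOffset",
                   prior_weight = "priorWeight", clamp = "clamp",
                   cutoff = "cutoff", backbone_sigma = "backboneSigma",
                   backbone_eps = "backboneEps",
                   stop("unknown energy-model config key: ", k))
      arg[[nm]] <- vals[i]
    }
  }
  if (length(refs)) arg$reference <- refs
  do.call(energyModelParams, arg)
}

# Backbone frames: per-residue N/CA/C/O/CB coordinates as matrices keyed
# by residue key. CB is taken from the atom table when present, otherwise
# built virtually from N/CA/C (always virtual for GLY).
.backboneFrames <- function(s) {
  at <- s@atoms
  akey <- paste0(at$chain, at$resno, at$icode)
  keys <- s@residues$key
  get1 <- function(k, nm) {
    i <- which(akey == k & at$elety == nm)
    if (length(i) == 0) return(rep(NA_real_, 3))
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  n <- t(vapply(keys, get1, numeric(3), nm = "N"))
  ca <- t(vapply(keys, get1, numeric(3), nm = "CA"))
  cc <- t(vapply(keys, get1, numeric(3), nm = "C"))
  o <- t(vapply(keys, get1, numeric(3), nm = "O"))
  cb <- t(vapply(keys, get1, numeric(3), nm = "CB"))
  for (i in seq_along(keys)) {
    if (anyNA(cb[i, ])) cb[i, ] <- virtualCB(n[i, ], ca[i, ], cc[i, ])
  }
  rownames(n) <- rownames(ca) <- rownames(cc) <- rownames(o) <-
    rownames(cb) <- keys
  list(N = n, CA = ca, C = cc, O = o, CB = cb)
}

# Side-chain pseudo-atom position for a residue type at a given chi1.
.scPosition <- function(aa, chi1, n, ca, cb) {
  d <- SC_DISTANCE[[aa]]
  if (d <= 0 || is.na(chi1)) return(cb)
  placeAtom(n, ca, cb, bond = d, angle = 114, dihedral = chi1)
}

#' Construct a residue state (type + rotamer) on a structure's backbone
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param position residue key (e.g. "A5").
#' @param aa one-letter amino-acid type.
#' @param rot rotamer index into \code{rotamerStates(aa)}.
#' @return a `ResidueState` list: position, aa, rot, chi1, sc (pseudo-atom
#'   xyz), cb.
#' @export
residueState <- function(s, position, aa, rot = 1) {
  stopifnot(aa %in% AA_ALPHABET)
  rs <- rotamerStates(aa)
  stopifnot(rot >= 1, rot <= nrow(rs))
  fr <- .backboneFrames(s)
  if (!position %in% rownames(fr$CA)) stop("no such position: ", position)
  chi1 <- rs$chi1[rot]
  sc <- .scPosition(aa, chi1, fr$N[position, ], fr$CA[position, ],
                    fr$CB[position, ])
  structure(list(position = position, aa = aa, rot = rot, chi1 = chi1,
                 prob = rs$prob[rot], sc = sc, cb = fr$CB[position, ]),
            class = "ResidueState")
}

# Residue key plus its chain neighbours (bonded residues are excluded
# from the clash term, as 1-2/1-3 interactions would otherwise dominate).
.selfAndNeighbors <- function(s, key) {
  res <- s@residues
  i <- match(key, res$key)
  same <- which(res$chain == res$chain[i])
  pos <- match(i, same)
  take <- pos + c(-1, 0, 1)
  take <- take[take >= 1 & take <= length(same)]
  res$key[same[take]]
}

# Context atoms for the one-body clash term: backbone N/CA/C/O and CB of
# every residue except `exclude` (the state's own residue and its bonded
# neighbours), plus optional extra atoms (native side-chain pseudo-atoms
# of nonmoving residues).
.clashContext <- function(frames, exclude) {
  keys <- setdiff(rownames(frames$CA), exclude)
  xyz <- rbind(frames$N[keys, , drop = FALSE],
               frames$CA[keys, , drop = FALSE],
               frames$C[keys, , drop = FALSE],
               frames$O[keys, , drop = FALSE],
               frames$CB[keys, , drop = FALSE])
  xyz[stats::complete.cases(xyz), , drop = FALSE]
}

.oneBodyFromContext <- function(aa, prob, sc, context, p,
                                extraXYZ = NULL, extraSigma = NULL,
                                extraEps = NULL) {
  e <- p$reference[[aa]] + p$priorWeight * (-log(prob))
  if (nrow(context)) {
    d <- sqrt(rowSums(sweep(context, 2, sc)^2))
    sig <- (p$sigma[[aa]] + p$backboneSigma) / 2
    eps <- sqrt(p$epsilon[[aa]] * p$backboneEps)
    e <- e + sum(wcaEnergy(d, sig, eps, p$clamp))
  }
  if (!is.null(extraXYZ) && nrow(extraXYZ)) {
    d <- sqrt(rowSums(sweep(extraXYZ, 2, sc)^2))
    sig <- (p$sigma[[aa]] + extraSigma) / 2
    eps <- sqrt(p$epsilon[[aa]] * extraEps)
    e <- e + sum(ljEnergy(d, sig, eps, p$clamp, p$cutoff))
  }
  e
}

#' One-body energy of a residue state
#'
#' Reference energy of the type, plus the rotamer prior term
#' (-log p(rotamer) x prior weight), plus a clamped repulsion-only clash
#' term between the side-chain pseudo-atom and the fixed backbone heavy
#' atoms (N, CA, C, O, CB) of all other residues. With no clashes and
#' zero reference energies the result is exactly 0 for non-rotameric
#' types.
#'
#' @param state a `ResidueState` from \code{\link{residueState}}.
#' @param s the \linkS4class{ProteinStructure}.
#' @param p an `EnergyModelParams` list.
#' @return energy in score units.
#' @export
oneBodyEnergy <- function(state, s, p = energyModelParams()) {
  fr <- .backboneFrames(s)
  ctx <- .clashContext(fr, exclude = .selfAndNeighbors(s, state$position))
  .oneBodyFromContext(state$aa, state$prob, state$sc, ctx, p)
}

#' Two-body interaction energy of two residue states
#'
#' Clamped 6-12 term between the side-chain pseudo-atoms (CB and backbone
#' contributions are state-independent and accounted for in one-body
#' terms). Symmetric in its arguments and exactly zero beyond the
#' interaction cutoff; its minimum is -eps at d = sigma * 2^(1/6).
#'
#' @param a,b `ResidueState`s at distinct positions.
#' @param p an `EnergyModelParams` list.
#' @return energy in score units.
#' @export
twoBodyEnergy <- function(a, b, p = energyModelParams()) {
  if (identical(a$position, b$position)) {
    stop("two-body term requires distinct positions")
  }
  sig <- (p$sigma[[a$aa]] + p$sigma[[b$aa]]) / 2
  eps <- sqrt(p$epsilon[[a$aa]] * p$epsilon[[b$aa]])
  d <- vnorm(a$sc - b$sc)
  ljEnergy(d, sig, eps, p$clamp, p$cutoff)
}

#' Fitness weights over residue groups
#'
#' Groups are chain IDs. The reweighted fitness is
#' sum_g wSelf(g) E(g,g) + sum_(g<h) wInt(g,h) E(g,h), where E(g,g) sums
#' one-body terms of g plus intra-group edges and E(g,h) sums inter-group
#' edges. The interface benchmark weights are 0.4 intramolecular, 1
#' intermolecular.
#'
#' @param self named numeric: group -> self weight.
#' @param int named numeric: "g:h" (alphabetical) -> interaction weight.
#'   May be empty for single-group systems.
#' @return a `FitnessWeights` list.
#' @export
fitnessWeights <- function(self, int = numeric()) {
  stopifnot(all(is.finite(self)), all(is.finite(int)),
            any(c(self, int) != 0))
  structure(list(self = self, int = int), class = "FitnessWeights")
}

.intKey <- function(g, h) paste(sort(c(g, h)), collapse = ":")

#' Uniform fitness weights for a set of groups
#' @param groups character vector of group labels.
#' @param w weight applied to every component (default 1).
#' @export
unitFitnessWeights <- function(groups, w = 1) {
  groups <- sort(unique(groups))
  int <- numeric()
  if (length(groups) > 1) {
    pr <- utils::combn(groups, 2)
    int <- stats::setNames(rep(w, ncol(pr)),
                           apply(pr, 2, paste, collapse = ":"))
  }
  fitnessWeights(stats::setNames(rep(w, length(groups)), groups), int)
}

#' Precompute the interaction graph for sequence scoring
#'
#' Builds the one-body vectors and two-body matrices over all states of
#' the movable positions: designed positions contribute every allowed
#' type x rotamer, repacked positions the native type's rotamers. Edges
#' are created only between positions whose CB atoms fall within the
#' interaction cutoff. Nonmoving residues enter the one-body terms (as
#' clash/interaction context) and a state-independent background constant,
#' split into per-group components.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param d a \linkS4class{DesignSpec}.
#' @param p an `EnergyModelParams` list.
#' @return an \linkS4class{InteractionGraph}.
#' @export
buildInteractionGraph <- function(s, d, p = energyModelParams()) {
  res <- s@residues
  designed <- d@designed
  if (any(vapply(designed, length, 0L) == 0)) {
    stop("designed position with empty allowed set")
  }
  movable <- res$key[res$key %in% c(names(designed), d@repacked)]
  nonmov <- setdiff(res$key, movable)
  fr <- .backboneFrames(s)

  # native side-chain pseudo-atoms of nonmoving residues
  nmAA <- res$aa[match(nonmov, res$key)]
  nmSC <- matrix(NA_real_, length(nonmov), 3, dimnames = list(nonmov, NULL))
  for (i in seq_along(nonmov)) {
    k <- nonmov[i]
    chi1 <- res$chi1[match(k, res$key)]
    nmSC[i, ] <- .scPosition(nmAA[i], chi1, fr$N[k, ], fr$CA[k, ], fr$CB[k, ])
  }

  states <- vector("list", length(movable))
  oneBody <- vector("list", length(movable))
  for (i in seq_along(movable)) {
    k <- movable[i]
    types <- if (k %in% names(designed)) designed[[k]]
             else res$aa[match(k, res$key)]
    st <- do.call(rbind, lapply(types, function(aa) {
      rs <- rotamerStates(aa)
      sc <- t(vapply(seq_len(nrow(rs)), function(r) {
        .scPosition(aa, rs$chi1[r], fr$N[k, ], fr$CA[k, ], fr$CB[k, ])
      }, numeric(3)))
      data.frame(aa = aa, rot = seq_len(nrow(rs)), chi1 = rs$chi1,
                 prob = rs$prob, sx = sc[, 1], sy = sc[, 2], sz = sc[, 3])
    }))
    rownames(st) <- NULL
    states[[i]] <- st
    ctx <- .clashContext(fr, exclude = .selfAndNeighbors(s, k))
    ob <- numeric(nrow(st))
    for (j in seq_len(nrow(st))) {
      aa <- st$aa[j]
      ob[j] <- .oneBodyFromContext(
        aa, st$prob[j], c(st$sx[j], st$sy[j], st$sz[j]), ctx, p,
        extraXYZ = nmSC,
        extraSigma = if (length(nonmov))
          mean(p$sigma[nmAA]) else NULL,
        extraEps = if (length(nonmov)) mean(p$epsilon[nmAA]) else NULL)
    }
    oneBody[[i]] <- ob
  }

  edges <- list()
  for (i in seq_along(movable)) {
    for (j in seq_along(movable)) {
      if (j <= i) next
      cbd <- vnorm(fr$CB[movable[i], ] - fr$CB[movable[j], ])
      if (cbd > p$cutoff) next
      si <- states[[i]]
      sj <- states[[j]]
      e <- matrix(0, nrow(si), nrow(sj))
      for (a in seq_len(nrow(si))) {
        dx <- sj$sx - si$sx[a]
        dy <- sj$sy - si$sy[a]
        dz <- sj$sz - si$sz[a]
        dd <- sqrt(dx * dx + dy * dy + dz * dz)
        sig <- (p$sigma[[si$aa[a]]] + p$sigma[sj$aa]) / 2
        eps <- sqrt(p$epsilon[[si$aa[a]]] * p$epsilon[sj$aa])
        e[a, ] <- ljEnergy(dd, sig, eps, p$clamp, p$cutoff)
      }
      edges[[length(edges) + 1]] <- list(i = i, j = j, e = e)
    }
  }

  # background: nonmoving residues' own reference/prior/clash terms plus
  # their mutual pairwise interactions, split into group components.
  groups <- stats::setNames(res$chain[match(movable, res$key)], movable)
  bg <- numeric()
  addBG <- function(bg, key, val) {
    bg[key] <- (if (key %in% names(bg)) bg[[key]] else 0) + val
    bg
  }
  for (i in seq_along(nonmov)) {
    k <- nonmov[i]
    aa <- nmAA[i]
    ri <- match(k, res$key)
    rs <- rotamerStates(aa)
    chi1 <- res$chi1[ri]
    prob <- if (anyNA(rs$chi1)) 1 else {
      bin <- which.min(abs(((chi1 - rs$chi1 + 180) %% 360) - 180))
      rs$prob[bin]
    }
    ctx <- .clashContext(fr, exclude = .selfAndNeighbors(s, k))
    e <- .oneBodyFromContext(aa, prob, nmSC[i, ], ctx, p)
    bg <- addBG(bg, paste0("self:", res$chain[ri]), e)
  }
  if (length(nonmov) > 1) {
    for (i in seq_along(nonmov)) {
      for (j in seq_along(nonmov)) {
        if (j <= i) next
        ki <- nonmov[i]; kj <- nonmov[j]
        d2 <- vnorm(nmSC[i, ] - nmSC[j, ])
        if (vnorm(fr$CB[ki, ] - fr$CB[kj, ]) > p$cutoff) next
        sig <- (p$sigma[[nmAA[i]]] + p$sigma[[nmAA[j]]]) / 2
        eps <- sqrt(p$epsilon[[nmAA[i]]] * p$epsilon[[nmAA[j]]])
        e <- ljEnergy(d2, sig, eps, p$clamp, p$cutoff)
        ci <- res$chain[match(ki, res$key)]
        cj <- res$chain[match(kj, res$key)]
        key <- if (ci == cj) paste0("self:", ci)
               else paste0("int:", .intKey(ci, cj))
        bg <- addBG(bg, key, e)
      }
    }
  }

  methods::new("InteractionGraph", positions = movable, states = states,
               oneBody = oneBody, edges = edges, groups = groups,
               background = bg,
               params = list(energy = p,
                             designed = intersect(movable,
                                                  names(designed))))
}

.checkAssignment <- function(g, assignment) {
  np <- length(g@positions)
  if (!is.null(names(assignment))) {
    if (!all(g@positions %in% names(assignment))) {
      stop("assignment missing position(s): ",
           paste(setdiff(g@positions, names(assignment)), collapse = ", "))
    }
    assignment <- assignment[g@positions]
  }
  if (length(assignment) != np) stop("assignment must cover every position")
  nstates <- vapply(g@states, nrow, 0L)
  if (any(assignment < 1 | assignment > nstates)) {
    stop("assignment contains an invalid state index")
  }
  as.integer(assignment)
}

#' Raw score of a full state assignment on an interaction graph
#'
#' Sum of all one-body terms, all edge terms and the fixed background.
#'
#' @param g an \linkS4class{InteractionGraph}.
#' @param assignment integer vector of state indices, one per graph
#'   position (optionally named by position key).
#' @return energy in score units.
#' @export
rawScore <- function(g, assignment) {
  a <- .checkAssignment(g, assignment)
  e <- sum(g@background)
  for (i in seq_along(a)) e <- e + g@oneBody[[i]][a[i]]
  for (ed in g@edges) e <- e + ed$e[a[ed$i], a[ed$j]]
  e
}

#' Group energy components of an assignment
#'
#' Decomposes the total energy into per-group self components
#' ("self:<g>": one-body terms of the group's positions plus intra-group
#' edges plus its share of the background) and pair interaction components
#' ("int:<g>:<h>": inter-group edges). The components sum to the raw
#' score.
#'
#' @inheritParams rawScore
#' @return named numeric vector of components.
#' @export
energyComponents <- function(g, assignment) {
  a <- .checkAssignment(g, assignment)
  gl <- sort(unique(c(g@groups, sub("^self:", "", grep(
    "^self:", names(g@background), value = TRUE)))))
  comp <- stats::setNames(rep(0, length(gl)), paste0("self:", gl))
  if (length(gl) > 1) {
    pr <- utils::combn(gl, 2)
    comp[paste0("int:", apply(pr, 2, paste, collapse = ":"))] <- 0
  }
  for (k in names(g@background)) {
    comp[k] <- comp[k] + g@background[[k]]
  }
  for (i in seq_along(a)) {
    key <- paste0("self:", g@groups[[i]])
    comp[key] <- comp[key] + g@oneBody[[i]][a[i]]
  }
  for (ed in g@edges) {
    gi <- g@groups[[ed$i]]
    gj <- g@groups[[ed$j]]
    key <- if (gi == gj) paste0("self:", gi)
           else paste0("int:", .intKey(gi, gj))
    comp[key] <- comp[key] + ed$e[a[ed$i], a[ed$j]]
  }
  comp
}

#' Reweighted fitness of an assignment
#'
#' A user-defined linear combination of the group self energies and
#' inter-group interaction energies (see \code{\link{fitnessWeights}}).
#' With unit weights this equals \code{\link{rawScore}}.
#'
#' @inheritParams rawScore
#' @param w a `FitnessWeights` list covering every group in the graph.
#' @return fitness in score units (lower is better).
#' @export
reweightedFitness <- function(g, assignment, w) {
  comp <- energyComponents(g, assignment)
  reweightComponents(comp, w)
}

#' Recombine stored energy components with (possibly new) weights
#'
#' @param comp named component vector (or matrix with component columns)
#'   as produced by \code{\link{energyComponents}}.
#' @param w a `FitnessWeights` list.
#' @return numeric fitness (vector if `comp` is a matrix).
#' @export
reweightComponents <- function(comp, w) {
  nm <- if (is.matrix(comp)) colnames(comp) else names(comp)
  wt <- numeric(length(nm))
  for (i in seq_along(nm)) {
    if (startsWith(nm[i], "self:")) {
      gr <- sub("^self:", "", nm[i])
      if (!gr %in% names(w$self)) stop("no self weight for group ", gr)
      wt[i] <- w$self[[gr]]
    } else {
      key <- sub("^int:", "", nm[i])
      if (!key %in% names(w$int)) stop("no interaction weight for ", key)
      wt[i] <- w$int[[key]]
    }
  }
  if (is.matrix(comp)) as.numeric(comp %*% wt) else sum(comp * wt)
}
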