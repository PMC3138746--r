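# Stage 1: backbone ensemble generation by backrub Monte Carlo.
#
# The move set mixes backrub rotations (a rigid rotation of a short
# backbone segment about the axis through its two end-pivot CA atoms),
# rotamer-prior-biased chi moves and uniform chi moves, with Metropolis
# acceptance. The lowest-energy snapshot over the trajectory is kept.

#' Monte Carlo move set
#'
#' Defaults follow the protocol: 75% backrub moves, 22.5% biased chi
#' moves, 2.5% uniform chi moves, Metropolis kT 0.6 and 10,000 moves per
#' trajectory. When `smProb > 0`, small phi/psi moves are mixed in and
#' the other probabilities renormalized.
#'
#' @param pBackrub,pBiasedChi,pUniformChi move-type probabilities (must
#'   sum to 1).
#' @param smProb probability of a small combined phi/psi move
#'   (experimental; downstream atoms move, no loop closure).
#' @param mcKT Metropolis temperature in score units.
#' @param nMoves proposals per trajectory.
#' @param segMin,segMax backrub segment length range in residues.
#' @param maxRotation maximum backrub rotation in degrees for the
#'   shortest segment; scaled down as segMin/length for longer segments.
#' @return a `MoveSet` list.
#' @export
moveSet <- function(pBackrub = 0.75, pBiasedChi = 0.225,
                    pUniformChi = 0.025, smProb = 0, mcKT = 0.6,
                    nMoves = 10000, segMin = 3, segMax = 12,
                    maxRotation = 40) {
  p <- c(pBackrub, pBiasedChi, pUniformChi)
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9, smProb >= 0, smProb < 1,
            mcKT > 0, nMoves >= 0, segMin >= 3, segMax >= segMin,
            maxRotation > 0)
  structure(list(pBackrub = pBackrub, pBiasedChi = pBiasedChi,
                 pUniformChi = pUniformChi, smProb = smProb, mcKT = mcKT,
                 nMoves = nMoves, segMin = segMin, segMax = segMax,
                 maxRotation = maxRotation),
            class = "MoveSet")
}

#' Total energy of a structure under the reference potential
#'
#' Per-residue reference + rotamer-prior terms, side-chain/backbone clash
#' terms and pairwise side-chain 6-12 interactions, consistent with the
#' interaction-graph decomposition.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param p an `EnergyModelParams` list.
#' @return energy in score units.
#' @export
structureEnergy <- function(s, p = energyModelParams()) {
  res <- s@residues
  fr <- .backboneFrames(s)
  n <- nrow(res)
  sc <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    sc[i, ] <- .scPosition(res$aa[i], res$chi1[i], fr$N[res$key[i], ],
                           fr$CA[res$key[i], ], fr$CB[res$key[i], ])
  }
  e <- 0
  # per-residue reference + rotamer prior at the nearest chi1 bin
  for (i in seq_len(n)) {
    aa <- res$aa[i]
    rs <- rotamerStates(aa)
    prob <- if (anyNA(rs$chi1)) 1 else {
      bin <- which.min(abs(((res$chi1[i] - rs$chi1 + 180) %% 360) - 180))
      rs$prob[bin]
    }
    e <- e + p$reference[[aa]] + p$priorWeight * (-log(prob))
  }
  # side chain vs fixed backbone (repulsion only)
  bbAll <- rbind(fr$N, fr$CA, fr$C, fr$O, fr$CB)
  bbRes <- rep(seq_len(n), 5)
  ok <- stats::complete.cases(bbAll)
  bbAll <- bbAll[ok, , drop = FALSE]
  bbRes <- bbRes[ok]
  for (i in seq_len(n)) {
    # exclude the residue itself and its bonded chain neighbours
    near <- which(res$chain == res$chain[i] & abs(seq_len(n) - i) <= 1)
    other <- !(bbRes %in% near)
    if (!any(other)) next
    d <- sqrt(rowSums(sweep(bbAll[other, , drop = FALSE], 2, sc[i, ])^2))
    sig <- (p$sigma[[res$aa[i]]] + p$backboneSigma) / 2
    eps <- sqrt(p$epsilon[[res$aa[i]]] * p$backboneEps)
    e <- e + sum(wcaEnergy(d, sig, eps, p$clamp))
  }
  # pairwise side-chain interactions within the cutoff
  if (n > 1) {
    cb <- fr$CB
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (vnorm(cb[i, ] - cb[j, ]) > p$cutoff) next
        sig <- (p$sigma[[res$aa[i]]] + p$sigma[[res$aa[j]]]) / 2
        eps <- sqrt(p$epsilon[[res$aa[i]]] * p$epsilon[[res$aa[j]]])
        e <- e + ljEnergy(vnorm(sc[i, ] - sc[j, ]), sig, eps,
                          p$clamp, p$cutoff)
      }
    }
  }
  e
}

#' Propose a backrub move
#'
#' Chooses a contiguous segment of `segMin`..`segMax` residues within one
#' chain and rigidly rotates all atoms strictly between the two pivot CA
#' atoms (the C/O of the first pivot, everything of the inner residues,
#' the N of the last pivot) about the axis through the pivot CAs. Pivot
#' CA coordinates and all atoms outside the segment are unchanged. The
#' rotation angle is uniform in +/- maxRotation * segMin / length.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param m a `MoveSet` (segment-length range and rotation bound).
#' @param angle optional fixed rotation angle in degrees (draws uniformly
#'   when NULL); angle 0 returns coordinates identical to the input.
#' @return the candidate \linkS4class{ProteinStructure}.
#' @export
proposeBackrub <- function(s, m = moveSet(), angle = NULL) {
  res <- s@residues
  chains <- split(seq_len(nrow(res)), res$chain)
  eligible <- chains[vapply(chains, length, 0L) >= m$segMin]
  if (length(eligible) == 0) stop("no chain long enough for a backrub segment")
  ch <- eligible[[sample.int(length(eligible), 1)]]
  maxLen <- min(m$segMax, length(ch))
  len <- sample(seq(m$segMin, maxLen), 1)
  start <- sample.int(length(ch) - len + 1, 1)
  seg <- ch[start:(start + len - 1)]
  if (is.null(angle)) {
    bound <- m$maxRotation * m$segMin / len
    angle <- stats::runif(1, -bound, bound)
  }

  at <- s@atoms
  akey <- paste0(at$chain, at$resno, at$icode)
  k1 <- res$key[seg[1]]
  k2 <- res$key[seg[len]]
  inner <- res$key[seg[-c(1, len)]]
  move <- (akey %in% inner) |
    (akey == k1 & at$elety %in% c("C", "O")) |
    (akey == k2 & at$elety == "N")
  if (any(move) && abs(angle) > 0) {
    ca <- caCoords(s)
    xyz <- as.matrix(at[move, c("x", "y", "z")])
    rot <- rotateAboutAxis(xyz, ca[k1, ], ca[k2, ] - ca[k1, ], angle)
    at[move, c("x", "y", "z")] <- rot
  }
  methods::initialize(s, atoms = at)
}

#' Propose a chi-angle move
#'
#' Reassigns one rotatable residue's chi1: in biased mode the new value
#' is drawn from the rotamer prior; in uniform mode it is uniform on
#' (-180, 180]. Backbone atoms never move; any explicit side-chain atoms
#' beyond CB are rotated with the new torsion.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param mode "biased" or "uniform".
#' @param position optional residue key (a random rotatable residue when
#'   NULL; ALA/GLY are never selected).
#' @return the candidate \linkS4class{ProteinStructure}.
#' @export
proposeChi <- function(s, mode = c("biased", "uniform"), position = NULL) {
  mode <- match.arg(mode)
  res <- s@residues
  rotatable <- res$key[!res$aa %in% c("A", "G")]
  if (length(rotatable) == 0) stop("no residue with a rotatable chi")
  if (is.null(position)) {
    position <- rotatable[sample.int(length(rotatable), 1)]
  }
  i <- match(position, res$key)
  aa <- res$aa[i]
  rs <- rotamerStates(aa)
  newChi <- if (mode == "biased") {
    rs$chi1[sample.int(nrow(rs), 1, prob = rs$prob)]
  } else {
    stats::runif(1, -180, 180)
  }
  delta <- newChi - res$chi1[i]
  res$chi1[i] <- newChi

  at <- s@atoms
  akey <- paste0(at$chain, at$resno, at$icode)
  scAtoms <- akey == position & !at$elety %in% c("N", "CA", "C", "O", "CB")
  if (any(scAtoms) && abs(delta) > 1e-12) {
    sub <- at[akey == position, , drop = FALSE]
    ca <- as.numeric(sub[match("CA", sub$elety), c("x", "y", "z")])
    cb <- as.numeric(sub[match("CB", sub$elety), c("x", "y", "z")])
    xyz <- as.matrix(at[scAtoms, c("x", "y", "z")])
    at[scAtoms, c("x", "y", "z")] <- rotateAboutAxis(xyz, ca, cb - ca, delta)
  }
  methods::initialize(s, atoms = at, residues = res)
}

#' Propose a small combined phi/psi move
#'
#' Perturbs one residue's phi and psi by up to `maxDelta` degrees each;
#' downstream atoms in the chain move rigidly (no loop closure). Only
#' mixed into trajectories when the move set's `smProb` is positive;
#' experimental.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param maxDelta maximum perturbation per torsion, degrees.
#' @param position residue key (random backbone-movable residue when
#'   NULL).
#' @param movemap optional \linkS4class{MoveMap}; restricts the eligible
#'   residues to its backbone-movable set.
#' @return the candidate \linkS4class{ProteinStructure}.
#' @export
proposeSmallMove <- function(s, maxDelta = 3, position = NULL,
                             movemap = NULL) {
  res <- s@residues
  cand <- res$key
  if (!is.null(movemap)) cand <- intersect(cand, movemap@bbMovable)
  if (length(cand) == 0) stop("no backbone-movable residue for a small move")
  if (is.null(position)) cand <- cand[sample.int(length(cand), 1)]
  else cand <- position
  i <- match(cand, res$key)
  at <- s@atoms
  akey <- paste0(at$chain, at$resno, at$icode)
  chainKeys <- res$key[res$chain == res$chain[i]]
  after <- chainKeys[which(chainKeys == cand) < seq_along(chainKeys)]
  sub <- at[akey == cand, , drop = FALSE]
  xyzOf <- function(nm) as.numeric(sub[match(nm, sub$elety), c("x", "y", "z")])
  nxyz <- xyzOf("N"); caxyz <- xyzOf("CA"); cxyz <- xyzOf("C")

  dphi <- stats::runif(1, -maxDelta, maxDelta)
  movePhi <- (akey %in% after) | (akey == cand & at$elety %in% c("C", "O"))
  at[movePhi, c("x", "y", "z")] <- rotateAboutAxis(
    as.matrix(at[movePhi, c("x", "y", "z")]), nxyz, caxyz - nxyz, dphi)

  dpsi <- stats::runif(1, -maxDelta, maxDelta)
  sub <- at[akey == cand, , drop = FALSE]
  cxyz <- as.numeric(sub[match("C", sub$elety), c("x", "y", "z")])
  movePsi <- (akey %in% after) | (akey == cand & at$elety == "O")
  at[movePsi, c("x", "y", "z")] <- rotateAboutAxis(
    as.matrix(at[movePsi, c("x", "y", "z")]), caxyz, cxyz - caxyz, dpsi)

  methods::initialize(s, atoms = at)
}

#' Metropolis acceptance test
#'
#' Accepts with probability min(1, exp(-dE/kT)); downhill and zero-cost
#' moves are always accepted.
#'
#' @param dE energy difference (candidate minus current), score units.
#' @param kT temperature in score units (> 0).
#' @return logical.
#' @export
metropolisAccept <- function(dE, kT) {
  if (kT <= 0) stop("kT must be positive")
  dE <= 0 || stats::runif(1) < exp(-dE / kT)
}

#' Run one backrub Monte Carlo trajectory
#'
#' Executes `nMoves` proposals with move types drawn by the move-set
#' probabilities and Metropolis acceptance at `mcKT`, and returns the
#' lowest-energy snapshot encountered (the input structure counts as the
#' first snapshot, so the returned energy never exceeds the input's).
#' Acceptance statistics are recorded in the result's provenance under
#' `$trajectory`.
#'
#' @param s the starting \linkS4class{ProteinStructure}.
#' @param m a `MoveSet`.
#' @param p an `EnergyModelParams` list.
#' @param seed optional RNG seed; identical seeds give bit-identical
#'   output.
#' @param movemap optional \linkS4class{MoveMap} restricting small
#'   phi/psi moves when `smProb > 0`.
#' @return the lowest-energy \linkS4class{ProteinStructure}.
#' @export
runTrajectory <- function(s, m = moveSet(), p = energyModelParams(),
                          seed = NULL, movemap = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- c("backrub", "biasedChi", "uniformChi", "small")
  probs <- c(m$pBackrub, m$pBiasedChi, m$pUniformChi, 0) * (1 - m$smProb)
  probs[4] <- m$smProb
  proposed <- accepted <- stats::setNames(rep(0L, 4), types)

  eCur <- structureEnergy(s, p)
  cur <- s
  best <- s
  eBest <- eCur
  hasRotatable <- any(!s@residues$aa %in% c("A", "G"))

  for (step in seq_len(m$nMoves)) {
    ty <- sample(types, 1, prob = probs)
    if (ty %in% c("biasedChi", "uniformChi") && !hasRotatable) ty <- "backrub"
    cand <- switch(ty,
      backrub = proposeBackrub(cur, m),
      biasedChi = proposeChi(cur, "biased"),
      uniformChi = proposeChi(cur, "uniform"),
      small = proposeSmallMove(cur, movemap = movemap))
    proposed[ty] <- proposed[ty] + 1L
    eCand <- structureEnergy(cand, p)
    if (metropolisAccept(eCand - eCur, m$mcKT)) {
      accepted[ty] <- accepted[ty] + 1L
      cur <- cand
      eCur <- eCand
      if (eCur < eBest) {
        eBest <- eCur
        best <- cur
      }
    }
  }
  prov <- best@provenance
  prov$trajectory <- list(seed = seed, proposed = proposed,
                          accepted = accepted, bestEnergy = eBest,
                          startEnergy = structureEnergy(s, p),
                          finalEnergy = eCur)
  methods::initialize(best, provenance = prov)
}

#' CA root-mean-square deviation between two structures
#'
#' No superposition is applied: backrub moves leave the frame fixed, so
#' the deviation directly measures local backbone change.
#' @param a,b \linkS4class{ProteinStructure}s over the same residues.
#' @return RMSD in Angstrom.
#' @export
caRMSD <- function(a, b) {
  ca <- caCoords(a)
  cb <- caCoords(b)[rownames(caCoords(a)), , drop = FALSE]
  sqrt(mean(rowSums((ca - cb)^2)))
}

#' Generate a backbone ensemble
#'
#' Runs `n` independent trajectories, each starting from the input
#' structure, with distinct seeds (duplicate seeds are rejected — members
#' must be independent). Per-member CA-RMSD to the input is recorded in
#' each member's provenance.
#'
#' @param s the starting \linkS4class{ProteinStructure}.
#' @param n ensemble size (at least 100 is recommended for results robust
#'   to stochastic variation; 200 for higher robustness).
#' @param m a `MoveSet`.
#' @param seeds integer vector of length `n`, all distinct.
#' @param p an `EnergyModelParams` list.
#' @param movemap optional \linkS4class{MoveMap} for small moves.
#' @return list of \linkS4class{ProteinStructure}s.
#' @export
generateEnsemble <- function(s, n, m = moveSet(), seeds = seq_len(n),
                             p = energyModelParams(), movemap = NULL) {
  stopifnot(n >= 1, length(seeds) == n)
  if (anyDuplicated(seeds)) stop("ensemble seeds must be distinct")
  lapply(seq_len(n), function(i) {
    out <- runTrajectory(s, m, p, seed = seeds[i], movemap = movemap)
    prov <- out@provenance
    prov$memberIndex <- i
    prov$caRMSD <- caRMSD(out, s)
    methods::initialize(out, provenance = prov)
  })
}

#' Premutate a structure and repack side chains
#'
#' Replaces amino-acid types at the given positions (dropping the old
#' side-chain atoms beyond CB), globally repacks side chains by simulated
#' annealing, and — when a \linkS4class{MoveMap} is supplied — performs
#' staged coordinate-descent torsion minimization in three stages: chi
#' only, then chi/phi/psi, then chi/phi/psi plus rigid-body degrees of
#' freedom. Each stage only ever lowers the total energy.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param mutations named character vector: position key -> new one-letter
#'   type (may be empty).
#' @param minimize optional \linkS4class{MoveMap} enabling staged
#'   minimization.
#' @param p an `EnergyModelParams` list.
#' @param schedule an `AnnealSchedule` for the repack.
#' @param seed RNG seed for the repack.
#' @return the mutated, repacked \linkS4class{ProteinStructure}.
#' @export
premutate <- function(s, mutations = character(), minimize = NULL,
                      p = energyModelParams(), schedule = annealSchedule(),
                      seed = 1) {
  res <- s@residues
  at <- s@atoms
  if (length(mutations)) {
    if (!all(mutations %in% AA_ALPHABET)) {
      stop("mutation to unknown type: ",
           paste(setdiff(mutations, AA_ALPHABET), collapse = ", "))
    }
    miss <- setdiff(names(mutations), res$key)
    if (length(miss)) stop("no such position(s): ", paste(miss, collapse = ", "))
    akey <- paste0(at$chain, at$resno, at$icode)
    for (k in names(mutations)) {
      i <- match(k, res$key)
      res$aa[i] <- mutations[[k]]
      res$chi1[i] <- if (mutations[[k]] %in% c("A", "G")) NA_real_ else 180
      drop <- akey == k & !at$elety %in% c("N", "CA", "C", "O", "CB")
      if (mutations[[k]] == "G") drop <- drop | (akey == k & at$elety == "CB")
      at$resid[akey == k] <- AA_THREE[[mutations[[k]]]]
      at <- at[!drop, , drop = FALSE]
      akey <- akey[!drop]
    }
  }
  s2 <- methods::initialize(s, atoms = at, residues = res)

  # global side-chain repack: every residue NATAA-equivalent
  spec <- methods::new("DesignSpec",
                       premutated = stats::setNames(character(), character()),
                       designed = list(), repacked = res$key,
                       nonmoving = character())
  g <- buildInteractionGraph(s2, spec, p)
  pk <- packRotamers(g, schedule = schedule, seed = seed)
  res2 <- s2@residues
  for (i in seq_along(g@positions)) {
    k <- g@positions[i]
    st <- g@states[[i]][pk$assignment[i], ]
    res2$chi1[match(k, res2$key)] <- st$chi1
  }
  s2 <- methods::initialize(s2, residues = res2)
  # realign any explicit side-chain atoms with the packed chi1
  if (!is.null(minimize)) s2 <- .stagedMinimize(s2, minimize, p)
  s2
}

# Cyclic coordinate descent with step halving over the movemap's degrees
# of freedom, in three stages of increasing freedom.
.stagedMinimize <- function(s, mm, p, sweeps = 2, chiStep = 20,
                            bbStep = 4, rbStep = 0.5) {
  stages <- list(
    list(chi = TRUE, bb = FALSE, rb = FALSE),
    list(chi = TRUE, bb = TRUE, rb = FALSE),
    list(chi = TRUE, bb = TRUE, rb = TRUE))
  for (stage in stages) {
    e <- structureEnergy(s, p)
    for (sw in seq_len(sweeps)) {
      if (stage$chi) {
        step <- chiStep / sw
        for (k in intersect(mm@chiMovable, s@residues$key)) {
          i <- match(k, s@residues$key)
          if (s@residues$aa[i] %in% c("A", "G")) next
          for (dir in c(-1, 1)) {
            cand <- s
            cand@residues$chi1[i] <- s@residues$chi1[i] + dir * step
            ec <- structureEnergy(cand, p)
            if (ec < e) {
              s <- cand
              e <- ec
            }
          }
        }
      }
      if (stage$bb) {
        for (k in intersect(mm@bbMovable, s@residues$key)) {
          cand <- proposeSmallMove(s, maxDelta = bbStep / sw, position = k)
          ec <- structureEnergy(cand, p)
          if (ec < e) {
            s <- cand
            e <- ec
          }
        }
      }
      if (stage$rb) {
        for (ch in mm@rigidChains) {
          for (ax in 1:3) {
            for (dir in c(-1, 1)) {
              cand <- s
              at <- cand@atoms
              sel <- at$chain == ch
              at[sel, c("x", "y", "z")[ax]] <-
                at[sel, c("x", "y", "z")[ax]] + dir * rbStep / sw
              cand <- methods::initialize(cand, atoms = at)
              ec <- structureEnergy(cand, p)
              if (ec < e) {
                s <- cand
                e <- ec
              }
            }
          }
        }
      }
    }
  }
  s
}
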