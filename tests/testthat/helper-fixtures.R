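# Shared fixtures, built in code at test time.

# Small single-chain helix with a mixed sequence.
toyHelix <- function(n = 8) makeToyStructure(toySpec(n))

# Two-chain complex close enough for inter-chain contacts.
toyComplex <- function(n = 5, offset = 7) {
  makeToyStructure(toySpec(n, nchains = 2, offset = offset))
}

# Random synthetic interaction graph with dense edges, for packing
# oracles. nstates states per position, single letter per state so type
# choice and rotamer choice coincide.
randomGraph <- function(npos, nstates, seed, nletters = nstates) {
  set.seed(seed)
  keys <- paste0("A", seq_len(npos))
  letters <- AA_ALPHABET[seq_len(nletters)]
  states <- lapply(seq_len(npos), function(i) {
    st <- expand.grid(rot = seq_len(ceiling(nstates / nletters)),
                      aa = letters, stringsAsFactors = FALSE)[, c("aa", "rot")]
    st <- st[seq_len(nstates), , drop = FALSE]
    st$chi1 <- NA_real_
    st$prob <- 1
    st$sx <- 0; st$sy <- 0; st$sz <- 0
    rownames(st) <- NULL
    st
  })
  oneBody <- lapply(seq_len(npos), function(i) stats::rnorm(nstates))
  edges <- list()
  if (npos > 1) {
    for (i in seq_len(npos - 1)) {
      for (j in (i + 1):npos) {
        edges[[length(edges) + 1]] <- list(
          i = i, j = j, e = matrix(stats::rnorm(nstates^2), nstates))
      }
    }
  }
  new("InteractionGraph", positions = keys, states = states,
      oneBody = oneBody, edges = edges,
      groups = stats::setNames(rep("A", npos), keys),
      background = c("self:A" = 0),
      params = list(designed = keys))
}

# Exhaustive minimum raw score over all assignments of a small graph.
enumerateOptimum <- function(g, allowedIdx = NULL) {
  ns <- vapply(g@states, nrow, 0L)
  if (is.null(allowedIdx)) allowedIdx <- lapply(ns, seq_len)
  grid <- expand.grid(rev(allowedIdx))
  grid <- grid[, rev(seq_along(allowedIdx)), drop = FALSE]
  best <- Inf
  bestA <- NULL
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    sc <- rawScore(g, a)
    if (sc < best) {
      best <- sc
      bestA <- a
    }
  }
  list(assignment = bestA, score = best)
}

# A random valid PWM: per-column Dirichlet(alpha) over the 20 letters.
randomPWM <- function(npos = 5, alpha = 0.3, seed = 1) {
  set.seed(seed)
  prof <- matrix(stats::rgamma(20 * npos, shape = alpha), 20, npos)
  prof <- sweep(prof, 2, colSums(prof), `/`)
  dimnames(prof) <- list(AA_ALPHABET, paste0("P", seq_len(npos)))
  new("PWM", profile = prof, positions = colnames(prof),
      metadata = list())
}

# Archive holding exactly the given sequences/fitnesses (one backbone).
manualArchive <- function(sequences, fitness, positions,
                          generation = rep(1L, length(sequences))) {
  rec <- data.frame(sequence = sequences, generation = generation,
                    backbone = 1L, rawScore = fitness, fitness = fitness,
                    firstSeen = !duplicated(sequences),
                    stringsAsFactors = FALSE)
  comp <- matrix(fitness, ncol = 1, dimnames = list(NULL, "self:A"))
  new("SequenceArchive", records = rec, components = comp,
      positions = positions, meta = list())
}
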