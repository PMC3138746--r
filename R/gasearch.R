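# Stage 2: genetic algorithm enriching low-fitness sequences per backbone.

#' Genetic algorithm parameters
#'
#' Protocol defaults: population 2000 (1999 random members plus the
#' design-seed member), 5 total generations including the initial one,
#' tournament of 2, half crossover / half mutation, 50% per-position
#' mutation probability, single elite. With these settings the archive
#' records 2000 + 4 x 1999 = 9996 scored-sequence slots per backbone —
#' slightly less than 10,000, since the elite is carried without
#' re-scoring.
#'
#' @param populationSize population per generation (>= 2).
#' @param generations total generations including the initial population.
#' @param tournamentSize parents per tournament (2).
#' @param crossoverFraction fraction of offspring made by crossover (the
#'   rest by mutation).
#' @param mutationProb per-position probability that a mutated offspring
#'   redraws the letter (the redraw may restore the original; see
#'   `strictMutation` in \code{\link{evolveSequences}}).
#' @param eliteCount best sequences propagated unchanged (1).
#' @param includeSeed whether the design-seed member counts toward the
#'   population size (default TRUE: size - 1 random + 1 seed).
#' @return a `GAParams` list.
#' @export
gaParams <- function(populationSize = 2000, generations = 5,
                     tournamentSize = 2, crossoverFraction = 0.5,
                     mutationProb = 0.5, eliteCount = 1,
                     includeSeed = TRUE) {
  stopifnot(populationSize >= 2, generations >= 1, tournamentSize >= 1,
            crossoverFraction >= 0, crossoverFraction <= 1,
            mutationProb >= 0, mutationProb <= 1, eliteCount >= 0)
  structure(list(populationSize = populationSize, generations = generations,
                 tournamentSize = tournamentSize,
                 crossoverFraction = crossoverFraction,
                 mutationProb = mutationProb, eliteCount = eliteCount,
                 includeSeed = includeSeed),
            class = "GAParams")
}

#' Initial GA population
#'
#' `populationSize - 1` sequences drawn uniformly from the allowed sets,
#' plus the design-seed member (the best-raw-score sequence from a
#' full-design annealing call).
#'
#' @param allowed named list: designed position key -> allowed letter
#'   vector.
#' @param params a `GAParams` list.
#' @param seedSeq the design-seed sequence (named vector or string).
#' @return character vector of sequence strings (the seed member last).
#' @export
initPopulation <- function(allowed, params, seedSeq) {
  if (any(lengths(allowed) == 0)) stop("empty allowed set")
  seedStr <- if (length(seedSeq) > 1) paste(seedSeq, collapse = "")
             else seedSeq
  letters <- strsplit(seedStr, "")[[1]]
  stopifnot(length(letters) == length(allowed),
            all(mapply(`%in%`, letters, allowed)))
  nRandom <- params$populationSize - as.integer(params$includeSeed)
  pop <- vapply(seq_len(nRandom), function(i) {
    paste(vapply(allowed, function(al) al[sample.int(length(al), 1)], ""),
          collapse = "")
  }, "")
  if (params$includeSeed) pop <- c(pop, seedStr)
  pop
}

#' Tournament selection
#'
#' Draws `k` members uniformly with replacement and returns the index of
#' the one with the best (lowest) fitness; ties go to the first drawn.
#'
#' @param fitness numeric fitness per population member (lower is
#'   better).
#' @param k tournament size (default 2).
#' @return integer index of the selected parent.
#' @export
tournamentSelect <- function(fitness, k = 2) {
  stopifnot(length(fitness) > 0, !anyNA(fitness))
  draws <- sample.int(length(fitness), k, replace = TRUE)
  draws[which.min(fitness[draws])]
}

#' Positionwise crossover of two parent sequences
#'
#' Each position independently takes either parent's letter with
#' probability 1/2 — no linkage between positions.
#'
#' @param p1,p2 sequence strings of equal length.
#' @return the child sequence string.
#' @export
crossoverSequences <- function(p1, p2) {
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  if (length(a) != length(b)) stop("parent sequences differ in length")
  pick <- stats::runif(length(a)) < 0.5
  paste(ifelse(pick, a, b), collapse = "")
}

#' Positionwise mutation of a parent sequence
#'
#' Each position independently, with probability `prob`, redraws its
#' letter uniformly from that position's allowed set. By default the
#' redraw may restore the original letter; `strict = TRUE` forces a
#' change whenever the allowed set permits one.
#'
#' @param p sequence string.
#' @param allowed named list of per-position allowed letters (in sequence
#'   order).
#' @param prob per-position mutation probability (default 0.5).
#' @param strict redraw from the allowed set minus the current letter.
#' @return the child sequence string.
#' @export
mutateSequence <- function(p, allowed, prob = 0.5, strict = FALSE) {
  a <- strsplit(p, "")[[1]]
  stopifnot(length(a) == length(allowed))
  hit <- stats::runif(length(a)) < prob
  for (i in which(hit)) {
    al <- allowed[[i]]
    if (strict) al <- setdiff(al, a[i])
    if (length(al)) a[i] <- al[sample.int(length(al), 1)]
  }
  paste(a, collapse = "")
}

#' Run the genetic algorithm on one backbone's interaction graph
#'
#' The initial population is scored, then each later generation is bred
#' by elitist propagation of the best-fitness sequence plus tournament
#' selection with half crossover / half mutation offspring. Every
#' offspring occupies a scored-sequence slot in the archive; the elite is
#' carried without re-scoring. Packing results are cached per distinct
#' sequence, so repeated sequences cost nothing to re-score.
#'
#' @param g an \linkS4class{InteractionGraph} with designed positions.
#' @param w a `FitnessWeights` list used for selection fitness.
#' @param params a `GAParams` list.
#' @param schedule an `AnnealSchedule` for per-sequence packing.
#' @param allowed optional named list of allowed letters per designed
#'   position (derived from the graph states by default).
#' @param seed RNG seed; a fixed seed reproduces the archive exactly.
#' @param backbone backbone index recorded in the archive.
#' @param strictMutation see \code{\link{mutateSequence}}.
#' @return a \linkS4class{SequenceArchive}.
#' @export
evolveSequences <- function(g, w, params = gaParams(),
                            schedule = annealSchedule(), allowed = NULL,
                            seed = 1, backbone = 1L,
                            strictMutation = FALSE) {
  set.seed(seed)
  dp <- g@params$designed
  if (is.null(dp) || length(dp) == 0) stop("graph has no designed positions")
  dpIdx <- match(dp, g@positions)
  if (is.null(allowed)) {
    allowed <- stats::setNames(
      lapply(dpIdx, function(i) unique(g@states[[i]]$aa)), dp)
  }

  cache <- new.env(parent = emptyenv())
  scoreSeq <- function(sq) {
    hit <- get0(sq, envir = cache)
    if (!is.null(hit)) return(hit)
    pk <- packRotamers(g, sequence = stats::setNames(
      strsplit(sq, "")[[1]], dp), schedule = schedule)
    comp <- energyComponents(g, pk$assignment)
    val <- list(raw = pk$score, comp = comp,
                fitness = reweightComponents(comp, w))
    assign(sq, val, envir = cache)
    val
  }

  seedSeq <- designSeed(g, schedule = schedule)
  pop <- initPopulation(allowed, params, seedSeq)

  nSlots <- params$populationSize +
    (params$generations - 1) * (params$populationSize - params$eliteCount)
  recSeq <- character(nSlots)
  recGen <- integer(nSlots)
  recRaw <- recFit <- numeric(nSlots)
  recFirst <- logical(nSlots)
  compRows <- vector("list", nSlots)
  slot <- 0L
  seen <- new.env(parent = emptyenv())
  addRecord <- function(sq, gen) {
    sc <- scoreSeq(sq)
    first <- is.null(get0(sq, envir = seen))
    if (first) assign(sq, TRUE, envir = seen)
    slot <<- slot + 1L
    recSeq[slot] <<- sq
    recGen[slot] <<- gen
    recRaw[slot] <<- sc$raw
    recFit[slot] <<- sc$fitness
    recFirst[slot] <<- first
    compRows[[slot]] <<- sc$comp
    sc$fitness
  }

  fitness <- vapply(pop, addRecord, 0, gen = 1L, USE.NAMES = FALSE)

  for (gen in seq_len(params$generations - 1) + 1L) {
    eliteIdx <- order(fitness)[seq_len(params$eliteCount)]
    elites <- pop[eliteIdx]
    eliteFit <- fitness[eliteIdx]
    nOff <- params$populationSize - params$eliteCount
    nCross <- round(nOff * params$crossoverFraction)
    newPop <- character(nOff)
    newFit <- numeric(nOff)
    for (o in seq_len(nOff)) {
      if (o <= nCross) {
        p1 <- pop[tournamentSelect(fitness, params$tournamentSize)]
        p2 <- pop[tournamentSelect(fitness, params$tournamentSize)]
        child <- crossoverSequences(p1, p2)
      } else {
        p1 <- pop[tournamentSelect(fitness, params$tournamentSize)]
        child <- mutateSequence(p1, allowed, params$mutationProb,
                                strict = strictMutation)
      }
      newFit[o] <- addRecord(child, gen)
      newPop[o] <- child
    }
    pop <- c(elites, newPop)
    fitness <- c(eliteFit, newFit)
  }

  rec <- data.frame(sequence = recSeq[seq_len(slot)],
                    generation = recGen[seq_len(slot)],
                    backbone = backbone,
                    rawScore = recRaw[seq_len(slot)],
                    fitness = recFit[seq_len(slot)],
                    firstSeen = recFirst[seq_len(slot)],
                    stringsAsFactors = FALSE)
  comp <- do.call(rbind, compRows[seq_len(slot)])
  methods::new("SequenceArchive", records = rec, components = comp,
               positions = dp,
               meta = list(params = params, weights = w, seed = seed,
                           seedSequence = paste(seedSeq, collapse = "")))
}

#' Theoretical sequence-library size of a design
#'
#' Product of the allowed-set sizes over the designed positions: the
#' number of sequences an exhaustive screen would need to cover (e.g.
#' 20^5 = 3.2e6 for five fully free positions, 20^6 = 6.4e7 for six).
#'
#' @param allowed named list of per-position allowed letters, or a
#'   \linkS4class{DesignSpec}.
#' @return numeric count.
#' @export
theoreticalLibrarySize <- function(allowed) {
  if (methods::is(allowed, "DesignSpec")) allowed <- allowed@designed
  prod(vapply(allowed, length, 0L))
}

#' Concatenate per-backbone archives
#' @param archives list of \linkS4class{SequenceArchive}s over the same
#'   designed positions.
#' @return a single \linkS4class{SequenceArchive}; firstSeen flags are
#'   kept per backbone (sequences are weighted within each backbone).
#' @export
bindArchives <- function(archives) {
  stopifnot(length(archives) >= 1)
  pos <- archives[[1]]@positions
  for (a in archives) stopifnot(identical(a@positions, pos))
  methods::new("SequenceArchive",
               records = do.call(rbind, lapply(archives, function(a)
                 a@records)),
               components = do.call(rbind, lapply(archives, function(a)
                 a@components)),
               positions = pos,
               meta = archives[[1]]@meta)
}
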