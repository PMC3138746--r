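# Side-chain packing: minimize the raw score over rotamer/type states of
# an interaction graph by Monte Carlo simulated annealing.

#' Simulated annealing schedule
#'
#' Defaults (start kT 30 to end 0.3, geometric decay 0.8, 20 inner
#' iterations per movable state, 3 restarts) are sized so that packing
#' matches exhaustive enumeration on small oracle instances.
#'
#' @param startKT,endKT temperature range in score units (start > end > 0).
#' @param decay geometric decay factor in (0, 1).
#' @param innerPerState inner iterations per temperature, per movable
#'   state.
#' @param restarts independent restarts; the best result is kept.
#' @return an `AnnealSchedule` list.
#' @export
annealSchedule <- function(startKT = 30, endKT = 0.3, decay = 0.8,
                           innerPerState = 20, restarts = 3) {
  stopifnot(startKT > endKT, endKT > 0, decay > 0, decay < 1,
            innerPerState >= 1, restarts >= 1)
  structure(list(startKT = startKT, endKT = endKT, decay = decay,
                 innerPerState = innerPerState, restarts = restarts),
            class = "AnnealSchedule")
}

# Allowed state indices per position for a fixed designed sequence:
# designed positions are restricted to the requested type, repacked
# positions keep all their (native-type) states.
.allowedStates <- function(g, sequence = NULL) {
  dp <- g@params$designed
  lapply(seq_along(g@positions), function(i) {
    k <- g@positions[i]
    if (!is.null(sequence) && k %in% names(sequence)) {
      idx <- which(g@states[[i]]$aa == sequence[[k]])
      if (length(idx) == 0) {
        stop("type ", sequence[[k]], " not in the allowed set at ", k)
      }
      idx
    } else if (!is.null(sequence) && k %in% dp) {
      stop("sequence does not assign a type to designed position ", k)
    } else {
      seq_len(nrow(g@states[[i]]))
    }
  })
}

# Energy delta of switching position i to state new, given assignment a.
.deltaE <- function(g, edgeIdx, a, i, new) {
  d <- g@oneBody[[i]][new] - g@oneBody[[i]][a[i]]
  for (eid in edgeIdx[[i]]) {
    ed <- g@edges[[eid]]
    if (ed$i == i) {
      d <- d + ed$e[new, a[ed$j]] - ed$e[a[ed$i], a[ed$j]]
    } else {
      d <- d + ed$e[a[ed$i], new] - ed$e[a[ed$i], a[ed$j]]
    }
  }
  d
}

.edgeIndex <- function(g) {
  idx <- vector("list", length(g@positions))
  for (eid in seq_along(g@edges)) {
    ed <- g@edges[[eid]]
    idx[[ed$i]] <- c(idx[[ed$i]], eid)
    idx[[ed$j]] <- c(idx[[ed$j]], eid)
  }
  idx
}

# Deterministic greedy sweep: set each position to the allowed state with
# the lowest local energy, ties broken by the lowest (type, rotamer)
# index; iterate to a fixed point.
.greedyTieBreak <- function(g, edgeIdx, a, allowed, maxSweeps = 10) {
  for (sw in seq_len(maxSweeps)) {
    changed <- FALSE
    for (i in seq_along(a)) {
      cand <- allowed[[i]]
      dE <- vapply(cand, function(st) .deltaE(g, edgeIdx, a, i, st), 0)
      ties <- cand[dE <= min(dE) + 1e-12]
      pick <- ties[1]
      if (pick != a[i] && (min(dE) < -1e-12 || pick < a[i])) {
        a[i] <- pick
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  a
}

.annealOnce <- function(g, edgeIdx, allowed, sched) {
  a <- vapply(allowed, function(x) x[sample.int(length(x), 1)], 0L)
  nStates <- sum(lengths(allowed))
  inner <- sched$innerPerState * nStates
  free <- which(lengths(allowed) > 1)
  best <- a
  eCur <- 0  # work in relative energies; absolute added later
  eBestRel <- 0
  kT <- sched$startKT
  while (kT >= sched$endKT) {
    for (it in seq_len(inner)) {
      if (length(free) == 0) break
      i <- free[sample.int(length(free), 1)]
      new <- allowed[[i]][sample.int(length(allowed[[i]]), 1)]
      if (new == a[i]) next
      d <- .deltaE(g, edgeIdx, a, i, new)
      if (d <= 0 || stats::runif(1) < exp(-d / kT)) {
        a[i] <- new
        eCur <- eCur + d
        if (eCur < eBestRel) {
          eBestRel <- eCur
          best <- a
        }
      }
    }
    kT <- kT * sched$decay
  }
  best
}

#' Pack side chains for a fixed designed sequence
#'
#' Finds the state assignment minimizing the raw score, restricted to the
#' given types at designed positions and native types at repacked
#' positions, by simulated annealing with restarts followed by a
#' deterministic greedy tie-break sweep.
#'
#' @param g an \linkS4class{InteractionGraph}.
#' @param sequence named character vector (designed position key -> type),
#'   or a bare string in designed-position order; NULL packs native types
#'   only (no designed positions restricted).
#' @param schedule an `AnnealSchedule`.
#' @param seed optional RNG seed (fixed seed gives identical assignments).
#' @return list with `assignment` (named state indices) and `score` (best
#'   raw score found).
#' @export
packRotamers <- function(g, sequence = NULL, schedule = annealSchedule(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(sequence) && is.null(names(sequence)) &&
      length(sequence) == 1) {
    dp <- g@params$designed
    letters <- strsplit(sequence, "")[[1]]
    stopifnot(length(letters) == length(dp))
    sequence <- stats::setNames(letters, dp)
  }
  allowed <- .allowedStates(g, sequence)
  edgeIdx <- .edgeIndex(g)
  bestA <- NULL
  bestE <- Inf
  for (r in seq_len(schedule$restarts)) {
    a <- .annealOnce(g, edgeIdx, allowed, schedule)
    a <- .greedyTieBreak(g, edgeIdx, a, allowed)
    e <- rawScore(g, a)
    if (e < bestE - 1e-12 ||
        (abs(e - bestE) <= 1e-12 && !is.null(bestA) &&
         .lexLess(a, bestA))) {
      bestE <- e
      bestA <- a
    }
  }
  list(assignment = stats::setNames(bestA, g@positions), score = bestE)
}

.lexLess <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Best-raw-score sequence by joint type/rotamer annealing
#'
#' Simulated annealing jointly over amino-acid types and rotamers at all
#' positions (the full-design call that seeds the genetic algorithm);
#' returns the sequence of the best assignment found.
#'
#' @param g an \linkS4class{InteractionGraph}.
#' @param schedule an `AnnealSchedule`.
#' @param seed optional RNG seed.
#' @return named character vector: designed position key -> type.
#' @export
designSeed <- function(g, schedule = annealSchedule(), seed = NULL) {
  pk <- packRotamers(g, sequence = NULL, schedule = schedule, seed = seed)
  dp <- g@params$designed
  if (is.null(dp)) dp <- g@positions
  idx <- match(dp, g@positions)
  stats::setNames(vapply(idx, function(i) {
    g@states[[i]]$aa[pk$assignment[i]]
  }, ""), dp)
}
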