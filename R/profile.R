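# Post-processing: Boltzmann/cutoff sequence weighting, per-backbone
# position weight matrices, percentile merging across backbones, and
# profile diagnostics.

#' Post-processing parameters
#'
#' @param tempOrThresh the Boltzmann factor kT in score units (type
#'   "boltzmann"; default 0.228, the interface-benchmark value — 0.59 is
#'   the suggested starting point for monomer-stability applications), or
#'   the fitness threshold above the minimum (type "cutoff").
#' @param type "boltzmann" or "cutoff" sequence weighting.
#' @param percentile percentile in [0, 1] used to merge per-backbone
#'   frequencies (0.5 = median).
#' @param fitnessCoef optional `FitnessWeights` used to recompute fitness
#'   from stored group energy components before weighting (post-processing
#'   may use different coefficients than GA selection did).
#' @return a `BoltzmannParams` list.
#' @export
boltzmannParams <- function(tempOrThresh = 0.228,
                            type = c("boltzmann", "cutoff"),
                            percentile = 0.5, fitnessCoef = NULL) {
  type <- match.arg(type)
  if (type == "boltzmann") stopifnot(tempOrThresh > 0)
  else stopifnot(tempOrThresh >= 0)
  stopifnot(percentile >= 0, percentile <= 1)
  structure(list(tempOrThresh = tempOrThresh, type = type,
                 percentile = percentile, fitnessCoef = fitnessCoef),
            class = "BoltzmannParams")
}

#' Boltzmann sequence weights
#'
#' w_i proportional to exp(-(f_i - min f)/kT), normalized to sum 1.
#' Scores are normalized to the lowest fitness, so the weights are
#' invariant under adding a constant to all fitnesses; kT -> Inf gives
#' uniform weights and kT -> 0+ concentrates on the minima.
#'
#' @param fitnesses numeric vector of reweighted fitness scores (lower is
#'   better).
#' @param kT Boltzmann factor in score units (> 0).
#' @return normalized weight vector.
#' @export
boltzmannWeights <- function(fitnesses, kT = 0.228) {
  stopifnot(length(fitnesses) > 0)
  if (kT <= 0) stop("kT must be positive")
  w <- exp(-(fitnesses - min(fitnesses)) / kT)
  w / sum(w)
}

#' Binary threshold cutoff weights
#'
#' Weight 1 for sequences within `threshold` of the minimum fitness, 0
#' otherwise; normalized.
#'
#' @param fitnesses numeric vector of fitness scores.
#' @param threshold fitness window above the minimum (>= 0).
#' @return normalized weight vector.
#' @export
cutoffWeights <- function(fitnesses, threshold) {
  stopifnot(length(fitnesses) > 0, threshold >= 0)
  w <- as.numeric(fitnesses - min(fitnesses) <= threshold)
  w / sum(w)
}

# Distinct (first-seen) records of one backbone, with their weights under
# the given post-processing parameters.
.weightedSequences <- function(archive, params, backbone = NULL) {
  rec <- archive@records
  comp <- archive@components
  sel <- if (is.null(backbone)) rep(TRUE, nrow(rec))
         else rec$backbone == backbone
  sel <- sel & rec$firstSeen
  if (!any(sel)) stop("archive holds no sequences for this backbone")
  rec <- rec[sel, , drop = FALSE]
  fit <- if (!is.null(params$fitnessCoef)) {
    reweightComponents(comp[sel, , drop = FALSE], params$fitnessCoef)
  } else {
    rec$fitness
  }
  w <- if (params$type == "boltzmann") {
    boltzmannWeights(fit, params$tempOrThresh)
  } else {
    cutoffWeights(fit, params$tempOrThresh)
  }
  list(sequences = rec$sequence, weights = w,
       generation = rec$generation)
}

.pwmFromWeighted <- function(sequences, weights, positions, metadata) {
  prof <- matrix(0, 20, length(positions),
                 dimnames = list(AA_ALPHABET, positions))
  sp <- strsplit(sequences, "")
  for (i in seq_along(sp)) {
    for (j in seq_along(positions)) {
      prof[sp[[i]][j], j] <- prof[sp[[i]][j], j] + weights[i]
    }
  }
  prof <- sweep(prof, 2, colSums(prof), `/`)
  methods::new("PWM", profile = prof, positions = positions,
               metadata = metadata)
}

#' Position weight matrix for one backbone
#'
#' Weights each distinct sequence of the backbone's archive (Boltzmann or
#' cutoff weighting of the reweighted fitness, optionally recomputed from
#' stored group components) and accumulates per-position residue
#' frequencies. Columns sum to 1.
#'
#' @param archive a \linkS4class{SequenceArchive}.
#' @param params a `BoltzmannParams` list.
#' @param backbone backbone index to select (NULL = all records, for
#'   single-backbone archives).
#' @return a \linkS4class{PWM}.
#' @export
backbonePWM <- function(archive, params = boltzmannParams(),
                        backbone = NULL) {
  ws <- .weightedSequences(archive, params, backbone)
  .pwmFromWeighted(ws$sequences, ws$weights, archive@positions,
                   list(backbone = backbone, params = params))
}

#' Merge per-backbone PWMs by elementwise percentile
#'
#' Takes the requested percentile (default the median) of every
#' position/letter element across backbones, then renormalizes each
#' column to sum 1 (elementwise percentiles of columns need not sum
#' to 1). Backbones contribute equally — no weighting by total score.
#'
#' @param pwms list of \linkS4class{PWM}s over identical positions.
#' @param percentile percentile in [0, 1]; 0.5 is the median.
#' @return the merged \linkS4class{PWM}.
#' @export
mergePWMs <- function(pwms, percentile = 0.5) {
  stopifnot(length(pwms) >= 1, percentile >= 0, percentile <= 1)
  pos <- pwms[[1]]@positions
  for (p in pwms) {
    if (!identical(p@positions, pos)) stop("PWM positions do not match")
  }
  cube <- vapply(pwms, function(p) p@profile,
                 matrix(0, 20, length(pos)))
  if (length(pos) == 1 && is.matrix(cube)) {
    cube <- array(cube, dim = c(20, 1, length(pwms)))
  }
  merged <- apply(cube, c(1, 2), stats::quantile, probs = percentile,
                  names = FALSE)
  merged <- sweep(merged, 2, colSums(merged), `/`)
  dimnames(merged) <- list(AA_ALPHABET, pos)
  methods::new("PWM", profile = merged, positions = pos,
               metadata = list(backboneCount = length(pwms),
                               percentile = percentile))
}

#' Information content of a PWM
#'
#' Per position, log2(20) + sum_a p_a log2 p_a (with 0 log 0 = 0):
#' 0 bits for a uniform column, log2(20) = 4.32 bits for a one-hot
#' column.
#'
#' @param pwm a \linkS4class{PWM}.
#' @return list with `perPosition` (named numeric) and `average`.
#' @export
informationBits <- function(pwm) {
  bits <- apply(pwm@profile, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  list(perPosition = stats::setNames(bits, pwm@positions),
       average = mean(bits))
}

#' Weighted residue co-occurrence at two positions
#'
#' Joint 20 x 20 frequency matrix of the Boltzmann-weighted sequences at
#' two designed positions; its marginals equal the corresponding
#' single-position PWM columns.
#'
#' @param archive a \linkS4class{SequenceArchive}.
#' @param params a `BoltzmannParams` list.
#' @param posI,posJ designed position keys.
#' @param backbone backbone index (NULL = all).
#' @return 20 x 20 matrix (rows = posI letters, columns = posJ letters).
#' @export
covariation <- function(archive, params = boltzmannParams(), posI, posJ,
                        backbone = NULL) {
  i <- match(posI, archive@positions)
  j <- match(posJ, archive@positions)
  if (anyNA(c(i, j))) stop("position not in archive")
  ws <- .weightedSequences(archive, params, backbone)
  joint <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  sp <- strsplit(ws$sequences, "")
  for (k in seq_along(sp)) {
    joint[sp[[k]][i], sp[[k]][j]] <- joint[sp[[k]][i], sp[[k]][j]] +
      ws$weights[k]
  }
  joint / sum(joint)
}

#' Per-generation contribution to the final weights
#'
#' For each GA generation, the total normalized weight of the sequences
#' first seen in that generation — the diagnostic showing whether later
#' generations still discover sequences that matter, or the initial
#' design seed dominates.
#'
#' @param archive a \linkS4class{SequenceArchive}.
#' @param params a `BoltzmannParams` list.
#' @param backbone backbone index (NULL = all).
#' @return named numeric vector over generations, summing to 1.
#' @export
generationContributions <- function(archive, params = boltzmannParams(),
                                    backbone = NULL) {
  ws <- .weightedSequences(archive, params, backbone)
  gmax <- max(archive@records$generation)
  out <- stats::setNames(rep(0, gmax), seq_len(gmax))
  agg <- tapply(ws$weights, ws$generation, sum)
  out[names(agg)] <- agg
  out
}

#' Write a PWM as a tab-separated frequency table
#'
#' Rows are the 20 amino acids, columns the positions; a logo-ready
#' frequency table.
#' @param pwm a \linkS4class{PWM}.
#' @param path output path.
#' @export
writePWM <- function(pwm, path) {
  df <- data.frame(aa = AA_ALPHABET, pwm@profile, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PWM written by \code{\link{writePWM}}
#' @param path input path.
#' @return a \linkS4class{PWM}.
#' @export
readPWM <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  prof <- as.matrix(df[, -1, drop = FALSE])
  rownames(prof) <- df$aa
  prof <- prof[AA_ALPHABET, , drop = FALSE]
  methods::new("PWM", profile = prof, positions = colnames(prof),
               metadata = list(source = path))
}

#' Write a sequence archive (records + group energy components) as TSV
#' @param archive a \linkS4class{SequenceArchive}.
#' @param path output path.
#' @export
writeArchive <- function(archive, path) {
  df <- cbind(archive@records, as.data.frame(archive@components,
                                             check.names = FALSE))
  attr(df, "positions") <- archive@positions
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(paste0("# positions: ",
                      paste(archive@positions, collapse = ",")),
               readLines(path)), path)
  invisible(path)
}

#' Read a sequence archive written by \code{\link{writeArchive}}
#' @param path input path.
#' @return a \linkS4class{SequenceArchive}.
#' @export
readArchive <- function(path) {
  first <- readLines(path, n = 1)
  pos <- strsplit(sub("# positions: ", "", first), ",")[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE)
  core <- c("sequence", "generation", "backbone", "rawScore", "fitness",
            "firstSeen")
  comp <- as.matrix(df[, setdiff(names(df), core), drop = FALSE])
  methods::new("SequenceArchive", records = df[, core],
               components = comp, positions = pos, meta = list())
}
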