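# End-to-end orchestration of the two-stage protocol: premutation ->
# backrub ensemble -> per-backbone interaction graph + genetic algorithm
# -> per-backbone PWMs -> percentile merge.

#' Assemble a protocol run configuration
#'
#' @param structure a \linkS4class{ProteinStructure}, or a PDB file path.
#' @param design a \linkS4class{DesignSpec}, or resfile text/path parsed
#'   against the structure.
#' @param moveset a `MoveSet` for ensemble generation.
#' @param ga a `GAParams` list.
#' @param gaWeights `FitnessWeights` used for GA selection (defaults to
#'   unit weights over the structure's chains).
#' @param post a `BoltzmannParams` list (post-processing weighting and
#'   merge percentile; may carry different fitness coefficients than the
#'   GA used).
#' @param ensembleSize number of backbones (at least 100 recommended for
#'   robust profiles; small values are fine for exploration).
#' @param masterSeed integer master seed; every stage seed derives from
#'   it.
#' @param premutations named character vector of point mutations applied
#'   before ensemble generation.
#' @param minimizeMovemap optional \linkS4class{MoveMap} for staged
#'   minimization after premutation.
#' @param energy an `EnergyModelParams` list.
#' @param schedule an `AnnealSchedule` for packing.
#' @param outputDir optional directory; when given, ensemble PDBs,
#'   archive TSVs and PWM TSVs are written there.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(structure, design, moveset = moveSet(),
                      ga = gaParams(), gaWeights = NULL,
                      post = boltzmannParams(), ensembleSize = 100,
                      masterSeed = 1, premutations = character(),
                      minimizeMovemap = NULL,
                      energy = energyModelParams(),
                      schedule = annealSchedule(), outputDir = NULL) {
  if (is.character(structure)) structure <- readPDB(structure)
  if (is.character(design)) {
    if (length(design) == 1 && file.exists(design)) {
      design <- paste(readLines(design), collapse = "\n")
    }
    design <- parseResfile(design, structure)
  }
  stopifnot(methods::is(structure, "ProteinStructure"),
            methods::is(design, "DesignSpec"), ensembleSize >= 1)
  refd <- c(names(design@designed), design@repacked, design@nonmoving,
            names(premutations))
  bad <- setdiff(refd, residueKeys(structure))
  if (length(bad)) stop("design refers to missing position(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(gaWeights)) {
    gaWeights <- unitFitnessWeights(unique(structure@residues$chain))
  }
  structure(list(structure = structure, design = design,
                 moveset = moveset, ga = ga, gaWeights = gaWeights,
                 post = post, ensembleSize = ensembleSize,
                 masterSeed = masterSeed, premutations = premutations,
                 minimizeMovemap = minimizeMovemap, energy = energy,
                 schedule = schedule, outputDir = outputDir),
            class = "RunConfig")
}

# Deterministic per-stage seed derivation: a fixed-seed draw of distinct
# sub-seeds below 2^31.
.deriveSeeds <- function(masterSeed, n) {
  set.seed(masterSeed)
  sample.int(2^31 - 1, n)
}

#' Run the full sequence-tolerance protocol
#'
#' Premutates (if requested), generates the backbone ensemble, builds a
#' per-backbone interaction graph, runs the genetic algorithm on each
#' backbone, converts each archive to a Boltzmann-weighted PWM and merges
#' the PWMs at the configured percentile. Fully deterministic for a fixed
#' master seed.
#'
#' @param cfg a `RunConfig` from \code{\link{runConfig}}.
#' @return list: `pwm` (merged \linkS4class{PWM}), `backbonePWMs`,
#'   `archive` (combined \linkS4class{SequenceArchive}), `ensemble`,
#'   `report` (per-stage diagnostics).
#' @export
runProtocol <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  n <- cfg$ensembleSize
  seeds <- .deriveSeeds(cfg$masterSeed, 2 * n + 1)
  ensSeeds <- seeds[seq_len(n)]
  gaSeeds <- seeds[n + seq_len(n)]

  s <- cfg$structure
  if (length(cfg$premutations)) {
    s <- premutate(s, cfg$premutations, minimize = cfg$minimizeMovemap,
                   p = cfg$energy, schedule = cfg$schedule,
                   seed = seeds[2 * n + 1])
  }

  ensemble <- generateEnsemble(s, n, cfg$moveset, seeds = ensSeeds,
                               p = cfg$energy)

  archives <- vector("list", n)
  pwms <- vector("list", n)
  for (i in seq_len(n)) {
    g <- buildInteractionGraph(ensemble[[i]], cfg$design, cfg$energy)
    archives[[i]] <- evolveSequences(g, cfg$gaWeights, cfg$ga,
                                     cfg$schedule, seed = gaSeeds[i],
                                     backbone = i)
    pwms[[i]] <- backbonePWM(archives[[i]], cfg$post, backbone = i)
  }
  merged <- mergePWMs(pwms, cfg$post$percentile)
  archive <- bindArchives(archives)

  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      writePDB(ensemble[[i]],
               file.path(cfg$outputDir, sprintf("backrub_%04d_low.pdb", i)))
      writePWM(pwms[[i]],
               file.path(cfg$outputDir, sprintf("pwm_%04d.tsv", i)))
    }
    writeArchive(archive, file.path(cfg$outputDir, "archive.tsv"))
    writePWM(merged, file.path(cfg$outputDir, "pwm_merged.tsv"))
  }

  report <- list(
    ensembleSize = n,
    caRMSD = vapply(ensemble, function(e) e@provenance$caRMSD, 0),
    scoredSlots = nrow(archive@records),
    distinctSequences = sum(archive@records$firstSeen),
    generationContributions = lapply(seq_len(n), function(i)
      generationContributions(archives[[i]], cfg$post, backbone = i)),
    masterSeed = cfg$masterSeed)
  list(pwm = merged, backbonePWMs = pwms, archive = archive,
       ensemble = ensemble, report = report)
}

#' Backbone-count convergence study
#'
#' Measures how the merged profile stabilizes as backbones accumulate:
#' for each requested count, repeatedly subsamples that many per-backbone
#' PWMs from a completed run, merges them, and reports the
#' root-mean-square frequency error against a ground-truth profile (by
#' default the merge of all backbones).
#'
#' @param run a completed \code{\link{runProtocol}} result (or a list of
#'   per-backbone \linkS4class{PWM}s).
#' @param backboneCounts integer vector of ensemble sizes to test.
#' @param replicates subsampling replicates per count.
#' @param truth optional ground-truth \linkS4class{PWM}.
#' @param expPWM optional experimental profile; when given, AUC against
#'   it is reported per subsample as well.
#' @param percentile merge percentile.
#' @param seed RNG seed for subsampling.
#' @return data.frame with columns count, replicate, rmse (and auc).
#' @export
convergenceStudy <- function(run, backboneCounts, replicates = 10,
                             truth = NULL, expPWM = NULL,
                             percentile = 0.5, seed = 1) {
  pwms <- if (is.list(run) && !is.null(run$backbonePWMs)) run$backbonePWMs
          else run
  stopifnot(length(pwms) >= max(backboneCounts))
  if (is.null(truth)) truth <- mergePWMs(pwms, percentile)
  set.seed(seed)
  rows <- list()
  for (cnt in backboneCounts) {
    for (r in seq_len(replicates)) {
      idx <- sample.int(length(pwms), cnt)
      m <- mergePWMs(pwms[idx], percentile)
      rmse <- sqrt(mean((m@profile - truth@profile)^2))
      row <- data.frame(count = cnt, replicate = r, rmse = rmse)
      if (!is.null(expPWM)) row$auc <- rocAUC(m, expPWM)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
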