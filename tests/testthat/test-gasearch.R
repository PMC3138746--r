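allowed4 <- list(A1 = c("A", "C", "D", "E"), A2 = c("A", "C", "D", "E"),
                 A3 = c("A", "C", "D", "E"))

test_that("initial population is size-1 random members plus the design seed", {
  params <- gaParams(populationSize = 50, generations = 5)
  set.seed(1)
  pop <- initPopulation(allowed4, params, "ACD")
  expect_length(pop, 50)
  expect_equal(pop[50], "ACD")

  # singleton alphabets force every member
  sing <- list(A1 = "K", A2 = "L")
  popS <- initPopulation(sing, gaParams(populationSize = 10), "KL")
  expect_true(all(popS == "KL"))

  expect_error(initPopulation(list(A1 = character()), params, "A"),
               "empty allowed set")
})

test_that("random members draw uniformly from the allowed sets", {
  set.seed(2)
  pop <- initPopulation(list(P1 = c("A", "C", "D", "E")),
                        gaParams(populationSize = 8000,
                                 includeSeed = FALSE), "A")
  tab <- table(factor(pop, levels = c("A", "C", "D", "E")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("tournament of two picks the better with probability 3/4", {
  set.seed(3)
  fit <- c(1.0, 5.0)
  n <- 2e4
  wins <- sum(replicate(n, tournamentSelect(fit)) == 1)
  pHat <- wins / n
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(pHat - 0.75), 4 * se)
  # a degenerate draw returns that member
  set.seed(4)
  expect_true(tournamentSelect(c(2)) == 1)
})

test_that("crossover mixes parents positionwise without linkage", {
  set.seed(5)
  expect_equal(crossoverSequences("ACD", "ACD"), "ACD")
  expect_error(crossoverSequences("AC", "ACD"), "length")
  kids <- replicate(5000, crossoverSequences("AA", "CC"))
  m <- do.call(rbind, strsplit(kids, ""))
  fracA <- colMeans(m == "A")
  expect_true(all(abs(fracA - 0.5) < 0.03))
  r <- stats::cor(m[, 1] == "A", m[, 2] == "A")
  expect_lt(abs(r), 0.05)
  # closure: every child letter comes from a parent
  kids2 <- replicate(200, crossoverSequences("ACD", "CDE"))
  m2 <- do.call(rbind, strsplit(kids2, ""))
  expect_true(all(m2[, 1] %in% c("A", "C"), m2[, 2] %in% c("C", "D"),
                  m2[, 3] %in% c("D", "E")))
})

test_that("mutation redraws half the positions (redraw may restore)", {
  set.seed(6)
  al <- list(c("A", "C", "D", "E"), c("A", "C", "D", "E"))
  kids <- replicate(5000, mutateSequence("AA", al, prob = 0.5))
  m <- do.call(rbind, strsplit(kids, ""))
  # P(letter changes) = 0.5 * 3/4 = 0.375 with a 4-letter set
  pChange <- mean(m != "A")
  expect_lt(abs(pChange - 0.375), 0.02)
  # strict mode always changes a redrawn position: P = 0.5
  kidsS <- replicate(5000, mutateSequence("AA", al, prob = 0.5,
                                          strict = TRUE))
  mS <- do.call(rbind, strsplit(kidsS, ""))
  expect_lt(abs(mean(mS != "A") - 0.5), 0.02)
  # singleton sets leave the parent untouched
  expect_equal(mutateSequence("KL", list("K", "L")), "KL")
  # closure
  expect_true(all(m %in% c("A", "C", "D", "E")))
})

test_that("archive bookkeeping matches elitist GA arithmetic", {
  g <- plantedLandscape(3, c("A", "C", "D", "E"), "ACD", gap = 2,
                        nrotamers = 1, edgeNoise = 0.2)
  w <- unitFitnessWeights("A")
  arc <- evolveSequences(g, w, gaParams(populationSize = 50,
                                        generations = 5),
                         annealSchedule(restarts = 1), seed = 7)
  rec <- archiveRecords(arc)
  # 50 + 4 x 49 scored-sequence slots: the elite is never re-scored
  expect_equal(nrow(rec), 50 + 4 * 49)
  expect_equal(unname(table(rec$generation)), c(50L, 49L, 49L, 49L, 49L),
               ignore_attr = TRUE)
  expect_true(all(rec$generation >= 1 & rec$generation <= 5))
  # elitism: per-generation minimum fitness never increases
  minFit <- tapply(rec$fitness, rec$generation, min)
  expect_true(all(diff(minFit) <= 1e-12))
  # firstSeen marks exactly the first record of each distinct sequence
  expect_equal(sum(rec$firstSeen), length(unique(rec$sequence)))
  expect_true(all(!duplicated(rec$sequence) == rec$firstSeen))
})

test_that("a single-generation run archives only the initial population", {
  g <- plantedLandscape(2, c("A", "C"), "AC", gap = 1)
  arc <- evolveSequences(g, unitFitnessWeights("A"),
                         gaParams(populationSize = 20, generations = 1),
                         annealSchedule(restarts = 1), seed = 1)
  expect_equal(nrow(archiveRecords(arc)), 20)
  expect_true(all(archiveRecords(arc)$generation == 1))
})

test_that("the GA archive is reproducible under a fixed seed", {
  g <- plantedLandscape(3, c("A", "C", "D"), "ACD", gap = 1,
                        nrotamers = 2, edgeNoise = 0.1)
  w <- unitFitnessWeights("A")
  a1 <- evolveSequences(g, w, gaParams(populationSize = 30,
                                       generations = 3),
                        annealSchedule(restarts = 1), seed = 42)
  a2 <- evolveSequences(g, w, gaParams(populationSize = 30,
                                       generations = 3),
                        annealSchedule(restarts = 1), seed = 42)
  expect_identical(archiveRecords(a1), archiveRecords(a2))
  expect_identical(archiveComponents(a1), archiveComponents(a2))
})

test_that("cached scoring returns identical results for repeated sequences", {
  g <- plantedLandscape(2, c("A", "C"), "AC", gap = 1, nrotamers = 2)
  arc <- evolveSequences(g, unitFitnessWeights("A"),
                         gaParams(populationSize = 30, generations = 3),
                         annealSchedule(restarts = 1), seed = 2)
  rec <- archiveRecords(arc)
  for (sq in unique(rec$sequence)) {
    expect_length(unique(rec$fitness[rec$sequence == sq]), 1)
  }
})

test_that("GA selection can use different weights than post-processing", {
  g <- plantedLandscape(2, c("A", "C", "D"), "AC", gap = 1,
                        groups = c("A", "B"))
  wGA <- fitnessWeights(self = c(A = 0.5, B = 0.5), int = c("A:B" = 1))
  arc <- evolveSequences(g, wGA, gaParams(populationSize = 20,
                                          generations = 2),
                         annealSchedule(restarts = 1), seed = 3)
  comp <- archiveComponents(arc)
  expect_setequal(colnames(comp), c("self:A", "self:B", "int:A:B"))
  wPost <- fitnessWeights(self = c(A = 0.4, B = 0.4), int = c("A:B" = 1))
  refit <- reweightComponents(comp, wPost)
  expect_false(isTRUE(all.equal(refit, archiveRecords(arc)$fitness)))
})

test_that("theoretical library sizes follow from the allowed sets", {
  all20 <- rep(list(AA_ALPHABET), 5)
  expect_equal(theoreticalLibrarySize(all20), 3.2e6)
  expect_equal(theoreticalLibrarySize(rep(list(AA_ALPHABET), 6)), 6.4e7)
  expect_equal(theoreticalLibrarySize(list(c("A", "C"), "D")), 2)
})
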