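test_that("Boltzmann weights follow the closed form and its limits", {
  expect_equal(boltzmannWeights(c(3, 3, 3)), rep(1 / 3, 3))
  kT <- 0.228
  w <- boltzmannWeights(c(0, kT), kT)
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  # shift invariance
  f <- c(0.2, 1.4, 0.9, 2.2)
  expect_equal(boltzmannWeights(f, kT), boltzmannWeights(f + 17.3, kT),
               tolerance = 1e-12)
  # kT limits
  expect_equal(boltzmannWeights(f, 1e9), rep(0.25, 4), tolerance = 1e-6)
  wCold <- boltzmannWeights(f, 1e-6)
  expect_equal(wCold[which.min(f)], 1, tolerance = 1e-9)
  expect_error(boltzmannWeights(f, 0), "positive")
})

test_that("cutoff weights pick exactly the window above the minimum", {
  f <- c(0.5, 0.1, 0.3, 0.9)
  expect_equal(cutoffWeights(f, 0), c(0, 1, 0, 0))
  expect_equal(cutoffWeights(f, Inf), rep(0.25, 4))
  # threshold including exactly k sequences (sort oracle)
  sorted <- sort(f - min(f))
  for (k in 1:4) {
    thr <- sorted[k]
    w <- cutoffWeights(f, thr)
    expect_equal(sum(w > 0), k)
    expect_true(all(w[w > 0] == 1 / k))
  }
})

test_that("single-backbone PWMs accumulate weighted residue frequencies", {
  arc1 <- manualArchive("AC", 0, positions = c("P1", "P2"))
  pwm1 <- backbonePWM(arc1)
  expect_equal(pwmProfile(pwm1)["A", "P1"], 1)
  expect_equal(pwmProfile(pwm1)["C", "P2"], 1)
  expect_equal(colSums(pwmProfile(pwm1)), c(P1 = 1, P2 = 1))

  arc2 <- manualArchive(c("AC", "DC"), c(0, 0), positions = c("P1", "P2"))
  pwm2 <- backbonePWM(arc2)
  expect_equal(pwmProfile(pwm2)["A", "P1"], 0.5)
  expect_equal(pwmProfile(pwm2)["D", "P1"], 0.5)
  expect_equal(pwmProfile(pwm2)["C", "P2"], 1)
})

test_that("an exhaustive archive recovers the exact Boltzmann marginals", {
  g <- plantedLandscape(3, c("A", "C", "D"), "ACD", gap = 0.4,
                        nrotamers = 1, edgeNoise = 0.1)
  w <- unitFitnessWeights("A")
  en <- enumerateSequences(g, w)
  arc <- manualArchive(en$sequence, en$fitness, positions = g@positions)
  pwm <- backbonePWM(arc, boltzmannParams(0.228))
  exact <- enumerateBoltzmannPWM(g, w, 0.228)
  expect_equal(pwmProfile(pwm), pwmProfile(exact), tolerance = 1e-12)
})

test_that("duplicate archive records contribute once via firstSeen", {
  arc <- manualArchive(c("AC", "AC", "DC"), c(0, 0, 0),
                       positions = c("P1", "P2"))
  pwm <- backbonePWM(arc)
  expect_equal(pwmProfile(pwm)["A", "P1"], 0.5)
})

test_that("percentile merge equals an independent quantile oracle", {
  set.seed(8)
  pwms <- lapply(1:5, function(i) randomPWM(3, seed = 20 + i))
  for (pct in c(0.25, 0.5, 0.9)) {
    merged <- mergePWMs(pwms, pct)
    cube <- simplify2array(lapply(pwms, pwmProfile))
    oracle <- apply(cube, c(1, 2), function(v)
      unname(stats::quantile(v, pct)))
    oracle <- sweep(oracle, 2, colSums(oracle), `/`)
    expect_equal(unname(pwmProfile(merged)), unname(oracle),
                 tolerance = 1e-12)
    expect_equal(unname(colSums(pwmProfile(merged))), rep(1, 3),
                 tolerance = 1e-9)
  }
  # identical inputs merge to themselves
  same <- mergePWMs(list(pwms[[1]], pwms[[1]]), 0.5)
  expect_equal(pwmProfile(same), pwmProfile(pwms[[1]]), tolerance = 1e-12)
  # median of three elements {0.1, 0.2, 0.9} is 0.2 before renormalization
  expect_equal(unname(stats::quantile(c(0.1, 0.2, 0.9), 0.5)), 0.2)
})

test_that("merge is monotone in the percentile before renormalization", {
  pwms <- lapply(1:4, function(i) randomPWM(2, seed = 40 + i))
  cube <- simplify2array(lapply(pwms, pwmProfile))
  q25 <- apply(cube, c(1, 2), stats::quantile, probs = 0.25, names = FALSE)
  q75 <- apply(cube, c(1, 2), stats::quantile, probs = 0.75, names = FALSE)
  expect_true(all(q25 <= q75 + 1e-12))
})

test_that("information content spans 0 to log2(20) bits", {
  uni <- methods::new("PWM",
    profile = matrix(1 / 20, 20, 1, dimnames = list(AA_ALPHABET, "P1")),
    positions = "P1", metadata = list())
  expect_equal(informationBits(uni)$average, 0, tolerance = 1e-12)

  onehot <- makeExperimentalPWM(list(P1 = c(W = 1)))
  expect_equal(informationBits(onehot)$average, log2(20),
               tolerance = 1e-12)

  two <- makeExperimentalPWM(list(P1 = c(A = 1, C = 1)))
  expect_equal(informationBits(two)$average, log2(20) - 1,
               tolerance = 1e-12)
})

test_that("covariation marginals equal the PWM columns", {
  arc <- manualArchive(c("AC", "AD", "CC", "CD"), c(0, 0.3, 0.7, 1.1),
                       positions = c("P1", "P2"))
  params <- boltzmannParams(0.5)
  joint <- covariation(arc, params, "P1", "P2")
  pwm <- backbonePWM(arc, params)
  expect_equal(rowSums(joint), pwmProfile(pwm)[, "P1"], tolerance = 1e-9)
  expect_equal(colSums(joint), pwmProfile(pwm)[, "P2"], tolerance = 1e-9)

  # single sequence -> one-hot joint
  j1 <- covariation(manualArchive("AC", 0, c("P1", "P2")),
                    boltzmannParams(), "P1", "P2")
  expect_equal(j1["A", "C"], 1)
  expect_equal(sum(j1), 1)
})

test_that("independent position preferences factorize the joint", {
  # additive fitness over two positions -> Boltzmann joint = outer product
  seqs <- c("AC", "AD", "CC", "CD")
  fA <- c(A = 0, C = 0.5)
  fB <- c(C = 0, D = 0.8)
  fit <- fA[substr(seqs, 1, 1)] + fB[substr(seqs, 2, 2)]
  arc <- manualArchive(seqs, unname(fit), positions = c("P1", "P2"))
  joint <- covariation(arc, boltzmannParams(0.228), "P1", "P2")
  expect_equal(unname(joint[c("A", "C"), c("C", "D")]),
               unname(rowSums(joint)[c("A", "C")] %o%
                      colSums(joint)[c("C", "D")]),
               tolerance = 1e-9)
})

test_that("generation contributions total 1 and follow first-seen weights", {
  arc <- manualArchive(c("AC", "DC", "AC"), c(0, 0.5, 0),
                       positions = c("P1", "P2"),
                       generation = c(1L, 2L, 3L))
  gc <- generationContributions(arc, boltzmannParams(0.228))
  expect_equal(sum(gc), 1, tolerance = 1e-12)
  expect_equal(unname(gc[3]), 0)  # AC was first seen in generation 1

  allG1 <- manualArchive(c("AC", "DC"), c(0, 1), c("P1", "P2"))
  gcl <- generationContributions(allG1, boltzmannParams(0.228))
  expect_equal(unname(gcl), 1)

  # a dominant generation-1 sequence takes everything as kT -> 0+
  dom <- manualArchive(c("AC", "DC", "DD"), c(0, 3, 4), c("P1", "P2"),
                       generation = c(1L, 2L, 3L))
  gcd <- generationContributions(dom, boltzmannParams(1e-4))
  expect_equal(unname(gcd[1]), 1, tolerance = 1e-9)
})

test_that("post-processing can rescore archives with new fitness coefficients", {
  rec <- data.frame(sequence = c("AC", "CD"), generation = 1L,
                    backbone = 1L, rawScore = c(1, 2), fitness = c(1, 2),
                    firstSeen = TRUE, stringsAsFactors = FALSE)
  comp <- cbind("self:A" = c(0.5, 2.0), "self:B" = c(0.5, 0.0),
                "int:A:B" = c(0.0, 0.0))
  arc <- methods::new("SequenceArchive", records = rec, components = comp,
                      positions = c("P1", "P2"), meta = list())
  wNew <- fitnessWeights(self = c(A = 0.4, B = 0.4), int = c("A:B" = 1))
  pwm <- backbonePWM(arc, boltzmannParams(0.228, fitnessCoef = wNew))
  # with the new coefficients the fitnesses are 0.4 and 0.8
  wts <- boltzmannWeights(c(0.4, 0.8), 0.228)
  expect_equal(pwmProfile(pwm)["A", "P1"], wts[1], tolerance = 1e-12)
})

test_that("PWM and archive TSV round trips preserve content", {
  pwm <- randomPWM(3, seed = 77)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePWM(pwm, f)
  pwm2 <- readPWM(f)
  expect_equal(pwmProfile(pwm2), pwmProfile(pwm), tolerance = 1e-12)

  arc <- manualArchive(c("AC", "DC"), c(0, 0.4), c("P1", "P2"))
  fa <- withr::local_tempfile(fileext = ".tsv")
  writeArchive(arc, fa)
  arc2 <- readArchive(fa)
  expect_equal(archiveRecords(arc2), archiveRecords(arc))
  expect_equal(archiveComponents(arc2), archiveComponents(arc))
  expect_equal(arc2@positions, arc@positions)
})
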