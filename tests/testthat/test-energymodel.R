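p0 <- energyModelParams(hisReferenceOffset = 0)

test_that("one-body terms vanish for a clash-free non-rotameric state", {
  # extended chain: side chains point away from each other
  s <- makeToyStructure(toySpec(5, geometry = "extended"))
  st <- residueState(s, "A3", "A", 1)
  expect_equal(oneBodyEnergy(st, s, p0), 0)
})

test_that("histidine reference offset shifts the one-body term by exactly +1.2", {
  s <- makeToyStructure(toySpec(5, geometry = "extended"))
  p <- energyModelParams(hisReferenceOffset = 1.2)
  # H and N share the rotamer prior, so with no clashes the difference is
  # purely the reference term
  dH <- oneBodyEnergy(residueState(s, "A3", "H", 1), s, p) -
    oneBodyEnergy(residueState(s, "A3", "N", 1), s, p)
  expect_equal(dH, 1.2, tolerance = 1e-12)
  pOff <- energyModelParams(hisReferenceOffset = 0)
  dH0 <- oneBodyEnergy(residueState(s, "A3", "H", 1), s, pOff) -
    oneBodyEnergy(residueState(s, "A3", "N", 1), s, pOff)
  expect_equal(dH0, 0, tolerance = 1e-12)
})

test_that("near-overlap clashes are clamped at the ceiling", {
  expect_equal(wcaEnergy(0.1, 3.5, 0.2, clamp = 10), 10)
  expect_equal(ljEnergy(0.1, 3.5, 0.2, clamp = 10), 10)
  # a state whose pseudo-atom overlaps another chain's CA at 0.1 A picks
  # up the full clamp contribution
  s <- makeToyStructure(toySpec(4, nchains = 2, offset = 25))
  st <- residueState(s, "A2", "W", 1)
  at <- atomRecords(s)
  caB1 <- as.numeric(at[at$chain == "B" & at$resno == 1 &
                        at$elety == "CA", c("x", "y", "z")])
  shift <- (st$sc + c(0.1, 0, 0)) - caB1
  selB <- at$chain == "B"
  at[selB, c("x", "y", "z")] <- sweep(at[selB, c("x", "y", "z")], 2,
                                      -shift)
  s2 <- methods::initialize(s, atoms = at)
  st2 <- residueState(s2, "A2", "W", 1)
  expect_gte(oneBodyEnergy(st2, s2, p0), p0$clamp)
})

test_that("two-body term is symmetric, zero beyond the cutoff, -eps at the LJ minimum", {
  mkState <- function(pos, aa, sc) {
    structure(list(position = pos, aa = aa, rot = 1L, chi1 = NA_real_,
                   prob = 1, sc = sc, cb = sc), class = "ResidueState")
  }
  sigAB <- (p0$sigma[["L"]] + p0$sigma[["F"]]) / 2
  epsAB <- sqrt(p0$epsilon[["L"]] * p0$epsilon[["F"]])
  a <- mkState("A1", "L", c(0, 0, 0))
  bMin <- mkState("A2", "F", c(sigAB * 2^(1 / 6), 0, 0))
  expect_equal(twoBodyEnergy(a, bMin, p0), -epsAB, tolerance = 1e-12)
  bFar <- mkState("A2", "F", c(2 * p0$cutoff, 0, 0))
  expect_identical(twoBodyEnergy(a, bFar, p0), 0)
  expect_error(twoBodyEnergy(a, mkState("A1", "F", c(3, 0, 0)), p0),
               "distinct")

  set.seed(42)
  for (i in 1:20) {
    x <- mkState("A1", sample(AA_ALPHABET, 1), stats::rnorm(3, sd = 3))
    y <- mkState("A2", sample(AA_ALPHABET, 1), stats::rnorm(3, sd = 3))
    expect_identical(twoBodyEnergy(x, y, p0), twoBodyEnergy(y, x, p0))
  }
})

test_that("compressing a clashing pair never decreases the pair energy", {
  # energy is non-increasing as the distance grows through the clash zone
  ds <- seq(0.3, 6, by = 0.1)
  e <- ljEnergy(ds, 4, 0.25, clamp = 10)
  clash <- ds < 4 * 2^(1 / 6)
  expect_true(all(diff(e[clash]) <= 1e-12))
  ew <- wcaEnergy(ds, 4, 0.25, clamp = 10)
  expect_true(all(diff(ew) <= 1e-12))
})

test_that("interaction graph bookkeeping: states, edges and cutoffs", {
  s <- makeToyStructure(toySpec(3, sequence = "VVV"))
  d <- parseResfile("NATRO\nstart\n1 A PIKAA CD\n2 A NATAA", s)
  g <- buildInteractionGraph(s, d, p0)
  # designed: 2 rotameric types x 3 rotamers; repacked: native V rotamers
  expect_equal(unname(stateCounts(g)), c(6L, 3L))
  expect_length(g@edges, 1)
  expect_equal(dim(g@edges[[1]]$e), c(6L, 3L))
  # an empty allowed set is rejected at DesignSpec construction already
  expect_error(
    methods::new("DesignSpec",
                 premutated = stats::setNames(character(), character()),
                 designed = list(A1 = character()),
                 repacked = "A2", nonmoving = "A3"),
    "non-empty")
})

test_that("positions beyond the CB cutoff share no edge", {
  s <- makeToyStructure(toySpec(3, geometry = "extended"))
  at <- atomRecords(s)
  sel <- at$resno == 3
  at[sel, "x"] <- at[sel, "x"] + 40  # push residue 3 far away
  sFar <- methods::initialize(s, atoms = at)
  d <- parseResfile("NATAA\nstart\n", sFar)
  g <- buildInteractionGraph(sFar, d, p0)
  pairs <- vapply(g@edges, function(e) paste(e$i, e$j), "")
  expect_false(paste(1, 3) %in% pairs)
  expect_false(paste(2, 3) %in% pairs)
})

test_that("graph raw score equals direct one-body/two-body summation", {
  # all residues movable -> no background, so the graph must reproduce a
  # brute-force sum of standalone energy calls exactly
  s <- makeToyStructure(toySpec(5, sequence = "VLSKF"))
  d <- parseResfile("NATAA\nstart\n2 A PIKAA ACDV\n4 A PIKAA KLM", s)
  g <- buildInteractionGraph(s, d, p0)
  fr <- SeqTolerance:::.backboneFrames(s)
  set.seed(7)
  for (rep in 1:10) {
    a <- vapply(g@states, function(st) sample.int(nrow(st), 1), 0L)
    direct <- 0
    statesList <- lapply(seq_along(a), function(i) {
      st <- g@states[[i]][a[i], ]
      residueState(s, g@positions[i], st$aa, st$rot)
    })
    for (i in seq_along(a)) {
      direct <- direct + oneBodyEnergy(statesList[[i]], s, p0)
    }
    for (i in seq_along(a)) {
      for (j in seq_along(a)) {
        if (j <= i) next
        cbd <- sqrt(sum((fr$CB[g@positions[i], ] -
                         fr$CB[g@positions[j], ])^2))
        if (cbd > p0$cutoff) next
        direct <- direct + twoBodyEnergy(statesList[[i]], statesList[[j]], p0)
      }
    }
    expect_equal(rawScore(g, a), direct, tolerance = 1e-9)
  }
})

test_that("unit-weight reweighted fitness equals the raw score", {
  s <- toyComplex(4)
  d <- parseResfile("NATAA\nstart\n2 A PIKAA ACD\n2 B PIKAA KLM", s)
  g <- buildInteractionGraph(s, d, p0)
  w1 <- unitFitnessWeights(c("A", "B"))
  set.seed(3)
  for (rep in 1:8) {
    a <- vapply(g@states, function(st) sample.int(nrow(st), 1), 0L)
    expect_equal(reweightedFitness(g, a, w1), rawScore(g, a),
                 tolerance = 1e-9)
  }
})

test_that("interface weighting 0.4 intra / 1 inter matches manual term sums", {
  s <- toyComplex(4)
  d <- parseResfile("NATAA\nstart\n2 A PIKAA ACD\n2 B PIKAA KLM", s)
  g <- buildInteractionGraph(s, d, p0)
  w <- fitnessWeights(self = c(A = 0.4, B = 0.4), int = c("A:B" = 1))
  set.seed(11)
  a <- vapply(g@states, function(st) sample.int(nrow(st), 1), 0L)
  comp <- energyComponents(g, a)
  manual <- 0.4 * (comp[["self:A"]] + comp[["self:B"]]) + comp[["int:A:B"]]
  expect_equal(reweightedFitness(g, a, w), manual, tolerance = 1e-12)
  expect_equal(sum(comp), rawScore(g, a), tolerance = 1e-12)
})

test_that("zero cross-chain weight makes fitness blind to interface edges", {
  s <- toyComplex(4)
  d <- parseResfile("NATAA\nstart\n2 A PIKAA ACD\n2 B PIKAA KLM", s)
  g <- buildInteractionGraph(s, d, p0)
  w0 <- fitnessWeights(self = c(A = 1, B = 1), int = c("A:B" = 0))
  g2 <- g
  for (k in seq_along(g2@edges)) {
    ed <- g2@edges[[k]]
    if (g2@groups[[ed$i]] != g2@groups[[ed$j]]) {
      g2@edges[[k]]$e <- ed$e + 5  # perturb cross-chain edges only
    }
  }
  a <- vapply(g@states, function(st) 1L, 0L)
  expect_equal(reweightedFitness(g, a, w0), reweightedFitness(g2, a, w0),
               tolerance = 1e-12)
})

test_that("energy-model config files round-trip the documented keys", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("his_reference_offset: 1.2", "clamp: 8",
               "cutoff: 11", "reference_C: 0.5", "# comment"), f)
  p <- readEnergyModelConfig(f)
  expect_equal(p$reference[["H"]], 1.2)
  expect_equal(p$reference[["C"]], 0.5)
  expect_equal(p$clamp, 8)
  expect_equal(p$cutoff, 11)
  expect_error(readEnergyModelConfig({
    f2 <- withr::local_tempfile(fileext = ".cfg")
    writeLines("frobnicate: 3", f2)
    f2
  }), "unknown")
})
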