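test_that("a zero-angle backrub proposal returns identical coordinates", {
  s <- toyHelix(8)
  set.seed(1)
  cand <- proposeBackrub(s, moveSet(), angle = 0)
  expect_identical(atomRecords(cand)[, c("x", "y", "z")],
                   atomRecords(s)[, c("x", "y", "z")])
})

test_that("backrub proposals are rigid rotations between fixed pivot CAs", {
  s <- toyHelix(10)
  set.seed(42)
  for (rep in 1:10) {
    cand <- proposeBackrub(s, moveSet())
    a0 <- as.matrix(atomRecords(s)[, c("x", "y", "z")])
    a1 <- as.matrix(atomRecords(cand)[, c("x", "y", "z")])
    moved <- rowSums(abs(a1 - a0)) > 0
    # atoms outside the segment are bitwise unchanged
    expect_identical(a1[!moved, ], a0[!moved, ])
    if (!any(moved)) next
    # pairwise distances within the rotated set are preserved (rigidity)
    d0 <- dist(a0[moved, , drop = FALSE])
    d1 <- dist(a1[moved, , drop = FALSE])
    expect_equal(max(abs(d1 - d0)), 0, tolerance = 1e-9)
    # some pair of unchanged CA atoms forms the rotation axis: distances
    # from every moved atom to both pivots are preserved
    ca <- atomRecords(s)$elety == "CA"
    caIdx <- which(ca)
    axisFound <- FALSE
    for (i in caIdx) {
      for (j in caIdx) {
        if (j <= i) next
        di0 <- sqrt(rowSums(sweep(a0[moved, , drop = FALSE], 2, a0[i, ])^2))
        di1 <- sqrt(rowSums(sweep(a1[moved, , drop = FALSE], 2, a0[i, ])^2))
        dj0 <- sqrt(rowSums(sweep(a0[moved, , drop = FALSE], 2, a0[j, ])^2))
        dj1 <- sqrt(rowSums(sweep(a1[moved, , drop = FALSE], 2, a0[j, ])^2))
        if (max(abs(di1 - di0)) < 1e-9 && max(abs(dj1 - dj0)) < 1e-9) {
          axisFound <- TRUE
        }
      }
    }
    expect_true(axisFound)
  }
})

test_that("chi moves leave the backbone untouched and land on prior bins", {
  s <- toyHelix(6)
  set.seed(3)
  cand <- proposeChi(s, "biased", position = "A2")
  bb <- atomRecords(s)$elety %in% c("N", "CA", "C", "O", "CB")
  expect_identical(atomRecords(cand)[bb, c("x", "y", "z")],
                   atomRecords(s)[bb, c("x", "y", "z")])
  expect_true(cand@residues$chi1[2] %in% rotamerStates("V")$chi1)
})

test_that("uniform chi draws are uniform on (-180, 180]", {
  s <- makeToyStructure(toySpec(3, sequence = "AVA"))
  set.seed(9)
  draws <- replicate(4000, {
    proposeChi(s, "uniform", position = "A2")@residues$chi1[2]
  })
  h <- table(cut(draws, breaks = seq(-180, 180, by = 45)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})

test_that("Metropolis criterion: downhill always, dE = kT near exp(-1)", {
  expect_true(metropolisAccept(-1, 0.6))
  expect_true(metropolisAccept(0, 0.6))
  expect_error(metropolisAccept(1, 0), "positive")
  set.seed(4)
  n <- 1e5
  acc <- sum(replicate(n, metropolisAccept(0.6, 0.6)))
  pHat <- acc / n
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(pHat - exp(-1)), 3 * se)
})

test_that("move types are drawn at the configured frequencies", {
  s <- toyHelix(5)
  m <- moveSet(nMoves = 600)
  out <- runTrajectory(s, m, seed = 17)
  prop <- out@provenance$trajectory$proposed
  expect_equal(sum(prop), 600)
  expect_equal(prop[["small"]], 0)
  p <- stats::chisq.test(prop[1:3],
                         p = c(0.75, 0.225, 0.025))$p.value
  expect_gt(p, 0.001)
})

test_that("trajectories return the lowest-energy snapshot, reproducibly", {
  s <- toyHelix(6)
  m0 <- moveSet(nMoves = 0)
  expect_identical(atomRecords(runTrajectory(s, m0, seed = 1)),
                   atomRecords(s))
  m <- moveSet(nMoves = 60)
  out <- runTrajectory(s, m, seed = 5)
  expect_lte(structureEnergy(out), structureEnergy(s))
  out2 <- runTrajectory(s, m, seed = 5)
  expect_identical(atomRecords(out), atomRecords(out2))
  expect_identical(out@residues$chi1, out2@residues$chi1)
  tr <- out@provenance$trajectory
  expect_true(all(tr$accepted <= tr$proposed))
  expect_lte(tr$bestEnergy, tr$finalEnergy + 1e-12)
})

test_that("ensembles require distinct seeds and diversify coordinates", {
  s <- toyHelix(6)
  expect_error(generateEnsemble(s, 2, moveSet(nMoves = 5), seeds = c(1, 1)),
               "distinct")
  ens0 <- generateEnsemble(s, 1, moveSet(nMoves = 0), seeds = 7)
  expect_identical(atomRecords(ens0[[1]]), atomRecords(s))
  ens <- generateEnsemble(s, 2, moveSet(nMoves = 40), seeds = c(2, 3))
  expect_false(identical(atomRecords(ens[[1]])[, c("x", "y", "z")],
                         atomRecords(ens[[2]])[, c("x", "y", "z")]))
  rmsds <- vapply(ens, function(e) e@provenance$caRMSD, 0)
  # regression bound: short toy trajectories stay near the start
  expect_true(all(rmsds >= 0 & rmsds < 5))
})

test_that("acceptance tends to 1 at high kT and to downhill-only at low kT", {
  s <- toyHelix(5)
  hot <- runTrajectory(s, moveSet(nMoves = 80, mcKT = 1e6), seed = 2)
  trHot <- hot@provenance$trajectory
  expect_gte(sum(trHot$accepted) / sum(trHot$proposed), 0.95)
  # at kT -> 0+ every accepted move was downhill at the time, so the
  # final energy can never exceed the start
  cold <- runTrajectory(s, moveSet(nMoves = 80, mcKT = 1e-9), seed = 2)
  trCold <- cold@provenance$trajectory
  expect_lte(trCold$finalEnergy, trCold$startEnergy + 1e-9)
})

test_that("premutation substitutes the type and repacks without moving the backbone", {
  s <- toyHelix(6)
  mu <- premutate(s, c(A3 = "K"), seed = 1)
  expect_equal(unname(residueSequence(mu)[["A3"]]), "K")
  bb <- atomRecords(s)$elety %in% c("N", "CA", "C", "O")
  expect_identical(atomRecords(mu)[atomRecords(mu)$elety %in%
                                     c("N", "CA", "C", "O"),
                                   c("x", "y", "z")],
                   atomRecords(s)[bb, c("x", "y", "z")])
  expect_error(premutate(s, c(A3 = "Z")), "unknown type")

  noop <- premutate(s, character(), seed = 1)
  expect_identical(atomRecords(noop)[, c("x", "y", "z")],
                   atomRecords(s)[, c("x", "y", "z")])
})

test_that("staged minimization only ever lowers the energy", {
  s <- toyHelix(6)
  mm <- parseMovemap("RESIDUE * BBCHI", s)
  mu <- premutate(s, c(A2 = "W", A5 = "F"), seed = 1)
  e0 <- structureEnergy(mu)
  muMin <- premutate(s, c(A2 = "W", A5 = "F"), minimize = mm, seed = 1)
  expect_lte(structureEnergy(muMin), e0 + 1e-9)
})

test_that("small phi/psi moves only change the chosen residue and downstream", {
  s <- toyHelix(8)
  set.seed(6)
  cand <- proposeSmallMove(s, position = "A4")
  a0 <- as.matrix(atomRecords(s)[, c("x", "y", "z")])
  a1 <- as.matrix(atomRecords(cand)[, c("x", "y", "z")])
  res <- atomRecords(s)$resno
  expect_identical(a1[res < 4, ], a0[res < 4, ])
  expect_false(identical(a1[res > 4, ], a0[res > 4, ]))
})
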