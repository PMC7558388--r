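# Correspondence search, brute-force oracle equivalence, matching
# invariances, and Kabsch superposition.

test_that("features on the exact consensus embedding match with zero deviation", {
  feats <- consensusEmbeddedFeatures()
  model <- builtinModel("bk_consensus")
  cors <- matchConformer(feats, model)
  expect_gte(length(cors), 1)
  expect_lt(cors[[1]]@maxDev, 1e-6)

  # removing the positive feature makes P1 unmatchable
  expect_length(matchConformer(feats[feats$type != "POSITIVE", ], model), 0)

  # inflating all coordinates by 1.5x pushes every pair out of tolerance
  blown <- feats
  blown$x <- blown$x * 1.5; blown$y <- blown$y * 1.5; blown$z <- blown$z * 1.5
  expect_length(matchConformer(blown, model), 0)
})

test_that("single-point counting and empty inputs behave per contract", {
  feats <- consensusEmbeddedFeatures()
  one <- pharmacophoreModel("one",
                            list(phPoint("P1", c("DONOR", "ACCEPTOR")),
                                 phPoint("P2", "AROMATIC")),
                            matrix(c(0, 9.6, 9.6, 0), 2))
  # correspondences = compatible-feature pairs within tolerance
  got <- bruteForceMatch(feats, one)
  expect_identical(corKey(got), corKey(matchConformer(feats, one)))
  # a 1-point model yields exactly one correspondence per compatible feature
  single <- pharmacophoreModel("single", list(phPoint("P1", "DONOR")),
                               matrix(0, 1, 1))
  expect_length(matchConformer(feats, single), sum(feats$type == "DONOR"))
  expect_identical(corKey(matchConformer(feats, single)),
                   corKey(bruteForceMatch(feats, single)))
  expect_length(bruteForceMatch(feats[0, ], one), 0)
  big <- do.call(rbind, rep(list(feats), 3))
  big$sourceAtoms <- as.list(seq_len(nrow(big)))
  expect_error(bruteForceMatch(big, one), "10")
})

test_that("backtracking search equals the brute-force oracle on random instances", {
  set.seed(123)
  nonTrivial <- 0
  for (rep in 1:120) {
    inst <- randomMatchInstance(sample(3:8, 1), sample(2:5, 1))
    a <- matchConformer(inst$features, inst$model)
    b <- bruteForceMatch(inst$features, inst$model)
    expect_identical(corKey(a), corKey(b))
    if (length(a)) {
      nonTrivial <- nonTrivial + 1
      expect_equal(vapply(a, function(co) co@sumSq, numeric(1)),
                   vapply(b, function(co) co@sumSq, numeric(1)))
      # every reported deviation respects its pair tolerance
      tolMat <- pairTolerances(inst$model)
      for (co in a) expect_lte(co@maxDev, max(tolMat))
    }
  }
  expect_gte(nonTrivial, 5)   # the comparison exercised real matches
})

test_that("tolerance monotonicity: valid at t implies valid at larger t", {
  set.seed(77)
  for (rep in 1:30) {
    inst <- randomMatchInstance(6, 3)
    lo <- matchConformer(inst$features, inst$model, tolerance = 1.0)
    hi <- matchConformer(inst$features, inst$model, tolerance = 2.5)
    expect_true(all(corKey(lo) %in% corKey(hi)))
  }
})

test_that("adding features never removes an existing correspondence", {
  set.seed(99)
  for (rep in 1:20) {
    inst <- randomMatchInstance(6, 3)
    base <- corKey(matchConformer(inst$features, inst$model))
    extra <- inst$features[1, ]
    extra$x <- extra$x + 20; extra$label <- "extra"
    grown <- rbind(inst$features, extra)
    grown$sourceAtoms <- as.list(seq_len(nrow(grown)))
    expect_true(all(base %in% corKey(matchConformer(grown, inst$model))))
  }
})

test_that("matching is invariant under rigid motion and reflection", {
  set.seed(5)
  for (rep in 1:15) {
    inst <- randomMatchInstance(7, 4)
    base <- matchConformer(inst$features, inst$model)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    P <- as.matrix(inst$features[, c("x", "y", "z")]) %*% R
    P <- sweep(P, 2, c(3, -1, 2), "+")
    moved <- inst$features; moved[, c("x", "y", "z")] <- P
    got <- matchConformer(moved, inst$model)
    expect_identical(corKey(got), corKey(base))
    if (length(base))
      expect_equal(vapply(got, function(co) co@sumSq, numeric(1)),
                   vapply(base, function(co) co@sumSq, numeric(1)),
                   tolerance = 1e-9)
    mirror <- inst$features; mirror$z <- -mirror$z
    expect_identical(corKey(matchConformer(mirror, inst$model)),
                     corKey(base))
  }
})

test_that("Kabsch superposition satisfies its contract", {
  set.seed(11)
  A <- matrix(runif(12, -3, 3), 4, 3)
  # self-superposition
  r <- kabschSuperpose(A, A)
  expect_equal(r$rmsd, 0, tolerance = 1e-12)
  expect_equal(r$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(r$rotation), 1, tolerance = 1e-12)
  # rigid motion is recovered exactly
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  B <- sweep(A %*% R, 2, c(1, 2, 3), "+")
  r2 <- kabschSuperpose(A, B)
  expect_lt(r2$rmsd, 1e-9)
  expect_equal(A %*% r2$rotation + rep(1, 4) %o% r2$translation, B,
               tolerance = 1e-9)
  # a chiral 4-point set cannot be superposed onto its mirror image by a
  # proper rotation; cross-check against the rotation-grid oracle
  chiral <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1.5, 0), c(0.4, 0.3, 2.5))
  mirror <- chiral %*% diag(c(1, 1, -1))
  r3 <- kabschSuperpose(chiral, mirror)
  expect_gt(r3$rmsd, 0.1)
  expect_equal(det(r3$rotation), 1, tolerance = 1e-9)
  oracle <- gridRmsdOracle(chiral, mirror)
  expect_lte(r3$rmsd, oracle + 1e-9)   # SVD finds the optimum
  expect_lt(abs(r3$rmsd - oracle), 0.12)  # grid resolution
  expect_error(kabschSuperpose(A, A[1:3, ]), "dimension")
  expect_error(kabschSuperpose(A[1:2, ], A[1:2, ]), "3 points")
})

test_that("ensemble matching picks the best conformer deterministically", {
  model <- builtinModel("bk_consensus")
  mol <- assignProtonation(parseSmiles("NCCCCCCCCCc1ccccc1", "amine-chain"))
  ens <- generateConformers(mol, n = 30, seed = 2, steps = 200)
  res <- matchMolecule(ens, model)
  expect_s4_class(res, "MatchResult")
  if (isMatched(res)) {
    expect_false(is.na(res@bestConformer))
    expect_lte(res@maxDeviation, max(pairTolerances(model)))
    # the best conformer's own correspondences contain the reported best
    feats <- perceiveFeatures(mol, conformers(ens)[[res@bestConformer]])
    cors <- matchConformer(feats, model)
    expect_equal(cors[[1]]@sumSq, res@sumSqDeviation, tolerance = 1e-9)
  } else {
    expect_true(is.na(res@bestConformer))
  }
  # a decoy without positive-ionizable groups can never match
  dec <- assignProtonation(parseSmiles("O=C(OCc1ccccc1)c1ccccc1",
                                       "benzyl benzoate"))
  dens <- generateConformers(dec, n = 10, seed = 3, steps = 200)
  expect_false(isMatched(matchMolecule(dens, model)))
})
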