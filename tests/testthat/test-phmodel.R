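# Built-in bradykinin models, distance-geometry embedding and realizability,
# serialization round trips.

test_that("built-in models carry the published distances and point types", {
  m <- builtinModel("bk_consensus")
  expect_length(points(m), 4)
  D <- targetDistances(m)
  expect_equal(D["P1", "P2"], 9.0)
  expect_equal(D["P1", "P3"], 14.0)
  expect_equal(D["P1", "P4"], 10.5)
  expect_equal(D["P2", "P3"], 6.0)
  expect_equal(D["P2", "P4"], 7.0)
  expect_equal(D["P3", "P4"], 7.5)
  expect_equal(points(m)[[1]]@acceptedTypes, "POSITIVE")
  expect_setequal(points(m)[[2]]@acceptedTypes, c("DONOR", "ACCEPTOR"))
  expect_equal(points(m)[[3]]@acceptedTypes, "AROMATIC")

  b1 <- builtinModel("bk_b1")
  expect_length(points(b1), 5)
  expect_equal(targetDistances(b1)["P4", "P5"], 5.7)
  expect_equal(targetDistances(b1)["P1", "P5"], 9.5)
  expect_equal(targetDistances(b1)["P2", "P5"], 9.3)
  expect_equal(targetDistances(b1)["P3", "P5"], 9.5)
  expect_equal(points(b1)[[5]]@acceptedTypes, "ACCEPTOR")

  b2 <- builtinModel("bk_b2")
  expect_equal(unname(targetDistances(b2)["P5", 1:4]), c(11, 9, 8.8, 8.4))
  expect_setequal(points(b2)[[5]]@acceptedTypes, c("HYDROPHOBIC", "AROMATIC"))
  # consensus block identical across the three models
  expect_equal(targetDistances(b1)[1:4, 1:4], targetDistances(m))
  expect_equal(targetDistances(b2)[1:4, 1:4], targetDistances(m))

  expect_error(builtinModel("x"), "bk_consensus")
})

test_that("strict embedding reproduces the consensus geometry exactly", {
  m <- builtinModel("bk_consensus")
  e <- embedModel(m, "strict")
  expect_true(e@realizable)
  expect_lte(e@maxResidual, 1e-6)
  realized <- as.matrix(dist(e@coordinates))
  expect_equal(unname(realized), unname(targetDistances(m)), tolerance = 1e-6)
  # agrees with the trilateration oracle up to rigid motion
  or <- trilaterate(targetDistances(m))
  expect_equal(unname(as.matrix(dist(or$coords))),
               unname(targetDistances(m)), tolerance = 1e-9)
  # distances cannot discriminate chirality: the embedding may be the
  # oracle's mirror image
  rmsd <- min(kabschSuperpose(e@coordinates, or$coords)$rmsd,
              kabschSuperpose(e@coordinates,
                              or$coords %*% diag(c(1, 1, -1)))$rmsd)
  expect_lt(rmsd, 1e-5)
  expect_lt(max(abs(colMeans(e@coordinates))), 1e-9)
})

test_that("the five-point models are not strictly realizable in 3D", {
  for (nm in c("bk_b1", "bk_b2")) {
    mod <- builtinModel(nm)
    e <- embedModel(mod, "strict")
    expect_false(e@realizable)
    # trilateration oracle: the directly constructed coordinates cannot
    # reproduce the printed distance set
    or <- trilaterate(targetDistances(mod))
    expect_gt(max(abs(as.matrix(dist(or$coords)) - targetDistances(mod))),
              1e-3)
    # least-squares embedding converges and reports its residual honestly
    ls <- embedModel(mod, "least_squares")
    expect_false(ls@realizable)
    expect_gt(ls@maxResidual, 1e-6)
    expect_lte(ls@maxResidual, e@maxResidual + 1e-9)
  }
  # the B1 oracle value: z^2 of about -4.9 square angstroms
  expect_equal(trilaterate(targetDistances(builtinModel("bk_b1")))$zsq[5],
               -4.9, tolerance = 0.25)
})

test_that("a two-point model embeds trivially", {
  m <- pharmacophoreModel("pair",
                          list(phPoint("A", "DONOR"), phPoint("B", "ACCEPTOR")),
                          matrix(c(0, 5, 5, 0), 2))
  e <- embedModel(m, "strict")
  expect_true(e@realizable)
  expect_equal(as.numeric(dist(e@coordinates)), 5, tolerance = 1e-9)
})

test_that("embedding recovers distances from random 3D point sets", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    X <- matrix(runif(n * 3, -8, 8), n, 3)
    D <- as.matrix(dist(X))
    e <- embedModel(D, "strict")
    expect_true(e@realizable)
    expect_lte(e@maxResidual, 1e-6)
  }
})

test_that("embedded distances are invariant under point permutation", {
  D <- targetDistances(builtinModel("bk_b2"))
  e0 <- sort(as.numeric(dist(embedModel(D, "strict")@coordinates)))
  set.seed(1)
  for (rep in 1:5) {
    p <- sample(nrow(D))
    ep <- sort(as.numeric(dist(embedModel(D[p, p], "strict")@coordinates)))
    expect_equal(ep, e0, tolerance = 1e-9)
  }
})

test_that("model serialization round-trips to full precision", {
  for (nm in c("bk_consensus", "bk_b1", "bk_b2")) {
    m <- builtinModel(nm)
    txt <- writePharmacophore(m)
    m2 <- readPharmacophore(text = txt)
    expect_equal(m2@name, m@name)
    expect_equal(pointLabels(m2), pointLabels(m))
    expect_identical(targetDistances(m2), targetDistances(m))
    expect_equal(pairTolerances(m2), pairTolerances(m))
    for (i in seq_along(points(m)))
      expect_setequal(points(m2)[[i]]@acceptedTypes,
                      points(m)[[i]]@acceptedTypes)
  }
  # file round trip
  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.yaml")
  writePharmacophore(builtinModel("bk_b2"), p)
  expect_equal(targetDistances(readPharmacophore(p))["P1", "P5"], 11.0)
})

test_that("model validation rejects malformed input", {
  txt <- writePharmacophore(builtinModel("bk_consensus"))
  asym <- sub("P2: 9.0", "P2: 8.0", txt, fixed = TRUE)
  expect_error(readPharmacophore(text = asym), "symmetric")
  badTol <- sub("default_tolerance: 1.5", "default_tolerance: -1.0", txt,
                fixed = TRUE)
  expect_error(readPharmacophore(text = badTol))
  badType <- sub("POSITIVE", "NEGATIVE", txt, fixed = TRUE)
  expect_error(readPharmacophore(text = badType), "feature type")
  # construction-time validity: triangle inequality violated beyond slack
  expect_error(pharmacophoreModel("bad",
    list(phPoint("A", "DONOR"), phPoint("B", "DONOR"), phPoint("C", "DONOR")),
    matrix(c(0, 1, 20, 1, 0, 1, 20, 1, 0), 3)), "triangle")
})
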