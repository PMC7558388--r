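# Molecule parsing, SDF/SMILES round trips, molecular weight, MW filter,
# and the fixture library.

test_that("SMILES parsing sanitizes and perceives aromaticity", {
  bz <- parseSmiles("c1ccccc1", "benzene")
  expect_s4_class(bz, "Molecule")
  expect_equal(numAtoms(bz), 6L)
  expect_true(all(atoms(bz)$elem == "C"))
  expect_true(all(atoms(bz)$aromatic))
  expect_true(all(bonds(bz)$aromatic))
  expect_false(hasCoords(bz))

  aa <- parseSmiles("CC(=O)O", "acetic acid")
  expect_equal(numAtoms(aa), 4L)
  expect_equal(sum(atoms(aa)$charge), 0L)

  expect_error(parseSmiles("C(", "bad"), "parse")
  expect_error(parseSmiles("C1CC", "bad"), "ring closure")
  expect_error(parseSmiles("", "bad"), "non-empty")
})

test_that("molecular weight sums standard atomic masses with implicit H", {
  expect_equal(molecularWeight(parseSmiles("c1ccccc1", "benzene")),
               6 * 12.011 + 6 * 1.008, tolerance = 1e-4)
  expect_equal(molecularWeight(parseSmiles("O", "water")),
               2 * 1.008 + 15.999, tolerance = 1e-4)
  # independent cross-check against OpenBabel's own molecular weight
  lib <- fixtureLibrary(0, 1)
  for (m in lib@hits) {
    obmw <- local({
      cob <- getNamespace("ChemmineOB")
      out <- NA_real_
      PhoreScreen:::.obForEach("SMI", m@source, function(mol) {
        cob$OBMol_AddHydrogens(mol)
        out <<- cob$OBMol_GetMolWt(mol)
      })
      out
    })
    expect_equal(molecularWeight(m), obmw, tolerance = 0.05)
  }
})

test_that("weight filter partitions on the closed [lo, hi] interval", {
  bz <- parseSmiles("c1ccccc1", "benzene")
  r <- weightFilter(list(bz), 200, 600)
  expect_length(r$retained, 0)
  expect_length(r$excluded, 1)

  expect_equal(weightFilter(list(), 200, 600),
               list(retained = list(), excluded = list()))
  expect_error(weightFilter(list(bz), 600, 200), "lo")

  # partition property on a mixed bag
  set.seed(7)
  mols <- c(lapply(1:3, function(i) parseSmiles("CCO", paste0("s", i))),
            fixtureLibrary(4, 2)@decoys)
  for (b in list(c(0, 100), c(100, 300), c(200, 600))) {
    r <- weightFilter(mols, b[1], b[2])
    expect_equal(length(r$retained) + length(r$excluded), length(mols))
    expect_true(all(vapply(r$retained, molecularWeight, numeric(1)) >= b[1]))
    expect_true(all(vapply(r$retained, molecularWeight, numeric(1)) <= b[2]))
  }
})

test_that("all eight fixture hits pass the [200, 600] filter", {
  lib <- fixtureLibrary(0, 1)
  expect_length(lib@hits, 8)
  expect_setequal(tolower(vapply(lib@hits, molName, character(1))),
                  c("raloxifene", "sildenafil", "cefepime", "cefpirome",
                    "imatinib", "ponatinib", "abemaciclib", "entrectinib"))
  r <- weightFilter(lib@hits)
  expect_length(r$retained, 8)
})

test_that("fixture decoys are seed-deterministic and within the MW window", {
  a <- fixtureLibrary(5, 7)
  b <- fixtureLibrary(5, 7)
  expect_identical(vapply(a@decoys, molName, character(1)),
                   vapply(b@decoys, molName, character(1)))
  expect_length(a@decoys, 5)
  mw <- vapply(a@decoys, molecularWeight, numeric(1))
  expect_true(all(mw >= 200 & mw <= 600))
  # oversampling recycles the pool deterministically
  big <- fixtureLibrary(40, 3)
  expect_length(big@decoys, 40)
  expect_length(unique(vapply(big@decoys, molName, character(1))), 40)
})

test_that("SDF round trip preserves structure and is byte-stable", {
  dir <- withr::local_tempdir()
  lib <- fixtureLibrary(0, 1)
  mols <- lib@hits[1:3]
  p1 <- file.path(dir, "a.sdf")
  writeMolecules(mols, p1, "sdf")
  back <- readMolecules(p1, "sdf")
  expect_length(back, 3)
  expect_equal(vapply(back, molName, character(1)),
               vapply(mols, molName, character(1)))
  for (i in 1:3) {
    expect_equal(numAtoms(back[[i]]), numAtoms(mols[[i]]))
    expect_equal(nrow(bonds(back[[i]])), nrow(bonds(mols[[i]])))
    expect_equal(atoms(back[[i]])$charge, atoms(mols[[i]])$charge)
  }
  p2 <- file.path(dir, "b.sdf")
  writeMolecules(back, p2, "sdf")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("SMILES list round trip preserves names and composition", {
  dir <- withr::local_tempdir()
  mols <- list(parseSmiles("CCO", "ethanol"), parseSmiles("c1ccccc1", "benzene"))
  p <- file.path(dir, "m.smi")
  writeMolecules(mols, p, "smiles")
  back <- readMolecules(p, "smiles")
  expect_equal(vapply(back, molName, character(1)), c("ethanol", "benzene"))
  expect_equal(vapply(back, numAtoms, integer(1)),
               vapply(mols, numAtoms, integer(1)))
})

test_that("empty and corrupt SDF input behave per contract", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.sdf")
  writeLines(character(0), p)
  expect_length(readMolecules(p, "sdf"), 0)

  good <- PhoreScreen:::.mol2sdf(parseSmiles("CCO", "ethanol"))
  corrupt <- "broken\n\n\n  X bad counts line\nM  END\n$$$$\n"
  p2 <- file.path(dir, "mixed.sdf")
  cat(good, corrupt, good, sep = "", file = p2)
  expect_warning(got <- readMolecules(p2, "sdf", lenient = TRUE),
                 "record 2")
  expect_length(got, 2)
  expect_error(suppressWarnings(readMolecules(p2, "sdf", lenient = FALSE)))
})
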