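# Selectivity truth table and the end-to-end screening pipeline.

mockMatch <- function(matched, model = "bk_consensus") {
  if (matched)
    new("MatchResult", matched = TRUE, molecule = "m", model = model,
        bestConformer = 1L,
        best = new("Correspondence", mapping = c(P1 = 1L),
                   deviations = numeric(0), sumSq = 0, maxDev = 0),
        maxDeviation = 0, sumSqDeviation = 0, superpositionRMSD = 0)
  else
    new("MatchResult", matched = FALSE, molecule = "m", model = model,
        bestConformer = NA_integer_, best = NULL, maxDeviation = NA_real_,
        sumSqDeviation = NA_real_, superpositionRMSD = NA_real_)
}

test_that("selectivity labels follow the truth table", {
  y <- mockMatch(TRUE); n <- mockMatch(FALSE)
  expect_equal(classifySelectivity(n, NULL, NULL), "no_match")
  expect_equal(classifySelectivity(n, y, y), "no_match")
  expect_equal(classifySelectivity(y, NULL, NULL), "consensus_only")
  # fulfilling the four common points suffices for a non-selective call
  expect_equal(classifySelectivity(y, n, n), "non_selective_candidate")
  expect_equal(classifySelectivity(y, y, y), "non_selective_candidate")
  expect_equal(classifySelectivity(y, y, n), "b1_biased")
  expect_equal(classifySelectivity(y, n, y), "b2_biased")
})

test_that("screen configuration validates its invariants", {
  expect_error(screenConfig(mwLo = 600, mwHi = 200), "mwLo")
  expect_error(screenConfig(nConformers = 0), "nConformers")
  expect_error(screenConfig(models = c("bk_b1")), "consensus")
  expect_error(screenConfig(models = c("bk_consensus", "zzz")), "unknown")
})

test_that("the pipeline filters, labels and partitions every molecule", {
  libry <- list(parseSmiles("CCO", "ethanol"),          # MW 46, filtered out
                parseSmiles("c1cc2ccc3cccc4ccc(c1)c2c34", "pyrene"))
  cfg <- screenConfig(nConformers = 5L, seed = 4L,
                      models = c("bk_consensus", "bk_b1", "bk_b2"))
  rep <- runScreen(libry, cfg)
  r <- results(rep)
  expect_equal(nrow(r), 2L)
  expect_equal(r$label[r$name == "ethanol"], "filtered_out")
  expect_false(r$passed_filter[r$name == "ethanol"])
  expect_equal(r$n_conformers[r$name == "ethanol"], 0L)
  expect_equal(r$label[r$name == "pyrene"], "no_match")
  expect_true(r$passed_filter[r$name == "pyrene"])
  expect_gte(r$n_conformers[r$name == "pyrene"], 1L)
  # every molecule receives exactly one label
  expect_true(all(nchar(r$label) > 0))

  # empty library gives an empty report with metadata
  empty <- runScreen(list(), cfg)
  expect_equal(nrow(results(empty)), 0L)
  expect_equal(empty@metadata$seed, 4L)
})

test_that("running the stages manually reproduces the pipeline result", {
  mol <- parseSmiles("O=C(OCc1ccccc1)c1ccccc1", "benzyl benzoate")
  cfg <- screenConfig(nConformers = 8L, seed = 6L,
                      models = c("bk_consensus", "bk_b1", "bk_b2"))
  rep <- runScreen(list(mol), cfg)
  r <- results(rep)
  # manual pipeline: filter -> protonation -> conformers -> match -> label
  expect_true(molecularWeight(mol) >= 200 && molecularWeight(mol) <= 600)
  prot <- assignProtonation(mol)
  ens <- generateConformers(prot, n = 8L, seed = 6L)
  expect_equal(r$n_conformers, numConformers(ens))
  mrs <- lapply(c("bk_consensus", "bk_b1", "bk_b2"), function(nm)
    matchMolecule(ens, builtinModel(nm)))
  expect_equal(r$matched_consensus, isMatched(mrs[[1]]))
  expect_equal(r$label,
               classifySelectivity(mrs[[1]], mrs[[2]], mrs[[3]]))
})

test_that("reports are written deterministically (CSV bytes, timestamp isolated)", {
  dir <- withr::local_tempdir()
  libry <- list(parseSmiles("c1cc2ccc3cccc4ccc(c1)c2c34", "pyrene"))
  cfg <- screenConfig(nConformers = 3L, seed = 2L)
  r1 <- runScreen(libry, cfg)
  r2 <- runScreen(libry, cfg)
  writeScreenReport(r1, file.path(dir, "run1"))
  writeScreenReport(r2, file.path(dir, "run2"))
  expect_identical(readLines(file.path(dir, "run1.csv")),
                   readLines(file.path(dir, "run2.csv")))
  s1 <- readLines(file.path(dir, "run1_summary.txt"))
  expect_true(any(grepl("^timestamp:", s1)))
  expect_true(any(grepl("config hash", s1)))
  # the CSV itself carries no timestamp
  expect_false(any(grepl("timestamp", readLines(file.path(dir, "run1.csv")))))
})
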