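flatParams <- function(val = -0.9, init = 0, au = 0) {
  steps <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                           paste0))
  NNParameterTable(setNames(rep(val, 16), steps), initDG = init,
                   terminalAUPenalty = au)
}

test_that("stepProfile returns the 18 dinucleotide-step energies", {
  expect_length(stepProfile(randomCore(1), refParams), 18L)
  expect_equal(stepProfile(strrep("A", 19), flatParams(-0.9)), rep(-0.9, 18))
  # independent dictionary-lookup oracle
  core <- randomCore(2)
  oracle <- vapply(1:18, function(j)
    refParams@stepDG[[substr(core, j, j + 1)]], numeric(1))
  expect_equal(stepProfile(core, refParams), oracle)
  expect_error(stepProfile("ACGTACGTACGTACGTACG", refParams), NA) # T -> U
  expect_error(stepProfile(strrep("N", 19), refParams), "non-ACGU")
  expect_error(stepProfile(strrep("A", 21), refParams), "19-nt")
})

test_that("duplexStability is initiation + step sum + terminal penalties", {
  expect_equal(duplexStability(randomCore(3), flatParams(0, init = 4.1)), 4.1)
  expect_equal(duplexStability(strrep("A", 19), flatParams(-0.9)), -16.2)
  # independent one-pass summation oracle, including the A/U end rule
  for (s in 4:6) {
    core <- randomCore(s)
    ends <- c(substr(core, 1, 1), substr(core, 19, 19))
    oracle <- refParams@initDG +
      sum(vapply(1:18, function(j)
        refParams@stepDG[[substr(core, j, j + 1)]], numeric(1))) +
      refParams@terminalAUPenalty * sum(ends %in% c("A", "U"))
    expect_equal(duplexStability(core, refParams), oracle)
  }
})

test_that("endDifferential is the 5' minus 3' terminal step energy", {
  core <- randomCore(7)
  expect_equal(endDifferential(core, refParams, endWindow = 1),
               refParams@stepDG[[substr(core, 1, 2)]] -
                 refParams@stepDG[[substr(core, 18, 19)]])
  expect_error(endDifferential(core, refParams, endWindow = 0), "\\[1, 9\\]")
  expect_error(endDifferential(core, refParams, endWindow = 10), "\\[1, 9\\]")
})

test_that("endDifferential is antisymmetric under duplex reversal", {
  # reading the duplex from the complementary strand reverses the step
  # profile (the table is complement-symmetric), negating the differential
  for (s in 8:12) {
    core <- randomCore(s)
    flipped <- reverseComplementRNA(core)
    for (w in c(1L, 3L, 9L))
      expect_equal(endDifferential(flipped, refParams, w),
                   -endDifferential(core, refParams, w))
  }
})

test_that("featurizeThermo emits 20 ordered descriptors per record", {
  rec <- makeRecords(4, seed = 20)
  feats <- featurizeThermo(rec, refParams)
  expect_identical(dim(feats), c(4L, 20L))
  expect_identical(colnames(feats)[1:2], c("duplex_dg", "end_diff"))
  expect_length(grep("^step_", colnames(feats)), 18L)
  # compositional oracle: equals the three sub-operations run independently
  core <- substr(rec@guide[2], 1, 19)
  expect_equal(unname(feats[2, ]),
               c(duplexStability(core, refParams),
                 endDifferential(core, refParams),
                 stepProfile(core, refParams)))
  # function of the guide sequence only
  twin <- SiRNASet(c("a", "b"), rep(rec@guide[1], 2))
  tf <- featurizeThermo(twin, refParams)
  expect_equal(unname(tf[1, ]), unname(tf[2, ]))
})

test_that("step-sum conservation holds exactly for random records", {
  for (s in 30:34) {
    core <- randomCore(s)
    ends <- c(substr(core, 1, 1), substr(core, 19, 19))
    pen <- refParams@terminalAUPenalty * sum(ends %in% c("A", "U"))
    expect_equal(duplexStability(core, refParams) - refParams@initDG - pen,
                 sum(stepProfile(core, refParams)), tolerance = 1e-12)
  }
})

test_that("the bundled parameter table reads completely and is reusable", {
  expect_s4_class(refParams, "NNParameterTable")
  expect_length(refParams@stepDG, 16L)
  expect_true(all(is.finite(refParams@stepDG)))
  # a user-supplied table with the same schema round-trips
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("#init_dg=1.5", "#terminal_au=0.2", "step\tdg_kcal_mol",
               paste(names(refParams@stepDG), -1.0, sep = "\t")), tmp)
  p <- readNNParams(tmp)
  expect_equal(p@initDG, 1.5)
  expect_equal(p@terminalAUPenalty, 0.2)
  expect_equal(unname(p@stepDG), rep(-1, 16))
})
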