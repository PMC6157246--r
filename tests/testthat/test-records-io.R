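test_that("FASTA + TSV round-trip preserves sequences and efficacies exactly", {
  rec <- makeRecords(8, seed = 1)
  rec@efficacy[3] <- NA_real_        # prediction-only record
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeSiRNARecords(rec, fa, tsv)
  back <- readSiRNARecords(fa, tsv)
  expect_identical(recordIds(back), recordIds(rec))
  expect_identical(as.character(guideSeqs(back)), as.character(guideSeqs(rec)))
  expect_identical(as.character(contextSeqs(back)), as.character(contextSeqs(rec)))
  expect_identical(unname(bindingOffset(back)), unname(bindingOffset(rec)))
  expect_identical(unname(efficacy(back)), unname(efficacy(rec)))
})

test_that("T is accepted on input and stored as U", {
  s <- SiRNASet("r1", "ACGTACGTACGTACGTACGTA")
  expect_identical(s@guide, "ACGUACGUACGUACGUACGUA")
  expect_identical(normalizeRNA("acgt"), "ACGU")
})

test_that("record validation rejects bad guides, efficacies and offsets", {
  expect_error(SiRNASet("short", strrep("A", 19)), "length 19")
  expect_error(SiRNASet("bad", strrep("A", 21), efficacy = 1.2), "outside")
  expect_error(SiRNASet("sym", paste0(strrep("A", 20), "X")), "symbols")
  expect_error(SiRNASet("off", strrep("A", 21), context = strrep("A", 30),
                        bindingOffset = 15L), "not contained")
})

test_that("reader reports id mismatches and malformed efficacies", {
  rec <- makeRecords(3, seed = 2)
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeSiRNARecords(rec, fa, tsv)
  tab <- read.delim(tsv, colClasses = "character")
  tab$id[1] <- "other001"
  tsv2 <- tempfile(fileext = ".tsv")
  write.table(tab, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSiRNARecords(fa, tsv2), "do not match")
  tab <- read.delim(tsv, colClasses = "character")
  tab$efficacy[2] <- "high"
  tsv3 <- tempfile(fileext = ".tsv")
  write.table(tab, tsv3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSiRNARecords(fa, tsv3), "not numeric")
})

test_that("extractWindow returns centered 21+2n windows with absent marks", {
  # exact fit: context is precisely 21 + 2n long at offset n
  n <- 4L
  rec <- makeRecords(1, seed = 3, flankAvail = n)
  w <- unname(extractWindow(rec, n))
  expect_identical(nchar(w), 21L + 2L * n)
  expect_false(grepl("-", w, fixed = TRUE))
  expect_identical(w, rec@context)

  # degenerate: context is the 21-nt site only -> 2n absent marks
  bare <- SiRNASet("b1", rec@guide)
  wb <- unname(extractWindow(bare, n))
  expect_identical(nchar(wb), 21L + 2L * n)
  expect_identical(substr(wb, 1, n), strrep("-", n))
  expect_identical(substr(wb, n + 22L, 21L + 2L * n), strrep("-", n))
  expect_identical(substr(wb, n + 1L, n + 21L),
                   reverseComplementRNA(rec@guide))

  # the selected flank length n = 20 gives 61 positions
  rec20 <- makeRecords(2, seed = 4)
  expect_identical(unique(nchar(extractWindow(rec20, 20L))), 61L)
})

test_that("window length is 21+2n for every record and n in 10..30", {
  rec <- makeRecords(5, seed = 5)
  for (n in c(10L, 17L, 25L, 30L)) {
    w <- extractWindow(rec, n)
    expect_true(all(nchar(w) == 21L + 2L * n))
  }
})

test_that("splitRecords partitions deterministically with the stated sizes", {
  rec <- makeRecords(10, seed = 6)
  s1 <- splitRecords(rec, 0.1, seed = 99)
  s2 <- splitRecords(rec, 0.1, seed = 99)
  expect_identical(recordIds(s1$test), recordIds(s2$test))
  expect_length(s1$test, 1L)
  expect_length(s1$train, 9L)
  expect_length(intersect(recordIds(s1$train), recordIds(s1$test)), 0L)
  expect_setequal(c(recordIds(s1$train), recordIds(s1$test)), recordIds(rec))

  # different seeds give (in general) different test sets
  picks <- vapply(1:8, function(s)
    recordIds(splitRecords(rec, 0.3, seed = s)$test)[1], character(1))
  expect_gt(length(unique(picks)), 1L)

  expect_error(splitRecords(rec, 1.5, seed = 1), "in \\(0, 1\\)")
  expect_error(splitRecords(rec[1], 0.5, seed = 1), "at least 2")
})

test_that("a 10% split of 4067 records holds out 407", {
  set.seed(8)
  guides <- vapply(seq_len(4067), function(i)
    paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE), collapse = ""),
    character(1))
  big <- SiRNASet(sprintf("g%04d", seq_len(4067)), guides)
  sp <- splitRecords(big, 0.1, seed = 1)
  expect_length(sp$test, 407L)
  expect_length(sp$train, 3660L)
})
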