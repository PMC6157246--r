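#' Read siRNA records from FASTA + TSV
#'
#' The FASTA file holds the sequences: an entry named \code{<id>} is the
#' 21-nt guide strand, and an optional entry named \code{<id>|context} is the
#' sense-strand target context. Records without a context entry fall back to
#' the reverse complement of the guide (binding region only, offset 0).
#' The tab-delimited table carries per-record metadata with header columns
#' \code{id}, \code{efficacy} (empty or "." for missing) and
#' \code{binding_offset} (0-based), plus an optional \code{source} column.
#'
#' @param fastaPath path to the FASTA file.
#' @param tablePath path to the metadata TSV.
#' @return a validated \linkS4class{SiRNASet}.
#' @export
readSiRNARecords <- function(fastaPath, tablePath) {
  seqs <- Biostrings::readBStringSet(fastaPath)
  tab <- read.delim(tablePath, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  need <- c("id", "efficacy", "binding_offset")
  if (!all(need %in% names(tab)))
    .stopf("metadata table must have columns %s", paste(need, collapse = ", "))
  nm <- names(seqs)
  isCtx <- grepl("\\|context$", nm)
  guideIds <- nm[!isCtx]
  ctxIds <- sub("\\|context$", "", nm[isCtx])
  if (!setequal(guideIds, tab$id))
    .stopf("FASTA guide ids and table ids do not match (e.g. %s)",
           paste(utils::head(c(setdiff(guideIds, tab$id),
                               setdiff(tab$id, guideIds)), 3), collapse = ", "))
  if (length(setdiff(ctxIds, guideIds)))
    .stopf("context entries without a matching guide: %s",
           paste(utils::head(setdiff(ctxIds, guideIds), 3), collapse = ", "))
  guides <- normalizeRNA(as.character(seqs[!isCtx]))
  names(guides) <- guideIds
  ctxs <- normalizeRNA(as.character(seqs[isCtx]))
  names(ctxs) <- ctxIds
  ord <- tab$id
  effRaw <- trimws(tab$efficacy)
  eff <- suppressWarnings(as.numeric(ifelse(effRaw %in% c("", ".", "NA"),
                                            NA_character_, effRaw)))
  badEff <- which(!(effRaw %in% c("", ".", "NA")) & is.na(eff))
  if (length(badEff))
    .stopf("efficacy of record '%s' is not numeric: '%s'",
           ord[badEff[1]], effRaw[badEff[1]])
  off <- suppressWarnings(as.integer(tab$binding_offset))
  src <- if ("source" %in% names(tab)) {
    s <- trimws(tab$source); ifelse(s %in% c("", "."), NA_character_, s)
  } else rep(NA_character_, nrow(tab))
  hasCtx <- ord %in% ctxIds
  context <- ifelse(hasCtx, ctxs[ord], reverseComplementRNA(guides[ord]))
  offset <- ifelse(hasCtx, off, 0L)
  set <- new("SiRNASet", id = ord, guide = unname(guides[ord]),
             context = unname(context), bindingOffset = as.integer(offset),
             efficacy = eff, source = src)
  validObject(set)
  set
}

#' Write siRNA records to FASTA + TSV
#'
#' Inverse of \code{\link{readSiRNARecords}}: sequences and efficacies
#' round-trip exactly. Contexts are always written, including the degenerate
#' revcomp fallback, so re-reading reproduces the object.
#'
#' @param x a SiRNASet.
#' @param fastaPath,tablePath output paths.
#' @return invisibly, the input.
#' @export
writeSiRNARecords <- function(x, fastaPath, tablePath) {
  seqs <- c(stats::setNames(x@guide, x@id),
            stats::setNames(x@context, paste0(x@id, "|context")))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), fastaPath)
  eff <- ifelse(is.na(x@efficacy), ".",
                format(x@efficacy, digits = 17, trim = TRUE, scientific = FALSE))
  tab <- data.frame(id = x@id, efficacy = eff,
                    binding_offset = x@bindingOffset,
                    source = ifelse(is.na(x@source), ".", x@source),
                    stringsAsFactors = FALSE)
  write.table(tab, tablePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Extract the flanked target-site window
#'
#' Returns, for each record, the sense-strand window of n upstream
#' nucleotides, the 21-nt binding region, and n downstream nucleotides
#' (length 21 + 2n). Positions outside the available context are marked
#' with \code{"-"}; downstream encoding turns those rows into flat 0.05
#' rows.
#'
#' @param x a SiRNASet.
#' @param n flank length; the scanned range is 10..30 but any n >= 0 is
#'   accepted for constructing degenerate fixtures.
#' @return character vector of windows, length 21 + 2n each, named by id.
#' @export
extractWindow <- function(x, n) {
  n <- as.integer(n)
  if (n < 0L) .stopf("flank length n must be >= 0, got %d", n)
  L <- 21L + 2L * n
  ctxLen <- nchar(x@context)
  off <- x@bindingOffset
  if (any(off < 0L | off + 21L > ctxLen))
    .stopf("binding region not contained in context for record '%s'",
           x@id[which(off < 0L | off + 21L > ctxLen)[1]])
  start <- off - n + 1L           # 1-based start of the window on the context
  out <- character(length(x))
  for (i in seq_along(out)) {
    lo <- max(start[i], 1L)
    hi <- min(start[i] + L - 1L, ctxLen[i])
    core <- substr(x@context[i], lo, hi)
    out[i] <- paste0(strrep(ABSENT_MARK, lo - start[i]), core,
                     strrep(ABSENT_MARK, (start[i] + L - 1L) - hi))
  }
  stats::setNames(out, x@id)
}

#' Randomly partition records into training and test sets
#'
#' Deterministic given the seed; the two parts are disjoint by id and
#' jointly cover the input. The test set size is round(fraction * N).
#'
#' @param x a SiRNASet.
#' @param testFraction fraction of records held out, in (0, 1).
#' @param seed RNG seed.
#' @return list with elements \code{train}, \code{test} (SiRNASet) and
#'   \code{seed}.
#' @export
splitRecords <- function(x, testFraction, seed) {
  if (length(x) < 2L) .stopf("need at least 2 records to split")
  if (testFraction <= 0 || testFraction >= 1)
    .stopf("testFraction must be in (0, 1)")
  nTest <- round(testFraction * length(x))
  nTest <- max(1L, min(length(x) - 1L, as.integer(nTest)))
  idx <- withSeed(seed, sample.int(length(x), nTest))
  list(train = x[setdiff(seq_len(length(x)), idx)], test = x[sort(idx)],
       seed = as.integer(seed))
}
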