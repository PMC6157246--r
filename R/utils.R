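#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif var cor
#' @importFrom utils read.delim write.table packageVersion
NULL

# Sentinel used in extracted windows for positions outside the available
# mRNA context; such positions are one-hot encoded as a flat 0.05 row.
ABSENT_MARK <- "-"

# Fixed one-hot column order; persisted in serialized models.
BASE_ORDER <- c("A", "U", "G", "C")

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and rewrites T as U. DNA and RNA spellings of the same
#' sequence are therefore treated as one sequence throughout the package.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,U\} (other symbols are left for the
#'   validators to reject).
#' @export
normalizeRNA <- function(x) {
  chartr("Tt", "Uu", toupper(as.character(x)))
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences (A/C/G/U; T accepted).
#' @return character vector of reverse complements, 5'->3'.
#' @export
reverseComplementRNA <- function(x) {
  x <- normalizeRNA(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed (kept well inside 32-bit range).
deriveSeed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)
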