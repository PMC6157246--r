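#' One-hot encode a single nucleotide
#'
#' Column order is fixed as A, U/T, G, C: A -> (1,0,0,0), U/T -> (0,1,0,0),
#' G -> (0,0,1,0), C -> (0,0,0,1). The absent-position mark \code{"-"}
#' encodes to the flat row (0.05, 0.05, 0.05, 0.05).
#'
#' @param symbol a single character in \{A,C,G,U,T,-\} (case-insensitive).
#' @return numeric 4-vector named A,U,G,C.
#' @export
encodeBase <- function(symbol) {
  s <- normalizeRNA(symbol)
  if (length(s) != 1L || nchar(s) != 1L)
    .stopf("encodeBase expects a single symbol")
  if (s == ABSENT_MARK)
    return(stats::setNames(rep(0.05, 4), BASE_ORDER))
  i <- match(s, BASE_ORDER)
  if (is.na(i)) .stopf("unknown nucleotide symbol '%s'", symbol)
  v <- numeric(4)
  v[i] <- 1
  stats::setNames(v, BASE_ORDER)
}

#' One-hot encode a flanked window
#'
#' @param window character string of length 21 + 2n over \{A,C,G,U,T,-\},
#'   as produced by \code{\link{extractWindow}}.
#' @param n the flank length the window was extracted with.
#' @return an \linkS4class{EncodedSequence}: a (21 + 2n) x 4 matrix whose
#'   real rows are unit basis vectors and whose absent rows are all 0.05,
#'   plus the absent-position mask.
#' @export
encodeWindow <- function(window, n) {
  n <- as.integer(n)
  L <- 21L + 2L * n
  w <- normalizeRNA(window)
  if (nchar(w) != L)
    .stopf("window has length %d, expected 21 + 2n = %d", nchar(w), L)
  ch <- .splitChars(w)[[1]]
  idx <- match(ch, BASE_ORDER)
  absent <- ch == ABSENT_MARK
  bad <- which(is.na(idx) & !absent)
  if (length(bad))
    .stopf("unknown symbol '%s' at window position %d", ch[bad[1]], bad[1])
  mat <- matrix(0, L, 4, dimnames = list(NULL, BASE_ORDER))
  mat[cbind(which(!absent), idx[!absent])] <- 1
  mat[absent, ] <- 0.05
  new("EncodedSequence", mat = mat, flankN = n, absentMask = absent)
}

#' Decode an EncodedSequence back to its window string
#'
#' Inverse of \code{\link{encodeWindow}} (absent rows decode to \code{"-"}).
#'
#' @param enc an EncodedSequence.
#' @return character string of length 21 + 2n.
#' @export
decodeWindow <- function(enc) {
  ch <- ifelse(enc@absentMask, ABSENT_MARK,
               BASE_ORDER[max.col(enc@mat, ties.method = "first")])
  paste(ch, collapse = "")
}

# Encode many windows into an N x L x 4 array (internal fast path used by
# the network; row semantics identical to encodeWindow).
encodeWindowArray <- function(windows, n) {
  n <- as.integer(n)
  L <- 21L + 2L * n
  N <- length(windows)
  lens <- nchar(windows)
  if (any(lens != L))
    .stopf("window %d has length %d, expected %d", which(lens != L)[1],
           lens[which(lens != L)[1]], L)
  ch <- matrix(unlist(.splitChars(normalizeRNA(windows))), nrow = N, byrow = TRUE)
  idx <- match(ch, BASE_ORDER)          # N*L values, column-major over (i, l)
  absent <- ch == ABSENT_MARK
  bad <- which(is.na(idx) & !absent)
  if (length(bad))
    .stopf("unknown symbol '%s' in window %d", ch[bad[1]],
           (bad[1] - 1L) %% N + 1L)
  arr <- array(0, dim = c(N, L, 4))
  pos <- which(!absent)                 # linear indices into N x L
  arr[pos + (idx[pos] - 1L) * (N * L)] <- 1
  if (any(absent)) {
    posA <- which(absent)
    for (b in 1:4) arr[posA + (b - 1L) * (N * L)] <- 0.05
  }
  arr
}
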