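# Shared fixtures: everything is generated in code, nothing is stored.

refParams <- defaultNNParams()

# Deterministic random records with full flanks (flankAvail per side).
makeRecords <- function(n, seed = 42, flankAvail = 30L, efficacy = NULL) {
  set.seed(seed)
  ctxLen <- 21L + 2L * flankAvail
  ctx <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), ctxLen, replace = TRUE),
          collapse = ""), character(1))
  guide <- reverseComplementRNA(substr(ctx, flankAvail + 1L, flankAvail + 21L))
  if (is.null(efficacy)) efficacy <- round(runif(n), 3)
  SiRNASet(id = sprintf("rec%03d", seq_len(n)), guide = guide,
           context = ctx, bindingOffset = rep(flankAvail, n),
           efficacy = efficacy)
}

# A small configuration that trains in well under a second.
tinyConfig <- function(maxIterations = 5L, seed = 7L, ...) {
  modelConfig(kernelHeights = c(3L, 5L), kernelsPerHeight = 1L,
              flankN = 2L, dnnUnits = 3L, maxIterations = maxIterations,
              seed = seed, ...)
}

# Independent brute-force sliding-window convolution (the oracle for
# convolveSeq and for the batched GEMM path).
bruteConv <- function(S, kernel, scale = 1) {
  m <- nrow(kernel)
  out <- numeric(nrow(S) - m + 1L)
  for (p in seq_along(out)) {
    acc <- 0
    for (j in seq_len(m)) for (b in 1:4) acc <- acc + S[p + j - 1L, b] * kernel[j, b]
    out[p] <- acc * scale
  }
  out
}

# Independent pair-counting AUC oracle (ties count 1/2).
pairCountAUC <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Random 19-nt guide core.
randomCore <- function(seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), 19, replace = TRUE), collapse = "")
}
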