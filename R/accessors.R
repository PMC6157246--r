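#' Construct a SiRNASet
#'
#' @param id character identifiers (unique).
#' @param guide 21-nt guide (antisense) strands, 5'->3'; T is normalized to U.
#' @param context sense-strand target context, 5'->3'. When NULL, the context
#'   defaults to the reverse complement of the guide (binding region only,
#'   offset 0), which serves records that come without mRNA context.
#' @param bindingOffset 0-based start of the 21-nt binding region within
#'   \code{context}.
#' @param efficacy observed efficacy in [0,1]; NA for prediction-only records.
#' @param source optional dataset-of-origin tag.
#' @return a validated \linkS4class{SiRNASet}.
#' @examples
#' s <- SiRNASet("r1", paste(rep("ACGU", 6), collapse = ""))
#' # a 24-nt string would fail validation; 21-mers are required
#' @export
SiRNASet <- function(id, guide, context = NULL, bindingOffset = NULL,
                     efficacy = NA_real_, source = NA_character_) {
  id <- as.character(id)
  guide <- normalizeRNA(guide)
  bad <- which(!grepl("^[ACGU]*$", guide))
  if (length(bad))
    .stopf("guide of record '%s' contains symbols outside A,C,G,U/T",
           id[bad[1]])
  if (is.null(context)) {
    context <- reverseComplementRNA(guide)
    bindingOffset <- rep(0L, length(id))
  }
  context <- normalizeRNA(context)
  if (is.null(bindingOffset))
    .stopf("bindingOffset is required when a context is supplied")
  n <- length(id)
  new("SiRNASet",
      id = id,
      guide = rep_len(guide, n),
      context = rep_len(context, n),
      bindingOffset = rep_len(as.integer(bindingOffset), n),
      efficacy = rep_len(as.numeric(efficacy), n),
      source = rep_len(as.character(source), n))
}

#' @describeIn SiRNASet number of records
#' @param x a SiRNASet.
#' @export
setMethod("length", "SiRNASet", function(x) length(x@id))

#' @describeIn SiRNASet subset records by index, logical mask or id
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "SiRNASet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@id)
  new("SiRNASet", id = x@id[i], guide = x@guide[i], context = x@context[i],
      bindingOffset = x@bindingOffset[i], efficacy = x@efficacy[i],
      source = x@source[i])
})

setMethod("show", "SiRNASet", function(object) {
  n <- length(object)
  lab <- sum(!is.na(object@efficacy))
  cat(sprintf("SiRNASet with %d record%s (%d with observed efficacy)\n",
              n, if (n == 1) "" else "s", lab))
  if (n > 0) {
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat(sprintf("  %s: %s  efficacy=%s\n", object@id[i], object@guide[i],
                  format(object@efficacy[i], digits = 3)))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

#' Record identifiers
#' @param x a SiRNASet.
#' @return character vector of ids.
#' @export
recordIds <- function(x) x@id

#' Guide (antisense) strands as an RNAStringSet
#' @param x a SiRNASet.
#' @return \link[Biostrings]{RNAStringSet} named by record id.
#' @export
guideSeqs <- function(x) {
  s <- Biostrings::RNAStringSet(x@guide)
  names(s) <- x@id
  s
}

#' Sense-strand target contexts as an RNAStringSet
#' @param x a SiRNASet.
#' @return \link[Biostrings]{RNAStringSet} named by record id.
#' @export
contextSeqs <- function(x) {
  s <- Biostrings::RNAStringSet(x@context)
  names(s) <- x@id
  s
}

#' 0-based binding-region offsets
#' @param x a SiRNASet.
#' @export
bindingOffset <- function(x) stats::setNames(x@bindingOffset, x@id)

#' Observed efficacies
#' @param x a SiRNASet.
#' @return numeric vector in [0,1], NA where unobserved.
#' @export
efficacy <- function(x) stats::setNames(x@efficacy, x@id)

#' Dataset-of-origin tags
#' @param x a SiRNASet.
#' @export
sourceTag <- function(x) stats::setNames(x@source, x@id)

#' Construct a nearest-neighbor parameter table
#'
#' @param stepDG named numeric of length 16 (names AA, AC, ..., UU; T in
#'   names is normalized to U) giving the free-energy contribution of each
#'   dinucleotide step, kcal/mol.
#' @param initDG duplex initiation free energy, kcal/mol.
#' @param terminalAUPenalty penalty per terminal A-U pair, kcal/mol.
#' @return a validated \linkS4class{NNParameterTable}.
#' @export
NNParameterTable <- function(stepDG, initDG = 0, terminalAUPenalty = 0) {
  names(stepDG) <- normalizeRNA(names(stepDG))
  new("NNParameterTable", stepDG = stepDG, initDG = as.numeric(initDG),
      terminalAUPenalty = as.numeric(terminalAUPenalty))
}

setMethod("show", "NNParameterTable", function(object) {
  cat("NNParameterTable (kcal/mol)\n")
  cat(sprintf("  initiation: %+.2f   terminal A-U penalty: %+.2f\n",
              object@initDG, object@terminalAUPenalty))
  cat(sprintf("  16 step parameters, range [%.2f, %.2f]\n",
              min(object@stepDG), max(object@stepDG)))
})

#' Construct a model configuration
#'
#' Defaults are the reference architecture: one kernel per height 6..20
#' (15 kernels), flank length n = 20, ReLU convolution activation, sigmoid
#' dense activation, 25 dense units, learning rate 0.1, and the stop rule
#' "more than 1000 iterations or training MSE below 0.001".
#'
#' @param kernelHeights integer kernel heights m, each in [2, 20].
#' @param kernelsPerHeight kernels instantiated per height.
#' @param flankN flank length n (window rows L = 21 + 2n).
#' @param dnnUnits dense-layer width.
#' @param convActivation "relu" or "sigmoid".
#' @param dnnActivation "relu" or "sigmoid".
#' @param learningRate gradient step size.
#' @param maxIterations iteration cap.
#' @param errorTolerance training-MSE stopping tolerance.
#' @param seed RNG seed for weight initialization.
#' @return a validated \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(kernelHeights = 6:20, kernelsPerHeight = 1L,
                        flankN = 20L, dnnUnits = 25L,
                        convActivation = "relu", dnnActivation = "sigmoid",
                        learningRate = 0.1, maxIterations = 1000L,
                        errorTolerance = 0.001, seed = 1L) {
  new("ModelConfig",
      kernelHeights = as.integer(kernelHeights),
      kernelsPerHeight = as.integer(kernelsPerHeight),
      flankN = as.integer(flankN),
      dnnUnits = as.integer(dnnUnits),
      convActivation = convActivation,
      dnnActivation = dnnActivation,
      learningRate = as.numeric(learningRate),
      maxIterations = as.integer(maxIterations),
      errorTolerance = as.numeric(errorTolerance),
      seed = as.integer(seed))
}

# Expanded kernel height list: each height repeated kernelsPerHeight times.
kernelHeightVector <- function(config) {
  rep(config@kernelHeights, each = config@kernelsPerHeight)
}

#' Number of kernels implied by a configuration
#' @param config a ModelConfig.
#' @export
nKernels <- function(config) length(kernelHeightVector(config))

setMethod("show", "ModelConfig", function(object) {
  hv <- kernelHeightVector(object)
  cat("ModelConfig\n")
  cat(sprintf("  kernels: %d (heights %s, %d per height)\n", length(hv),
              paste(range(object@kernelHeights), collapse = ".."),
              object@kernelsPerHeight))
  cat(sprintf("  flank n: %d (input rows L = %d)\n", object@flankN,
              21L + 2L * object@flankN))
  cat(sprintf("  activations: conv %s, dense %s (%d units)\n",
              object@convActivation, object@dnnActivation, object@dnnUnits))
  cat(sprintf("  lr %g, stop: iter > %d or MSE < %g, seed %d\n",
              object@learningRate, object@maxIterations,
              object@errorTolerance, object@seed))
})

setMethod("show", "TrainedModel", function(object) {
  d <- length(object@kernels)
  cat(sprintf("TrainedModel: %d kernels -> %d pooled + 20 thermo = %d merged features\n",
              d, 2L * d, 2L * d + 20L))
  cat(sprintf("  dense layer: %d units (%s); trained %d iterations, final MSE %.4g\n",
              length(object@outW), object@config@dnnActivation,
              length(object@trainingLog),
              if (length(object@trainingLog)) utils::tail(object@trainingLog, 1) else NA))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (n = %d): PCC %.4f, AUC %.4f (efficacy cutoff %.2f)\n",
              object@n, object@pcc, object@auc, object@threshold))
})
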