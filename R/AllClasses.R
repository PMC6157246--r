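#' SiRNASet: a collection of siRNA records
#'
#' Container for siRNA records: a 21-nt guide (antisense) strand written
#' 5'->3', the mRNA (sense) target-site context written 5'->3', the 0-based
#' half-open offset of the 21-nt binding region on that context, and an
#' observed silencing efficacy in [0,1] (NA for prediction-only records).
#' Guides are stored with T normalized to U.
#'
#' @slot id character, unique record identifiers.
#' @slot guide character, 21-nt guide strands over \{A,C,G,U\}.
#' @slot context character, sense-strand context containing the binding site.
#' @slot bindingOffset integer, 0-based start of the binding region in
#'   \code{context}.
#' @slot efficacy numeric in [0,1] or NA.
#' @slot source character, dataset-of-origin tag (NA when unknown).
#' @export
setClass("SiRNASet", representation(
  id = "character",
  guide = "character",
  context = "character",
  bindingOffset = "integer",
  efficacy = "numeric",
  source = "character"
))

setValidity("SiRNASet", function(object) {
  n <- length(object@id)
  msgs <- character(0)
  if (length(object@guide) != n || length(object@context) != n ||
      length(object@bindingOffset) != n || length(object@efficacy) != n ||
      length(object@source) != n)
    return("all slots must have the same length")
  if (anyDuplicated(object@id))
    msgs <- c(msgs, "record ids must be unique")
  bad <- which(nchar(object@guide) != 21L)
  if (length(bad))
    msgs <- c(msgs, sprintf("guide of record '%s' has length %d, expected 21",
                            object@id[bad[1]], nchar(object@guide[bad[1]])))
  alpha <- !grepl("^[ACGU]*$", object@guide)
  if (any(alpha))
    msgs <- c(msgs, sprintf("guide of record '%s' contains symbols outside A,C,G,U/T",
                            object@id[which(alpha)[1]]))
  eff <- object@efficacy
  bad <- which(!is.na(eff) & (eff < 0 | eff > 1))
  if (length(bad))
    msgs <- c(msgs, sprintf("efficacy %g of record '%s' is outside [0,1]",
                            eff[bad[1]], object@id[bad[1]]))
  off <- object@bindingOffset
  bad <- which(is.na(off) | off < 0L | off + 21L > nchar(object@context))
  if (length(bad))
    msgs <- c(msgs, sprintf(
      "binding region of record '%s' (offset %s) is not contained in its context (length %d)",
      object@id[bad[1]], off[bad[1]], nchar(object@context[bad[1]])))
  if (length(msgs)) msgs else TRUE
})

#' NNParameterTable: nearest-neighbor free-energy parameters
#'
#' Additive nearest-neighbor model of RNA duplex stability: each of the 16
#' dinucleotide steps (read 5'->3' on one strand of a Watson-Crick duplex)
#' contributes a free energy, plus a duplex initiation term and an optional
#' penalty per terminal A-U pair. All values in kcal/mol.
#'
#' @slot stepDG named numeric of length 16, names AA..UU.
#' @slot initDG numeric(1), duplex initiation free energy.
#' @slot terminalAUPenalty numeric(1), per-end A/U terminal penalty
#'   (0 disables it).
#' @export
setClass("NNParameterTable", representation(
  stepDG = "numeric",
  initDG = "numeric",
  terminalAUPenalty = "numeric"
))

setValidity("NNParameterTable", function(object) {
  steps <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  if (!all(steps %in% names(object@stepDG)))
    return(sprintf("stepDG is missing steps: %s",
                   paste(setdiff(steps, names(object@stepDG)), collapse = ", ")))
  if (!all(is.finite(object@stepDG)))
    return("stepDG values must be finite")
  if (length(object@initDG) != 1L || !is.finite(object@initDG))
    return("initDG must be a single finite value")
  if (length(object@terminalAUPenalty) != 1L || !is.finite(object@terminalAUPenalty))
    return("terminalAUPenalty must be a single finite value")
  TRUE
})

#' ModelConfig: architecture and training hyperparameters
#'
#' @slot kernelHeights integer, distinct convolution kernel heights m,
#'   each in [2, 20].
#' @slot kernelsPerHeight integer(1), kernels instantiated per height.
#' @slot flankN integer(1), flanking nucleotides n on each side of the
#'   21-nt binding region (input rows L = 21 + 2n).
#' @slot dnnUnits integer(1), width of the dense (DNN) layer.
#' @slot convActivation "relu" or "sigmoid", convolution-layer activation.
#' @slot dnnActivation "relu" or "sigmoid", dense-layer activation.
#' @slot learningRate numeric(1), gradient-descent step size.
#' @slot maxIterations integer(1), iteration cap of the stop rule.
#' @slot errorTolerance numeric(1), training MSE below which training stops.
#' @slot seed integer(1), RNG seed for initialization.
#' @export
setClass("ModelConfig", representation(
  kernelHeights = "integer",
  kernelsPerHeight = "integer",
  flankN = "integer",
  dnnUnits = "integer",
  convActivation = "character",
  dnnActivation = "character",
  learningRate = "numeric",
  maxIterations = "integer",
  errorTolerance = "numeric",
  seed = "integer"
))

setValidity("ModelConfig", function(object) {
  if (length(object@kernelHeights) < 1L)
    return("at least one kernel height is required")
  if (any(object@kernelHeights < 2L | object@kernelHeights > 20L))
    return("kernel heights must satisfy 2 <= m <= 20")
  if (object@kernelsPerHeight < 1L)
    return("kernelsPerHeight must be >= 1")
  if (object@flankN < 0L)
    return("flankN must be >= 0")
  if (!object@convActivation %in% c("relu", "sigmoid"))
    return("convActivation must be 'relu' or 'sigmoid'")
  if (!object@dnnActivation %in% c("relu", "sigmoid"))
    return("dnnActivation must be 'relu' or 'sigmoid'")
  if (object@learningRate <= 0)
    return("learningRate must be > 0")
  if (object@dnnUnits < 1L)
    return("dnnUnits must be >= 1")
  if (object@maxIterations < 1L)
    return("maxIterations must be >= 1")
  TRUE
})

#' TrainedModel: learned weights of the two-modality architecture
#'
#' @slot config the \linkS4class{ModelConfig} used for training.
#' @slot kernels list of m x 4 kernel weight matrices (columns A,U,G,C).
#' @slot kernelScale numeric, learnable per-kernel scale delta_k.
#' @slot bnGamma,bnBeta numeric, batch-norm scale/shift over the merged
#'   (2d + 20)-vector.
#' @slot bnMean,bnVar numeric, feature statistics frozen at end of training.
#' @slot dnnW numeric matrix, merged-vector -> dense-layer weights.
#' @slot dnnB numeric, dense-layer biases.
#' @slot outW numeric, dense layer -> output weights (no output bias; the
#'   output is sigmoid of the weighted sum).
#' @slot trainingLog numeric, per-iteration training MSE.
#' @slot baseOrder character(4), one-hot column order metadata.
#' @export
setClass("TrainedModel", representation(
  config = "ModelConfig",
  kernels = "list",
  kernelScale = "numeric",
  bnGamma = "numeric",
  bnBeta = "numeric",
  bnMean = "numeric",
  bnVar = "numeric",
  dnnW = "matrix",
  dnnB = "numeric",
  outW = "numeric",
  trainingLog = "numeric",
  baseOrder = "character"
))

setValidity("TrainedModel", function(object) {
  d <- length(object@kernels)
  f <- 2L * d + 20L
  if (length(object@kernelScale) != d)
    return("one scale per kernel is required")
  if (length(object@bnGamma) != f || length(object@bnBeta) != f ||
      length(object@bnMean) != f || length(object@bnVar) != f)
    return(sprintf("batch-norm parameter length must be 2d + 20 = %d", f))
  if (nrow(object@dnnW) != f)
    return("dnnW must map the merged (2d + 20)-vector")
  if (ncol(object@dnnW) != length(object@dnnB) ||
      ncol(object@dnnW) != length(object@outW))
    return("dense-layer dimensions are inconsistent")
  TRUE
})

#' EvalReport: regression and ranking metrics for one evaluation
#'
#' @slot pcc numeric(1), Pearson correlation between observed and predicted
#'   efficacies.
#' @slot auc numeric(1), area under the ROC curve after binarizing observed
#'   efficacy at \code{threshold}.
#' @slot rocPoints data.frame with columns fpr (1 - specificity) and tpr
#'   (sensitivity), monotone nondecreasing.
#' @slot threshold numeric(1), efficacy cutoff used for binarization.
#' @slot n integer(1), number of evaluated pairs.
#' @export
setClass("EvalReport", representation(
  pcc = "numeric",
  auc = "numeric",
  rocPoints = "data.frame",
  threshold = "numeric",
  n = "integer"
))

#' EncodedSequence: one-hot matrix of a flanked window
#'
#' @slot mat numeric (21 + 2n) x 4 matrix; rows of real positions are unit
#'   basis vectors in column order A,U,G,C; rows of absent positions are
#'   (0.05, 0.05, 0.05, 0.05).
#' @slot flankN integer(1), the flank length n.
#' @slot absentMask logical of length 21 + 2n, TRUE where the flank position
#'   lies outside the available context.
#' @export
setClass("EncodedSequence", representation(
  mat = "matrix",
  flankN = "integer",
  absentMask = "logical"
))

setValidity("EncodedSequence", function(object) {
  L <- 21L + 2L * object@flankN
  if (nrow(object@mat) != L || ncol(object@mat) != 4L)
    return(sprintf("matrix must be (21 + 2n) x 4 = %d x 4", L))
  if (length(object@absentMask) != L)
    return("absentMask length must equal the number of rows")
  TRUE
})
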