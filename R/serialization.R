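MODEL_SCHEMA_VERSION <- "1.0"

configToList <- function(config) {
  list(kernelHeights = config@kernelHeights,
       kernelsPerHeight = config@kernelsPerHeight,
       flankN = config@flankN,
       dnnUnits = config@dnnUnits,
       convActivation = config@convActivation,
       dnnActivation = config@dnnActivation,
       learningRate = config@learningRate,
       maxIterations = config@maxIterations,
       errorTolerance = config@errorTolerance,
       seed = config@seed)
}

configFromList <- function(x) {
  modelConfig(kernelHeights = x$kernelHeights,
              kernelsPerHeight = x$kernelsPerHeight,
              flankN = x$flankN,
              dnnUnits = x$dnnUnits,
              convActivation = x$convActivation,
              dnnActivation = x$dnnActivation,
              learningRate = x$learningRate,
              maxIterations = x$maxIterations,
              errorTolerance = x$errorTolerance,
              seed = x$seed)
}

#' Serialize a trained model to JSON
#'
#' Writes a single versioned JSON archive holding the configuration, the
#' one-hot column-order metadata, and every weight array at full floating
#' point precision, so identical models serialize to identical files.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    schema = MODEL_SCHEMA_VERSION,
    package = "sirnadeep",
    baseOrder = model@baseOrder,
    config = configToList(model@config),
    kernels = lapply(model@kernels, function(k) unname(as.matrix(k))),
    kernelScale = model@kernelScale,
    bnGamma = model@bnGamma, bnBeta = model@bnBeta,
    bnMean = model@bnMean, bnVar = model@bnVar,
    dnnW = unname(model@dnnW), dnnB = model@dnnB, outW = model@outW,
    trainingLog = model@trainingLog)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path path to a JSON archive written by \code{\link{writeModel}}.
#' @return a \linkS4class{TrainedModel}.
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, MODEL_SCHEMA_VERSION))
    .stopf("unsupported model schema '%s' (expected %s)",
           obj$schema, MODEL_SCHEMA_VERSION)
  kernels <- lapply(obj$kernels, function(k) {
    k <- as.matrix(k)
    colnames(k) <- obj$baseOrder
    k
  })
  new("TrainedModel",
      config = configFromList(obj$config),
      kernels = kernels,
      kernelScale = as.numeric(obj$kernelScale),
      bnGamma = as.numeric(obj$bnGamma), bnBeta = as.numeric(obj$bnBeta),
      bnMean = as.numeric(obj$bnMean), bnVar = as.numeric(obj$bnVar),
      dnnW = as.matrix(obj$dnnW), dnnB = as.numeric(obj$dnnB),
      outW = as.numeric(obj$outW),
      trainingLog = as.numeric(obj$trainingLog),
      baseOrder = as.character(obj$baseOrder))
}

# EvalReport <-> JSON (used by the CLI).
reportToList <- function(report) {
  list(pcc = report@pcc, auc = report@auc, threshold = report@threshold,
       n = report@n, rocPoints = report@rocPoints)
}

writeEvalReport <- function(report, path) {
  jsonlite::write_json(reportToList(report), path, auto_unbox = TRUE,
                       digits = NA, always_decimal = TRUE)
  invisible(path)
}
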