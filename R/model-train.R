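#' Train the two-modality efficacy model
#'
#' Full-batch gradient descent on the mean-squared error between predicted
#' and observed efficacies, with back-propagation through the sigmoid
#' output, the dense layer, batch normalization of the merged
#' (2d + 20)-vector, max/average pooling, the convolution activation and
#' the kernel weights (including the per-kernel scale delta_k). Training
#' stops when the iteration count exceeds \code{maxIterations} or the
#' training MSE falls below \code{errorTolerance}. Batch-norm statistics
#' are frozen over the full training set at the end of training and used
#' for inference. Deterministic given the config seed.
#'
#' @param records a \linkS4class{SiRNASet}; records with NA efficacy are
#'   dropped with a message.
#' @param config a \linkS4class{ModelConfig}.
#' @param params an \linkS4class{NNParameterTable}.
#' @param verbose print the loss every 100 iterations.
#' @return a \linkS4class{TrainedModel}.
#' @export
trainModel <- function(records, config = modelConfig(),
                       params = defaultNNParams(), verbose = FALSE) {
  validObject(config)
  labeled <- which(!is.na(efficacy(records)))
  if (length(labeled) < length(records))
    message(sprintf("dropping %d record(s) without observed efficacy",
                    length(records) - length(labeled)))
  if (length(labeled) < 2L)
    .stopf("training requires at least 2 records with observed efficacy")
  records <- records[labeled]
  data <- buildNetData(records, config, params)
  hv <- data$heights
  state <- initNetState(config)
  wmask <- kernelWeightMask(hv, data$maxm)
  lr <- config@learningRate
  log <- numeric(0)
  for (iter in seq_len(config@maxIterations)) {
    fw <- netForward(state, data, config, stats = NULL)
    loss <- mean((fw$pred - data$y)^2)
    if (!is.finite(loss))
      .stopf("training loss became non-finite at iteration %d", iter)
    log[iter] <- loss
    if (verbose && iter %% 100L == 0L)
      message(sprintf("iter %d: MSE %.6f", iter, loss))
    if (loss < config@errorTolerance) break
    gr <- netBackward(state, data, config, fw, wmask)
    state$W <- state$W - lr * gr$W
    state$delta <- state$delta - lr * gr$delta
    state$gamma <- state$gamma - lr * gr$gamma
    state$beta <- state$beta - lr * gr$beta
    state$W1 <- state$W1 - lr * gr$W1
    state$b1 <- state$b1 - lr * gr$b1
    state$w2 <- state$w2 - lr * gr$w2
  }
  # freeze inference statistics over the full training set
  fw <- netForward(state, data, config, stats = NULL)
  mu <- unname(colMeans(fw$H0))
  v <- pmax(unname(colMeans(fw$H0 * fw$H0)) - mu * mu, 0)
  kernels <- lapply(seq_along(hv), function(k) {
    K <- matrix(state$W[seq_len(4L * hv[k]), k], nrow = hv[k], ncol = 4,
                byrow = TRUE, dimnames = list(NULL, BASE_ORDER))
    K
  })
  new("TrainedModel", config = config, kernels = kernels,
      kernelScale = state$delta, bnGamma = state$gamma, bnBeta = state$beta,
      bnMean = mu, bnVar = v, dnnW = state$W1, dnnB = state$b1,
      outW = state$w2, trainingLog = log, baseOrder = BASE_ORDER)
}

# Rebuild the flat network state from a TrainedModel.
modelToState <- function(model) {
  hv <- vapply(model@kernels, nrow, integer(1))
  maxm <- max(hv)
  d <- length(hv)
  W <- matrix(0, 4L * maxm, d)
  for (k in seq_len(d))
    W[seq_len(4L * hv[k]), k] <- as.vector(t(model@kernels[[k]]))
  list(W = W, delta = model@kernelScale, gamma = model@bnGamma,
       beta = model@bnBeta, W1 = model@dnnW, b1 = model@dnnB,
       w2 = model@outW)
}

#' Predict silencing efficacy for siRNA records
#'
#' Runs the forward pass — one-hot encoding of the flanked window,
#' convolutional motif detectors, activation, global max/average pooling,
#' merge with the 20 thermodynamic descriptors, batch normalization with
#' the frozen training statistics, dense layer, sigmoid output — so every
#' prediction lies strictly in (0, 1).
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param records a \linkS4class{SiRNASet}.
#' @param params an \linkS4class{NNParameterTable}.
#' @return named numeric vector of predicted efficacies in (0, 1).
#' @export
predictEfficacy <- function(model, records, params = defaultNNParams()) {
  data <- buildNetData(records, model@config, params)
  hv <- kernelHeightVector(model@config)
  if (!identical(hv, vapply(model@kernels, nrow, integer(1))))
    .stopf("model kernels do not match the model's configuration")
  state <- modelToState(model)
  fw <- netForward(state, data, model@config,
                   stats = list(mean = model@bnMean, var = model@bnVar))
  stats::setNames(fw$pred, recordIds(records))
}

#' Select the kernel-height set by cross-validated correlation
#'
#' For every candidate height m, trains one single-height network with
#' 22 - m kernels of that height, cross-validates it, and keeps the heights
#' whose CV Pearson correlation exceeds the threshold (default 0.6).
#'
#' @param records labeled \linkS4class{SiRNASet}.
#' @param candidateHeights integer heights, each in [2, 20].
#' @param params an \linkS4class{NNParameterTable}.
#' @param threshold PCC cutoff for admission to the kernel set.
#' @param baseConfig template \linkS4class{ModelConfig} supplying flank
#'   length, activations, learning rate and stop rule.
#' @param cvFolds number of cross-validation folds.
#' @param seed RNG seed for fold assignment and initialization.
#' @return integer vector of selected heights, with attribute \code{scan}
#'   (a data.frame of per-height m, pcc, auc) and attribute
#'   \code{nNetworks} (number of networks trained).
#' @export
selectKernelSet <- function(records, candidateHeights = 2:20,
                            params = defaultNNParams(), threshold = 0.6,
                            baseConfig = modelConfig(), cvFolds = 10L,
                            seed = baseConfig@seed) {
  candidateHeights <- as.integer(candidateHeights)
  if (length(candidateHeights) == 0L)
    .stopf("candidateHeights must not be empty")
  if (any(candidateHeights < 2L | candidateHeights > 20L))
    .stopf("candidate heights must lie in [2, 20]")
  rows <- lapply(candidateHeights, function(m) {
    cfg <- baseConfig
    cfg@kernelHeights <- m
    cfg@kernelsPerHeight <- 22L - m
    cfg@seed <- deriveSeed(seed, m)
    cv <- crossValidate(records, cfg, params, k = cvFolds,
                        seed = deriveSeed(seed, m))
    pcc <- if (is.na(cv$meanPCC)) cv$pooled@pcc else cv$meanPCC
    data.frame(m = m, pcc = pcc, auc = cv$meanAUC)
  })
  scan <- do.call(rbind, rows)
  score <- ifelse(is.na(scan$pcc), -Inf, scan$pcc)
  out <- candidateHeights[score > threshold]
  attr(out, "scan") <- scan
  attr(out, "nNetworks") <- nrow(scan)
  out
}

# Maximum relative disagreement between analytic gradients and central
# finite differences of the training-mode loss, on whatever model/data is
# supplied (intended for tiny configurations).
gradientCheck <- function(records, config, params, eps = 1e-5) {
  data <- buildNetData(records, config, params)
  state <- initNetState(config)
  wmask <- kernelWeightMask(data$heights, data$maxm)
  fw <- netForward(state, data, config, stats = NULL)
  gr <- netBackward(state, data, config, fw, wmask)
  worst <- 0
  for (nm in names(state)) {
    p <- state[[nm]]
    for (j in seq_along(p)) {
      if (nm == "W" && !wmask[j]) next
      sp <- state; sm <- state
      sp[[nm]][j] <- p[j] + eps
      sm[[nm]][j] <- p[j] - eps
      num <- (netLoss(sp, data, config) - netLoss(sm, data, config)) / (2 * eps)
      ana <- gr[[nm]][j]
      rel <- abs(ana - num) / max(1e-6, abs(ana) + abs(num))
      worst <- max(worst, rel)
    }
  }
  worst
}
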