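#' Scan the flank length n
#'
#' Cross-validates the model at each flank length and tabulates the mean
#' CV Pearson correlation and AUC. Each row is independently reproducible
#' from (config, seed).
#'
#' @param records labeled \linkS4class{SiRNASet}.
#' @param config template \linkS4class{ModelConfig}; its flankN is
#'   overridden per row.
#' @param params an \linkS4class{NNParameterTable}.
#' @param nValues flank lengths to scan (the canonical scan is 10..30).
#' @param k CV folds.
#' @param seed RNG seed.
#' @param aucThreshold efficacy cutoff for AUC.
#' @return data.frame with columns n, pcc, auc.
#' @export
scanFlankLength <- function(records, config = modelConfig(),
                            params = defaultNNParams(), nValues = 10:30,
                            k = 10L, seed = config@seed,
                            aucThreshold = 0.7) {
  nValues <- as.integer(nValues)
  if (length(nValues) == 0L) .stopf("nValues must not be empty")
  do.call(rbind, lapply(nValues, function(n) {
    cfg <- config
    cfg@flankN <- n
    cfg@seed <- deriveSeed(seed, n)
    cv <- crossValidate(records, cfg, params, k = k,
                        seed = deriveSeed(seed, n),
                        aucThreshold = aucThreshold)
    data.frame(n = n, pcc = cv$meanPCC, auc = cv$meanAUC)
  }))
}

#' Scan the convolution kernel height m
#'
#' One single-height network per candidate m, with 22 - m kernels of that
#' height (taller kernels detect longer motifs but get fewer detectors),
#' cross-validated. Scanning the full 2..20 range instantiates 19
#' networks.
#'
#' @inheritParams scanFlankLength
#' @param mValues kernel heights to scan, each in [2, 20].
#' @return data.frame with columns m, pcc, auc.
#' @export
scanKernelHeight <- function(records, config = modelConfig(),
                             params = defaultNNParams(), mValues = 2:20,
                             k = 10L, seed = config@seed,
                             aucThreshold = 0.7) {
  mValues <- as.integer(mValues)
  if (length(mValues) == 0L) .stopf("mValues must not be empty")
  if (any(mValues < 2L | mValues > 20L))
    .stopf("kernel heights must lie in [2, 20]; got %s",
           paste(mValues[mValues < 2L | mValues > 20L], collapse = ", "))
  do.call(rbind, lapply(mValues, function(m) {
    cfg <- config
    cfg@kernelHeights <- m
    cfg@kernelsPerHeight <- 22L - m
    cfg@seed <- deriveSeed(seed, m)
    cv <- crossValidate(records, cfg, params, k = k,
                        seed = deriveSeed(seed, m),
                        aucThreshold = aucThreshold)
    data.frame(m = m, pcc = cv$meanPCC, auc = cv$meanAUC)
  }))
}

#' Compare activation-function combinations
#'
#' Cross-validates the four combinations of \{relu, sigmoid\} in the
#' convolution layer x \{relu, sigmoid\} in the dense layer.
#'
#' @inheritParams scanFlankLength
#' @param combos data.frame with columns conv and dnn naming the
#'   activations to compare; defaults to all four combinations.
#' @return data.frame with columns conv, dnn, pcc, auc (4 rows by
#'   default).
#' @export
scanActivations <- function(records, config = modelConfig(),
                            params = defaultNNParams(),
                            combos = expand.grid(
                              conv = c("relu", "sigmoid"),
                              dnn = c("relu", "sigmoid"),
                              stringsAsFactors = FALSE),
                            k = 10L, seed = config@seed,
                            aucThreshold = 0.7) {
  if (nrow(combos) == 0L) .stopf("combos must not be empty")
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cfg <- config
    cfg@convActivation <- combos$conv[i]
    cfg@dnnActivation <- combos$dnn[i]
    cfg@seed <- deriveSeed(seed, i)
    cv <- crossValidate(records, cfg, params, k = k,
                        seed = deriveSeed(seed, i),
                        aucThreshold = aucThreshold)
    data.frame(conv = combos$conv[i], dnn = combos$dnn[i],
               pcc = cv$meanPCC, auc = cv$meanAUC)
  }))
}

#' Compare learning rates
#'
#' Cross-validates the model at each learning rate under the shared stop
#' rule (iterations > maxIterations or training MSE < errorTolerance).
#'
#' @inheritParams scanFlankLength
#' @param rates learning rates to compare; the canonical comparison uses
#'   0.5, 0.1, 0.01 and 0.001.
#' @return data.frame with columns lr, pcc, auc.
#' @export
scanLearningRate <- function(records, config = modelConfig(),
                             params = defaultNNParams(),
                             rates = c(0.5, 0.1, 0.01, 0.001),
                             k = 10L, seed = config@seed,
                             aucThreshold = 0.7) {
  if (length(rates) == 0L) .stopf("rates must not be empty")
  if (any(rates <= 0)) .stopf("learning rates must be > 0")
  do.call(rbind, lapply(seq_along(rates), function(i) {
    cfg <- config
    cfg@learningRate <- rates[i]
    cfg@seed <- deriveSeed(seed, i)
    cv <- crossValidate(records, cfg, params, k = k,
                        seed = deriveSeed(seed, i),
                        aucThreshold = aucThreshold)
    data.frame(lr = rates[i], pcc = cv$meanPCC, auc = cv$meanAUC)
  }))
}
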