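#' Pearson correlation between observed and predicted efficacies
#'
#' The standard sample Pearson correlation,
#' (1/(n-1)) * sum(((X - mean(X))/sd(X)) * ((Y - mean(Y))/sd(Y))).
#'
#' @param actual,predicted numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
pcc <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    .stopf("actual and predicted must have equal length")
  if (length(actual) < 2L) .stopf("need at least 2 pairs")
  if (anyNA(actual) || anyNA(predicted)) .stopf("inputs must not contain NA")
  if (var(actual) == 0 || var(predicted) == 0)
    .stopf("correlation is undefined for zero-variance input")
  cor(actual, predicted)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a randomly chosen positive is
#' scored above a randomly chosen negative, with ties counting 1/2; the ROC
#' curve plots sensitivity against 1 - specificity over all score
#' thresholds.
#'
#' @param labels logical (or 0/1) class labels; both classes must occur.
#' @param scores numeric scores, higher meaning more positive.
#' @return list with elements \code{auc} (numeric) and \code{rocPoints}
#'   (data.frame fpr, tpr, nondecreasing in both columns).
#' @export
rocAuc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores))
    .stopf("labels and scores must have equal length")
  if (anyNA(labels) || anyNA(scores)) .stopf("inputs must not contain NA")
  if (length(unique(labels)) < 2L)
    .stopf("both classes must be present to compute a ROC curve")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  list(auc = as.numeric(r$auc), rocPoints = pts)
}

#' Sensitivity and specificity from a confusion count
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP).
#'
#' @param tp,fn,tn,fp nonnegative counts; tp + fn and tn + fp must be
#'   positive.
#' @return named numeric 2-vector (sensitivity, specificity).
#' @export
sensitivitySpecificity <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0)) .stopf("counts must be nonnegative")
  if (tp + fn == 0) .stopf("no positives: sensitivity is undefined")
  if (tn + fp == 0) .stopf("no negatives: specificity is undefined")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Evaluate a trained model on labeled records
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param records a \linkS4class{SiRNASet} with observed efficacies.
#' @param params an \linkS4class{NNParameterTable}.
#' @param aucThreshold efficacy cutoff for the positive class when
#'   computing AUC (the ranking task has no canonical cutoff; 0.7 is the
#'   package default and is configurable everywhere it is used).
#' @return an \linkS4class{EvalReport}. AUC is NA (with a message) when the
#'   cutoff leaves a single class.
#' @export
evaluateModel <- function(model, records, params = defaultNNParams(),
                          aucThreshold = 0.7) {
  obs <- efficacy(records)
  keep <- which(!is.na(obs))
  if (length(keep) < 2L) .stopf("need at least 2 labeled records")
  records <- records[keep]
  obs <- unname(obs[keep])
  pred <- unname(predictEfficacy(model, records, params))
  evalFromPredictions(obs, pred, aucThreshold)
}

# Assemble an EvalReport from raw observed/predicted vectors.
evalFromPredictions <- function(obs, pred, aucThreshold = 0.7) {
  p <- tryCatch(pcc(obs, pred), error = function(e) NA_real_)
  labels <- obs >= aucThreshold
  if (length(unique(labels)) < 2L) {
    auc <- NA_real_
    pts <- data.frame(fpr = numeric(0), tpr = numeric(0))
  } else {
    ra <- rocAuc(labels, pred)
    auc <- ra$auc
    pts <- ra$rocPoints
  }
  new("EvalReport", pcc = p, auc = auc, rocPoints = pts,
      threshold = as.numeric(aucThreshold), n = length(obs))
}

#' k-fold cross-validation of the model
#'
#' Records are assigned to k disjoint, exhaustive folds (deterministic
#' given the seed); each fold is predicted by a model trained on the other
#' folds. Per-fold PCC/AUC are reported together with their means and a
#' pooled report over all out-of-fold predictions (per-fold PCC is
#' undefined for folds of size 1, e.g. leave-one-out, where only the
#' pooled report is meaningful).
#'
#' @param records labeled \linkS4class{SiRNASet}.
#' @param config a \linkS4class{ModelConfig}; each fold's model is
#'   initialized from a fold-derived seed.
#' @param params an \linkS4class{NNParameterTable}.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param aucThreshold efficacy cutoff for AUC.
#' @return list with \code{folds} (data.frame fold, n, pcc, auc),
#'   \code{meanPCC}, \code{meanAUC} (means over defined folds),
#'   \code{pooled} (an \linkS4class{EvalReport} over pooled out-of-fold
#'   predictions), and \code{assignment} (fold id per record).
#' @export
crossValidate <- function(records, config = modelConfig(),
                          params = defaultNNParams(), k = 10L,
                          seed = config@seed, aucThreshold = 0.7) {
  keep <- which(!is.na(efficacy(records)))
  records <- records[keep]
  N <- length(records)
  k <- as.integer(k)
  if (k < 2L) .stopf("k must be >= 2")
  if (k > N) .stopf("k = %d exceeds the number of labeled records (%d)", k, N)
  fold <- withSeed(seed, sample(rep_len(seq_len(k), N)))
  obs <- unname(efficacy(records))
  pooledPred <- numeric(N)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(fold == f)
    cfg <- config
    cfg@seed <- deriveSeed(seed, f)
    fit <- trainModel(records[-testIdx], cfg, params)
    pred <- unname(predictEfficacy(fit, records[testIdx], params))
    pooledPred[testIdx] <- pred
    rep <- evalFromPredictions(obs[testIdx], pred, aucThreshold)
    rows[[f]] <- data.frame(fold = f, n = length(testIdx),
                            pcc = rep@pcc, auc = rep@auc)
  }
  folds <- do.call(rbind, rows)
  list(folds = folds,
       meanPCC = if (all(is.na(folds$pcc))) NA_real_ else mean(folds$pcc, na.rm = TRUE),
       meanAUC = if (all(is.na(folds$auc))) NA_real_ else mean(folds$auc, na.rm = TRUE),
       pooled = evalFromPredictions(obs, pooledPred, aucThreshold),
       assignment = stats::setNames(fold, recordIds(records)))
}
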