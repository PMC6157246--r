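test_that("convolveSeq matches the printed output length and brute force", {
  # all-zero kernel -> all-zero output
  e <- encodeWindow(strrep("G", 21), 0)
  expect_equal(convolveSeq(e, matrix(0, 4, 4)), rep(0, 18))

  # bare 21-nt input with m = 15 -> 22 - m = 7 positions
  expect_length(convolveSeq(e, matrix(1, 15, 4)), 7L)

  # a one-hot kernel matching a planted motif peaks at the plant site
  motif <- "GAUC"
  w <- paste0(strrep("A", 6), motif, strrep("C", 11))
  K <- t(vapply(strsplit(motif, "")[[1]],
                function(b) unname(encodeBase(b)), numeric(4)))
  out <- convolveSeq(encodeWindow(w, 0), K, scale = 2)
  expect_identical(which.max(out), 7L)
  expect_equal(max(out), 4 * 2)   # m * delta

  # random inputs agree with the independent sliding-window oracle
  set.seed(21)
  for (i in 1:5) {
    n <- sample(0:4, 1)
    w <- paste(sample(c("A", "C", "G", "U", "-"), 21 + 2 * n,
                      replace = TRUE), collapse = "")
    S <- encodeWindow(w, n)
    K <- matrix(rnorm(6 * 4), 6, 4)
    expect_equal(convolveSeq(S, K, scale = 1.7), bruteConv(S@mat, K, 1.7))
  }
  expect_error(convolveSeq(e, matrix(1, 25, 4)), "exceeds")
})

test_that("activation functions follow their closed forms", {
  expect_equal(activate(-3, "relu"), 0)
  expect_equal(activate(2.5, "relu"), 2.5)
  expect_equal(activate(0, "sigmoid"), 0.5)
  expect_equal(activate(c(-1, 0, 2), "relu"), c(0, 0, 2))
})

test_that("pooling returns the global max and mean of the feature map", {
  expect_equal(poolFeatureMap(rep(3.2, 9)), c(max = 3.2, avg = 3.2))
  expect_equal(poolFeatureMap(c(0, 1, 2, 3)), c(max = 3, avg = 1.5))
  expect_error(poolFeatureMap(numeric(0)), "empty")
  set.seed(22)
  for (i in 1:10) {
    fm <- activate(rnorm(sample(3:30, 1)), "relu")
    p <- poolFeatureMap(fm)
    expect_gte(p[["max"]], p[["avg"]])
    expect_gte(p[["avg"]], 0)
  }
})

test_that("the batched convolution/pooling stage equals the per-record path", {
  rec <- makeRecords(7, seed = 23)
  cfg <- modelConfig(kernelHeights = c(2L, 5L, 9L), kernelsPerHeight = 2L,
                     flankN = 3L, seed = 3L)
  data <- sirnadeep:::buildNetData(rec, cfg, refParams)
  state <- sirnadeep:::initNetState(cfg)
  fw <- sirnadeep:::netForward(state, data, cfg)
  hv <- sirnadeep:::kernelHeightVector(cfg)
  windows <- extractWindow(rec, cfg@flankN)
  for (i in seq_along(rec)) {
    S <- encodeWindow(windows[[i]], cfg@flankN)
    for (k in seq_along(hv)) {
      K <- matrix(state$W[seq_len(4L * hv[k]), k], nrow = hv[k], byrow = TRUE)
      fmap <- activate(convolveSeq(S, K, state$delta[k]), cfg@convActivation)
      p <- poolFeatureMap(fmap)
      expect_equal(fw$H0[i, 2 * k - 1], p[["max"]], tolerance = 1e-12)
      expect_equal(fw$H0[i, 2 * k], p[["avg"]], tolerance = 1e-12)
    }
    # thermo block sits after the 2d pooled values
    expect_equal(unname(fw$H0[i, -(seq_len(2 * length(hv)))]),
                 unname(featurizeThermo(rec[i], refParams)[1, ]))
  }
})

test_that("forward output dimensions follow the architecture bookkeeping", {
  rec <- makeRecords(6, seed = 24)
  # reference kernel set: one kernel per height 6..20 -> d = 15, pooled 30
  ref <- modelConfig()
  expect_identical(nKernels(ref), 15L)
  data <- sirnadeep:::buildNetData(rec, ref, refParams)
  fw <- sirnadeep:::netForward(sirnadeep:::initNetState(ref), data, ref)
  expect_identical(ncol(fw$H0), 2L * 15L + 20L)   # merged = 50

  # pooled dimension is 2d for arbitrary kernel multisets
  for (heights in list(2L, c(4L, 7L), c(3L, 3L, 10L, 20L))) {
    cfg <- modelConfig(kernelHeights = heights, kernelsPerHeight = 1L,
                       flankN = 1L)
    d <- nKernels(cfg)
    dat <- sirnadeep:::buildNetData(rec, cfg, refParams)
    f <- sirnadeep:::netForward(sirnadeep:::initNetState(cfg), dat, cfg)
    expect_identical(ncol(f$H0), 2L * d + 20L)
  }
})

test_that("predictions are strictly inside (0,1) and 0.5 at zero weights", {
  rec <- makeRecords(10, seed = 25)
  fit <- trainModel(rec, tinyConfig(), refParams)
  pred <- predictEfficacy(fit, rec, refParams)
  expect_true(all(pred > 0 & pred < 1))
  # zero output weights force sigmoid(0) = 0.5 everywhere
  fit0 <- fit
  fit0@outW[] <- 0
  expect_equal(unname(predictEfficacy(fit0, rec, refParams)), rep(0.5, 10))
})

test_that("the full forward pass equals a step-by-step hand computation", {
  rec <- makeRecords(4, seed = 26)
  cfg <- modelConfig(kernelHeights = c(3L, 6L), kernelsPerHeight = 1L,
                     flankN = 2L, dnnUnits = 2L, seed = 9L)
  fit <- trainModel(rec, cfg, refParams)
  pred <- predictEfficacy(fit, rec, refParams)
  sg <- function(x) 1 / (1 + exp(-x))
  windows <- extractWindow(rec, cfg@flankN)
  for (i in seq_along(rec)) {
    S <- encodeWindow(windows[[i]], cfg@flankN)
    pooled <- numeric(0)
    for (k in 1:2) {
      fmap <- pmax(convolveSeq(S, fit@kernels[[k]], fit@kernelScale[k]), 0)
      pooled <- c(pooled, max(fmap), mean(fmap))
    }
    merged <- c(pooled, featurizeThermo(rec[i], refParams)[1, ])
    hn <- fit@bnGamma * (merged - fit@bnMean) /
      sqrt(fit@bnVar + sirnadeep:::BN_EPS) + fit@bnBeta
    h1 <- sg(as.vector(hn %*% fit@dnnW) + fit@dnnB)
    expect_equal(unname(pred[i]), sg(sum(fit@outW * h1)), tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  tiny <- makeRecords(9, seed = 27, flankAvail = 4L)
  for (conv in c("relu", "sigmoid")) {
    cfg <- modelConfig(kernelHeights = c(3L, 5L), kernelsPerHeight = 1L,
                       flankN = 2L, dnnUnits = 2L, convActivation = conv,
                       dnnActivation = "sigmoid", seed = 5L)
    err <- sirnadeep:::gradientCheck(tiny, cfg, refParams)
    expect_lt(err, 1e-4)
  }
})

test_that("training drives predictions to a constant target and stops early", {
  rec <- makeRecords(20, seed = 28, efficacy = rep(0.6, 20))
  cfg <- modelConfig(kernelHeights = c(3L, 5L), kernelsPerHeight = 1L,
                     flankN = 2L, dnnUnits = 3L, maxIterations = 500L,
                     seed = 2L)
  fit <- trainModel(rec, cfg, refParams)
  expect_lt(tail(fit@trainingLog, 1), cfg@errorTolerance)
  expect_lt(length(fit@trainingLog), 500L)   # the MSE stop rule fired
  expect_true(all(abs(predictEfficacy(fit, rec, refParams) - 0.6) < 0.1))
})

test_that("training is reproducible from the seed and sensitive to it", {
  rec <- makeRecords(15, seed = 29)
  cfg <- tinyConfig(maxIterations = 20L)
  f1 <- trainModel(rec, cfg, refParams)
  f2 <- trainModel(rec, cfg, refParams)
  expect_identical(f1@trainingLog, f2@trainingLog)
  expect_identical(f1@kernels, f2@kernels)
  cfg2 <- cfg; cfg2@seed <- 8L
  f3 <- trainModel(rec, cfg2, refParams)
  expect_false(identical(f1@trainingLog, f3@trainingLog))
})

test_that("training requires labeled records", {
  rec <- makeRecords(5, seed = 30)
  rec@efficacy[] <- NA_real_
  expect_error(trainModel(rec, tinyConfig(), refParams), "at least 2")
})

test_that("selectKernelSet trains one network per candidate height", {
  rec <- makeRecords(24, seed = 31, flankAvail = 2L)
  cfg <- modelConfig(kernelHeights = 3L, flankN = 2L, dnnUnits = 2L,
                     maxIterations = 2L, seed = 4L)
  sel <- selectKernelSet(rec, candidateHeights = c(4L, 8L, 12L),
                         params = refParams, threshold = 1.1,
                         baseConfig = cfg, cvFolds = 2L)
  expect_length(sel, 0L)                       # unattainable bound
  expect_identical(attr(sel, "nNetworks"), 3L)
  scan <- attr(sel, "scan")
  expect_identical(scan$m, c(4L, 8L, 12L))
  selAll <- selectKernelSet(rec, candidateHeights = c(4L, 8L, 12L),
                            params = refParams, threshold = -1.1,
                            baseConfig = cfg, cvFolds = 2L)
  expect_identical(as.integer(selAll), c(4L, 8L, 12L))  # vacuous bound
  expect_error(selectKernelSet(rec, integer(0), refParams), "empty")
  expect_error(selectKernelSet(rec, c(1L, 5L), refParams), "\\[2, 20\\]")
})

test_that("model configs reject out-of-range hyperparameters", {
  expect_error(modelConfig(kernelHeights = 21L), "2 <= m <= 20")
  expect_error(modelConfig(kernelHeights = 1L), "2 <= m <= 20")
  expect_error(modelConfig(learningRate = 0), "> 0")
})
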