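#' Convolve an encoded window with one motif-detector kernel
#'
#' Sliding dot product of an m x 4 kernel over the L x 4 one-hot matrix,
#' scaled by the kernel's learnable scalar: output position k is
#' scale * sum_j sum_i S[k+j-1, i] * M[j, i]. The output has L - m + 1
#' positions; with the bare 21-nt site (n = 0) that is the classic 22 - m.
#'
#' @param encoded an \linkS4class{EncodedSequence} or a numeric L x 4 matrix.
#' @param kernel numeric m x 4 kernel matrix (columns in A,U,G,C order).
#' @param scale per-kernel multiplicative scale delta_k.
#' @return numeric vector of length L - m + 1.
#' @export
convolveSeq <- function(encoded, kernel, scale = 1) {
  S <- if (is(encoded, "EncodedSequence")) encoded@mat else as.matrix(encoded)
  kernel <- as.matrix(kernel)
  if (ncol(S) != 4L || ncol(kernel) != 4L)
    .stopf("input and kernel must both have 4 columns")
  m <- nrow(kernel)
  L <- nrow(S)
  if (m > L) .stopf("kernel height %d exceeds input length %d", m, L)
  out <- numeric(L - m + 1L)
  for (p in seq_along(out))
    out[p] <- sum(S[p:(p + m - 1L), ] * kernel)
  out * scale
}

#' Elementwise activation
#'
#' @param x numeric vector or matrix.
#' @param fn "relu" (max(0, x)) or "sigmoid" (1 / (1 + exp(-x))).
#' @return activated values, same shape as x.
#' @export
activate <- function(x, fn = c("relu", "sigmoid")) {
  fn <- match.arg(fn)
  if (fn == "relu") pmax(x, 0) else .sigmoid(x)
}

.activationGrad <- function(x, a, fn) {
  if (fn == "relu") (x > 0) * 1 else a * (1 - a)
}

#' Global max + average pooling of one feature map
#'
#' The pooling window spans the whole map (pool size L - m + 1), so each
#' kernel contributes exactly two pooled values: the strongest motif match
#' anywhere in the window and the average response.
#'
#' @param featureMap numeric vector (one kernel's activated convolution
#'   output).
#' @return named numeric 2-vector (max, avg).
#' @export
poolFeatureMap <- function(featureMap) {
  if (length(featureMap) == 0L) .stopf("cannot pool an empty feature map")
  c(max = max(featureMap), avg = mean(featureMap))
}

# ---- internal batched network -------------------------------------------
#
# All kernel heights are zero-padded to the maximum height and evaluated as
# one im2col GEMM; positions that would run past the true input length for a
# given height are masked out of pooling. This is algebraically identical to
# per-height convolution (the padded kernel rows are pinned to zero) and is
# verified against convolveSeq() in the tests.

BN_EPS <- 1e-5

# Precompute the batched representation of a dataset for a given config.
buildNetData <- function(records, config, params) {
  hv <- kernelHeightVector(config)
  L <- 21L + 2L * config@flankN
  if (max(hv) > L)
    .stopf("kernel height %d exceeds input length %d", max(hv), L)
  windows <- extractWindow(records, config@flankN)
  enc <- encodeWindowArray(unname(windows), config@flankN)
  N <- dim(enc)[1]
  minm <- min(hv); maxm <- max(hv)
  P <- L - minm + 1L                     # shared position count
  Lp <- L + (maxm - minm)                # zero-padded input length
  encPad <- array(0, dim = c(N, Lp, 4))
  encPad[, seq_len(L), ] <- enc
  Z <- matrix(0, N * P, 4L * maxm)
  for (j in seq_len(maxm)) {
    block <- encPad[, j:(j + P - 1L), , drop = FALSE]     # N x P x 4
    Z[, (4L * (j - 1L) + 1L):(4L * j)] <- matrix(aperm(block, c(2, 1, 3)),
                                                 N * P, 4)
  }
  thermo <- featurizeThermo(records, params)
  list(Z = Z, N = N, P = P, L = L, heights = hv,
       Pm = L - hv + 1L, maxm = maxm,
       thermo = thermo, y = unname(efficacy(records)))
}

# Seeded parameter initialization: uniform(-r, r) with r = 1/sqrt(fan-in).
initNetState <- function(config, seed = config@seed) {
  hv <- kernelHeightVector(config)
  d <- length(hv)
  maxm <- max(hv)
  f <- 2L * d + 20L
  u <- config@dnnUnits
  withSeed(seed, {
    W <- matrix(0, 4L * maxm, d)
    for (k in seq_len(d)) {
      rows <- seq_len(4L * hv[k])
      W[rows, k] <- runif(length(rows), -1, 1) / sqrt(4 * hv[k])
    }
    W1 <- matrix(runif(f * u, -1, 1) / sqrt(f), f, u)
    w2 <- runif(u, -1, 1) / sqrt(u)
    list(W = W, delta = rep(1, d), gamma = rep(1, f), beta = rep(0, f),
         W1 = W1, b1 = rep(0, u), w2 = w2)
  })
}

# Mask of trainable kernel-weight entries (padding rows stay zero).
kernelWeightMask <- function(heights, maxm) {
  d <- length(heights)
  mask <- matrix(FALSE, 4L * maxm, d)
  for (k in seq_len(d)) mask[seq_len(4L * heights[k]), k] <- TRUE
  mask
}

# Forward pass over a prepared dataset. stats = NULL -> batch statistics
# (training mode); otherwise a list(mean, var) of frozen statistics.
netForward <- function(state, data, config, stats = NULL) {
  N <- data$N; P <- data$P; d <- length(data$heights)
  X <- data$Z %*% sweep(state$W, 2, state$delta, "*")  # scaled conv, (N*P) x d
  pool <- .poolForward(X, N, P, data$Pm,
                       if (config@convActivation == "relu") 0L else 1L)
  Pool <- matrix(0, N, 2L * d)
  Pool[, seq(1L, 2L * d, by = 2L)] <- pool$max
  Pool[, seq(2L, 2L * d, by = 2L)] <- pool$avg
  amax <- pool$argmax
  H0 <- cbind(Pool, data$thermo)
  if (is.null(stats)) {
    mu <- colMeans(H0)
    v <- pmax(colMeans(H0 * H0) - mu * mu, 0)
  } else {
    mu <- stats$mean; v <- stats$var
  }
  istd <- 1 / sqrt(v + BN_EPS)
  Hhat <- sweep(sweep(H0, 2, mu, "-"), 2, istd, "*")
  Hn <- sweep(sweep(Hhat, 2, state$gamma, "*"), 2, state$beta, "+")
  A1 <- sweep(Hn %*% state$W1, 2, state$b1, "+")
  H1 <- activate(A1, config@dnnActivation)
  z2 <- as.vector(H1 %*% state$w2)
  pred <- .sigmoid(z2)
  list(X = X, amax = amax, H0 = H0, mu = mu, istd = istd,
       Hhat = Hhat, Hn = Hn, A1 = A1, H1 = H1, pred = pred)
}

# Backward pass: gradients of mean((pred - y)^2) w.r.t. every parameter,
# using training-mode (batch-statistic) batch normalization.
netBackward <- function(state, data, config, fw, wmask) {
  N <- data$N; P <- data$P; d <- length(data$heights)
  r <- fw$pred - data$y
  dz2 <- (2 / N) * r * fw$pred * (1 - fw$pred)
  dw2 <- as.vector(crossprod(fw$H1, dz2))
  dH1 <- tcrossprod(dz2, state$w2)
  dA1 <- dH1 * .activationGrad(fw$A1, fw$H1, config@dnnActivation)
  dW1 <- crossprod(fw$Hn, dA1)
  db1 <- colSums(dA1)
  dHn <- tcrossprod(dA1, state$W1)
  dgamma <- colSums(dHn * fw$Hhat)
  dbeta <- colSums(dHn)
  dHhat <- sweep(dHn, 2, state$gamma, "*")
  s1 <- colSums(dHhat)
  s2 <- colSums(dHhat * fw$Hhat)
  dH0 <- sweep(sweep(dHhat, 2, s1 / N, "-") -
               sweep(fw$Hhat, 2, s2 / N, "*"),
               2, fw$istd, "*")
  dPool <- dH0[, seq_len(2L * d), drop = FALSE]
  dymax <- dPool[, seq(1L, 2L * d, by = 2L), drop = FALSE]
  dyavg <- dPool[, seq(2L, 2L * d, by = 2L), drop = FALSE]
  dA <- .poolBackward(fw$X, dymax, dyavg, fw$amax, N, P, data$Pm,
                      if (config@convActivation == "relu") 0L else 1L)
  dim(dA) <- c(N * P, d)
  # x_k = delta_k * (Z w_k): with G = Z' dA, the scale gradient is
  # ddelta_k = w_k . G_k and the kernel gradient is delta_k * G_k
  G <- crossprod(data$Z, dA)
  ddelta <- colSums(G * state$W)
  dW <- sweep(G, 2, state$delta, "*")
  dW[!wmask] <- 0
  list(W = dW, delta = ddelta, gamma = dgamma, beta = dbeta,
       W1 = dW1, b1 = db1, w2 = dw2)
}

netLoss <- function(state, data, config) {
  fw <- netForward(state, data, config, stats = NULL)
  mean((fw$pred - data$y)^2)
}
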