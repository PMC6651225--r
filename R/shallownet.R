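#' ShallowNet baseline configuration
#'
#' The shallow convolutional EEG decoder used as a raw-signal baseline:
#' temporal convolution (40 kernels of 1 x 25), spatial convolution over
#' all electrodes (40 kernels of E x 1), batch normalization, squaring
#' activation, average pooling (1 x 75, stride 100), log activation,
#' dropout and a dense softmax layer. For a 3 x 500 epoch the layer
#' outputs are 40 x 3 x 476 -> 40 x 1 x 476 -> pooled 1 x 40 x 5 ->
#' flattened 200 -> 2 class probabilities.
#'
#' @param n_temporal_filters,temporal_kernel Temporal convolution size.
#' @param n_spatial_filters Spatial convolution filters.
#' @param n_electrodes Number of electrodes E.
#' @param input_samples Epoch length in samples.
#' @param pool_width,pool_stride Average-pooling window and stride. The
#'   stride of 100 makes `floor((476 - 75)/100) + 1 = 5` pooled frames,
#'   matching the flattened size of 200.
#' @param dropout_rate Dropout probability before the dense layer.
#' @param log_epsilon Clamp inside `log(max(x, eps))`, keeping the log
#'   finite for zero pooled activations.
#' @param bn_eps,bn_momentum Batch-normalization variance floor and
#'   running-average momentum.
#' @param n_classes Output classes.
#' @return Object of class `shallownet_config`.
#' @export
shallownet_config <- function(n_temporal_filters = 40, temporal_kernel = 25,
                              n_spatial_filters = 40, n_electrodes = 3,
                              input_samples = 500,
                              pool_width = 75, pool_stride = 100,
                              dropout_rate = 0.5, log_epsilon = 1e-6,
                              bn_eps = 1e-5, bn_momentum = 0.1,
                              n_classes = 2) {
  t_out <- input_samples - temporal_kernel + 1
  p_out <- (t_out - pool_width) %/% pool_stride + 1
  if (p_out < 1) stop("pooling produces no output frames", call. = FALSE)
  structure(
    list(n_temporal_filters = as.integer(n_temporal_filters),
         temporal_kernel = as.integer(temporal_kernel),
         n_spatial_filters = as.integer(n_spatial_filters),
         n_electrodes = as.integer(n_electrodes),
         input_samples = as.integer(input_samples),
         pool_width = as.integer(pool_width),
         pool_stride = as.integer(pool_stride),
         dropout_rate = dropout_rate, log_epsilon = log_epsilon,
         bn_eps = bn_eps, bn_momentum = bn_momentum,
         n_classes = as.integer(n_classes),
         t_out = as.integer(t_out), p_out = as.integer(p_out),
         flat = as.integer(n_spatial_filters * p_out)),
    class = "shallownet_config")
}

#' Numerically stable softmax
#'
#' `f(x)_i = exp(x_i) / sum_k exp(x_k)` with max-subtraction.
#'
#' @param x Numeric vector.
#' @return Probability vector summing to one.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

shallownet_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "shallownet_config"))
  set.seed(as.integer(seed))
  gmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  Fn <- cfg$n_temporal_filters
  list(
    K = gmat(Fn, cfg$temporal_kernel, 1 / sqrt(cfg$temporal_kernel)),
    b1 = numeric(Fn),
    S = gmat(cfg$n_spatial_filters, Fn * cfg$n_electrodes,
             1 / sqrt(Fn * cfg$n_electrodes)),
    b2 = numeric(cfg$n_spatial_filters),
    gamma = rep(1, cfg$n_spatial_filters),
    beta = numeric(cfg$n_spatial_filters),
    Wd = gmat(cfg$n_classes, cfg$flat, 1 / sqrt(cfg$flat)),
    bd = numeric(cfg$n_classes),
    run_mean = numeric(cfg$n_spatial_filters),
    run_var = rep(1, cfg$n_spatial_filters))
}

## internal batched forward; X is (E*input_samples x n), per-epoch layout
## electrode-fastest (as.vector of an E x T matrix)
shallownet_forward_batch <- function(params, cfg, X, train = FALSE,
                                     drop_mask = NULL) {
  n <- ncol(X)
  E <- cfg$n_electrodes; Tn <- cfg$input_samples
  Fn <- cfg$n_temporal_filters; To <- cfg$t_out
  Xa <- array(X, dim = c(E, Tn, n))

  ## temporal convolution per electrode: Y[[e]] is (To*n) x Fn, rows (t, i)
  tidx <- outer(seq_len(cfg$temporal_kernel), 0:(To - 1), "+")  # K x To
  Y <- Xc <- vector("list", E)
  for (e in seq_len(E)) {
    Xe <- matrix(Xa[e, , ], Tn, n)
    Xce <- Xe[as.vector(tidx), , drop = FALSE]
    dim(Xce) <- c(cfg$temporal_kernel, To, n)
    Xc[[e]] <- matrix(aperm(Xce, c(2, 3, 1)), To * n, cfg$temporal_kernel)
    Y[[e]] <- sweep(Xc[[e]] %*% t(params$K), 2, params$b1, "+")
  }

  ## spatial convolution across (filter, electrode): U is (Fn*E) x (To*n)
  U <- do.call(rbind, lapply(Y, t))     # rows f + (e-1)*Fn
  Z <- params$S %*% U + params$b2       # (G x To*n)

  ## batch normalization per spatial filter
  if (train) {
    mu <- rowMeans(Z)
    va <- rowMeans((Z - mu)^2)
  } else {
    mu <- params$run_mean
    va <- params$run_var
  }
  sd_ <- sqrt(va + cfg$bn_eps)
  Xhat <- (Z - mu) / sd_
  BN <- params$gamma * Xhat + params$beta

  SQ <- BN^2
  SQa <- array(SQ, dim = c(cfg$n_spatial_filters, To, n))
  pooled <- array(0, dim = c(cfg$n_spatial_filters, cfg$p_out, n))
  for (p in seq_len(cfg$p_out)) {
    t0 <- (p - 1L) * cfg$pool_stride + 1L
    sl <- SQa[, t0:(t0 + cfg$pool_width - 1L), , drop = FALSE]
    pooled[, p, ] <- colSums(aperm(sl, c(2, 1, 3))) / cfg$pool_width
  }
  LG <- log(pmax(pooled, cfg$log_epsilon))
  Fl <- matrix(LG, cfg$flat, n)

  if (train && cfg$dropout_rate > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(stats::rbinom(cfg$flat * n, 1,
                                        1 - cfg$dropout_rate) /
                            (1 - cfg$dropout_rate), cfg$flat, n)
    Fd <- Fl * drop_mask
  } else {
    drop_mask <- NULL
    Fd <- Fl
  }
  logits <- params$Wd %*% Fd + params$bd
  lm <- apply(logits, 2, max)
  Elog <- exp(sweep(logits, 2, lm, "-"))
  probs <- sweep(Elog, 2, colSums(Elog), "/")

  list(Xc = Xc, Y = Y, U = U, Z = Z, mu = mu, va = va, sd_ = sd_,
       Xhat = Xhat, BN = BN, SQ = SQ, pooled = pooled, LG = LG, Fl = Fl,
       drop_mask = drop_mask, Fd = Fd, probs = probs, n = n)
}

shallownet_batch_loss <- function(fw, labels) {
  n <- fw$n
  p_true <- fw$probs[cbind(as.integer(labels) + 1L, seq_len(n))]
  -mean(log(pmax(p_true, 1e-12)))
}

shallownet_backward_batch <- function(fw, labels, cfg, params) {
  n <- fw$n
  E <- cfg$n_electrodes; Fn <- cfg$n_temporal_filters; To <- cfg$t_out
  G <- cfg$n_spatial_filters
  grads <- list()

  dlogits <- fw$probs
  dlogits[cbind(as.integer(labels) + 1L, seq_len(n))] <-
    dlogits[cbind(as.integer(labels) + 1L, seq_len(n))] - 1
  dlogits <- dlogits / n
  grads$Wd <- tcrossprod(dlogits, fw$Fd)
  grads$bd <- rowSums(dlogits)
  dFd <- crossprod(params$Wd, dlogits)
  dFl <- if (!is.null(fw$drop_mask)) dFd * fw$drop_mask else dFd

  dLG <- array(dFl, dim = c(G, cfg$p_out, n))
  dpool <- dLG * (fw$pooled > cfg$log_epsilon) / pmax(fw$pooled,
                                                      cfg$log_epsilon)
  dSQ <- matrix(0, G, To * n)
  dim(dSQ) <- c(G, To, n)
  for (p in seq_len(cfg$p_out)) {
    t0 <- (p - 1L) * cfg$pool_stride + 1L
    rng <- t0:(t0 + cfg$pool_width - 1L)
    add <- array(dpool[, p, ], dim = c(G, 1, n))[, rep(1, cfg$pool_width), ,
                                                 drop = FALSE]
    dSQ[, rng, ] <- dSQ[, rng, ] + add / cfg$pool_width
  }
  dim(dSQ) <- c(G, To * n)
  dBN <- 2 * fw$BN * dSQ

  ## batch-norm backward (per row over m = To*n elements)
  m <- To * n
  grads$gamma <- rowSums(dBN * fw$Xhat)
  grads$beta <- rowSums(dBN)
  dXhat <- dBN * params$gamma
  xc <- fw$Z - fw$mu
  dvar <- rowSums(dXhat * xc) * (-0.5) / fw$sd_^3
  dmu <- rowSums(-dXhat / fw$sd_) + dvar * rowMeans(-2 * xc)
  dZ <- dXhat / fw$sd_ + dvar * 2 * xc / m + dmu / m

  grads$S <- tcrossprod(dZ, fw$U)
  grads$b2 <- rowSums(dZ)
  dU <- crossprod(params$S, dZ)         # (Fn*E) x (To*n)
  grads$K <- matrix(0, Fn, cfg$temporal_kernel)
  grads$b1 <- numeric(Fn)
  for (e in seq_len(E)) {
    dYe <- t(dU[(e - 1L) * Fn + seq_len(Fn), , drop = FALSE])  # (To*n) x Fn
    grads$K <- grads$K + t(crossprod(fw$Xc[[e]], dYe))
    grads$b1 <- grads$b1 + colSums(dYe)
  }
  grads
}

#' ShallowNet forward pass on one epoch
#'
#' Evaluation-mode forward pass (batch normalization uses the stored
#' running statistics; dropout is disabled).
#'
#' @param epoch A 3 x 500 numeric matrix (channels x samples).
#' @param params ShallowNet parameters (from training or
#'   `shallownet_init`).
#' @param cfg A [shallownet_config()].
#' @return Named numeric vector of 2 class probabilities (left, right).
#' @export
shallownet_forward <- function(epoch, params, cfg = shallownet_config()) {
  if (is.null(dim(epoch)) ||
      !identical(dim(epoch), c(cfg$n_electrodes, cfg$input_samples)))
    stop(sprintf("epoch must be %d x %d", cfg$n_electrodes,
                 cfg$input_samples), call. = FALSE)
  X <- matrix(as.vector(epoch), ncol = 1)
  fw <- shallownet_forward_batch(params, cfg, X, train = FALSE)
  p <- drop(fw$probs)
  names(p) <- c("left", "right")
  p
}

## internal: layer-by-layer output shapes for a single epoch, mirroring
## the architecture table
shallownet_shapes <- function(cfg = shallownet_config()) {
  list(temporal = c(cfg$n_temporal_filters, cfg$n_electrodes, cfg$t_out),
       spatial = c(cfg$n_spatial_filters, 1L, cfg$t_out),
       pooled = c(1L, cfg$n_spatial_filters, cfg$p_out),
       flatten = cfg$flat,
       output = cfg$n_classes)
}
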