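## Internal neural-network primitives shared by the capsule network and
## the ShallowNet baseline. Batches are stored as (features x n) matrices;
## a multi-channel feature map of height H, width W, C channels is
## flattened column-major as (H, W, C).

## index map for valid convolution: returns a (kh*kw*C) x P matrix of
## linear indices into an (H, W, C) volume, P = out_h * out_w positions
im2col_index <- function(H, W, C, kh, kw, stride) {
  out_h <- (H - kh) %/% stride + 1L
  out_w <- (W - kw) %/% stride + 1L
  ## offsets of one patch relative to its top-left corner
  off <- as.vector(outer(0:(kh - 1),
                         outer((0:(kw - 1)) * H, (0:(C - 1)) * H * W, "+"),
                         "+"))
  ## top-left linear index of each output position
  tl <- as.vector(outer((0:(out_h - 1)) * stride,
                        (0:(out_w - 1)) * stride * H, "+")) + 1L
  idx <- outer(off, tl, "+")            # K x P
  list(idx = idx, out_h = out_h, out_w = out_w,
       K = kh * kw * C, P = out_h * out_w)
}

## X: (H*W*C) x n -> list(out = (P*F) x n, cache)
## Wmat: K x F kernel matrix, b: length-F bias
conv_forward <- function(X, map, Wmat, b) {
  n <- ncol(X)
  K <- map$K; P <- map$P; F <- ncol(Wmat)
  Xc <- X[as.vector(map$idx), , drop = FALSE]      # (K*P) x n, K fastest
  dim(Xc) <- c(K, P, n)
  Xcm <- matrix(aperm(Xc, c(2, 3, 1)), P * n, K)   # rows (p, i)
  Y <- Xcm %*% Wmat
  Y <- sweep(Y, 2, b, "+")                         # (P*n) x F
  dim(Y) <- c(P, n, F)
  out <- matrix(aperm(Y, c(1, 3, 2)), P * F, n)    # (p, f) fastest-p
  list(out = out, Xcm = Xcm)
}

## dOut: (P*F) x n; returns gradients and dX ((H*W*C) x n)
conv_backward <- function(dOut, X_nrow, map, Wmat, Xcm) {
  n <- ncol(dOut)
  K <- map$K; P <- map$P; F <- ncol(Wmat)
  dY <- dOut
  dim(dY) <- c(P, F, n)
  dYm <- matrix(aperm(dY, c(1, 3, 2)), P * n, F)
  dW <- crossprod(Xcm, dYm)                        # K x F
  db <- colSums(dYm)
  dXcm <- dYm %*% t(Wmat)                          # (P*n) x K
  dim(dXcm) <- c(P, n, K)
  dXc <- aperm(dXcm, c(3, 1, 2))                   # K x P x n
  dX <- matrix(0, X_nrow, n)
  for (k in seq_len(K)) {
    rows <- map$idx[k, ]
    dX[rows, ] <- dX[rows, ] + matrix(dXc[k, , ], P, n)
  }
  list(dW = dW, db = db, dX = dX)
}

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for `x > 0` and
#' `lambda * alpha * (exp(x) - 1)` otherwise, with the standard
#' self-normalizing constants `lambda = 1.0507`, `alpha = 1.6733`.
#'
#' @param x Numeric scalar or array.
#' @param lambda,alpha SELU constants.
#' @return Same shape as `x`.
#' @export
#' @examples
#' selu(0); selu(2); selu(-1e3)  # -> 0, ~2.101, -> -lambda*alpha
selu <- function(x, lambda = 1.0507, alpha = 1.6733) {
  ifelse(x > 0, lambda * x, lambda * alpha * (exp(x) - 1))
}

selu_grad <- function(x, lambda = 1.0507, alpha = 1.6733) {
  ifelse(x > 0, lambda, lambda * alpha * exp(x))
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

## squash applied column-wise to a (dim x m) matrix of capsule vectors
squash_cols <- function(S, eps = 1e-12) {
  r2 <- colSums(S * S)
  a <- sqrt(r2) / (1 + r2)              # v = a * s, ||v|| = r^2/(1+r^2)
  a[r2 < eps] <- 0
  sweep(S, 2, a, "*")
}

## backward of squash_cols: given dV, S -> dS
## v = a(r) s with a(r) = r/(1+r^2), r = ||s||;
## ds = a dv + (a'(r)/r) (s . dv) s, a'(r) = (1 - r^2)/(1+r^2)^2
squash_cols_backward <- function(dV, S, eps = 1e-12) {
  r2 <- colSums(S * S)
  r <- sqrt(r2)
  a <- r / (1 + r2)
  sdot <- colSums(S * dV)
  coef <- ifelse(r2 < eps, 0, (1 - r2) / (1 + r2)^2 / pmax(r, eps) * sdot)
  a[r2 < eps] <- 0
  sweep(dV, 2, a, "*") + sweep(S, 2, coef, "*")
}

## row-stabilized softmax over columns of a matrix (each row sums to 1)
softmax_rows <- function(B) {
  M <- B - apply(B, 1, max)
  E <- exp(M)
  E / rowSums(E)
}
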