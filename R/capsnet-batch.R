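## Internal batched forward/backward passes of the capsule network.
## A batch of images is a (pixels x n) matrix; per-image layout is
## (freq, time, channel) column-major. All math is 64-bit.
##
## Capsule quantities are kept as per-class lists of contiguous arrays:
## prediction vectors uh[[j]] have dim (N, n, D) so that every inner
## routing/backprop operation is an elementwise op on an (N x n) slice.

caps_maps <- function(cfg) {
  H <- cfg$image_dim[2]; W <- cfg$image_dim[3]; C <- cfg$image_dim[1]
  m1 <- im2col_index(H, W, C, 3L, 3L, 1L)
  m2 <- im2col_index(m1$out_h, m1$out_w, cfg$conv_channels, 3L, 3L, 2L)
  list(m1 = m1, m2 = m2)
}

## per-class routing weights as (N, q, D) arrays (slices contiguous in i)
caps_flat_W <- function(params, cfg) {
  lapply(seq_len(cfg$n_classes), function(j) {
    wj <- array(params$W[, , , j], dim = dim(params$W)[1:3])  # D x q x N
    aperm(wj, c(3, 2, 1))
  })
}

## forward pass; labels (0-based) are used for the decoder mask when
## train = TRUE, otherwise the predicted class is used
caps_forward_batch <- function(params, cfg, X, labels = NULL, train = TRUE,
                               maps = NULL, Wflat = NULL, keep_state = FALSE) {
  if (is.null(maps)) maps <- caps_maps(cfg)
  if (is.null(Wflat)) Wflat <- caps_flat_W(params, cfg)
  n <- ncol(X)
  q <- cfg$primary_dim; D <- cfg$mi_dim; J <- cfg$n_classes
  N <- cfg$n_primary; P2 <- cfg$primary_grid^2

  c1 <- conv_forward(X, maps$m1, params$W1, params$b1)
  H1 <- selu(c1$out, cfg$selu_scale, cfg$selu_alpha)
  c2 <- conv_forward(H1, maps$m2, params$W2, params$b2)

  ## primary capsules: (P2 * F2) x n -> (q x N*n), i = pos + (chan-1)*P2
  A <- c2$out
  dim(A) <- c(P2, q, cfg$primary_channels, n)
  u_raw <- aperm(A, c(2, 1, 3, 4))
  dim(u_raw) <- c(q, N * n)
  U <- squash_cols(u_raw)               # columns are capsules
  ## per-dimension slices Uk[[k]]: (N x n)
  Um <- array(U, dim = c(q, N, n))
  Uk <- lapply(seq_len(q), function(k) matrix(Um[k, , ], N, n))

  ## prediction vectors uh[[j]]: (N, n, D)
  uh <- vector("list", J)
  for (j in seq_len(J)) {
    acc <- array(0, dim = c(N, n, D))
    for (d in seq_len(D)) {
      s <- Wflat[[j]][, 1, d] * Uk[[1]]
      for (k in seq.int(2, length.out = q - 1))
        s <- s + Wflat[[j]][, k, d] * Uk[[k]]
      acc[, , d] <- s
    }
    uh[[j]] <- acc
  }

  ## dynamic routing (the agreement loop), storing per-iteration state
  r <- cfg$routing_iters
  B <- lapply(seq_len(J), function(j) matrix(0, N, n))
  iters <- vector("list", r)
  Cs <- Ss <- Vs <- NULL
  for (it in seq_len(r)) {
    Bmax <- B[[1]]
    if (J > 1) for (j in 2:J) Bmax <- pmax(Bmax, B[[j]])
    E <- lapply(B, function(b) exp(b - Bmax))
    Esum <- Reduce(`+`, E)
    Cs <- lapply(E, function(e) e / Esum)
    Ss <- Vs <- vector("list", J)
    for (j in seq_len(J)) {
      s <- matrix(0, D, n)
      for (d in seq_len(D)) s[d, ] <- colSums(uh[[j]][, , d] * Cs[[j]])
      Ss[[j]] <- s
      Vs[[j]] <- squash_cols(s)
    }
    iters[[it]] <- list(C = Cs, S = Ss, V = Vs)
    if (it < r) {
      for (j in seq_len(J)) {
        a <- matrix(0, N, n)
        for (d in seq_len(D))
          a <- a + uh[[j]][, , d] * rep(Vs[[j]][d, ], each = N)
        B[[j]] <- B[[j]] + a
      }
    }
  }
  vnorm <- do.call(rbind, lapply(Vs, function(v) sqrt(colSums(v * v))))

  ## decoder with masking (true label when training, prediction otherwise)
  recon <- NULL; dec <- NULL; mask <- NULL
  if (cfg$reconstruction) {
    mask <- if (train && !is.null(labels)) as.integer(labels) + 1L
            else max.col(t(vnorm), ties.method = "first")
    M <- matrix(0, J * D, n)
    for (j in seq_len(J)) {
      sel <- mask == j
      if (any(sel))
        M[(j - 1L) * D + seq_len(D), sel] <- Vs[[j]][, sel]
    }
    Z1d <- params$Wd1 %*% M + params$bd1
    A1d <- relu(Z1d)
    Z2d <- params$Wd2 %*% A1d + params$bd2
    A2d <- relu(Z2d)
    R <- sigmoid(params$Wd3 %*% A2d + params$bd3)
    recon <- R
    dec <- list(M = M, Z1d = Z1d, A1d = A1d, Z2d = Z2d, A2d = A2d, R = R)
  }

  state <- NULL
  if (keep_state) {
    ## single-sample routing state in the documented layouts
    stopifnot(n == 1)
    u1 <- t(matrix(U[, seq_len(N)], q, N))
    uh1 <- array(0, dim = c(N, J, D))
    a1 <- b1 <- c1s <- matrix(0, N, J)
    v1 <- s1 <- matrix(0, J, D)
    for (j in seq_len(J)) {
      uhj <- matrix(uh[[j]][, 1, ], N, D)
      uh1[, j, ] <- uhj
      v1[j, ] <- Vs[[j]][, 1]
      s1[j, ] <- Ss[[j]][, 1]
      c1s[, j] <- Cs[[j]][, 1]
      b1[, j] <- B[[j]][, 1]
      a1[, j] <- uhj %*% v1[j, ]
    }
    state <- list(u = u1, u_hat = uh1, b = b1, c = c1s, s = s1, v = v1,
                  a = a1)
  }

  list(X = X, c1 = c1, H1 = H1, c2 = c2, u_raw = u_raw, Uk = Uk, uh = uh,
       iters = iters, vnorm = vnorm, recon = recon, dec = dec, mask = mask,
       maps = maps, Wflat = Wflat, state = state, n = n)
}

## mean per-sample total loss of a forward pass (labels 0-based)
caps_batch_loss <- function(fw, labels, cfg) {
  n <- fw$n
  J <- cfg$n_classes
  Tm <- matrix(0, J, n)
  Tm[cbind(as.integer(labels) + 1L, seq_len(n))] <- 1
  margin <- sum(Tm * pmax(0, cfg$m_plus - fw$vnorm)^2 +
                  cfg$lambda_margin * (1 - Tm) *
                    pmax(0, fw$vnorm - cfg$m_minus)^2) / n
  rec <- 0
  if (cfg$reconstruction)
    rec <- sum((fw$recon - fw$X)^2) / n
  list(total = margin + if (cfg$reconstruction) cfg$lambda_rec * rec else 0,
       margin = margin, reconstruction_sse = rec)
}

## backward pass: gradients of the mean per-sample total loss
caps_backward_batch <- function(fw, labels, cfg, params) {
  n <- fw$n
  q <- cfg$primary_dim; D <- cfg$mi_dim; J <- cfg$n_classes
  N <- cfg$n_primary; P2 <- cfg$primary_grid^2
  grads <- list()

  ## margin-loss gradient on the class capsules
  Tm <- matrix(0, J, n)
  Tm[cbind(as.integer(labels) + 1L, seq_len(n))] <- 1
  vnorm <- fw$vnorm
  dnorm <- (Tm * (-2) * pmax(0, cfg$m_plus - vnorm) +
              cfg$lambda_margin * (1 - Tm) * 2 *
                pmax(0, vnorm - cfg$m_minus)) / n
  Vlast <- fw$iters[[cfg$routing_iters]]$V
  dV <- vector("list", J)
  for (j in seq_len(J)) {
    vn <- pmax(vnorm[j, ], 1e-12)
    dV[[j]] <- sweep(Vlast[[j]], 2, dnorm[j, ] / vn, "*")
  }

  ## reconstruction branch
  if (cfg$reconstruction) {
    dec <- fw$dec
    dR <- 2 * cfg$lambda_rec * (dec$R - fw$X) / n
    dZ3 <- dR * dec$R * (1 - dec$R)
    grads$Wd3 <- tcrossprod(dZ3, dec$A2d)
    grads$bd3 <- rowSums(dZ3)
    dA2 <- crossprod(params$Wd3, dZ3)
    dZ2 <- dA2 * (dec$Z2d > 0)
    grads$Wd2 <- tcrossprod(dZ2, dec$A1d)
    grads$bd2 <- rowSums(dZ2)
    dA1 <- crossprod(params$Wd2, dZ2)
    dZ1 <- dA1 * (dec$Z1d > 0)
    grads$Wd1 <- tcrossprod(dZ1, dec$M)
    grads$bd1 <- rowSums(dZ1)
    dM <- crossprod(params$Wd1, dZ1)    # (J*D) x n
    for (j in seq_len(J)) {
      sel <- fw$mask == j
      if (any(sel)) {
        block <- dM[(j - 1L) * D + seq_len(D), , drop = FALSE]
        block[, !sel] <- 0
        dV[[j]] <- dV[[j]] + block
      }
    }
  } else {
    z <- function(x) array(0, dim = dim(x))
    grads$Wd1 <- z(params$Wd1); grads$bd1 <- numeric(length(params$bd1))
    grads$Wd2 <- z(params$Wd2); grads$bd2 <- numeric(length(params$bd2))
    grads$Wd3 <- z(params$Wd3); grads$bd3 <- numeric(length(params$bd3))
  }

  ## routing backward, unrolled over the stored iterations
  duh <- lapply(seq_len(J), function(j) array(0, dim = c(N, n, D)))
  dB <- lapply(seq_len(J), function(j) matrix(0, N, n))  # grad wrt b_{t+1}
  for (t in seq.int(cfg$routing_iters, 1)) {
    st <- fw$iters[[t]]
    if (t < cfg$routing_iters) {
      ## b_{t+1} = b_t + uh . v_t : contributions to v_t and uh
      dVt <- vector("list", J)
      for (j in seq_len(J)) {
        dv <- matrix(0, D, n)
        for (d in seq_len(D)) {
          dv[d, ] <- colSums(dB[[j]] * fw$uh[[j]][, , d])
          duh[[j]][, , d] <- duh[[j]][, , d] +
            dB[[j]] * rep(st$V[[j]][d, ], each = N)
        }
        dVt[[j]] <- dv
      }
      dV <- dVt
    }
    ## squash and weighted-sum backward; the coupling gradient is only
    ## needed when it can reach an earlier iteration's logits (b_1 is a
    ## constant, so dC is dead work at t = 1)
    need_dC <- t > 1
    dC <- vector("list", J)
    for (j in seq_len(J)) {
      dS <- squash_cols_backward(dV[[j]], st$S[[j]])
      dcj <- if (need_dC) matrix(0, N, n) else NULL
      for (d in seq_len(D)) {
        dsd <- rep(dS[d, ], each = N)
        if (need_dC) dcj <- dcj + fw$uh[[j]][, , d] * dsd
        duh[[j]][, , d] <- duh[[j]][, , d] + st$C[[j]] * dsd
      }
      dC[[j]] <- dcj
    }
    if (need_dC) {
      ## softmax backward per (capsule, sample)
      dot <- matrix(0, N, n)
      for (j in seq_len(J)) dot <- dot + st$C[[j]] * dC[[j]]
      for (j in seq_len(J))
        dB[[j]] <- dB[[j]] + st$C[[j]] * (dC[[j]] - dot)
    }
  }

  ## prediction-vector backward: dU and dW
  dUk <- lapply(seq_len(q), function(k) matrix(0, N, n))
  grads$W <- array(0, dim = dim(params$W))
  for (j in seq_len(J)) {
    dWj <- array(0, dim = c(N, q, D))
    for (d in seq_len(D)) {
      duhd <- duh[[j]][, , d]
      for (k in seq_len(q)) {
        dWj[, k, d] <- rowSums(duhd * fw$Uk[[k]])
        dUk[[k]] <- dUk[[k]] + fw$Wflat[[j]][, k, d] * duhd
      }
    }
    grads$W[, , , j] <- aperm(dWj, c(3, 2, 1))
  }

  ## primary squash backward and un-reshape to the conv layout
  dU <- array(0, dim = c(q, N, n))
  for (k in seq_len(q)) dU[k, , ] <- dUk[[k]]
  dU_flat <- matrix(dU, q, N * n)
  dS_prim <- squash_cols_backward(dU_flat, fw$u_raw)
  dA <- array(dS_prim, dim = c(q, P2, cfg$primary_channels, n))
  dZ2c <- aperm(dA, c(2, 1, 3, 4))
  dim(dZ2c) <- c(P2 * q * cfg$primary_channels, n)

  bw2 <- conv_backward(dZ2c, nrow(fw$H1), fw$maps$m2, params$W2, fw$c2$Xcm)
  grads$W2 <- bw2$dW; grads$b2 <- bw2$db
  dZ1c <- bw2$dX * selu_grad(fw$c1$out, cfg$selu_scale, cfg$selu_alpha)
  bw1 <- conv_backward(dZ1c, nrow(fw$X), fw$maps$m1, params$W1, fw$c1$Xcm)
  grads$W1 <- bw1$dW; grads$b1 <- bw1$db
  grads
}
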