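#' Capsule network configuration
#'
#' Architecture and loss hyperparameters for the motor-imagery capsule
#' network. The default configuration is: a 3x3/stride-1 convolution with
#' 4 channels and SELU activation (14x14x3 image -> 4 x 12x12 maps), a
#' primary capsule layer realized as a 3x3/stride-2 convolution with
#' `primary_channels * primary_dim` maps (-> 5x5 grid, i.e.
#' `128 * 25 = 3200` four-dimensional capsules, each squashed), one
#' 8-dimensional class capsule per class coupled by dynamic routing, and
#' a three-layer reconstruction decoder (512, 1024, 588 units) whose
#' squared-error loss is weighted by `lambda_rec` in the total loss.
#'
#' @param conv_channels Channels of the first convolution.
#' @param primary_channels Number of primary-capsule channels.
#' @param primary_dim Dimensionality of each primary capsule.
#' @param mi_dim Dimensionality of each class capsule.
#' @param n_classes Number of classes (2: left / right hand).
#' @param routing_iters Dynamic-routing iterations r (>= 1).
#' @param reconstruction Enable the reconstruction regularizer?
#' @param m_plus,m_minus Margin-loss margins for present / absent classes.
#' @param lambda_margin Down-weight for absent-class margin terms.
#' @param lambda_rec Weight of the reconstruction loss in the total loss.
#' @param decoder_sizes Decoder layer widths; the last must equal the
#'   pixel count of the input image (3 * 14 * 14 = 588).
#' @param image_dim Input image dimensions (channels, height, width).
#' @param selu_scale,selu_alpha SELU constants.
#' @return Object of class `capsnet_config`.
#' @export
capsnet_config <- function(conv_channels = 4,
                           primary_channels = 128,
                           primary_dim = 4,
                           mi_dim = 8,
                           n_classes = 2,
                           routing_iters = 1,
                           reconstruction = TRUE,
                           m_plus = 0.9, m_minus = 0.1,
                           lambda_margin = 0.5,
                           lambda_rec = 0.0005,
                           decoder_sizes = c(512, 1024, 588),
                           image_dim = c(3, 14, 14),
                           selu_scale = 1.0507, selu_alpha = 1.6733) {
  if (routing_iters < 1) stop("`routing_iters` must be >= 1", call. = FALSE)
  if (!(0 <= m_minus && m_minus < m_plus && m_plus <= 1))
    stop("need 0 <= m_minus < m_plus <= 1", call. = FALSE)
  if (lambda_rec <= 0) stop("`lambda_rec` must be > 0", call. = FALSE)
  H <- image_dim[2]; W <- image_dim[3]
  h1 <- H - 3 + 1                       # conv1: 3x3, stride 1, valid
  g <- (h1 - 3) %/% 2 + 1               # primary: 3x3, stride 2, valid
  if (h1 < 3 || g < 1)
    stop("image too small for the convolutional stack", call. = FALSE)
  n_pix <- prod(image_dim)
  if (decoder_sizes[length(decoder_sizes)] != n_pix)
    stop(sprintf("last decoder size must equal the pixel count (%d)", n_pix),
         call. = FALSE)
  structure(
    list(conv_channels = as.integer(conv_channels),
         primary_channels = as.integer(primary_channels),
         primary_dim = as.integer(primary_dim),
         mi_dim = as.integer(mi_dim),
         n_classes = as.integer(n_classes),
         routing_iters = as.integer(routing_iters),
         reconstruction = isTRUE(reconstruction),
         m_plus = m_plus, m_minus = m_minus,
         lambda_margin = lambda_margin, lambda_rec = lambda_rec,
         decoder_sizes = as.integer(decoder_sizes),
         image_dim = as.integer(image_dim),
         conv_out = as.integer(h1), primary_grid = as.integer(g),
         n_primary = as.integer(primary_channels * g * g),
         selu_scale = selu_scale, selu_alpha = selu_alpha),
    class = "capsnet_config")
}

#' Initialize capsule network parameters
#'
#' Routing weights are zero-mean Gaussian with sd 0.1; convolution and
#' dense weights use fan-in-scaled Gaussians (`sd = 1/sqrt(fan_in)`).
#'
#' @param cfg A [capsnet_config()].
#' @param seed Integer seed.
#' @return A `capsnet_params` list: `W1`, `b1` (conv), `W2`, `b2`
#'   (primary conv), `W` (routing tensor, dim `mi_dim x primary_dim x
#'   n_primary x n_classes`), and decoder weights `Wd1`..`bd3`.
#' @export
capsnet_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "capsnet_config"))
  set.seed(as.integer(seed))
  C <- cfg$image_dim[1]
  K1 <- 3 * 3 * C
  K2 <- 3 * 3 * cfg$conv_channels
  F2 <- cfg$primary_channels * cfg$primary_dim
  gmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  p <- list(
    W1 = gmat(K1, cfg$conv_channels, 1 / sqrt(K1)),
    b1 = numeric(cfg$conv_channels),
    W2 = gmat(K2, F2, 1 / sqrt(K2)),
    b2 = numeric(F2),
    W = array(stats::rnorm(cfg$mi_dim * cfg$primary_dim * cfg$n_primary *
                             cfg$n_classes, sd = 0.1),
              dim = c(cfg$mi_dim, cfg$primary_dim, cfg$n_primary,
                      cfg$n_classes)))
  d <- cfg$decoder_sizes
  din <- cfg$n_classes * cfg$mi_dim
  p$Wd1 <- gmat(d[1], din, 1 / sqrt(din)); p$bd1 <- numeric(d[1])
  p$Wd2 <- gmat(d[2], d[1], 1 / sqrt(d[1])); p$bd2 <- numeric(d[2])
  p$Wd3 <- gmat(d[3], d[2], 1 / sqrt(d[2])); p$bd3 <- numeric(d[3])
  structure(p, class = "capsnet_params")
}

#' Squash non-linearity
#'
#' Maps a capsule's raw vector `s` to `v = (||s||^2 / (1 + ||s||^2)) *
#' s / ||s||`, preserving direction while compressing the norm into
#' \[0, 1); `squash(0) = 0` by continuous extension.
#'
#' @param s Numeric vector.
#' @return Vector of the same length with `||v|| < 1`.
#' @export
#' @examples
#' sqrt(sum(squash(c(1, 0))^2))  # 0.5
squash <- function(s) {
  drop(squash_cols(matrix(s, ncol = 1)))
}

#' Routing softmax for one input capsule's coupling logits
#'
#' `c_ij = exp(b_ij) / sum_k exp(b_ik)`, max-stabilized; the coupling
#' coefficients of each input capsule sum to one across classes.
#'
#' @param b_row Numeric vector of per-class logits.
#' @return Probability vector of the same length.
#' @export
coupling_softmax <- function(b_row) {
  e <- exp(b_row - max(b_row))
  e / sum(e)
}

#' Prediction vectors from primary capsule outputs
#'
#' Computes `u_hat[j|i] = W[i,j] %*% u[i]` for every (input capsule i,
#' class j) pair.
#'
#' @param u Matrix `n_primary x primary_dim` of capsule outputs.
#' @param W Routing tensor, dim `mi_dim x primary_dim x n_primary x
#'   n_classes`.
#' @return Array `n_primary x n_classes x mi_dim`.
#' @export
prediction_vectors <- function(u, W) {
  dW <- dim(W)
  if (length(dW) != 4 || dW[2] != ncol(u) || dW[3] != nrow(u))
    stop("shapes of `u` and `W` are inconsistent", call. = FALSE)
  N <- nrow(u); J <- dW[4]; D <- dW[1]
  out <- array(0, dim = c(N, J, D))
  for (j in seq_len(J))
    for (k in seq_len(ncol(u)))
      out[, j, ] <- out[, j, ] + u[, k] * t(W[, k, , j])
  out
}

#' Dynamic routing by agreement
#'
#' Runs the routing loop: starting from zero logits, repeat `r` times —
#' couplings `c = softmax(b)` per input capsule, weighted sums
#' `s_j = sum_i c_ij u_hat[j|i]`, outputs `v_j = squash(s_j)`, and logit
#' updates `b_ij <- b_ij + u_hat[j|i] . v_j`. Returns the outputs of the
#' final iteration.
#'
#' @param u_hat Array `n_primary x n_classes x mi_dim` of prediction
#'   vectors.
#' @param r Number of routing iterations (>= 1).
#' @return List with `v` (`n_classes x mi_dim`), `c` (`n_primary x
#'   n_classes` couplings of the final iteration) and `b` (final logits).
#' @export
dynamic_routing <- function(u_hat, r = 1) {
  if (r < 1) stop("`r` must be >= 1", call. = FALSE)
  N <- dim(u_hat)[1]; J <- dim(u_hat)[2]; D <- dim(u_hat)[3]
  b <- matrix(0, N, J)
  v <- matrix(0, J, D)
  cc <- matrix(0, N, J)
  for (it in seq_len(r)) {
    cc <- softmax_rows(b)
    for (j in seq_len(J)) {
      s <- colSums(cc[, j] * matrix(u_hat[, j, ], N, D))
      v[j, ] <- squash(s)
    }
    for (j in seq_len(J))
      b[, j] <- b[, j] + matrix(u_hat[, j, ], N, D) %*% v[j, ]
  }
  list(v = v, c = cc, b = b)
}

#' Margin loss on class-capsule norms
#'
#' `L_k = T_k max(0, m+ - ||v_k||)^2 +
#'  lambda (1 - T_k) max(0, ||v_k|| - m-)^2`, summed over classes.
#'
#' @param class_norms Numeric vector of capsule norms, in \[0, 1).
#' @param target One-hot vector (or single 0-based class index).
#' @param cfg A [capsnet_config()].
#' @return Non-negative scalar.
#' @export
#' @examples
#' margin_loss(c(0.5, 0.5), c(0, 1), capsnet_config())  # 0.24
margin_loss <- function(class_norms, target, cfg = capsnet_config()) {
  if (length(target) == 1)
    target <- as.numeric(seq_along(class_norms) - 1 == target)
  if (sum(target == 1) != 1 || any(!target %in% c(0, 1)))
    stop("`target` must be one-hot", call. = FALSE)
  sum(target * pmax(0, cfg$m_plus - class_norms)^2 +
        cfg$lambda_margin * (1 - target) *
          pmax(0, class_norms - cfg$m_minus)^2)
}

#' Total loss: margin plus weighted reconstruction error
#'
#' @param margin Margin loss (scalar >= 0).
#' @param reconstruction_sse Sum of squared pixel differences between the
#'   decoder output and the input image.
#' @param cfg A [capsnet_config()].
#' @return `margin + lambda_rec * reconstruction_sse`, or `margin` alone
#'   when reconstruction is disabled.
#' @export
total_loss <- function(margin, reconstruction_sse = 0, cfg = capsnet_config()) {
  stopifnot(margin >= 0, reconstruction_sse >= 0)
  if (!cfg$reconstruction) return(margin)
  margin + cfg$lambda_rec * reconstruction_sse
}

#' Predicted class from capsule norms
#'
#' Argmax of the class-capsule norms; ties break toward the lower index.
#'
#' @param class_norms Numeric vector of norms.
#' @return 0-based class index (0 = left, 1 = right).
#' @export
predict_class <- function(class_norms) {
  which.max(class_norms) - 1L
}

#' Reconstruct the input image from the class capsules
#'
#' The class capsules are concatenated with all non-selected capsules
#' zeroed (masking), then passed through the three fully connected
#' decoder layers (rectifier on the hidden layers, logistic on the output
#' so pixels lie in (0, 1)).
#'
#' @param v Matrix `n_classes x mi_dim` of class capsules.
#' @param label_mask One-hot vector (or single 0-based class index)
#'   selecting the capsule to reconstruct from.
#' @param params A `capsnet_params`.
#' @return Numeric vector of pixel values in (0, 1), length 588 with the
#'   default architecture.
#' @export
decoder_reconstruct <- function(v, label_mask, params) {
  J <- nrow(v)
  if (length(label_mask) == 1)
    label_mask <- as.numeric(seq_len(J) - 1 == label_mask)
  if (sum(label_mask == 1) != 1 || any(!label_mask %in% c(0, 1)))
    stop("`label_mask` must be one-hot", call. = FALSE)
  m <- as.vector(t(v * label_mask))     # class-major concatenation
  a1 <- relu(drop(params$Wd1 %*% m) + params$bd1)
  a2 <- relu(drop(params$Wd2 %*% a1) + params$bd2)
  sigmoid(drop(params$Wd3 %*% a2) + params$bd3)
}

#' Full forward pass of the capsule network on one image
#'
#' @param image An `mi_image` (or bare 3 x 14 x 14 array in \[0, 1\]).
#' @param params A `capsnet_params` from [capsnet_init()] or training.
#' @param cfg The matching [capsnet_config()].
#' @param label_mask Optional 0-based class index or one-hot vector used
#'   to mask the decoder; defaults to the predicted class.
#' @return List with `class_norms` (per-class capsule norms),
#'   `prediction` (0-based class), `v` (`n_classes x mi_dim`),
#'   `reconstruction` (pixel vector, `NULL` when reconstruction is
#'   disabled) and `state` (per-pass routing quantities `u`, `u_hat`,
#'   `b`, `c`, `s`, `v`, `a`).
#' @export
capsnet_forward <- function(image, params, cfg = capsnet_config(),
                            label_mask = NULL) {
  img <- unclass(image)
  if (!identical(dim(img), cfg$image_dim))
    stop(sprintf("image must be %s", paste(cfg$image_dim, collapse = " x ")),
         call. = FALSE)
  X <- matrix(as.vector(aperm(img, c(2, 3, 1))), ncol = 1)
  fw <- caps_forward_batch(params, cfg, X, labels = NULL, train = FALSE,
                           keep_state = TRUE)
  norms <- drop(fw$vnorm)
  pred <- predict_class(norms)
  recon <- NULL
  if (cfg$reconstruction) {
    mask <- if (is.null(label_mask)) pred else label_mask
    recon <- decoder_reconstruct(fw$state$v, mask, params)
  }
  list(class_norms = norms, prediction = pred, v = fw$state$v,
       reconstruction = recon, state = fw$state)
}
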