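## Independent oracles used across the suite. These are deliberately
## written as plain, unvectorized loops straight from the definitions so
## they share no code path with the package implementation.

## dynamic routing by agreement: straight-loop reference
## u_hat: array (N, J, D); returns list(v = J x D, c = N x J, b = N x J)
oracle_routing <- function(u_hat, r) {
  N <- dim(u_hat)[1]; J <- dim(u_hat)[2]; D <- dim(u_hat)[3]
  b <- matrix(0, N, J)
  v <- matrix(0, J, D)
  cc <- matrix(0, N, J)
  for (it in seq_len(r)) {
    for (i in seq_len(N)) {
      e <- exp(b[i, ] - max(b[i, ]))
      cc[i, ] <- e / sum(e)
    }
    for (j in seq_len(J)) {
      s <- rep(0, D)
      for (i in seq_len(N)) s <- s + cc[i, j] * u_hat[i, j, ]
      ns <- sqrt(sum(s^2))
      v[j, ] <- if (ns > 0) (ns^2 / (1 + ns^2)) * s / ns else rep(0, D)
    }
    for (i in seq_len(N))
      for (j in seq_len(J))
        b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
  }
  list(v = v, c = cc, b = b)
}

## dense DFT magnitude of one tapered frame (definition-level loop)
oracle_dft_mag <- function(x) {
  n <- length(x)
  sapply(0:(n %/% 2), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  })
}

## periodic Hann taper, matching the documented STFT convention
oracle_hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

## finite-difference gradient of a scalar function of one parameter entry
fd_grad <- function(loss_fn, params, nm, i, h = 1e-5) {
  p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
  p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - h
  (loss_fn(p2) - loss_fn(p3)) / (2 * h)
}

## small strong-effect image fixture shared by training tests
make_image_fixture <- function(n_per_class, seed, erd_depth = 0.8,
                               noise_sd = 0.3) {
  cfg <- synth_config(erd_depth = erd_depth, noise_sd = noise_sd)
  ts <- synthesize_dataset(cfg, n_per_class, seed = seed)
  epochs_to_images(build_epochset(ts))
}
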