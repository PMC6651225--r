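test_that("selu matches its closed form and limits", {
  expect_equal(selu(0), 0)
  expect_equal(selu(2), 2 * 1.0507)
  expect_equal(selu(-1e4), -1.0507 * 1.6733, tolerance = 1e-12)
  x <- c(-3, -0.5, 0.7, 4)
  expect_equal(selu(x),
               ifelse(x > 0, 1.0507 * x, 1.0507 * 1.6733 * (exp(x) - 1)))
})

test_that("squash compresses norms into [0,1) and preserves direction", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v1 <- squash(c(1, 0))
  expect_equal(sqrt(sum(v1^2)), 0.5)
  s <- c(3, 0, 0)
  v3 <- squash(s)
  expect_equal(sqrt(sum(v3^2)), 0.9)
  expect_equal(v3 / sqrt(sum(v3^2)), s / 3)  # parallel
  ## norm strictly increasing in the input norm, always < 1
  norms <- sapply(c(0.1, 0.5, 1, 2, 5, 50), function(r)
    sqrt(sum(squash(c(r, 0))^2)))
  expect_true(all(diff(norms) > 0))
  expect_true(all(norms < 1))
})

test_that("coupling softmax reproduces closed forms and sums to one", {
  expect_equal(coupling_softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(coupling_softmax(c(log(2), 0)), c(2/3, 1/3))
  set.seed(1)
  for (i in 1:5) {
    cs <- coupling_softmax(rnorm(4, sd = 5))
    expect_equal(sum(cs), 1)
    expect_true(all(cs > 0 & cs < 1))
  }
  expect_equal(coupling_softmax(c(1000, 1000)), c(0.5, 0.5))  # stabilized
})

test_that("prediction vectors equal the per-pair matrix products", {
  set.seed(2)
  N <- 5; q <- 3; D <- 4; J <- 2
  u <- matrix(rnorm(N * q), N, q)
  W <- array(rnorm(D * q * N * J), dim = c(D, q, N, J))
  uh <- prediction_vectors(u, W)
  expect_equal(dim(uh), c(N, J, D))
  for (i in seq_len(N))
    for (j in seq_len(J))
      expect_equal(uh[i, j, ], drop(W[, , i, j] %*% u[i, ]), tolerance = 1e-12)
  ## identity weights copy the inputs; zero weights give zeros
  Wid <- array(0, dim = c(q, q, N, J))
  for (i in seq_len(N)) for (j in seq_len(J)) Wid[, , i, j] <- diag(q)
  uh_id <- prediction_vectors(u, Wid)
  for (j in seq_len(J)) expect_equal(uh_id[, j, ], u)
  expect_true(all(prediction_vectors(u, W * 0) == 0))
  expect_error(prediction_vectors(matrix(0, 4, 2), W), "inconsistent")
})

test_that("one routing iteration reduces to uniform coupling", {
  set.seed(3)
  N <- 6; J <- 2; D <- 3
  uh <- array(rnorm(N * J * D), dim = c(N, J, D))
  out <- dynamic_routing(uh, r = 1)
  for (j in seq_len(J)) {
    s <- colSums(uh[, j, ]) / J         # softmax of zeros = 1/J
    expect_equal(out$v[j, ], squash(s), tolerance = 1e-12)
  }
  expect_true(all(abs(out$c - 1 / J) < 1e-12))
  expect_error(dynamic_routing(uh, r = 0), "r")
})

test_that("vectorized routing matches the straight-loop oracle to 1e-10", {
  set.seed(4)
  for (case in 1:6) {
    N <- sample(2:10, 1); J <- 2; D <- sample(2:4, 1)
    r <- sample(1:3, 1)
    uh <- array(rnorm(N * J * D), dim = c(N, J, D))
    got <- dynamic_routing(uh, r)
    want <- oracle_routing(uh, r)
    expect_equal(got$v, want$v, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    ## coupling conservation per input capsule
    expect_equal(rowSums(got$c), rep(1, N), tolerance = 1e-6)
    ## output capsules stay strictly inside the unit ball
    expect_true(all(sqrt(rowSums(got$v^2)) < 1))
  }
})

test_that("agreement routing favors the stronger coherent prediction", {
  set.seed(5)
  N <- 4; D <- 3
  u1 <- c(2, 0, 0); u2 <- c(0, 0.4, 0)   # class 1 predictions much longer
  uh <- array(0, dim = c(N, 2, D))
  for (i in seq_len(N)) { uh[i, 1, ] <- u1; uh[i, 2, ] <- u2 }
  out <- dynamic_routing(uh, r = 3)
  expect_true(all(out$c[, 1] > out$c[, 2]))
})

test_that("routing is equivariant under permutation of input capsules", {
  set.seed(6)
  N <- 8; J <- 2; D <- 4
  uh <- array(rnorm(N * J * D), dim = c(N, J, D))
  perm <- sample(N)
  out1 <- dynamic_routing(uh, r = 3)
  out2 <- dynamic_routing(uh[perm, , , drop = FALSE], r = 3)
  expect_equal(out2$v, out1$v, tolerance = 1e-12)
  expect_equal(out2$c, out1$c[perm, ], tolerance = 1e-12)
})

test_that("margin loss reproduces hand values and is monotone", {
  cfg <- capsnet_config()
  expect_equal(margin_loss(c(0.95, 0.05), c(1, 0), cfg), 0)
  expect_equal(margin_loss(c(0.5, 0.5), c(0, 1), cfg),
               (0.9 - 0.5)^2 + 0.5 * (0.5 - 0.1)^2)  # 0.24
  ## non-increasing in the target norm, non-decreasing in the other
  l_target <- sapply(seq(0, 0.9, 0.1), function(v)
    margin_loss(c(v, 0.3), c(1, 0), cfg))
  expect_true(all(diff(l_target) <= 0))
  l_other <- sapply(seq(0, 0.9, 0.1), function(v)
    margin_loss(c(0.8, v), c(1, 0), cfg))
  expect_true(all(diff(l_other) >= 0))
  expect_error(margin_loss(c(0.5, 0.5), c(1, 1), cfg), "one-hot")
})

test_that("total loss adds the weighted reconstruction error", {
  cfg <- capsnet_config()
  expect_equal(total_loss(0.24, 100, cfg), 0.29)
  expect_equal(total_loss(0.24, 0, cfg), 0.24)
  cfg_off <- capsnet_config(reconstruction = FALSE)
  expect_equal(total_loss(0.24, 100, cfg_off), 0.24)
})

test_that("prediction takes the argmax with lower-index ties", {
  expect_equal(predict_class(c(0.9, 0.1)), 0L)
  expect_equal(predict_class(c(0.1, 0.9)), 1L)
  expect_equal(predict_class(c(0.5, 0.5)), 0L)
})

test_that("forward pass has the documented shapes and zero propagation", {
  cfg <- capsnet_config()
  expect_equal(cfg$conv_out, 12L)       # 14 - 3 + 1
  expect_equal(cfg$primary_grid, 5L)    # floor((12 - 3)/2) + 1
  expect_equal(cfg$n_primary, 3200L)

  params <- capsnet_init(cfg, seed = 1)
  img <- array(runif(588), dim = c(3, 14, 14))
  out <- capsnet_forward(img, params, cfg)
  expect_length(out$class_norms, 2)
  expect_true(all(out$class_norms >= 0 & out$class_norms < 1))
  expect_equal(dim(out$v), c(2, 8))
  expect_length(out$reconstruction, 588)
  expect_true(all(out$reconstruction > 0 & out$reconstruction < 1))
  ## routing state invariants
  st <- out$state
  expect_equal(dim(st$u), c(3200, 4))
  expect_equal(dim(st$u_hat), c(3200, 2, 8))
  expect_equal(rowSums(st$c), rep(1, 3200), tolerance = 1e-6)
  expect_true(all(sqrt(rowSums(st$v^2)) < 1))

  ## all-zero image with zero biases gives zero class norms
  out0 <- capsnet_forward(array(0, dim = c(3, 14, 14)), params, cfg)
  expect_equal(out0$class_norms, c(0, 0))

  expect_error(capsnet_forward(array(0, dim = c(3, 10, 10)), params, cfg),
               "14")
})

test_that("decoder masking silences the non-selected capsule", {
  cfg <- capsnet_config()
  params <- capsnet_init(cfg, seed = 2)
  set.seed(7)
  v <- matrix(rnorm(16, sd = 0.3), 2, 8)
  r1 <- decoder_reconstruct(v, 0L, params)
  v_mod <- v; v_mod[2, ] <- rnorm(8)    # perturb the masked capsule
  r2 <- decoder_reconstruct(v_mod, 0L, params)
  expect_identical(r1, r2)
  r3 <- decoder_reconstruct(v, 1L, params)
  expect_false(identical(r1, r3))
  expect_length(r1, 588)
  expect_true(all(r1 > 0 & r1 < 1))
  expect_error(decoder_reconstruct(v, c(1, 1), params), "one-hot")
})

test_that("analytic gradients of the total loss pass finite differences", {
  ## compact architecture, 3 routing iterations, reconstruction on: every
  ## gradient path (conv, squash, routing unroll, margin, decoder) active
  cfg <- capsnet_config(conv_channels = 3, primary_channels = 4,
                        primary_dim = 3, mi_dim = 4, routing_iters = 3,
                        decoder_sizes = c(16, 24, 588))
  params <- capsnet_init(cfg, seed = 42)
  set.seed(7)
  X <- matrix(runif(588 * 2), 588, 2)
  y <- c(0L, 1L)
  maps <- micaps:::caps_maps(cfg)
  fw <- micaps:::caps_forward_batch(params, cfg, X, labels = y, train = TRUE,
                                    maps = maps)
  grads <- micaps:::caps_backward_batch(fw, y, cfg, params)
  loss_fn <- function(p) {
    f <- micaps:::caps_forward_batch(p, cfg, X, labels = y, train = TRUE,
                                     maps = maps)
    micaps:::caps_batch_loss(f, y, cfg)$total
  }
  set.seed(11)
  for (nm in c("W1", "b1", "W2", "b2", "W", "Wd1", "bd1", "Wd2", "Wd3")) {
    for (k in 1:3) {
      i <- sample(length(params[[nm]]), 1)
      num <- fd_grad(loss_fn, params, nm, i)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
    }
  }
})

test_that("checkpoints round-trip configuration and weights", {
  im <- make_image_fixture(2, seed = 30)
  cfg <- capsnet_config(conv_channels = 2, primary_channels = 2,
                        primary_dim = 2, mi_dim = 2,
                        decoder_sizes = c(8, 8, 588))
  m <- train_model(im, model_cfg = cfg,
                   train_cfg = train_config(epochs = 1, batch_size = 4,
                                            seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  expect_equal(back$model_cfg$primary_dim, 2)
  expect_equal(back$history$train_loss, m$history$train_loss)
  ## reloaded model predicts identically
  expect_equal(predict(back, im), predict(m, im))
})
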