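#' Training configuration
#'
#' Mini-batch stochastic gradient descent with classical (heavy-ball)
#' momentum on the model's total loss. Defaults follow the reference
#' training protocol: batches of 50, learning rate 0.01, momentum 0.7,
#' 500 epochs. All arithmetic is 64-bit; with a fixed seed single-threaded
#' runs are bit-reproducible.
#'
#' @param batch_size Mini-batch size (the final short batch is used, not
#'   dropped).
#' @param epochs Number of passes over the training data.
#' @param learning_rate,momentum SGD hyperparameters.
#' @param seed Integer seed driving initialization, per-epoch shuffling
#'   and dropout.
#' @param early_stopping Enable validation-based early stopping?
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping.
#' @param validation_fraction Fraction of the training trials (the last
#'   ones, stratified by label) held out for validation when early
#'   stopping is on.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 50, epochs = 500,
                         learning_rate = 0.01, momentum = 0.7,
                         seed = 1L, early_stopping = FALSE,
                         patience = 10, validation_fraction = 0.2) {
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (early_stopping &&
      (validation_fraction <= 0 || validation_fraction >= 1))
    stop("`validation_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed),
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

## -- architecture engines ---------------------------------------------

engine_for <- function(model_cfg) {
  if (inherits(model_cfg, "capsnet_config")) {
    maps <- NULL
    list(
      arch = "capsnet",
      init = function(seed) capsnet_init(model_cfg, seed),
      grad = function(params, X, y) {
        if (is.null(maps)) maps <<- caps_maps(model_cfg)
        fw <- caps_forward_batch(params, model_cfg, X, labels = y,
                                 train = TRUE, maps = maps)
        loss <- caps_batch_loss(fw, y, model_cfg)
        pred <- max.col(t(fw$vnorm), ties.method = "first") - 1L
        list(loss = loss$total, acc = mean(pred == y),
             grads = caps_backward_batch(fw, y, model_cfg, params),
             params = params)
      },
      eval = function(params, X, y) {
        if (is.null(maps)) maps <<- caps_maps(model_cfg)
        fw <- caps_forward_batch(params, model_cfg, X, labels = y,
                                 train = FALSE, maps = maps)
        loss <- caps_batch_loss(fw, y, model_cfg)
        pred <- max.col(t(fw$vnorm), ties.method = "first") - 1L
        list(loss = loss$total, acc = mean(pred == y), pred = pred)
      })
  } else if (inherits(model_cfg, "shallownet_config")) {
    list(
      arch = "shallownet",
      init = function(seed) shallownet_init(model_cfg, seed),
      grad = function(params, X, y) {
        fw <- shallownet_forward_batch(params, model_cfg, X, train = TRUE)
        loss <- shallownet_batch_loss(fw, y)
        pred <- max.col(t(fw$probs), ties.method = "first") - 1L
        grads <- shallownet_backward_batch(fw, y, model_cfg, params)
        mom <- model_cfg$bn_momentum
        params$run_mean <- (1 - mom) * params$run_mean + mom * fw$mu
        params$run_var <- (1 - mom) * params$run_var + mom * fw$va
        list(loss = loss, acc = mean(pred == y), grads = grads,
             params = params)
      },
      eval = function(params, X, y) {
        fw <- shallownet_forward_batch(params, model_cfg, X, train = FALSE)
        pred <- max.col(t(fw$probs), ties.method = "first") - 1L
        list(loss = shallownet_batch_loss(fw, y),
             acc = mean(pred == y), pred = pred)
      })
  } else stop("unknown model configuration", call. = FALSE)
}

## coerce supported containers to (features x n, labels)
as_training_matrix <- function(x, model_cfg) {
  if (inherits(x, "image_set")) {
    list(X = imageset_matrix(x), y = x$labels)
  } else if (inherits(x, "epoch_set")) {
    n <- dim(x$data)[1]
    X <- matrix(0, dim(x$data)[2] * dim(x$data)[3], n)
    for (i in seq_len(n)) X[, i] <- as.vector(x$data[i, , ])
    list(X = X, y = x$labels)
  } else if (is.matrix(x)) {
    list(X = x, y = NULL)
  } else stop("`x` must be an image_set, epoch_set or feature matrix",
              call. = FALSE)
}

#' Train a model with mini-batch momentum SGD
#'
#' Trains either the capsule network (on an `image_set`) or the
#' ShallowNet baseline (on an `epoch_set`), depending on the class of
#' `model_cfg`. Data are reshuffled every epoch; parameters are updated
#' with classical momentum. With early stopping enabled, the last
#' `validation_fraction` of trials per class is held out, validation loss
#' is monitored with [early_stop_monitor()], and the best-validation
#' parameters are returned; otherwise the final-epoch parameters are
#' returned.
#'
#' @param x An `image_set`, `epoch_set`, or features x n matrix.
#' @param y Integer labels (0 = left, 1 = right); taken from `x` when it
#'   is a data set object.
#' @param model_cfg A [capsnet_config()] or [shallownet_config()].
#' @param train_cfg A [train_config()].
#' @return An `mi_model`: list with `params`, `model_cfg`, `train_cfg`,
#'   `arch`, `history` (one row per completed epoch: train/validation
#'   loss and accuracy) and, with early stopping, `best_epoch`.
#' @export
train_model <- function(x, y = NULL, model_cfg, train_cfg = train_config()) {
  stopifnot(inherits(train_cfg, "train_config"))
  dat <- as_training_matrix(x, model_cfg)
  X <- dat$X
  if (is.null(y)) y <- dat$y
  if (is.null(y) || length(y) != ncol(X))
    stop("labels are missing or do not match the data", call. = FALSE)
  y <- as.integer(y)
  n <- ncol(X)
  if (n < 1) stop("empty training set", call. = FALSE)

  ## validation split: last fraction per class, order preserved
  Xv <- NULL; yv <- NULL
  if (train_cfg$early_stopping) {
    idx_val <- unlist(lapply(unique(y), function(cl) {
      ids <- which(y == cl)
      k <- max(1L, floor(length(ids) * train_cfg$validation_fraction))
      utils::tail(ids, k)
    }))
    idx_val <- sort(idx_val)
    Xv <- X[, idx_val, drop = FALSE]; yv <- y[idx_val]
    X <- X[, -idx_val, drop = FALSE]; y <- y[-idx_val]
    n <- ncol(X)
    if (n < 1) stop("no training data left after validation split",
                    call. = FALSE)
  }

  eng <- engine_for(model_cfg)
  set.seed(train_cfg$seed)
  params <- eng$init(seed = sample.int(.Machine$integer.max - 1L, 1))
  vel <- NULL
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best <- list(loss = Inf, epoch = 0L, params = params)

  for (ep in seq_len(train_cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq.int(1L, n, by = train_cfg$batch_size)
    ep_loss <- 0; ep_correct <- 0
    for (s in starts) {
      ids <- perm[s:min(s + train_cfg$batch_size - 1L, n)]
      g <- eng$grad(params, X[, ids, drop = FALSE], y[ids])
      if (!is.finite(g$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
             call. = FALSE)
      params <- g$params                 # running statistics updates
      if (is.null(vel)) vel <- lapply(g$grads, function(gr) gr * 0)
      for (nm in names(g$grads)) {
        vel[[nm]] <- train_cfg$momentum * vel[[nm]] -
          train_cfg$learning_rate * g$grads[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
      ep_loss <- ep_loss + g$loss * length(ids)
      ep_correct <- ep_correct + g$acc * length(ids)
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                      train_acc = ep_correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(Xv)) {
      ev <- eng$eval(params, Xv, yv)
      row$val_loss <- ev$loss; row$val_acc <- ev$acc
      if (ev$loss < best$loss)
        best <- list(loss = ev$loss, epoch = ep, params = params)
    }
    hist <- rbind(hist, row)
    if (train_cfg$early_stopping) {
      mon <- early_stop_monitor(hist$val_loss, train_cfg$patience)
      if (mon$stop) break
    }
  }

  out <- list(params = params, model_cfg = model_cfg,
              train_cfg = train_cfg, arch = eng$arch, history = hist)
  if (train_cfg$early_stopping) {
    out$params <- best$params
    out$best_epoch <- best$epoch
  }
  structure(out, class = "mi_model")
}

#' @export
print.mi_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<mi_model> %s, %d epochs trained, final train loss %.4f, train acc %.3f\n",
              x$arch, nrow(h), h$train_loss[nrow(h)], h$train_acc[nrow(h)]))
  if (!is.null(x$best_epoch))
    cat(sprintf("  early stopping: best validation epoch %d\n", x$best_epoch))
  invisible(x)
}

#' Predict class labels
#'
#' @param object An `mi_model`.
#' @param newdata An `image_set` / `epoch_set` matching the architecture,
#'   or a features x n matrix.
#' @param ... Unused.
#' @return Integer vector of 0-based class labels (0 = left, 1 = right).
#' @export
predict.mi_model <- function(object, newdata, ...) {
  dat <- as_training_matrix(newdata, object$model_cfg)
  eng <- engine_for(object$model_cfg)
  y0 <- dat$y
  if (is.null(y0)) y0 <- integer(ncol(dat$X))
  eng$eval(object$params, dat$X, y0)$pred
}

#' Classification accuracy of a trained model
#'
#' Accuracy is `1 - misclassification rate`, with argmax ties broken
#' toward the lower class index.
#'
#' @param model An `mi_model`.
#' @param x Evaluation data (`image_set`, `epoch_set` or matrix).
#' @param y Labels; taken from `x` when it is a data set object.
#' @return Accuracy fraction in \[0, 1\].
#' @export
evaluate <- function(model, x, y = NULL) {
  dat <- as_training_matrix(x, model$model_cfg)
  if (is.null(y)) y <- dat$y
  if (is.null(y) || length(y) == 0) stop("empty evaluation set", call. = FALSE)
  eng <- engine_for(model$model_cfg)
  eng$eval(model$params, dat$X, as.integer(y))$acc
}

#' Early-stopping decision from a validation-loss trace
#'
#' Signals a stop when the validation loss has not strictly improved on
#' its running minimum for `patience` consecutive epochs. The best epoch
#' is the argmin of the trace (first occurrence).
#'
#' @param val_loss Numeric vector of per-epoch validation losses (or a
#'   history data frame with a `val_loss` column).
#' @param patience Consecutive non-improving epochs tolerated (>= 1).
#' @return List with `stop` (logical), `best_epoch`, and `wait` (current
#'   non-improvement streak).
#' @export
early_stop_monitor <- function(val_loss, patience) {
  if (is.data.frame(val_loss)) val_loss <- val_loss$val_loss
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  best <- Inf; best_epoch <- 0L; wait <- 0L; stop_now <- FALSE
  for (i in seq_along(val_loss)) {
    if (val_loss[i] < best) {
      best <- val_loss[i]; best_epoch <- i; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { stop_now <- TRUE; break }
    }
  }
  list(stop = stop_now, best_epoch = best_epoch, wait = wait)
}

#' Hyperparameter grid specification
#'
#' The full factorial search space over routing iterations,
#' reconstruction, and layer sizes explored for the capsule network.
#'
#' @param routing_iters,reconstruction,conv_channels,primary_channels,primary_dim,mi_dim
#'   Candidate values for each hyperparameter.
#' @return Object of class `grid_spec` (a data frame of grid points).
#' @export
grid_spec <- function(routing_iters = 1:3,
                      reconstruction = c(TRUE, FALSE),
                      conv_channels = c(256, 128, 64, 32, 16, 8, 4),
                      primary_channels = c(128, 64, 32, 16, 8, 4),
                      primary_dim = c(32, 16, 8, 4),
                      mi_dim = c(16, 8, 4)) {
  g <- expand.grid(routing_iters = routing_iters,
                   reconstruction = reconstruction,
                   conv_channels = conv_channels,
                   primary_channels = primary_channels,
                   primary_dim = primary_dim, mi_dim = mi_dim,
                   KEEP.OUT.ATTRS = FALSE)
  structure(g, class = c("grid_spec", "data.frame"))
}

#' Grid search over capsule-network configurations
#'
#' Trains and evaluates one model per grid point with a shared seed and
#' returns the result table sorted by decreasing test accuracy. Invalid
#' grid points are skipped with a warning and recorded with `NA`
#' accuracy.
#'
#' @param grid A [grid_spec()] (or data frame with its columns).
#' @param train_images,test_images `image_set`s for training/evaluation.
#' @param train_cfg A [train_config()] shared by all grid points.
#' @return Data frame: grid columns + `accuracy` + `status`, sorted by
#'   descending accuracy (NA rows last).
#' @export
grid_search <- function(grid, train_images, test_images,
                        train_cfg = train_config()) {
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  acc <- rep(NA_real_, nrow(grid))
  status <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      cfg <- capsnet_config(
        conv_channels = grid$conv_channels[i],
        primary_channels = grid$primary_channels[i],
        primary_dim = grid$primary_dim[i],
        mi_dim = grid$mi_dim[i],
        routing_iters = grid$routing_iters[i],
        reconstruction = grid$reconstruction[i])
      m <- train_model(train_images, model_cfg = cfg, train_cfg = train_cfg)
      list(acc = evaluate(m, test_images), status = "ok")
    }, error = function(e) {
      warning(sprintf("grid point %d skipped: %s", i, conditionMessage(e)),
              call. = FALSE)
      list(acc = NA_real_, status = conditionMessage(e))
    })
    acc[i] <- res$acc
    status[i] <- res$status
  }
  out <- cbind(as.data.frame(grid), accuracy = acc, status = status)
  out[order(-out$accuracy, na.last = TRUE), , drop = FALSE]
}

#' Signed effect of the reconstruction regularizer in a grid result
#'
#' Pairs grid-search rows that differ only in the `reconstruction` flag
#' and reports the signed accuracy difference (with minus without) per
#' matched configuration.
#'
#' @param results A data frame returned by [grid_search()].
#' @return Data frame with the shared configuration columns,
#'   `acc_with`, `acc_without` and `effect = acc_with - acc_without`.
#' @export
reconstruction_effect <- function(results) {
  keys <- c("routing_iters", "conv_channels", "primary_channels",
            "primary_dim", "mi_dim")
  on <- results[results$reconstruction %in% TRUE, , drop = FALSE]
  off <- results[results$reconstruction %in% FALSE, , drop = FALSE]
  merged <- merge(on[, c(keys, "accuracy")], off[, c(keys, "accuracy")],
                  by = keys, suffixes = c("_with", "_without"))
  if (nrow(merged) == 0) return(merged)
  names(merged)[names(merged) == "accuracy_with"] <- "acc_with"
  names(merged)[names(merged) == "accuracy_without"] <- "acc_without"
  merged$effect <- merged$acc_with - merged$acc_without
  merged
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding a schema version, the architecture name,
#' the configuration as JSON text, all weight arrays and the training
#' history.
#'
#' @param model An `mi_model`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mi_model"))
  saveRDS(list(schema = "micaps-model-v1", arch = model$arch,
               config_json = jsonlite::toJSON(unclass(model$model_cfg),
                                              auto_unbox = TRUE),
               config_class = class(model$model_cfg)[1],
               params = model$params, history = model$history,
               best_epoch = model$best_epoch,
               train_cfg = unclass(model$train_cfg)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "micaps-model-v1"))
    stop("not a micaps model checkpoint", call. = FALSE)
  cfg <- jsonlite::fromJSON(obj$config_json)
  cfg <- structure(cfg, class = obj$config_class)
  structure(list(params = obj$params, model_cfg = cfg,
                 train_cfg = structure(obj$train_cfg, class = "train_config"),
                 arch = obj$arch, history = obj$history,
                 best_epoch = obj$best_epoch),
            class = "mi_model")
}
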