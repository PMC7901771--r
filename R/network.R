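#' Model configuration
#'
#' Bundles every hyperparameter of the multi-channel convolutional
#' classifier. Parallel channels each apply a convolution whose filter
#' spans the full alphabet width (4 or 12 columns), so each filter is a
#' 1-D scan over sequence positions, followed by max pooling over
#' non-overlapping blocks of `pool_size` positions. The pooled maps are
#' flattened, concatenated across channels, and passed through a
#' 1024-unit ReLU layer, dropout, and a 2-unit softmax output (class
#' order: negative, positive). `pool_size = Inf` gives global
#' max-over-positions pooling (one value per filter).
#'
#' Defaults are the values selected for the human/mouse window sets by the
#' staged cross-validated grid search (batch 16, 50 epochs, 9 channels,
#' filter height 5, learning rate 5e-4, dropout 0.5); the number of
#' filters per channel (32) and the early-stopping patience (10 epochs)
#' are this package's documented defaults.
#'
#' @param input_rows window length, `2 * xi + 1`.
#' @param input_cols alphabet size: 4 (general) or 12 (merged-seq).
#' @param n_channels number of parallel convolution channels.
#' @param filter_heights filter height(s), recycled to `n_channels`; every
#'   height must lie in `[1, input_rows]`.
#' @param filters_per_channel convolution filters per channel.
#' @param pool_size max-pooling block length in positions (default 2);
#'   `Inf` pools globally. Blocks are non-overlapping and a trailing
#'   partial block is dropped; a channel whose convolution output is
#'   shorter than `pool_size` is pooled globally.
#' @param dense_units width of the first fully connected layer.
#' @param dropout_p dropout probability after the dense layer, in `[0, 1)`.
#' @param learning_rate Adam step size, positive.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation-loss improvement
#'   tolerated before stopping (best weights are restored).
#' @param seed integer seed controlling weight initialization, shuffling
#'   and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(input_rows, input_cols,
                         n_channels = 9L, filter_heights = 5L,
                         filters_per_channel = 32L, pool_size = 2,
                         dense_units = 1024L,
                         dropout_p = 0.5, learning_rate = 5e-4,
                         batch_size = 16L, max_epochs = 50L,
                         early_stop_patience = 10L, seed = 1L) {
  filter_heights <- rep_len(as.integer(filter_heights), n_channels)
  cfg <- list(
    input_rows = as.integer(input_rows), input_cols = as.integer(input_cols),
    n_channels = as.integer(n_channels), filter_heights = filter_heights,
    filters_per_channel = as.integer(filters_per_channel),
    pool_size = pool_size,
    dense_units = as.integer(dense_units), dropout_p = dropout_p,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    seed = as.integer(seed)
  )
  class(cfg) <- "model_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$filter_heights) != cfg$n_channels) {
    abort("filter_heights must supply one height per channel")
  }
  if (any(cfg$filter_heights < 1L | cfg$filter_heights > cfg$input_rows)) {
    abort(paste0("filter heights must lie in [1, ", cfg$input_rows,
                 "] (the window length)"))
  }
  if (!cfg$input_cols %in% c(4L, 12L)) {
    abort("input_cols must be 4 (general) or 12 (merged-seq encoding)")
  }
  if (cfg$dropout_p < 0 || cfg$dropout_p >= 1) {
    abort("dropout_p must lie in [0, 1)")
  }
  if (cfg$learning_rate <= 0) {
    abort("learning_rate must be positive")
  }
  if (!(is.infinite(cfg$pool_size) || cfg$pool_size >= 1)) {
    abort("pool_size must be a positive integer or Inf (global)")
  }
  invisible(cfg)
}

# pooled positions per channel: conv output length P_c = rows - h_c + 1,
# pooled into floor(P_c / pool) non-overlapping blocks (>= 1)
channel_geometry <- function(cfg) {
  P <- cfg$input_rows - cfg$filter_heights + 1L
  pool <- pmin(cfg$pool_size, P)
  Q <- pmax(1L, P %/% pool)
  list(P = P, pool = as.integer(pool), Q = as.integer(Q))
}

n_features <- function(cfg) {
  sum(channel_geometry(cfg)$Q) * cfg$filters_per_channel
}

#' Build an untrained multi-channel network
#'
#' Initializes weights for the graph
#' `input -> [conv(h_c x width, ReLU) -> max pool -> flatten] per channel
#' -> concatenate -> dense(1024, ReLU) -> dropout -> dense(2, softmax)`.
#' Convolution and first dense layer use He-normal initialization (ReLU
#' layers), the output layer Glorot-normal; all draws come from
#' `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @return An object of class `psi_cnn` holding the configuration and
#'   weight arrays; `trained` is `FALSE` until [train_cnn()] is run.
#' @export
build_model <- function(cfg) {
  validate_config(cfg)
  params <- withr::with_seed(cfg$seed, init_params(cfg))
  structure(
    list(config = cfg, params = params, trained = FALSE, history = NULL),
    class = "psi_cnn"
  )
}

init_params <- function(cfg) {
  C <- cfg$input_cols
  F_ <- cfg$filters_per_channel
  params <- list()
  for (ch in seq_len(cfg$n_channels)) {
    fanin <- cfg$filter_heights[ch] * C
    params[[paste0("convW", ch)]] <-
      matrix(stats::rnorm(fanin * F_, sd = sqrt(2 / fanin)), fanin, F_)
    params[[paste0("convb", ch)]] <- numeric(F_)
  }
  K <- n_features(cfg)
  params$W1 <- matrix(stats::rnorm(K * cfg$dense_units, sd = sqrt(2 / K)),
                      K, cfg$dense_units)
  params$b1 <- numeric(cfg$dense_units)
  params$W2 <- matrix(
    stats::rnorm(cfg$dense_units * 2, sd = sqrt(2 / (cfg$dense_units + 2))),
    cfg$dense_units, 2
  )
  params$b2 <- numeric(2)
  params
}

#' Count of trainable parameters per layer
#'
#' @param model a `psi_cnn`.
#' @return Tibble with one row per weight array: layer, shape, parameters.
#' @export
parameter_counts <- function(model) {
  p <- model$params
  tibble::tibble(
    layer = names(p),
    rows = vapply(p, function(w) if (is.matrix(w)) nrow(w) else length(w), 0L),
    cols = vapply(p, function(w) if (is.matrix(w)) ncol(w) else 1L, 0L),
    parameters = vapply(p, length, 0L)
  )
}

# im2col: n x R x C array -> (n*P) x (h*C) matrix, row (i-1)*P + p holds the
# flattened h x C patch of sample i starting at position p.
im2col <- function(x, h) {
  n <- dim(x)[1]; R <- dim(x)[2]; C <- dim(x)[3]
  P <- R - h + 1L
  out <- array(0, dim = c(n, P, h * C))
  for (dp in seq_len(h)) {
    out[, , ((dp - 1L) * C + 1L):(dp * C)] <- x[, dp:(dp + P - 1L), , drop = FALSE]
  }
  m <- matrix(aperm(out, c(2, 1, 3)), nrow = n * P)
  attr(m, "n") <- n
  attr(m, "P") <- P
  m
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass for a batch. cols: list of im2col matrices per UNIQUE height,
# already subset to the batch. Returns activations needed for backprop.
# Pooled feature layout: channels in order; within a channel, blocks of
# filters_per_channel per pooling window: column (w-1)*F + f.
cnn_forward <- function(params, cfg, cols, hmap, n, dropout_mask = NULL) {
  F_ <- cfg$filters_per_channel
  geo <- channel_geometry(cfg)
  pooled <- matrix(0, n, n_features(cfg))
  argmax <- vector("list", cfg$n_channels)
  offset <- 0L
  for (ch in seq_len(cfg$n_channels)) {
    M <- cols[[hmap[ch]]]
    P <- attr(M, "P")
    A <- relu(sweep(M %*% params[[paste0("convW", ch)]], 2,
                    params[[paste0("convb", ch)]], `+`))
    pool <- geo$pool[ch]
    Q <- geo$Q[ch]
    # blockwise max over positions with argmax tracking; A rows (i-1)*P + p
    am <- matrix(1L, n, Q * F_)
    for (w in seq_len(Q)) {
      p0 <- (w - 1L) * pool
      cur <- A[seq(p0 + 1L, n * P, by = P), , drop = FALSE]
      amw <- matrix(p0 + 1L, n, F_)
      if (pool > 1) {
        for (dp in 2:pool) {
          sl <- A[seq(p0 + dp, n * P, by = P), , drop = FALSE]
          upd <- sl > cur
          amw[upd] <- p0 + dp
          cur[upd] <- sl[upd]
        }
      }
      cols_w <- offset + (w - 1L) * F_ + seq_len(F_)
      pooled[, cols_w] <- cur
      am[, (w - 1L) * F_ + seq_len(F_)] <- amw
    }
    argmax[[ch]] <- am
    offset <- offset + Q * F_
  }
  pre1 <- sweep(pooled %*% params$W1, 2, params$b1, `+`)
  H <- relu(pre1)
  Hd <- if (is.null(dropout_mask)) H else H * dropout_mask
  logits <- sweep(Hd %*% params$W2, 2, params$b2, `+`)
  probs <- softmax_rows(logits)
  list(argmax = argmax, pooled = pooled, H = H, Hd = Hd, probs = probs)
}

# Gradients of mean categorical cross-entropy wrt every parameter.
cnn_backward <- function(params, cfg, cols, hmap, n, fwd, Y, dropout_mask) {
  F_ <- cfg$filters_per_channel
  g <- list()
  dlogits <- (fwd$probs - Y) / n
  g$W2 <- crossprod(fwd$Hd, dlogits)
  g$b2 <- colSums(dlogits)
  dHd <- dlogits %*% t(params$W2)
  dH <- if (is.null(dropout_mask)) dHd else dHd * dropout_mask
  dpre1 <- dH * (fwd$H > 0)
  g$W1 <- crossprod(fwd$pooled, dpre1)
  g$b1 <- colSums(dpre1)
  dpooled <- dpre1 %*% t(params$W1)
  geo <- channel_geometry(cfg)
  offset <- 0L
  for (ch in seq_len(cfg$n_channels)) {
    M <- cols[[hmap[ch]]]
    P <- attr(M, "P")
    QF <- geo$Q[ch] * F_
    idx <- offset + seq_len(QF)
    # route gradient to the argmax position; ReLU is already embedded in the
    # conv output, so a pooled max of 0 gets zero gradient
    dp <- dpooled[, idx, drop = FALSE] * (fwd$pooled[, idx, drop = FALSE] > 0)
    dA <- matrix(0, n * P, F_)
    am <- fwd$argmax[[ch]]                 # n x (Q*F), window-major blocks
    rows <- as.vector(am) + P * (rep(seq_len(n), times = QF) - 1L)
    filt <- rep(rep(seq_len(F_), each = n), times = geo$Q[ch])
    # pooling blocks are disjoint, so no (row, filter) cell is hit twice
    dA[cbind(rows, filt)] <- as.vector(dp)
    g[[paste0("convW", ch)]] <- crossprod(M, dA)
    g[[paste0("convb", ch)]] <- colSums(dA)
    offset <- offset + QF
  }
  g
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

one_hot_labels <- function(y) {
  Y <- matrix(0, length(y), 2)
  Y[cbind(seq_along(y), y + 1L)] <- 1   # column 1 = negative, 2 = positive
  Y
}

#' Train the multi-channel network
#'
#' Minimizes mean categorical cross-entropy with Adam, shuffled
#' minibatches, inverted dropout after the dense layer, and early stopping
#' on validation loss (patience from the configuration, best weights
#' restored). All randomness — shuffling and dropout — descends from the
#' configuration seed, so two runs with the same seed produce identical
#' histories.
#'
#' @param model an untrained or trained `psi_cnn` from [build_model()].
#' @param train list with `x` (n x rows x cols array) and `y` (0/1 labels),
#'   e.g. from [encode_dataset()].
#' @param validation like `train`; when `NULL`, a stratified
#'   `validation_split` fraction of `train` is held out.
#' @param validation_split fraction used when `validation` is `NULL`.
#' @return The trained `psi_cnn`, with `history` a tibble of per-epoch
#'   `loss`, `accuracy`, `val_loss`, `val_accuracy`.
#' @export
train_cnn <- function(model, train, validation = NULL, validation_split = 0.2) {
  cfg <- model$config
  check_shapes(train$x, cfg)
  if (length(train$y) == 0L) {
    abort("empty training set")
  }
  if (length(unique(train$y)) < 2L) {
    warn("training labels are all one class; the fit will be degenerate")
  }
  withr::with_seed(cfg$seed, {
    if (is.null(validation)) {
      hold <- stratified_holdout(train$y, validation_split)
      validation <- list(x = train$x[hold, , , drop = FALSE], y = train$y[hold])
      train <- list(x = train$x[-hold, , , drop = FALSE], y = train$y[-hold])
    } else {
      check_shapes(validation$x, cfg)
    }
    model <- train_loop(model, train, validation)
  })
  model
}

check_shapes <- function(x, cfg) {
  d <- dim(x)
  if (length(d) != 3L || d[2] != cfg$input_rows || d[3] != cfg$input_cols) {
    abort(paste0("input shape ", paste(d, collapse = "x"),
                 " does not match the configured ", cfg$input_rows, "x",
                 cfg$input_cols, " window"))
  }
}

stratified_holdout <- function(y, frac) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ii) {
    ii <- sample(ii)
    head(ii, max(1L, round(length(ii) * frac)))
  }), use.names = FALSE)
  sort(idx)
}

train_loop <- function(model, train, validation) {
  cfg <- model$config
  params <- model$params
  n <- length(train$y)
  heights <- unique(cfg$filter_heights)
  hmap <- match(cfg$filter_heights, heights)
  cols_all <- lapply(heights, function(h) im2col(train$x, h))
  cols_val <- lapply(heights, function(h) im2col(validation$x, h))
  Y <- one_hot_labels(train$y)
  Yval <- one_hot_labels(validation$y)
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    for (bi in seq_len(nb)) {
      take <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      nbatch <- length(take)
      cols_b <- lapply(cols_all, subset_im2col, idx = take)
      mask <- if (cfg$dropout_p > 0) {
        matrix(
          (runif(nbatch * cfg$dense_units) >= cfg$dropout_p) / (1 - cfg$dropout_p),
          nbatch, cfg$dense_units
        )
      }
      fwd <- cnn_forward(params, cfg, cols_b, hmap, nbatch, mask)
      grads <- cnn_backward(params, cfg, cols_b, hmap, nbatch, fwd,
                            Y[take, , drop = FALSE], mask)
      upd <- adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    tr <- evaluate_pass(params, cfg, cols_all, hmap, n, Y)
    va <- evaluate_pass(params, cfg, cols_val, hmap, length(validation$y), Yval)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = tr$loss, accuracy = tr$acc,
      val_loss = va$loss, val_accuracy = va$acc
    )
    if (va$loss < best$loss) {
      best <- list(loss = va$loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- dplyr::bind_rows(hist)
  model
}

subset_im2col <- function(M, idx) {
  P <- attr(M, "P")
  rows <- rep((idx - 1L) * P, each = P) + rep(seq_len(P), times = length(idx))
  out <- M[rows, , drop = FALSE]
  attr(out, "n") <- length(idx)
  attr(out, "P") <- P
  out
}

evaluate_pass <- function(params, cfg, cols, hmap, n, Y) {
  fwd <- cnn_forward(params, cfg, cols, hmap, n, dropout_mask = NULL)
  p <- pmax(fwd$probs, 1e-12)
  loss <- -mean(log(p[Y == 1]))
  acc <- mean(max.col(fwd$probs, ties.method = "last") == max.col(Y))
  list(loss = loss, acc = acc)
}

#' Predict class probabilities for encoded windows
#'
#' @param object a trained `psi_cnn`.
#' @param newdata a list with element `x` (from [encode_dataset()]) or a
#'   3-D array `n x rows x cols`.
#' @param ... unused.
#' @return Tibble with `p_negative`, `p_positive` (softmax outputs, summing
#'   to 1) and the hard `label` (argmax; an exact 0.5/0.5 tie resolves to
#'   the positive class).
#' @export
predict.psi_cnn <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  if (length(dim(x)) != 3L) {
    abort("newdata must be an n x rows x cols array (see encode_dataset)")
  }
  n <- dim(x)[1]
  if (n == 0L) {
    return(tibble::tibble(p_negative = numeric(), p_positive = numeric(),
                          label = integer()))
  }
  cfg <- object$config
  check_shapes(x, cfg)
  heights <- unique(cfg$filter_heights)
  hmap <- match(cfg$filter_heights, heights)
  cols <- lapply(heights, function(h) im2col(x, h))
  fwd <- cnn_forward(object$params, cfg, cols, hmap, n)
  tibble::tibble(
    p_negative = fwd$probs[, 1],
    p_positive = fwd$probs[, 2],
    label = as.integer(fwd$probs[, 2] >= fwd$probs[, 1])
  )
}

#' @export
print.psi_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<psi_cnn> ", cfg$n_channels, " channel(s), heights [",
      paste(cfg$filter_heights, collapse = ", "), "], ",
      cfg$filters_per_channel, " filters/channel, input ",
      cfg$input_rows, "x", cfg$input_cols, "\n", sep = "")
  cat(if (x$trained) {
    paste0("trained (best epoch ", x$best_epoch, ", val loss ",
           signif(min(x$history$val_loss), 4), ")\n")
  } else "untrained\n")
  invisible(x)
}

#' Tidy a fitted network
#'
#' `tidy()` returns per-layer parameter shapes and counts; `glance()`
#' returns a one-row summary of the fit.
#'
#' @param x a `psi_cnn`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy psi_cnn
#' @export
tidy.psi_cnn <- function(x, ...) {
  parameter_counts(x)
}

#' @rdname tidy.psi_cnn
#' @method glance psi_cnn
#' @export
glance.psi_cnn <- function(x, ...) {
  if (!x$trained) {
    return(tibble::tibble(
      trained = FALSE,
      parameters = sum(parameter_counts(x)$parameters)
    ))
  }
  last <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(
    trained = TRUE,
    parameters = sum(parameter_counts(x)$parameters),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    loss = last$loss, accuracy = last$accuracy,
    val_loss = last$val_loss, val_accuracy = last$val_accuracy
  )
}

#' Save or load a fitted model
#'
#' Serializes the configuration and weights to a single file.
#'
#' @param model a `psi_cnn`.
#' @param path archive path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `psi_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "psi_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "psi_cnn")) {
    abort("file does not contain a saved psi_cnn model")
  }
  model
}
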