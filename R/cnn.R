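#' Configuration for the 1D convolutional classifier
#'
#' The network is `Conv1D(f1,k1) -> BN -> ReLU -> Conv1D(f2,k2) -> BN ->
#' ReLU -> Conv1D(f3,k3) -> BN -> ReLU -> global average pooling ->
#' L2 normalisation -> dense softmax`, trained with Adam on categorical
#' cross-entropy for a fixed number of epochs (no early stopping).
#' Defaults follow the reference fully-convolutional baseline: feature
#' maps 128/256/128, kernels 8/5/3 with "same" padding, learning rate
#' 0.005, 50 epochs, batch size 32.
#'
#' @param n_channels Number of input channels `C` (set automatically at
#'   training time when `NA`).
#' @param n_classes Number of classes (default 7).
#' @param feature_maps Integer vector of three conv widths.
#' @param kernel_sizes Integer vector of three kernel sizes.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed RNG seed controlling initialisation and batch shuffling.
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(n_channels = NA_integer_, n_classes = 7L,
                       feature_maps = c(128L, 256L, 128L),
                       kernel_sizes = c(8L, 5L, 3L),
                       lr = 0.005, epochs = 50L, batch_size = 32L,
                       seed = 1L) {
  stopifnot(length(feature_maps) == 3L, length(kernel_sizes) == 3L,
            lr > 0, epochs >= 1, batch_size >= 2, n_classes >= 2)
  if (!is.na(n_channels) && n_channels <= 0)
    stop("config error: n_channels must be positive")
  structure(list(n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 feature_maps = as.integer(feature_maps),
                 kernel_sizes = as.integer(kernel_sizes),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

BN_EPS <- 1e-3       # variance floor inside batch norm
BN_MOMENTUM <- 0.9   # running-statistics update: r <- m*r + (1-m)*batch
L2_EPS <- 1e-12      # embedding normalisation floor
ADAM_B1 <- 0.9
ADAM_B2 <- 0.999
ADAM_EPS <- 1e-8

# ---- layer primitives --------------------------------------------------
# Batches are (C, W, N) arrays; convolutions use stride 1 and "same"
# zero padding (left pad = floor((k-1)/2)).

pad_same <- function(X, k) {
  d <- dim(X)
  pl <- (k - 1L) %/% 2L
  Xp <- array(0, dim = c(d[1], d[2] + k - 1L, d[3]))
  Xp[, (pl + 1L):(pl + d[2]), ] <- X
  Xp
}

# (C, Wp, N) padded array -> (C*k, W*N) matrix; column (n-1)*W + w holds
# the receptive field of output position w in window n, rows are
# tap-major blocks of C channels.
im2col <- function(Xp, k, W) {
  C <- dim(Xp)[1]; N <- dim(Xp)[3]
  out <- matrix(0, C * k, W * N)
  for (tau in seq_len(k))
    out[((tau - 1L) * C + 1L):(tau * C), ] <-
      Xp[, tau:(tau + W - 1L), , drop = FALSE]
  out
}

col2im <- function(dXc, C, k, W, N) {
  dXp <- array(0, dim = c(C, W + k - 1L, N))
  for (tau in seq_len(k)) {
    blk <- array(dXc[((tau - 1L) * C + 1L):(tau * C), ], dim = c(C, W, N))
    dXp[, tau:(tau + W - 1L), ] <- dXp[, tau:(tau + W - 1L), ] + blk
  }
  pl <- (k - 1L) %/% 2L
  dXp[, (pl + 1L):(pl + W), , drop = FALSE]
}

conv_forward <- function(X, Wm, k) {
  d <- dim(X)
  Xc <- im2col(pad_same(X, k), k, d[2])
  Z <- Wm %*% Xc
  list(Z = array(Z, dim = c(nrow(Wm), d[2], d[3])), Xc = Xc)
}

conv_backward <- function(dZ, Xc, Wm, C, k, W, N) {
  dZm <- matrix(dZ, nrow = dim(dZ)[1])
  list(dW = dZm %*% t(Xc),
       dX = col2im(crossprod(Wm, dZm), C, k, W, N))
}

bn_forward <- function(Z, gamma, beta, rmean, rvar, training) {
  d <- dim(Z)
  Zm <- matrix(Z, nrow = d[1])
  if (training) {
    mu <- rowMeans(Zm)
    v <- rowMeans(Zm * Zm) - mu^2
  } else {
    mu <- rmean; v <- rvar
  }
  inv <- 1 / sqrt(v + BN_EPS)
  Zhat <- (Zm - mu) * inv
  out <- gamma * Zhat + beta
  list(out = array(out, dim = d), Zhat = Zhat, inv = inv, mu = mu, v = v)
}

bn_backward <- function(dOut, cache, gamma) {
  d <- dim(dOut)
  dY <- matrix(dOut, nrow = d[1])
  m <- ncol(dY)
  Zhat <- cache$Zhat; inv <- cache$inv
  dgamma <- rowSums(dY * Zhat)
  dbeta <- rowSums(dY)
  dZhat <- dY * gamma
  dZ <- inv / m * (m * dZhat - rowSums(dZhat) -
                   Zhat * rowSums(dZhat * Zhat))
  list(dZ = array(dZ, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# ---- model -------------------------------------------------------------

#' Build an untrained 1D CNN
#'
#' Initialises the network weights (He-normal for convolutions,
#' Glorot-uniform for the dense layer) deterministically from
#' `config$seed`.
#'
#' @param config A [cnn_config()] with `n_channels` set.
#' @return Object of class `poseclass_cnn` (untrained).
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  if (is.na(config$n_channels) || config$n_channels <= 0)
    stop("config error: n_channels must be set to build the network")
  set.seed(config$seed)
  fm <- config$feature_maps
  ks <- config$kernel_sizes
  cin <- c(config$n_channels, fm[1], fm[2])
  params <- list()
  for (l in 1:3) {
    fan_in <- cin[l] * ks[l]
    params[[paste0("W", l)]] <-
      matrix(rnorm(fm[l] * fan_in, sd = sqrt(2 / fan_in)), fm[l], fan_in)
    params[[paste0("gamma", l)]] <- rep(1, fm[l])
    params[[paste0("beta", l)]] <- rep(0, fm[l])
  }
  lim <- sqrt(6 / (fm[3] + config$n_classes))
  params$Wd <- matrix(runif(config$n_classes * fm[3], -lim, lim),
                      config$n_classes, fm[3])
  params$bd <- rep(0, config$n_classes)
  running <- list()
  for (l in 1:3) {
    running[[paste0("mean", l)]] <- rep(0, fm[l])
    running[[paste0("var", l)]] <- rep(1, fm[l])
  }
  structure(list(kind = "cnn", config = config, params = params,
                 running = running, trained = FALSE, class_names = NULL,
                 channel_names = NULL, history = numeric(0)),
            class = "poseclass_cnn")
}

# Forward pass over a (C, W, N) batch. Returns probabilities, embeddings
# and (when training) the caches needed for the backward pass.
cnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  r <- model$running
  caches <- list()
  A <- X
  for (l in 1:3) {
    k <- cfg$kernel_sizes[l]
    cv <- conv_forward(A, p[[paste0("W", l)]], k)
    bn <- bn_forward(cv$Z, p[[paste0("gamma", l)]], p[[paste0("beta", l)]],
                     r[[paste0("mean", l)]], r[[paste0("var", l)]],
                     training)
    relu_mask <- bn$out > 0
    A_out <- bn$out * relu_mask
    if (training)
      caches[[l]] <- list(A_in = A, Xc = cv$Xc, bn = bn, mask = relu_mask,
                          k = k)
    A <- A_out
  }
  d <- dim(A)
  G <- matrix(0, d[1], d[3])
  for (n in seq_len(d[3])) G[, n] <- rowMeans(A[, , n, drop = FALSE])
  norms <- sqrt(colSums(G^2) + L2_EPS)
  Zn <- sweep(G, 2L, norms, "/")
  logits <- p$Wd %*% Zn + p$bd
  logits <- sweep(logits, 2L, apply(logits, 2L, max))
  expl <- exp(logits)
  P <- sweep(expl, 2L, colSums(expl), "/")
  list(P = P, embedding = Zn, G = G, norms = norms, caches = caches,
       width = d[2])
}

# Backward pass; y_idx are 1-based class indices for the batch.
cnn_backward <- function(model, fwd, y_idx) {
  cfg <- model$config
  p <- model$params
  N <- length(y_idx)
  Y <- matrix(0, cfg$n_classes, N)
  Y[cbind(y_idx, seq_len(N))] <- 1
  dlogits <- (fwd$P - Y) / N
  grads <- list(Wd = dlogits %*% t(fwd$embedding),
                bd = rowSums(dlogits))
  dZn <- crossprod(p$Wd, dlogits)
  # through L2 normalisation: dG = (dZn - Zn * <Zn, dZn>) / norm
  dots <- colSums(fwd$embedding * dZn)
  dG <- sweep(dZn - sweep(fwd$embedding, 2L, dots, "*"), 2L, fwd$norms, "/")
  # through global average pooling
  W <- fwd$width
  dA <- aperm(array(dG / W, dim = c(nrow(dG), N, W)), c(1L, 3L, 2L))
  for (l in 3:1) {
    cache <- fwd$caches[[l]]
    dA <- dA * cache$mask
    bnb <- bn_backward(dA, cache$bn, p[[paste0("gamma", l)]])
    grads[[paste0("gamma", l)]] <- bnb$dgamma
    grads[[paste0("beta", l)]] <- bnb$dbeta
    din <- dim(cache$A_in)
    cvb <- conv_backward(bnb$dZ, cache$Xc, p[[paste0("W", l)]],
                         din[1], cache$k, din[2], din[3])
    grads[[paste0("W", l)]] <- cvb$dW
    dA <- cvb$dX
  }
  grads
}

cnn_loss <- function(P, y_idx) {
  -mean(log(pmax(P[cbind(y_idx, seq_along(y_idx))], 1e-12)))
}

#' Train the 1D CNN
#'
#' Runs the fixed Adam training schedule (no early stopping) on a windowed
#' dataset or a raw `C x W x N` array. Batch-norm running statistics are
#' accumulated during training and used at prediction time. Training is
#' reproducible: the same `config$seed` yields the same initial weights,
#' shuffling order and final model.
#'
#' @param model A `poseclass_cnn` from [build_cnn()], or a [cnn_config()]
#'   (the network is then built on entry, inferring `n_channels` from the
#'   data).
#' @param data A `windowed_dataset` or a `C x W x N` array.
#' @param labels Per-window labels (taken from `data$labels` for a
#'   windowed dataset).
#' @param quiet Suppress the per-epoch loss message.
#' @return A trained `poseclass_cnn` with `history` holding the mean
#'   cross-entropy per epoch.
#' @export
train_cnn <- function(model, data, labels = NULL, quiet = TRUE) {
  if (inherits(data, "windowed_dataset")) {
    X <- data$X
    labels <- labels %||% data$labels
    channel_names <- data$channel_names
  } else {
    X <- data
    channel_names <- dimnames(X)[[1]]
  }
  if (inherits(model, "cnn_config")) {
    if (is.na(model$n_channels)) model$n_channels <- dim(X)[1]
    model <- build_cnn(model)
  }
  stopifnot(inherits(model, "poseclass_cnn"))
  cfg <- model$config
  if (dim(X)[1] != cfg$n_channels)
    stop("shape error: expected ", cfg$n_channels, " channels, got ",
         dim(X)[1])
  if (dim(X)[2] < max(cfg$kernel_sizes))
    stop("window width ", dim(X)[2], " is smaller than the largest kernel (",
         max(cfg$kernel_sizes), ")")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("training labels must cover at least 2 classes")
  if (nlevels(y) != cfg$n_classes)
    stop("config declares ", cfg$n_classes, " classes but labels have ",
         nlevels(y))
  y_idx <- as.integer(y)
  N <- dim(X)[3]
  # Adam state
  mstate <- lapply(model$params, function(p) p * 0)
  vstate <- lapply(model$params, function(p) p * 0)
  step <- 0L
  set.seed(cfg$seed + 1L)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    starts <- seq.int(1L, N, by = cfg$batch_size)
    # fold a trailing singleton into the previous batch (batch norm
    # needs more than one sample)
    if (length(starts) > 1L && N - starts[length(starts)] == 0L)
      starts <- starts[-length(starts)]
    losses <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- ord[starts[b]:min(starts[b] + cfg$batch_size - 1L, N)]
      if (b == length(starts)) idx <- ord[starts[b]:N]
      Xb <- X[, , idx, drop = FALSE]
      fwd <- cnn_forward(model, Xb, training = TRUE)
      losses[b] <- cnn_loss(fwd$P, y_idx[idx])
      grads <- cnn_backward(model, fwd, y_idx[idx])
      # update running batch-norm statistics
      for (l in 1:3) {
        bn <- fwd$caches[[l]]$bn
        model$running[[paste0("mean", l)]] <-
          BN_MOMENTUM * model$running[[paste0("mean", l)]] +
          (1 - BN_MOMENTUM) * bn$mu
        model$running[[paste0("var", l)]] <-
          BN_MOMENTUM * model$running[[paste0("var", l)]] +
          (1 - BN_MOMENTUM) * bn$v
      }
      step <- step + 1L
      corr <- sqrt(1 - ADAM_B2^step) / (1 - ADAM_B1^step)
      for (nm in names(grads)) {
        g <- grads[[nm]]
        mstate[[nm]] <- ADAM_B1 * mstate[[nm]] + (1 - ADAM_B1) * g
        vstate[[nm]] <- ADAM_B2 * vstate[[nm]] + (1 - ADAM_B2) * g * g
        model$params[[nm]] <- model$params[[nm]] -
          cfg$lr * corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + ADAM_EPS)
      }
    }
    history[epoch] <- mean(losses)
    if (!quiet)
      message(sprintf("epoch %3d/%d  loss %.4f", epoch, cfg$epochs,
                      history[epoch]))
  }
  model$trained <- TRUE
  model$class_names <- levels(y)
  model$channel_names <- channel_names
  model$history <- history
  model
}

#' Predict exercise classes with a trained CNN
#'
#' @param object A trained `poseclass_cnn`.
#' @param newdata A `windowed_dataset` or `C x W x N` array.
#' @param type `"class"` for labels, `"prob"` for the per-window class
#'   probability matrix, `"embedding"` for the L2-normalised pooled
#'   embedding.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Factor of labels, or an `n_classes x N` / `F3 x N` matrix.
#' @export
predict.poseclass_cnn <- function(object, newdata,
                                  type = c("class", "prob", "embedding"),
                                  batch_size = 256L, ...) {
  type <- match.arg(type)
  if (!object$trained && type == "class")
    stop("model is not trained")
  X <- if (inherits(newdata, "windowed_dataset")) newdata$X else newdata
  if (inherits(newdata, "windowed_dataset") &&
      !is.null(object$channel_names) &&
      !identical(newdata$channel_names, object$channel_names))
    stop("shape error: dataset channels do not match the trained model (",
         "expected ", length(object$channel_names), " channels: ",
         paste(head(object$channel_names, 3), collapse = ", "),
         ", ...; got ", length(newdata$channel_names), ")")
  if (dim(X)[1] != object$config$n_channels)
    stop("shape error: expected ", object$config$n_channels,
         " channels, got ", dim(X)[1])
  N <- dim(X)[3]
  P <- NULL; E <- NULL
  for (s in seq.int(1L, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, N)
    fwd <- cnn_forward(object, X[, , idx, drop = FALSE], training = FALSE)
    P <- cbind(P, fwd$P)
    if (type == "embedding") E <- cbind(E, fwd$embedding)
  }
  if (type == "embedding") return(E)
  if (type == "prob") {
    rownames(P) <- object$class_names
    return(P)
  }
  factor(object$class_names[max.col(t(P), ties.method = "first")],
         levels = object$class_names)
}

#' @export
print.poseclass_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<poseclass_cnn> conv %s (kernels %s) -> GAP -> L2 -> dense(%d)\n",
    paste(cfg$feature_maps, collapse = "/"),
    paste(cfg$kernel_sizes, collapse = "/"), cfg$n_classes))
  cat(sprintf("  channels=%s, %s\n",
              ifelse(is.na(cfg$n_channels), "?", cfg$n_channels),
              if (x$trained)
                sprintf("trained %d epochs (final loss %.4f)",
                        length(x$history), tail(x$history, 1))
              else "untrained"))
  invisible(x)
}
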