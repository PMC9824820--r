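# Independent brute-force oracles used to check the vectorised
# implementations.

# the eleven engineered features, computed one formula at a time
naive_features <- function(x) {
  W <- length(x)
  mu <- sum(x) / W
  m2 <- sum((x - mu)^2) / W
  m3 <- sum((x - mu)^3) / W
  m4 <- sum((x - mu)^4) / W
  dft <- sapply(seq_len(W), function(k) {
    sum(x * exp(-2i * pi * (k - 1) * (seq_len(W) - 1) / W))
  })
  cross <- 0
  for (i in 2:W)
    if ((x[i] > mu) != (x[i - 1] > mu)) cross <- cross + 1
  c(mean = mu,
    median = median(x),
    abs_energy = sum(x^2),
    std = sqrt(m2),
    var = m2,
    min = min(x),
    max = max(x),
    skew = if (m2 > 0) m3 / m2^1.5 else 0,
    kurt = if (m2 > 0) m4 / m2^2 - 3 else 0,
    mean_spec_energy = mean(Mod(dft)^2),
    mean_crossings = cross)
}

# enumerate every valid window start explicitly
brute_force_starts <- function(n, width, stride) {
  starts <- integer(0)
  s <- 0L
  while (s + width <= n) {
    starts <- c(starts, s)
    s <- s + stride
  }
  starts
}

# balanced accuracy from an explicitly built confusion matrix
confusion_balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(y_true)) {
    if (y_pred[i] %in% classes)
      cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1
  }
  recalls <- diag(cm) / vapply(classes, function(cl)
    sum(y_true == cl), numeric(1))
  mean(recalls)
}

# random proper rotation matrix
random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply a global rigid motion (rotation + translation) to every frame
rigid_move <- function(seq, Q, shift) {
  out <- seq
  for (i in seq_len(n_frames(seq)))
    out$coords[i, , 1:3] <- matrix(seq$coords[i, , 1:3], ncol = 3) %*%
      t(Q) + rep(shift, each = 33)
  out
}
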