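FEATURE_NAMES <- c("mean", "median", "abs_energy", "std", "var", "min",
                   "max", "skew", "kurt", "mean_spec_energy",
                   "mean_crossings")

# Vectorised core: rows of M are independent time series of length W.
# Returns an nrow(M) x 11 matrix in FEATURE_NAMES order. Moments are
# population moments (divide by W); skewness and excess kurtosis of a
# zero-variance series are defined as 0.
feature_block <- function(M) {
  W <- ncol(M)
  mu <- rowMeans(M)
  D <- M - mu
  m2 <- rowMeans(D^2)
  m3 <- rowMeans(D^3)
  m4 <- rowMeans(D^4)
  pos <- m2 > 0
  skew <- ifelse(pos, m3 / m2^1.5, 0)
  kurt <- ifelse(pos, m4 / m2^2 - 3, 0)
  spec <- rowMeans(Mod(t(stats::mvfft(t(M))))^2)
  above <- M > mu
  crossings <- rowSums(above[, -1L, drop = FALSE] !=
                       above[, -W, drop = FALSE])
  cbind(mean = mu,
        median = apply(M, 1L, median),
        abs_energy = rowSums(M^2),
        std = sqrt(m2),
        var = m2,
        min = do.call(pmin, as.data.frame(M)),
        max = do.call(pmax, as.data.frame(M)),
        skew = skew,
        kurt = kurt,
        mean_spec_energy = spec,
        mean_crossings = crossings)
}

#' Engineered time-series features for one window
#'
#' Computes, per channel, the eleven summary features used by the linear
#' SVM baseline: mean, median, absolute energy (sum of squares), standard
#' deviation, variance, minimum, maximum, skewness, excess kurtosis, mean
#' spectral energy (mean squared magnitude of the discrete Fourier
#' transform) and the number of crossings of the channel mean. Moments are
#' population moments; a zero-variance channel gets skewness and kurtosis
#' 0. Features are concatenated channel-major.
#'
#' @param window A `C x W` numeric matrix (one window, channels in rows),
#'   `W >= 4`.
#' @param channel_names Optional channel labels used to name the output.
#' @return Named numeric vector of length `11 * C`.
#' @export
compute_features <- function(window, channel_names = NULL) {
  window <- as.matrix(window)
  if (ncol(window) < 4L)
    stop("windows must have at least 4 samples for moment features")
  fb <- feature_block(window)
  channel_names <- channel_names %||%
    rownames(window) %||% paste0("ch", seq_len(nrow(window)))
  out <- as.vector(t(fb))
  names(out) <- as.vector(t(outer(channel_names, FEATURE_NAMES, paste,
                                  sep = ".")))
  out
}

#' Feature matrix for a windowed dataset
#'
#' Applies [compute_features()] to every window, vectorised over the whole
#' dataset.
#'
#' @param wd A `windowed_dataset`.
#' @return An `N x (11*C)` matrix with named columns.
#' @export
feature_matrix <- function(wd) {
  stopifnot(inherits(wd, "windowed_dataset"))
  C <- dim(wd$X)[1]; W <- wd$width; N <- n_windows(wd)
  # stack all windows' channels as rows: row (i-1)*C + c is channel c of
  # window i
  M <- matrix(aperm(wd$X, c(1L, 3L, 2L)), nrow = C * N, ncol = W)
  fb <- feature_block(M)
  out <- matrix(0, N, 11L * C)
  for (f in 1:11)
    out[, seq.int(f, by = 11L, length.out = C)] <-
      matrix(fb[, f], nrow = N, ncol = C, byrow = TRUE)
  colnames(out) <- as.vector(t(outer(wd$channel_names, FEATURE_NAMES,
                                     paste, sep = ".")))
  out
}
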