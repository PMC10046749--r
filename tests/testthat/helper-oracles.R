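# Shared oracles and small fixture builders.  Everything here is
# deliberately naive and independent of the package's own signal path.

# Local-maximum peak detector with greedy minimum-separation pruning:
# candidate peaks are strict local maxima, kept tallest-first subject to a
# minimum distance.  Returns sample indices (1-based).
find_peaks <- function(x, fs, min_dist_s = 0.45, min_height = NULL) {
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!is.null(min_height)) cand <- cand[x[cand] >= min_height]
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  min_dist <- min_dist_s * fs
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

# Beat-level features of a cleaned PPG trace: mean peak-to-peak interval in
# seconds and mean peak amplitude.
beat_features <- function(sig, fs) {
  peaks <- find_peaks(sig, fs, min_dist_s = 0.45,
                      min_height = 0.2 * max(sig))
  list(interval = mean(diff(peaks)) / fs, amplitude = mean(sig[peaks]))
}

# Quiet generator: no noise, drift or motion coupling — the pulse train
# alone, for tests that need exact beat geometry.
quiet_generator_config <- function(..., seed = 1) {
  generator_config(hrv_sd = 0, dc_drift_amp = 0, noise_sd = 0, ma_gain = 0,
                   seed = seed, ...)
}

# Batch (growing-window) least squares of d on the last `order` lags of
# ref, with ridge term delta matching the RLS initialization.
lagged_ls_weights <- function(d, ref, order, delta = 0) {
  T <- length(d)
  U <- sapply(seq_len(order) - 1L, function(lag) {
    c(numeric(lag), ref)[seq_len(T)]
  })
  solve(crossprod(U) + delta * diag(order), crossprod(U, d))
}

lagged_ls_residual <- function(d, ref, order) {
  T <- length(d)
  U <- sapply(seq_len(order) - 1L, function(lag) {
    c(numeric(lag), ref)[seq_len(T)]
  })
  as.numeric(d - U %*% solve(crossprod(U), crossprod(U, d)))
}

# Mann–Whitney rank AUC (ties counted half) — independent of the package's
# trapezoidal construction.
rank_auc <- function(y_true, y_prob) {
  pos <- y_prob[y_true == 1]
  neg <- y_prob[y_true == 0]
  gr <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# Small ridge-image maker for classifier wiring tests: a bright band at a
# given row plus uniform speckle.
ridge_image <- function(row, size = 16, noise = 0.2) {
  m <- matrix(0.1, size, size)
  m[row:min(row + 1, size), ] <- 1
  arr <- array(0, c(size, size, 3))
  for (k in 1:3) {
    arr[, , k] <- pmin(m + matrix(runif(size * size, 0, noise), size), 1)
  }
  arr
}

# Three blocks rather than four: a 16 px input pooled four times ends at a
# 1x1 map, which throws away the ridge-row position these wiring tests rely
# on; three blocks keep a 2x2 map.
small_cnn_config <- function(size = 16, filters = 4, n_blocks = 3, ...) {
  cnn_config(input_shape = c(size, size, 3), filters = filters,
             n_blocks = n_blocks, ...)
}
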