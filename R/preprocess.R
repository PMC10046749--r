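#' Preprocessing configuration
#'
#' Parameters for the artifact-aware preprocessing chain: first-order IIR DC
#' removal, Chebyshev type-II bandpass filtering, infrared/red fusion, and
#' recursive-least-squares (RLS) motion-artifact cancellation against the
#' best-correlated accelerometer axis.
#'
#' @param a DC-remover pole parameter in (0, 1]; at `a = 1` the stage is the
#'   identity, and the closer `a` is to 1 the lower the high-pass cutoff.
#' @param band_lo,band_hi Bandpass edges in Hz (human pulse band).
#' @param cheby_order Chebyshev type-II design order.
#' @param stop_atten_db Stopband attenuation in dB.
#' @param r_threshold Absolute-correlation threshold above which an
#'   accelerometer axis is accepted as the RLS reference.
#' @param rls_lambda RLS forgetting factor in (0, 1]; 1 weighs all history
#'   equally, smaller values adapt faster.
#' @param rls_order Number of adaptive filter taps.
#' @param rls_delta Initialization scale: the inverse-correlation matrix
#'   starts at `diag(1/rls_delta)`.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(a = 0.95,
                              band_lo = 0.5,
                              band_hi = 3.5,
                              cheby_order = 4,
                              stop_atten_db = 30,
                              r_threshold = 0.3,
                              rls_lambda = 0.999,
                              rls_order = 12,
                              rls_delta = 0.01) {
  if (!is_scalar_number(a) || a <= 0 || a > 1) {
    stop("`a` must lie in (0, 1]", call. = FALSE)
  }
  if (!(band_lo > 0 && band_lo < band_hi)) {
    stop("need 0 < band_lo < band_hi", call. = FALSE)
  }
  if (!is_scalar_number(rls_lambda) || rls_lambda <= 0 || rls_lambda > 1) {
    stop("`rls_lambda` must lie in (0, 1]", call. = FALSE)
  }
  if (rls_order < 1) stop("`rls_order` must be >= 1", call. = FALSE)
  if (r_threshold < 0 || r_threshold > 1) {
    stop("`r_threshold` must lie in [0, 1]", call. = FALSE)
  }
  if (rls_delta <= 0) stop("`rls_delta` must be positive", call. = FALSE)
  structure(
    list(a = a, band_lo = band_lo, band_hi = band_hi,
         cheby_order = as.integer(cheby_order),
         stop_atten_db = stop_atten_db, r_threshold = r_threshold,
         rls_lambda = rls_lambda, rls_order = as.integer(rls_order),
         rls_delta = rls_delta),
    class = "preprocess_config"
  )
}

#' First-order IIR DC remover
#'
#' Implements the recursion `m(t) = x(t) + a * m(t-1)`,
#' `y(t) = m(t) - m(t-1)`, i.e. the transfer function
#' `(1 - z^-1) / (1 - a z^-1)`.  Its gain at 0 Hz is exactly zero for any
#' `a < 1`, so the running value `m` tracks (and the output discards) the DC
#' drift; at `a = 1` the filter reduces to the identity.
#'
#' @param x Input sample vector.
#' @param a Pole parameter in (0, 1].
#' @param m0 Initial running value `m(0)`.  The default `x[1] / (1 - a)` is
#'   the steady state for a constant input, which suppresses the start-up
#'   transient (for `a = 1` the default is 0; the output does not depend on
#'   `m0` there).
#' @return Filtered vector of the same length.
#' @export
#' @examples
#' dc_remove(c(1, 1, 1), a = 0.5, m0 = 0)   # 1.00 0.50 0.25
dc_remove <- function(x, a, m0 = NULL) {
  if (!is_scalar_number(a) || a <= 0 || a > 1) {
    stop("`a` must lie in (0, 1]", call. = FALSE)
  }
  if (!length(x)) return(numeric(0))
  if (is.null(m0)) {
    m0 <- if (a < 1) x[1] / (1 - a) else 0
  }
  m <- as.numeric(stats::filter(x, a, method = "recursive", init = m0))
  m - c(m0, m[-length(m)])
}

#' Chebyshev type-II bandpass filter
#'
#' Causal (forward-only) Chebyshev type-II bandpass of the configured order,
#' stopband attenuation and band edges, as a streaming device would apply it.
#'
#' @param x Input sample vector.
#' @param fs Sampling rate in Hz; must exceed `2 * band_hi`.
#' @param cfg A [preprocess_config()].
#' @return Filtered vector of the same length.
#' @export
bandpass <- function(x, fs, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (fs <= 2 * cfg$band_hi) {
    stop("`fs` must exceed twice the upper band edge", call. = FALSE)
  }
  flt <- signal::cheby2(cfg$cheby_order, cfg$stop_atten_db,
                        c(cfg$band_lo, cfg$band_hi) / (fs / 2),
                        type = "pass")
  as.numeric(signal::filter(flt, x))
}

#' Fuse the infrared and red PPG channels
#'
#' Each channel is z-scored (zero mean, unit variance) and the two are
#' averaged into a composite PPG.  The normalization makes fusion invariant
#' to per-channel gain, and averaging independent channel noise reduces its
#' variance.
#'
#' @param ir,red Equal-length sample vectors.
#' @return Fused vector.
#' @export
fuse_channels <- function(ir, red) {
  if (length(ir) != length(red)) {
    stop("`ir` and `red` must have equal length", call. = FALSE)
  }
  zscore <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warning("constant channel in fusion; left at zero")
      return(v - mean(v))
    }
    (v - mean(v)) / s
  }
  (zscore(ir) + zscore(red)) / 2
}

#' Pearson correlation with a zero-variance guard
#'
#' Standard product-moment correlation between a PPG trace and one
#' accelerometer axis.  A constant input has no defined correlation; it is
#' reported as 0 with a warning so that reference selection simply never
#' picks such an axis.
#'
#' @param ppg,acc_axis Equal-length vectors (length >= 2).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(ppg, acc_axis) {
  if (length(ppg) != length(acc_axis)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (length(ppg) < 2) stop("need at least 2 samples", call. = FALSE)
  if (var(ppg) == 0 || var(acc_axis) == 0) {
    warning("zero-variance input; correlation reported as 0")
    return(0)
  }
  as.numeric(cor(ppg, acc_axis))
}

#' Select the motion-artifact reference axis
#'
#' Computes the Pearson correlation between the PPG and each accelerometer
#' axis and returns the axis with the largest absolute correlation, provided
#' `|r|_max` exceeds the threshold; otherwise no reference is selected and
#' RLS cancellation is bypassed.  Exact ties are broken in fixed axis order
#' x, y, z.
#'
#' @param ppg Sample vector.
#' @param acc 3 x T acceleration matrix (rows x, y, z), aligned with `ppg`.
#' @param threshold Absolute-correlation threshold.
#' @return A list with `axis` (`"x"`, `"y"`, `"z"` or `"none"`), `r_max`
#'   (the signed correlation of the selected axis; the largest `|r|` when no
#'   axis passes), and `r_per_axis`.
#' @export
select_reference <- function(ppg, acc, threshold = 0.3) {
  if (!is.matrix(acc) || nrow(acc) != 3L || ncol(acc) != length(ppg)) {
    stop("`acc` must be a 3 x length(ppg) matrix", call. = FALSE)
  }
  axes <- c("x", "y", "z")
  r <- vapply(1:3, function(i) pearson_r(ppg, acc[i, ]), numeric(1))
  names(r) <- axes
  best <- which.max(abs(r))  # first max wins: fixed x -> y -> z tie-break
  if (abs(r[best]) > threshold) {
    list(axis = axes[best], r_max = unname(r[best]), r_per_axis = r)
  } else {
    list(axis = "none", r_max = unname(r[best]), r_per_axis = r)
  }
}

#' RLS adaptive motion-artifact cancellation
#'
#' Exponentially weighted recursive least squares: at sample `n` the
#' regressor is the most recent `rls_order` samples of the reference,
#' the artifact estimate is `N'(n) = w(n)' N(n)`, and the cleaned output is
#' the a-priori error `X'(n) = d(n) - N'(n)`.  Weights and the inverse
#' correlation matrix are updated by the standard RLS recursion with
#' forgetting factor `rls_lambda`; the matrix starts at `diag(1/rls_delta)`
#' and the weights at zero.
#'
#' @param d Corrupted signal (desired input).
#' @param n_ref Reference signal of equal length.
#' @param cfg A [preprocess_config()]; `rls_order`, `rls_lambda` and
#'   `rls_delta` are used.
#' @return Cleaned vector with attribute `"weights"` holding the final
#'   weight vector.
#' @export
rls_cancel <- function(d, n_ref, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  T <- length(d)
  if (length(n_ref) != T) {
    stop("`d` and `n_ref` must have equal length", call. = FALSE)
  }
  M <- cfg$rls_order
  if (M > T) stop("`rls_order` exceeds signal length", call. = FALSE)
  lam <- cfg$rls_lambda
  w <- numeric(M)
  P <- diag(M) / cfg$rls_delta
  out <- numeric(T)
  refp <- c(numeric(M - 1), n_ref)    # zero history before the first sample
  for (n in seq_len(T)) {
    u <- refp[(n + M - 1):n]          # newest sample first
    Pu <- P %*% u
    denom <- lam + sum(u * Pu)
    k <- Pu / denom
    e <- d[n] - sum(w * u)
    w <- w + k[, 1] * e
    P <- (P - k %*% crossprod(u, P)) / lam
    P <- (P + t(P)) / 2               # keep symmetric against round-off
    out[n] <- e
    if (!all(is.finite(w)) || !is.finite(out[n])) {
      stop(sprintf("RLS update became non-finite at sample %d", n),
           call. = FALSE)
    }
  }
  attr(out, "weights") <- w
  out
}

#' Preprocess one recording
#'
#' Full preprocessing chain: DC removal and bandpass filtering applied to
#' both PPG channels and all three acceleration channels (the accelerometer
#' is conditioned exactly like the PPG), z-score fusion of the two PPG
#' channels, correlation-based reference selection over the whole recording,
#' and RLS cancellation against the selected axis.  When no axis passes the
#' correlation threshold the fused signal passes through unchanged —
#' adapting against an uncorrelated reference would only inject noise.
#'
#' @param rec A `raw_recording`.
#' @param cfg A [preprocess_config()].
#' @return An object of class `clean_ppg`: `subject_id`, `condition`, `fs`,
#'   `signal`, `reference_axis_used` (`"x"`, `"y"`, `"z"` or `"none"`),
#'   `r_max`, and `r_per_axis`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "preprocess_config"))
  clean1 <- function(x) bandpass(dc_remove(x, cfg$a), rec$fs, cfg)
  ir <- clean1(rec$ppg_ir)
  red <- clean1(rec$ppg_red)
  acc <- rbind(x = clean1(rec$acc["x", ]),
               y = clean1(rec$acc["y", ]),
               z = clean1(rec$acc["z", ]))
  fused <- fuse_channels(ir, red)
  sel <- select_reference(fused, acc, cfg$r_threshold)
  sig <- if (sel$axis == "none") {
    fused
  } else {
    as.numeric(rls_cancel(fused, acc[sel$axis, ], cfg))
  }
  structure(
    list(subject_id = rec$subject_id,
         condition = rec$condition,
         fs = rec$fs,
         signal = sig,
         reference_axis_used = sel$axis,
         r_max = sel$r_max,
         r_per_axis = sel$r_per_axis),
    class = "clean_ppg"
  )
}

#' @export
print.clean_ppg <- function(x, ...) {
  cat(sprintf(
    "<clean_ppg> subject %s, %s, %d samples; reference axis %s (|r| = %.3f)\n",
    x$subject_id, x$condition, length(x$signal), x$reference_axis_used,
    abs(x$r_max)))
  invisible(x)
}
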