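#' Generalized Morse wavelet parameters
#'
#' The generalized Morse family is defined in the frequency domain as
#' `a_{beta,gamma} * w^beta * exp(-w^gamma)` on `w >= 0` (analytic: zero for
#' negative frequencies).  `gamma` controls the symmetry of the wavelet and
#' `beta` its compactness; the peak (center) angular frequency of the mother
#' wavelet is `(beta/gamma)^(1/gamma)`.
#'
#' @param gamma Symmetry parameter, > 0.
#' @param beta Compactness parameter, > 0.
#' @param voices_per_octave Number of scales per octave in the filter bank.
#' @param freq_min,freq_max Band covered by the bank, in Hz.
#' @return An object of class `morse_params`.
#' @export
morse_params <- function(gamma = 3, beta = 20, voices_per_octave = 12,
                         freq_min = 0.4, freq_max = 8) {
  if (gamma <= 0 || beta <= 0) {
    stop("`gamma` and `beta` must be positive", call. = FALSE)
  }
  if (!(freq_min > 0 && freq_min < freq_max)) {
    stop("need 0 < freq_min < freq_max", call. = FALSE)
  }
  if (voices_per_octave < 1) {
    stop("`voices_per_octave` must be >= 1", call. = FALSE)
  }
  structure(
    list(gamma = gamma, beta = beta,
         voices_per_octave = as.integer(voices_per_octave),
         freq_min = freq_min, freq_max = freq_max),
    class = "morse_params"
  )
}

# Peak angular frequency (radians/sample at scale 1) of the Morse window
# w^beta exp(-w^gamma): the root of d/dw [beta log w - w^gamma] = 0.
morse_peak_omega <- function(beta, gamma) (beta / gamma)^(1 / gamma)

#' Convert a CWT scale to frequency
#'
#' `F = Fc * fs / a`, where `Fc` is the center frequency of the mother
#' wavelet in cycles per sample and `fs` the sampling rate in Hz.
#'
#' @param a Scale value(s), > 0.
#' @param Fc Mother-wavelet center frequency in cycles/sample.
#' @param fs Sampling rate in Hz.
#' @return Frequency in Hz.
#' @export
#' @examples
#' scale_to_freq(10, Fc = 0.1, fs = 100)   # 1 Hz
scale_to_freq <- function(a, Fc, fs) {
  if (any(a <= 0)) stop("scales must be positive", call. = FALSE)
  Fc * fs / a
}

#' Build a Morse CWT filter bank
#'
#' One frequency-domain generalized Morse wavelet per scale, with scales
#' geometrically spaced (`voices_per_octave` per octave) so that the bank's
#' center frequencies run from `freq_max` down to `freq_min`.  Each row is
#' normalized to unit peak, and rows are zero at and above the Nyquist
#' mirror (analytic wavelets).  The transform zero-pads each segment to at
#' least twice its length (next power of two) to limit circular wrap-around.
#'
#' @param params A [morse_params()].
#' @param n_samples Segment length the bank is designed for.
#' @param fs Sampling rate in Hz; `freq_max` must not exceed `fs / 2`.
#' @return An object of class `morse_bank` with the bank matrix
#'   (`n_scales x nfft`) and a `grid` (class `scale_grid`) carrying `scales`,
#'   `freqs` (Hz, decreasing in scale), `center_freq` (cycles/sample) and
#'   `fs`; `freqs * scales == center_freq * fs` elementwise.
#' @export
morse_filterbank <- function(params, n_samples, fs) {
  stopifnot(inherits(params, "morse_params"))
  if (params$freq_max > fs / 2) {
    stop("`freq_max` must not exceed fs/2", call. = FALSE)
  }
  min_len <- ceiling(fs / params$freq_min)
  if (n_samples < min_len) {
    stop(sprintf(
      "segment too short for freq_min = %g Hz: need at least %d samples (one full period), got %d",
      params$freq_min, min_len, n_samples), call. = FALSE)
  }
  omega_p <- morse_peak_omega(params$beta, params$gamma)
  Fc <- omega_p / (2 * pi)                        # cycles per sample
  n_oct <- log2(params$freq_max / params$freq_min)
  n_scales <- floor(n_oct * params$voices_per_octave) + 1L
  freqs <- params$freq_max *
    2^(-(seq_len(n_scales) - 1L) / params$voices_per_octave)
  scales <- Fc * fs / freqs

  nfft <- 2^ceiling(log2(2 * n_samples))
  omega <- 2 * pi * (seq_len(nfft) - 1L) / nfft   # radians/sample
  pos <- omega > 0 & omega <= pi                  # analytic support
  bank <- matrix(0, nrow = n_scales, ncol = nfft)
  for (s in seq_len(n_scales)) {
    aw <- scales[s] * omega[pos]
    row <- aw^params$beta * exp(-aw^params$gamma)
    mx <- max(row)
    if (mx > 0) row <- row / mx                   # unit peak per row
    bank[s, pos] <- row
  }
  structure(
    list(bank = bank, nfft = nfft, n_samples = as.integer(n_samples),
         params = params,
         grid = structure(
           list(scales = scales, freqs = freqs, center_freq = Fc, fs = fs),
           class = "scale_grid"
         )),
    class = "morse_bank"
  )
}

#' Continuous wavelet transform via a Morse filter bank
#'
#' Frequency-domain implementation: the zero-padded segment spectrum is
#' multiplied by each wavelet row and inverse-transformed; the stored
#' scalogram is the coefficient magnitude for every scale and translation.
#' The transform is linear, so doubling the input amplitude exactly doubles
#' the magnitude.
#'
#' @param x Sample vector of length `bank$n_samples`; must be finite.
#' @param bank A [morse_filterbank()].
#' @return An object of class `ppg_scalogram` with `magnitude`
#'   (`n_scales x n_samples`, rows ordered from `freq_max` down to
#'   `freq_min`) and the bank's `grid`.
#' @export
cwt_morse <- function(x, bank) {
  stopifnot(inherits(bank, "morse_bank"))
  if (length(x) != bank$n_samples) {
    stop(sprintf("segment length %d does not match bank design length %d",
                 length(x), bank$n_samples), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("input contains non-finite values", call. = FALSE)
  }
  X <- fft(c(x, numeric(bank$nfft - length(x))))
  # One inverse FFT per scale, batched: columns are X * bank rows.
  prod_mat <- t(bank$bank) * X            # nfft x n_scales
  coef <- mvfft(prod_mat, inverse = TRUE) / bank$nfft
  mag <- t(Mod(coef[seq_len(bank$n_samples), , drop = FALSE]))
  structure(
    list(magnitude = mag, grid = bank$grid),
    class = "ppg_scalogram"
  )
}

#' Ridge frequency of a scalogram
#'
#' Frequency of the scale with the largest magnitude at the mid-segment
#' column — a robust summary of the dominant oscillation.
#'
#' @param scal A `ppg_scalogram`.
#' @return Frequency in Hz.
#' @export
ridge_frequency <- function(scal) {
  stopifnot(inherits(scal, "ppg_scalogram"))
  mid <- ceiling(ncol(scal$magnitude) / 2)
  scal$grid$freqs[which.max(scal$magnitude[, mid])]
}

scalogram_colormap <- function(n = 256L) {
  t(col2rgb(hcl.colors(n, "viridis"))) / 255
}

#' Render a scalogram as a fixed-size RGB image
#'
#' The magnitude matrix is resampled (separable linear interpolation) to
#' `size x size`, min–max normalized to \[0, 1\] per image, and mapped
#' through a fixed perceptual colormap (the "viridis" palette of
#' [grDevices::hcl.colors()]) to three channels.  Time runs along the
#' horizontal axis and frequency decreases downward.  Per-image
#' normalization makes the rendering invariant to overall signal amplitude.
#'
#' @param scal A `ppg_scalogram` (or a bare magnitude matrix).
#' @param size Output image side length in pixels.
#' @param grayscale If `TRUE`, replicate the normalized magnitude across the
#'   three channels instead of colormapping.
#' @return A `size x size x 3` array with values in \[0, 1\].
#' @export
render_scalogram <- function(scal, size = 224, grayscale = FALSE) {
  mag <- if (inherits(scal, "ppg_scalogram")) scal$magnitude else scal
  if (!is.matrix(mag) || !length(mag)) {
    stop("`scal` must contain a non-empty magnitude matrix", call. = FALSE)
  }
  Wr <- interp_matrix(nrow(mag), size)
  Wc <- interp_matrix(ncol(mag), size)
  img <- Wr %*% mag %*% t(Wc)
  rng <- range(img)
  if (rng[2] > rng[1]) {
    img <- (img - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("constant scalogram magnitude; rendering uniform image")
    img <- matrix(0, size, size)
  }
  if (grayscale) {
    return(array(rep(img, 3L), dim = c(size, size, 3L)))
  }
  lut <- scalogram_colormap()
  idx <- pmin(pmax(floor(img * 255) + 1L, 1L), 256L)
  array(c(lut[idx, 1], lut[idx, 2], lut[idx, 3]), dim = c(size, size, 3L))
}

#' Write / read a rendered scalogram image as 8-bit PNG
#'
#' @param img A `size x size x 3` array in \[0, 1\].
#' @param path PNG file path.
#' @return `path` invisibly (writer); an array in \[0, 1\] (reader).
#' @export
write_scalogram_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_scalogram_png
#' @export
read_scalogram_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE]
}
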