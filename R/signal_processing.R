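#' Spectrogram parameters
#'
#' Defaults match the published preprocessing: a 100-point Hamming window
#' slid with 90 points of overlap, zero-padded to a 256-point FFT. Each
#' windowed segment contributes one magnitude-squared periodogram column
#' (no frame averaging), so a 2000-sample, 100 Hz signal yields a
#' 129 x 191 one-sided grid with a bin width of 100/256 Hz.
#'
#' @param window_len analysis window length in samples.
#' @param overlap overlap between consecutive windows in samples.
#' @param nfft FFT length (>= window_len; the segment is zero-padded).
#' @param scaling "linear_power" or "log_power".
#' @return a `spectrogram_params` object.
#' @export
spectrogram_params <- function(window_len = 100L, overlap = 90L,
                               nfft = 256L,
                               scaling = c("linear_power", "log_power")) {
  scaling <- match.arg(scaling)
  window_len <- as.integer(window_len)
  overlap <- as.integer(overlap)
  nfft <- as.integer(nfft)
  if (overlap >= window_len) stop("overlap must be < window_len")
  if (nfft < window_len) stop("nfft must be >= window_len")
  structure(list(window_len = window_len, overlap = overlap, nfft = nfft,
                 scaling = scaling), class = "spectrogram_params")
}

# Symmetric Hamming window (0.54 - 0.46 cos), the common DSP convention.
hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# Linear-phase low-pass FIR by Hamming-windowed sinc, unit DC gain.
design_lowpass_fir <- function(cutoff_hz, fs, n_taps) {
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- (n_taps - 1L) / 2L
  t <- (-m):m
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * t) * hamming_window(n_taps)
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase FIR filtering: reflect-pad by the group delay, FFT-convolve,
# keep the delay-compensated centre. Symmetric taps make this zero phase.
fir_filter_zerophase <- function(x, h) {
  m <- (length(h) - 1L) %/% 2L
  n <- length(x)
  left <- if (m > 0L) x[pmin(n, m:1 + 1L)] else numeric(0)
  right <- if (m > 0L) x[pmax(1L, n - (1:m))] else numeric(0)
  xp <- c(left, x, right)
  nfft <- 2^ceiling(log2(length(xp) + length(h) - 1L))
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(2L * m + 1L):(2L * m + n)]
}

#' Downsample a tremor signal
#'
#' Anti-aliased integer-factor decimation to `target_fs` (default 100 Hz,
#' the pipeline's working rate; clinically 1500 -> 100, factor 15). A
#' linear-phase windowed-sinc low-pass with cutoff 0.45 x `target_fs`
#' (45 Hz) is applied with delay compensation before decimation, so the
#' passband up to the ~20 Hz tremor range is untouched and content above
#' the new Nyquist is suppressed by > 40 dB.
#'
#' @param signal a [tremor_signal()] whose `fs` is an integer multiple of
#'   `target_fs`.
#' @param target_fs target sampling rate in Hz.
#' @return the downsampled [tremor_signal()].
#' @export
downsample_signal <- function(signal, target_fs = 100) {
  stopifnot(inherits(signal, "tremor_signal"))
  factor <- signal$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("unsupported rate: fs=%g is not an integer multiple of %g",
                 signal$fs, target_fs))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(signal)
  # ~100 taps per decimation unit keeps the transition band inside
  # [0.45, 0.5] x target_fs with > 50 dB stopband (Hamming design)
  h <- design_lowpass_fir(0.45 * target_fs, signal$fs, 100L * factor + 1L)
  y <- fir_filter_zerophase(signal$samples, h)
  y <- y[seq(1L, length(y), by = factor)]
  # restore the sample mean: the decimator is exactly DC-preserving, so
  # demeaning commutes with downsampling to machine precision
  out <- signal
  out$samples <- y + (mean(signal$samples) - mean(y))
  out$fs <- target_fs
  out
}

#' Remove the calibration offset
#'
#' Subtracts the sample mean of the recording from itself, eliminating the
#' accelerometer calibration offset and the posture-dependent gravity bias.
#'
#' @param signal a [tremor_signal()].
#' @return the demeaned [tremor_signal()].
#' @export
demean_signal <- function(signal) {
  stopifnot(inherits(signal, "tremor_signal"))
  if (length(signal$samples) == 0L) stop("empty signal")
  signal$samples <- signal$samples - mean(signal$samples)
  signal
}

#' Short-time spectrogram of a tremor signal
#'
#' Slides the Hamming window along the signal with the configured hop,
#' zero-pads each segment to `nfft` and stores the one-sided
#' magnitude-squared FFT as one column per frame. Frame j (0-based) covers
#' samples [hop*j, hop*j + window_len). For the default parameters and a
#' 2000-sample, 100 Hz input this yields floor((2000-100)/10)+1 = 191
#' frames by 256/2+1 = 129 bins; bin k sits at k*100/256 Hz.
#'
#' @param signal a [tremor_signal()] sampled at 100 Hz.
#' @param params a [spectrogram_params()].
#' @return a `spectrogram` object: `power` (bins x frames matrix),
#'   `freq_step_hz`, `time_step_s` and `source` provenance.
#' @export
compute_spectrogram <- function(signal, params = spectrogram_params()) {
  stopifnot(inherits(signal, "tremor_signal"),
            inherits(params, "spectrogram_params"))
  if (signal$fs != 100) {
    stop(sprintf("spectrogram shape error: expected fs=100, got %g",
                 signal$fs))
  }
  x <- signal$samples
  L <- params$window_len
  hop <- L - params$overlap
  if (length(x) < L) stop("spectrogram shape error: signal shorter than window")
  n_frames <- (length(x) - L) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  seg <- x[outer(1:L, starts, `+`)]
  dim(seg) <- c(L, n_frames)
  seg <- seg * hamming_window(L)
  padded <- rbind(seg, matrix(0, params$nfft - L, n_frames))
  spec <- abs(stats::mvfft(padded))^2
  n_bins <- params$nfft %/% 2L + 1L
  power <- spec[seq_len(n_bins), , drop = FALSE]
  structure(
    list(power = power, freq_step_hz = signal$fs / params$nfft,
         time_step_s = hop / signal$fs, params = params,
         scaled = FALSE,
         source = signal[c("patient_id", "group", "visit", "hand", "task",
                           "trial", "axis")]),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames, %.4f Hz/bin, %.2f s/frame%s\n",
              nrow(x$power), ncol(x$power), x$freq_step_hz, x$time_step_s,
              if (isTRUE(x$scaled)) " (network-scaled)" else ""))
  invisible(x)
}

#' Scale a spectrogram for the network
#'
#' Takes log10(power + 1e-12) and standardises the grid to zero mean and
#' unit variance. The per-grid standardisation makes the arbitrary
#' accelerometer calibration irrelevant to the network; a zero-variance
#' grid (e.g. an all-zero signal) maps to all zeros.
#'
#' @param spec a linear-power `spectrogram`.
#' @return the scaled `spectrogram` (marked `scaled = TRUE`).
#' @export
scale_for_network <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  if (isTRUE(spec$scaled)) stop("spectrogram already network-scaled")
  g <- log10(spec$power + 1e-12)
  s <- stats::sd(g)
  g <- if (is.na(s) || s < 1e-12) g * 0 else (g - mean(g)) / s
  spec$power <- g
  spec$scaled <- TRUE
  spec
}

# downsample -> demean -> spectrogram -> network scaling for one signal
preprocess_signal <- function(signal, target_fs = 100,
                              params = spectrogram_params(),
                              scale = TRUE) {
  s <- demean_signal(downsample_signal(signal, target_fs))
  spec <- compute_spectrogram(s, params)
  if (scale) scale_for_network(spec) else spec
}
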