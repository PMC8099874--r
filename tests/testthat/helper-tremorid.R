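# Shared fixtures: everything is generated in code at test time.

# Small network that fits toy inputs; used wherever the architecture
# itself (not the standard spectrogram geometry) is under test.
tiny_cnn_config <- function(seed = 7L, ...) {
  stage1_config(conv1_filters = 3L, conv1_kernel = 3L, conv2_filters = 2L,
                conv2_kernel = 3L, dense_widths = c(8L, 5L, 2L),
                seed = seed, ...)
}

tiny_input_dim <- c(20L, 24L)

random_tiny_samples <- function(n, seed = 1L, input_dim = tiny_input_dim) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lab <- c("PD", "ET")[1L + (i %% 2L)]
    # class-dependent mean shift so training has signal
    x <- matrix(stats::rnorm(prod(input_dim)), input_dim[1], input_dim[2]) +
      if (lab == "PD") 0.5 else -0.5
    list(x = x, hint = encode_task_hint(included_tasks()[1L + (i %% 6L)]),
         label = lab, patient_id = sprintf("P%02d", 1L + (i %% 8L)))
  })
}

# A pure test tone wrapped as a tremor signal.
tone_signal <- function(freq, fs = 100, duration_s = 20, amp = 1,
                        offset = 0, ...) {
  t <- (seq_len(round(fs * duration_s)) - 1L) / fs
  tremor_signal(amp * sin(2 * pi * freq * t) + offset, fs = fs, ...,
                patient_id = "tone")
}

# In-memory synthetic cohort at 100 Hz raw rate (fast; the 1500 Hz
# downsampling path is exercised separately by the tone oracles).
small_cohort <- function(n_pd = 2L, n_et = 2L, seed = 5L,
                         separation = "easy", raw_fs = 100, visits = 1L,
                         snr_db = 20, bilateral = FALSE, ...) {
  profiles <- default_profiles(separation)
  if (bilateral) {
    profiles$PD$bilateral_prob <- 1
    profiles$ET$bilateral_prob <- 1
  }
  simulate_cohort(cohort_spec(n_pd = n_pd, n_et = n_et, visits = visits,
                              raw_fs = raw_fs, snr_db = snr_db,
                              seed = seed, profiles = profiles, ...))
}

# Independent single-bin DFT magnitude at frequency index k (0-based)
# of a zero-padded, windowed segment; brute-force oracle for the
# spectrogram path.
brute_dft_power <- function(segment, k, nfft = 256L) {
  n <- seq_along(segment) - 1L
  re <- sum(segment * cos(-2 * pi * k * n / nfft))
  im <- sum(segment * sin(-2 * pi * k * n / nfft))
  re^2 + im^2
}

# Naive multivariate normal density (solve/det), the oracle the QDA
# implementation (Cholesky, log space) is checked against.
naive_mvn_density <- function(f, mu, sigma) {
  d <- length(f)
  diff <- as.numeric(f - mu)
  exp(-0.5 * as.numeric(t(diff) %*% solve(sigma) %*% diff)) /
    sqrt((2 * pi)^d * det(sigma))
}

random_spd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(d * d), d, d)
  crossprod(A) / d + diag(0.5, d)
}
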