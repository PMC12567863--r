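POSTURES <- c("supine", "prone", "left", "right")

# spatial pressure templates over a 4x4 grid, one per posture
posture_templates <- function() {
  t4 <- function(v) v / sum(v)
  list(
    supine = t4(c(1, 3, 3, 1, 2, 6, 6, 2, 2, 6, 6, 2, 1, 3, 3, 1)),
    prone  = t4(c(2, 5, 5, 2, 3, 5, 5, 3, 1, 4, 4, 1, 1, 2, 2, 1)),
    left   = t4(c(4, 4, 1, 1, 6, 5, 1, 1, 6, 5, 1, 1, 3, 2, 1, 1)),
    right  = t4(c(1, 1, 4, 4, 1, 1, 5, 6, 1, 1, 5, 6, 1, 1, 2, 3))
  )
}

#' Simulate one night of multirate AI-bed signals
#'
#' Builds the four bed streams at their native rates -- a 16-cell pressure
#' grid at 10 Hz, a load-cell channel at 50 Hz, a 3-axis IMU at 25 Hz and
#' environment sensors at 1 Hz -- with a planted respiration sinusoid, a
#' cardiac sinusoid, a posture schedule reflected in the pressure grid,
#' noisy per-second posture observations, and spike artifacts at recorded
#' positions. The planted state is returned under `$truth` for recovery
#' tests.
#'
#' @param resp_hz Planted respiration frequency, must lie in `[0.1, 0.5]` Hz.
#' @param duration_s Night length in seconds (>= 60).
#' @param cardiac_hz Cardiac proxy frequency (default 1.2 Hz).
#' @param noise_sd Load-channel noise standard deviation (signal amplitude 1).
#' @param n_artifacts Number of load-channel spike artifacts.
#' @param n_posture_segments Number of posture blocks across the night.
#' @param obs_flip_prob Probability a per-second posture observation is
#'   flipped to a random other state (emission noise for the HMM smoother).
#' @param seed Integer seed; identical seeds give identical nights.
#' @return A `sleeprec_night` list: `pressure` (matrix, 10 Hz x 16 cells),
#'   `load` (50 Hz), `imu` (25 Hz x 3), `env` (1 Hz tibble), `posture_obs`
#'   (1 Hz factor), `rates`, `duration_s`, `truth`.
#' @export
simulate_night <- function(resp_hz, duration_s = 480, cardiac_hz = 1.2,
                           noise_sd = 0.3, n_artifacts = 5,
                           n_posture_segments = 4, obs_flip_prob = 0.1,
                           seed = 1L) {
  if (resp_hz < 0.1 || resp_hz > 0.5)
    abort("simulate_night: resp_hz must be in [0.1, 0.5] Hz")
  if (duration_s < 60) abort("simulate_night: duration_s must be >= 60")
  withr::with_seed(seed, {
    t50 <- seq(0, duration_s - 1 / 50, by = 1 / 50)
    load <- 30 + sin(2 * pi * resp_hz * t50) +
      0.3 * sin(2 * pi * cardiac_hz * t50) + rnorm(length(t50), 0, noise_sd)
    artifact_idx <- integer(0)
    if (n_artifacts > 0) {
      artifact_idx <- sort(sample.int(length(t50), n_artifacts))
      load[artifact_idx] <- load[artifact_idx] + 100 * sample(c(-1, 1), n_artifacts, TRUE)
    }
    # posture schedule: contiguous blocks over the night
    cuts <- sort(sample(seq_len(duration_s - 1), n_posture_segments - 1))
    bounds <- c(0, cuts, duration_s)
    states <- character(0)
    prev <- sample(POSTURES, 1)
    for (b in seq_len(n_posture_segments)) {
      if (b > 1) prev <- sample(setdiff(POSTURES, prev), 1)
      states <- c(states, rep(prev, bounds[b + 1] - bounds[b]))
    }
    tmpl <- posture_templates()
    n10 <- duration_s * 10
    sec_of_10 <- rep(seq_len(duration_s), each = 10)
    base <- do.call(rbind, lapply(states[sec_of_10], function(s) tmpl[[s]]))
    t10 <- seq(0, duration_s - 1 / 10, by = 1 / 10)
    pressure <- base * 30 * (1 + 0.05 * sin(2 * pi * resp_hz * t10)) +
      matrix(abs(rnorm(n10 * 16, 0, 0.15)), n10, 16)
    imu <- matrix(rnorm(duration_s * 25 * 3, 0, 0.05), ncol = 3)
    env <- tibble::tibble(temp = rnorm(duration_s, 21.5, 0.05),
                          light = abs(rnorm(duration_s, 3, 0.5)),
                          noise = rnorm(duration_s, 30, 1))
    flip <- runif(duration_s) < obs_flip_prob
    obs <- states
    obs[flip] <- vapply(states[flip],
                        function(s) sample(setdiff(POSTURES, s), 1), character(1))
    structure(list(pressure = pressure, load = load, imu = imu, env = env,
                   posture_obs = obs,
                   rates = c(pressure = 10, load = 50, imu = 25, env = 1),
                   duration_s = duration_s,
                   truth = list(resp_hz = resp_hz, posture = states,
                                artifact_idx = artifact_idx)),
              class = "sleeprec_night")
  })
}

#' Hampel outlier filter
#'
#' Sliding-window median/MAD despiking: a sample deviating from the local
#' median by more than `n_mad` scaled MADs (1.4826 factor) is replaced by
#' that median. Thin wrapper around [pracma::hampel()]; the first and last
#' `window` samples are passed through unchanged, as is conventional.
#'
#' @param series Numeric vector.
#' @param window Half-width of the sliding window in samples (default 5).
#' @param n_mad Rejection threshold in scaled MADs (default 3).
#' @return Filtered series, same length.
#' @export
hampel <- function(series, window = 5, n_mad = 3) {
  if (window < 1) abort("hampel: window must be >= 1")
  if (length(series) < 2 * window + 1)
    abort("hampel: series shorter than the filter window")
  pracma::hampel(series, k = window, t0 = n_mad)$y
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion. Respiration band
#' 0.1-0.5 Hz and cardiac band 0.8-2.5 Hz are the intended uses.
#'
#' @param series Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param f_low,f_high Band edges in Hz; `0 < f_low < f_high < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered series, same length.
#' @export
bandpass <- function(series, fs, f_low, f_high, order = 4) {
  if (!(f_low > 0 && f_low < f_high && f_high < fs / 2))
    abort("bandpass: need 0 < f_low < f_high < fs/2 (Nyquist)")
  bf <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, series))
}

#' Resample a multirate night to a 1 Hz aligned frame
#'
#' Aggregates every stream to per-second bin means on the shared clock:
#' total grid pressure and the 16 cell means, load mean, IMU magnitude mean,
#' environment channels, and the observed posture state. One row per second
#' of the night.
#'
#' @param night A `sleeprec_night`.
#' @return An aligned-frame tibble with `second` and one column per channel.
#' @export
resample_1hz <- function(night) {
  stopifnot(inherits(night, "sleeprec_night"))
  d <- night$duration_s
  expect_len <- c(pressure = d * 10, load = d * 50, imu = d * 25, env = d)
  actual <- c(pressure = nrow(night$pressure), load = length(night$load),
              imu = nrow(night$imu), env = nrow(night$env))
  bad <- names(which(actual != expect_len))
  if (length(bad))
    abort(sprintf("resample_1hz: stream(s) not covering the night window: %s",
                  paste(bad, collapse = ", ")))
  bin <- function(x, rate) {
    as.numeric(tapply(x, rep(seq_len(d), each = rate), mean))
  }
  cells <- apply(night$pressure, 2, bin, rate = 10)
  colnames(cells) <- sprintf("cell_%02d", 1:16)
  frame <- tibble::tibble(
    second = seq_len(d),
    load_mean = bin(night$load, 50),
    pressure_total = rowSums(cells),
    imu_mag = bin(sqrt(rowSums(night$imu^2)), 25),
    temp = night$env$temp, light = night$env$light, noise = night$env$noise,
    posture_obs = night$posture_obs
  )
  dplyr::bind_cols(frame, tibble::as_tibble(cells))
}

#' Smooth a posture observation sequence with a sticky HMM
#'
#' Viterbi decoding over the 4-posture alphabet under a sticky transition
#' matrix (self-transition `stickiness`, remainder spread evenly) and a
#' symmetric emission confusion (correct with probability `1 - epsilon`).
#' High stickiness removes isolated one-sample glitches while leaving
#' consistent blocks untouched.
#'
#' @param observed Character vector of observed states (subset of
#'   supine/prone/left/right) or a factor.
#' @param stickiness Self-transition probability (default 0.95).
#' @param epsilon Emission error probability (default 0.1).
#' @return Character vector of decoded states, same length.
#' @export
smooth_posture <- function(observed, stickiness = 0.95, epsilon = 0.1) {
  observed <- as.character(observed)
  if (!all(observed %in% POSTURES))
    abort(sprintf("smooth_posture: unknown state symbol(s): %s",
                  paste(unique(setdiff(observed, POSTURES)), collapse = ", ")))
  S <- length(POSTURES)
  obs <- match(observed, POSTURES)
  logA <- log(matrix((1 - stickiness) / (S - 1), S, S) +
                diag(rep(stickiness - (1 - stickiness) / (S - 1), S)))
  logB <- log(matrix(epsilon / (S - 1), S, S) +
                diag(rep(1 - epsilon - epsilon / (S - 1), S)))
  n <- length(obs)
  delta <- matrix(-Inf, n, S)
  psi <- matrix(0L, n, S)
  delta[1, ] <- log(1 / S) + logB[, obs[1]]
  if (n > 1) {
    for (t in 2:n) {
      for (s in seq_len(S)) {
        cand <- delta[t - 1, ] + logA[, s]
        psi[t, s] <- which.max(cand)
        delta[t, s] <- cand[psi[t, s]] + logB[s, obs[t]]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  POSTURES[path]
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-detrended segment averaging with 50% overlap and
#' zero-padding for a finer frequency grid. Used for the dominant-frequency
#' respiration estimate.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param segment_s Segment length in seconds (default 60).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param pad Zero-padding factor (default 4).
#' @return Tibble with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, segment_s = 60, overlap = 0.5, pad = 4) {
  nseg <- min(length(x), round(segment_s * fs))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  nfft <- pad * nseg
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(c(seg, rep(0, nfft - nseg))))^2
    acc <- acc + sp[seq_len(nfft %/% 2 + 1)]
  }
  tibble::tibble(freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft,
                 power = acc / length(starts))
}

# frequency of maximum Welch power inside a band
dominant_frequency <- function(x, fs, band, ...) {
  psd <- welch_psd(x, fs, ...)
  inband <- psd[psd$freq >= band[1] & psd$freq <= band[2], ]
  inband$freq[which.max(inband$power)]
}

#' Preprocess a simulated night into an aligned 1 Hz frame
#'
#' The full cleaning pipeline: Hampel despiking of the 50 Hz load channel,
#' zero-phase band-pass into the respiration (0.1-0.5 Hz) and cardiac
#' (0.8-2.5 Hz) bands, then per-second resampling of all streams. The
#' respiration-band and cardiac-band series are carried as `resp_band` and
#' `cardiac_proxy` columns (the cardiac band, above the 1 Hz Nyquist, is
#' kept as a binned amplitude envelope).
#'
#' @param night A `sleeprec_night`.
#' @param hampel_window,hampel_n_mad Hampel parameters.
#' @return Aligned-frame tibble (see [resample_1hz()]) plus `resp_band`,
#'   `cardiac_proxy`.
#' @export
preprocess_night <- function(night, hampel_window = 5, hampel_n_mad = 3) {
  stopifnot(inherits(night, "sleeprec_night"))
  clean <- hampel(night$load, hampel_window, hampel_n_mad)
  resp <- bandpass(clean, 50, 0.1, 0.5)
  card <- abs(bandpass(clean, 50, 0.8, 2.5))
  d <- night$duration_s
  frame <- resample_1hz(night)
  frame$resp_band <- as.numeric(tapply(resp, rep(seq_len(d), each = 50), mean))
  frame$cardiac_proxy <- as.numeric(tapply(card, rep(seq_len(d), each = 50), mean))
  frame
}

#' Extract the four bed-derived features from an aligned frame
#'
#' * `respiratory_rate`: 60 x the dominant Welch frequency of the
#'   respiration-band load signal (falls back to `load_mean` when no
#'   `resp_band` column is present), in breaths/min.
#' * `posture_transitions`: state-change count of the HMM-smoothed posture
#'   sequence.
#' * `micro_movement_index`: mean absolute first difference of total grid
#'   pressure at 1 Hz (cohort-level z-scaling happens downstream).
#' * `pressure_entropy`: Shannon entropy (bits) of the night-averaged
#'   normalized spatial pressure distribution; bounded by log2(#cells).
#'
#' @param frame Aligned-frame tibble from [preprocess_night()] or
#'   [resample_1hz()].
#' @param stickiness,epsilon Posture-smoother parameters.
#' @return One-row tibble with the four features.
#' @export
extract_bed_features <- function(frame, stickiness = 0.95, epsilon = 0.1) {
  if (nrow(frame) < 60)
    abort("extract_bed_features: frame shorter than 60 s; spectral estimate undefined")
  sig <- if ("resp_band" %in% names(frame)) frame$resp_band else frame$load_mean
  f_dom <- dominant_frequency(sig, fs = 1, band = c(0.1, 0.5))
  decoded <- smooth_posture(frame$posture_obs, stickiness, epsilon)
  cells <- as.matrix(frame[grep("^cell_", names(frame))])
  p <- colMeans(cells)
  p <- p / sum(p)
  p <- p[p > 0]
  tibble::tibble(
    respiratory_rate = 60 * f_dom,
    posture_transitions = sum(decoded[-1] != decoded[-length(decoded)]),
    micro_movement_index = mean(abs(diff(frame$pressure_total))),
    pressure_entropy = -sum(p * log2(p))
  )
}
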