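#' Simulate RR intervals from a hidden two-state Markov chain
#'
#' Ground-truth generator for testing the whole pipeline: a hidden chain on
#' states \{A, N\} evolves under the row-stochastic matrix `p_true`;
#' in state N the emitted RR interval is uniform inside the reference band,
#' in state A it is uniform in a strip of width `out_of_band_width_ms`
#' beyond the band (above, below, or a 50/50 mix of both sides). Optional
#' Gaussian jitter is added and then clipped so every emission stays on the
#' correct side of the band edges — by construction,
#' [classify_states] applied to the output recovers the hidden state
#' sequence exactly.
#'
#' The chain starts from the stationary distribution of `p_true` unless
#' `start_state` is given (required when `p_true` is the identity, which
#' has no unique stationary law).
#'
#' @param p_true 2x2 row-stochastic matrix, rows and columns ordered
#'   (A, N). Default rows (0.8, 0.2) and (0.3, 0.7).
#' @param band An [alpha_band] (default arachnophobia preset).
#' @param n_intervals Number of intervals to draw (>= 2).
#' @param out_of_band_mode `"above"`, `"below"` or `"mixed"`.
#' @param out_of_band_width_ms Width of the arrhythmic emission strip
#'   beyond the band edge (default 200 ms).
#' @param emission_jitter_ms Standard deviation of Gaussian jitter added to
#'   emissions before clipping (default 0).
#' @param seed Integer seed; identical seeds and configs give bit-identical
#'   output.
#' @param start_state Optional `"A"` or `"N"` to force the initial state.
#' @return A list with `rr` (an [rr_series], `source = "synthetic"`) and
#'   `states` (the hidden `state_sequence`).
#' @examples
#' sim <- simulate_markov_rr(n_intervals = 50, seed = 7)
#' identical(classify_states(sim$rr, default_band())$labels,
#'           sim$states$labels)
#' @export
simulate_markov_rr <- function(p_true = matrix(c(0.8, 0.3, 0.2, 0.7), 2, 2,
                                               dimnames = list(c("A", "N"),
                                                               c("A", "N"))),
                               band = default_band("arachnophobia"),
                               n_intervals = 1000,
                               out_of_band_mode = c("above", "below", "mixed"),
                               out_of_band_width_ms = 200,
                               emission_jitter_ms = 0,
                               seed = 1,
                               start_state = NULL) {
  out_of_band_mode <- match.arg(out_of_band_mode)
  stopifnot(inherits(band, "alpha_band"))
  p_true <- as.matrix(p_true)
  if (!all(dim(p_true) == c(2, 2)) || any(p_true < 0) || any(p_true > 1) ||
      any(abs(rowSums(p_true) - 1) > 1e-9)) {
    stop("p_true must be a 2x2 row-stochastic matrix", call. = FALSE)
  }
  if (n_intervals < 2) stop("n_intervals must be >= 2", call. = FALSE)
  if (emission_jitter_ms < 0 || out_of_band_width_ms <= 0) {
    stop("jitter must be >= 0 and the out-of-band width > 0", call. = FALSE)
  }
  set.seed(seed)

  p_an <- p_true[1, 2]; p_na <- p_true[2, 1]
  if (is.null(start_state)) {
    if (p_an + p_na == 0) {
      stop("p_true is the identity matrix: no unique stationary start;",
           " supply start_state", call. = FALSE)
    }
    pi_a <- p_na / (p_an + p_na)
    state <- if (stats::runif(1) < pi_a) "A" else "N"
  } else {
    state <- match.arg(start_state, c("A", "N"))
  }

  labels <- character(n_intervals)
  u <- stats::runif(n_intervals)
  for (k in seq_len(n_intervals)) {
    labels[k] <- state
    stay <- if (state == "A") p_true[1, 1] else p_true[2, 2]
    if (u[k] >= stay) state <- if (state == "A") "N" else "A"
  }

  lo <- band$lower; hi <- band$upper
  eps <- 1e-6
  w <- out_of_band_width_ms
  is_a <- labels == "A"
  rr <- numeric(n_intervals)
  rr[!is_a] <- stats::runif(sum(!is_a), lo, hi)
  n_a <- sum(is_a)
  if (n_a) {
    side_above <- switch(out_of_band_mode,
                         above = rep(TRUE, n_a),
                         below = rep(FALSE, n_a),
                         mixed = stats::runif(n_a) < 0.5)
    a_vals <- numeric(n_a)
    a_vals[side_above] <- stats::runif(sum(side_above), hi + eps, hi + w)
    lo_strip <- max(1, lo - w)
    a_vals[!side_above] <- stats::runif(sum(!side_above), lo_strip, lo - eps)
    rr[is_a] <- a_vals
  }
  if (emission_jitter_ms > 0) {
    rr <- rr + stats::rnorm(n_intervals, 0, emission_jitter_ms)
    # clip back to the correct side of the band edges
    rr[!is_a] <- pmin(pmax(rr[!is_a], lo), hi)
    if (n_a) {
      above <- rr[is_a] > (lo + hi) / 2
      rr[is_a] <- ifelse(above, pmax(rr[is_a], hi + eps),
                         pmax(pmin(rr[is_a], lo - eps), 1))
    }
  }

  list(rr = rr_series(rr, subject_id = sprintf("sim-seed%d", seed),
                      source = "synthetic"),
       states = state_sequence(labels,
                               subject_id = sprintf("sim-seed%d", seed),
                               band = band))
}

#' Simulate a respiratory-modulated RR series
#'
#' A deliberately simple fixture for respiratory sinus arrhythmia: RR
#' length oscillates sinusoidally with the respiratory cycle around a mean,
#' plus Gaussian noise. Interval `k` is
#' `mean + amplitude * sin(2 pi f t_k) + noise`, where `t_k` is the
#' cumulative elapsed time in seconds (`t_0 = 0`,
#' `t_(k+1) = t_k + RR_k / 1000`). Values are hard-clipped at 1 ms. This is
#' a signal-shape generator, not a physiological cardiac model.
#'
#' @param mean_rr_ms Mean RR interval in ms (default 900).
#' @param modulation_amplitude_ms Amplitude of the respiratory modulation
#'   in ms (default 80).
#' @param respiratory_freq_hz Breathing frequency in Hz (default 0.25,
#'   i.e. 15 breaths/min).
#' @param noise_sd_ms Gaussian noise standard deviation in ms (default 0).
#' @param n_intervals Number of intervals to generate.
#' @param seed Integer seed.
#' @return An [rr_series] with `source = "synthetic"`.
#' @export
simulate_rsa_rr <- function(mean_rr_ms = 900, modulation_amplitude_ms = 80,
                            respiratory_freq_hz = 0.25, noise_sd_ms = 0,
                            n_intervals = 300, seed = 1) {
  if (mean_rr_ms <= 0 || modulation_amplitude_ms < 0 || noise_sd_ms < 0 ||
      respiratory_freq_hz <= 0 || n_intervals < 1) {
    stop("invalid RSA generator configuration", call. = FALSE)
  }
  if (mean_rr_ms <= modulation_amplitude_ms + 3 * noise_sd_ms) {
    warning("mean_rr_ms <= amplitude + 3 * noise_sd: intervals may be",
            " clipped at 1 ms", call. = FALSE)
  }
  set.seed(seed)
  noise <- if (noise_sd_ms > 0) stats::rnorm(n_intervals, 0, noise_sd_ms)
           else numeric(n_intervals)
  rr <- numeric(n_intervals)
  t_s <- 0
  for (k in seq_len(n_intervals)) {
    val <- mean_rr_ms +
      modulation_amplitude_ms * sin(2 * pi * respiratory_freq_hz * t_s) +
      noise[k]
    rr[k] <- max(val, 1)
    t_s <- t_s + rr[k] / 1000
  }
  rr_series(rr, subject_id = sprintf("rsa-seed%d", seed),
            source = "synthetic")
}

#' Synthesize an EKG-like pulse train from an RR series
#'
#' Places unit-amplitude triangular pulses at the cumulative beat times
#' (rounded to the nearest sample, first beat at sample 0) and adds
#' optional Gaussian noise. Returns the signal together with the planted
#' ground-truth peak locations, the oracle for testing [detect_r_peaks].
#'
#' @param rr An [rr_series] or numeric vector of RR intervals in ms.
#' @param sampling_rate_hz Sampling rate (default 100 Hz).
#' @param pulse_width_ms Full width of each triangular pulse (default 40).
#' @param noise_sd Additive Gaussian noise standard deviation in amplitude
#'   units (default 0).
#' @param seed Integer seed for the noise.
#' @return A list with `ekg` (an [ekg_signal]) and `peaks` (the
#'   ground-truth [peak_indices], 0-based).
#' @examples
#' simulate_ekg_pulsetrain(c(900, 950))$peaks # samples 0, 90, 185
#' @export
simulate_ekg_pulsetrain <- function(rr, sampling_rate_hz = 100,
                                    pulse_width_ms = 40, noise_sd = 0,
                                    seed = 1) {
  rr <- as_rr_series(rr)
  fs <- sampling_rate_hz
  if (fs <= 0) stop("sampling_rate_hz must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  beat_times_ms <- cumsum(c(0, rr$intervals))
  peaks <- as.integer(round(beat_times_ms / 1000 * fs))
  if (length(peaks) > 1 && min(diff(peaks)) < 2) {
    stop("sampling rate too low to resolve the shortest RR interval",
         call. = FALSE)
  }
  half_w <- max(1L, as.integer(round(pulse_width_ms / 2 / 1000 * fs)))
  n <- peaks[length(peaks)] + half_w + as.integer(round(0.25 * fs)) + 1L
  x <- numeric(n)
  offsets <- -half_w:half_w
  shape <- 1 - abs(offsets) / (half_w + 1)
  for (p in peaks) {
    idx <- p + offsets + 1L # to 1-based
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + shape[ok]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  list(ekg = ekg_signal(x, fs), peaks = peak_indices(peaks, n_samples = n))
}
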