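#' Construct an R-peak index list
#'
#' Peak locations are stored as 0-based sample offsets into the parent EKG
#' signal, so that the time of peak `i` is `indices[i] / sampling_rate_hz`
#' seconds. The 0-based convention is deliberate and documented here once:
#' it keeps the index-to-time conversion free of off-by-one adjustments.
#'
#' @param indices Integer vector of strictly increasing 0-based sample
#'   offsets.
#' @param n_samples Optional length of the parent signal; when supplied,
#'   every index must be smaller than it.
#' @return An object of class `peak_indices`.
#' @export
peak_indices <- function(indices, n_samples = NULL) {
  indices <- as.integer(round(indices))
  if (length(indices)) {
    if (any(indices < 0)) stop("peak indices must be >= 0", call. = FALSE)
    if (any(diff(indices) <= 0)) {
      stop("peak indices must be strictly increasing", call. = FALSE)
    }
    if (!is.null(n_samples) && any(indices >= n_samples)) {
      stop("peak index beyond end of signal", call. = FALSE)
    }
  }
  structure(indices, class = "peak_indices")
}

#' @export
print.peak_indices <- function(x, ...) {
  cat(sprintf("R-peak indices: %d peaks (0-based sample offsets)\n",
              length(x)))
  if (length(x)) print(unclass(x))
  invisible(x)
}

# Centered moving average with windows truncated at the edges, O(n).
moving_average <- function(x, k) {
  n <- length(x)
  h <- k %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Centered sliding maximum over window half-width h, via the block
# prefix/suffix-max decomposition, O(n).
sliding_max <- function(x, h) {
  n <- length(x)
  w <- 2L * h + 1L
  if (w >= n) return(rep(max(x), n))
  nb <- ceiling(n / w)
  pad <- nb * w - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = w)
  pre <- apply(m, 2, cummax)
  suf <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  pre <- as.vector(pre)
  suf <- as.vector(suf)
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  pmax(suf[lo], pre[hi])
}

#' Detect R peaks in a raw EKG signal
#'
#' An automatic stand-in for manual beat annotation. The pipeline is:
#' moving-average detrend to remove baseline wander, squared first
#' difference to emphasise the steep QRS flanks, smoothing of that energy,
#' an adaptive threshold equal to `threshold_factor` times a rolling
#' maximum of the smoothed energy, and refinement of each supra-threshold
#' region to the local maximum of the detrended signal. Peaks closer than
#' `refractory_ms` are resolved by keeping the larger one, mirroring the
#' physiological refractory period of the myocardium.
#'
#' Because manual annotation is the reference procedure for careful HRV
#' work, beat-for-beat agreement with a human annotator is not promised;
#' on clean signals with well-separated beats the detector is exact.
#'
#' @param signal An [ekg_signal].
#' @param refractory_ms Minimum separation between accepted peaks, in ms
#'   (default 250, i.e. a 240 bpm ceiling).
#' @param threshold_factor Fraction of the rolling energy maximum a
#'   candidate must exceed (default 0.5).
#' @return A [peak_indices] object (0-based offsets). A signal shorter than
#'   one refractory window yields an empty result with a warning.
#' @export
detect_r_peaks <- function(signal, refractory_ms = 250,
                           threshold_factor = 0.5) {
  stopifnot(inherits(signal, "ekg_signal"))
  if (refractory_ms <= 0) stop("refractory_ms must be > 0", call. = FALSE)
  fs <- signal$sampling_rate_hz
  x <- signal$samples
  n <- length(x)
  refr <- max(1L, as.integer(round(refractory_ms / 1000 * fs)))
  if (n == 0 || n < refr) {
    warning("signal shorter than one refractory window; no peaks detected",
            call. = FALSE)
    return(peak_indices(integer(0)))
  }

  k_detrend <- max(3L, as.integer(round(0.15 * fs)) %/% 2L * 2L + 1L)
  d <- x - moving_average(x, k_detrend)
  e <- c(0, diff(d))^2
  k_smooth <- max(3L, as.integer(round(0.08 * fs)) %/% 2L * 2L + 1L)
  es <- moving_average(e, k_smooth)

  thr <- threshold_factor * sliding_max(es, h = as.integer(2 * fs))
  cand <- es > thr & es > 0
  if (!any(cand)) return(peak_indices(integer(0)))

  # contiguous supra-threshold runs -> local argmax of the detrended signal
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  half <- k_smooth %/% 2L
  peaks <- vapply(which(keep), function(j) {
    lo <- max(1L, starts[j] - half)
    hi <- min(n, ends[j] + half)
    lo + which.max(d[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))

  # refractory pass: among peaks closer than refr samples keep the larger
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      last <- out[length(out)]
      if (p - last >= refr) {
        out <- c(out, p)
      } else if (d[p] > d[last]) {
        out[length(out)] <- p
      }
    }
    peaks <- out
  }
  peak_indices(peaks - 1L, n_samples = n)
}

#' Derive an RR series from R-peak locations
#'
#' Interval `k` is the elapsed time between peak `k` and peak `k + 1`:
#' `(indices[k + 1] - indices[k]) / sampling_rate_hz * 1000` ms. The result
#' has one interval fewer than there are peaks.
#'
#' @param peaks A [peak_indices] object or integer vector of 0-based
#'   offsets; at least two peaks are required.
#' @param sampling_rate_hz Sampling rate of the parent signal, in Hz.
#' @param subject_id Subject identifier for the derived series.
#' @return An [rr_series] with `source = "ekg_derived"`.
#' @export
rr_from_peaks <- function(peaks, sampling_rate_hz, subject_id = "unknown") {
  if (!inherits(peaks, "peak_indices")) peaks <- peak_indices(peaks)
  if (length(peaks) < 2) {
    stop("at least two peaks are required to form an RR interval",
         call. = FALSE)
  }
  if (sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  rr_series(diff(as.integer(peaks)) / sampling_rate_hz * 1000,
            subject_id = subject_id, source = "ekg_derived")
}
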