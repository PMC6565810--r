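# Zero-phase Butterworth band-pass filtering, the four canonical infant EEG
# bands, and the log-spaced carrier / amplitude filter banks.

#' Band specification around a center frequency
#'
#' Pass-band edges at `0.85 f` and `1.15 f`, stop-band edges at `0.5 f` and
#' `1.5 f`, with a stop-band attenuation of 20 dB: the narrow-band filter
#' geometry of the carrier and amplitude filter banks.
#'
#' @param f center frequency (Hz).
#' @param attenuation stop-band attenuation (dB), default 20.
#' @return an object of class `band_spec` with fields `center`, `pass_lo`,
#'   `pass_hi`, `stop_lo`, `stop_hi`, `attenuation`.
#' @export
band_spec <- function(f, attenuation = 20) {
  stopifnot(f > 0, attenuation > 0)
  structure(list(center = f, pass_lo = 0.85 * f, pass_hi = 1.15 * f,
                 stop_lo = 0.5 * f, stop_hi = 1.5 * f,
                 attenuation = attenuation),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("band_spec: center %.4g Hz, pass %.4g-%.4g, stop %.4g-%.4g, %g dB\n",
              x$center, x$pass_lo, x$pass_hi, x$stop_lo, x$stop_hi,
              x$attenuation))
  invisible(x)
}

#' The four canonical infant EEG frequency bands
#'
#' delta 0.4-1.5 Hz, theta 4-8 Hz, alpha 8-13 Hz, low beta 13-22 Hz.
#'
#' @return a data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo = c(0.4, 4, 8, 13),
             hi = c(1.5, 8, 13, 22))
}

#' Log-spaced carrier filter bank
#'
#' 21 narrow bands with centers `f_k = 0.5 * 1.2^(k-1)` Hz (so
#' `f_21 = 19.2` Hz): consecutive centers in a fixed ratio of 1.2, giving
#' bands of equal width on a logarithmic axis.
#'
#' @param attenuation stop-band attenuation (dB).
#' @return list of 21 [band_spec()] objects.
#' @export
build_carrier_bank <- function(attenuation = 20) {
  lapply(0.5 * 1.2^(0:20), band_spec, attenuation = attenuation)
}

#' Log-spaced amplitude (envelope) filter bank
#'
#' 15 narrow bands with centers `f_k = 0.015 * 1.2^(k-1)` Hz (so
#' `f_15 = 0.19` Hz), designed with the same geometry as the carrier bank and
#' applied to amplitude envelopes.
#'
#' @param attenuation stop-band attenuation (dB).
#' @return list of 15 [band_spec()] objects.
#' @export
build_amplitude_bank <- function(attenuation = 20) {
  lapply(0.015 * 1.2^(0:14), band_spec, attenuation = attenuation)
}

# minimal-order Butterworth meeting `atten` dB at the stop edge and a 0.5 dB
# droop at the pass edge for a single pass (the forward-backward application
# doubles both, keeping in-band tones within a few percent of unit gain).
# Order capped for numerical stability of the transfer-function form.
design_butter <- function(pass, stop, fs, atten, type, rp = 0.5,
                          max_order = 10) {
  nyq <- fs / 2
  if (pass <= 0 || pass >= nyq) stop("band edge outside (0, Nyquist)")
  stop <- max(min(stop, 0.98 * nyq), 1e-6)
  bo <- signal::buttord(Wp = pass / nyq, Ws = stop / nyq, Rp = rp,
                        Rs = atten)
  n <- min(bo$n, max_order)
  # very low normalized cutoffs make high-order transfer-function
  # coefficients singular in double precision: reduce the order until the
  # realized impulse response is numerically stable (bounded and decaying)
  repeat {
    flt <- signal::butter(n, bo$Wc, type = type)
    if (n == 1 || impulse_stable(flt, bo$Wc)) break
    n <- n - 1
  }
  flt
}

impulse_stable <- function(flt, wc) {
  # probe long enough to see divergence at slow time constants (~ 1/Wc)
  len <- min(2e5, max(5000, round(200 / max(min(wc), 1e-4))))
  h <- signal::filter(flt, c(1, numeric(len - 1)))
  m <- max(abs(h))
  is.finite(m) && m < 1e3 &&
    max(abs(h[(len - len %/% 20):len])) < 1e-6 * max(m, 1)
}

#' Zero-phase Butterworth band-pass filter
#'
#' A high-pass and a low-pass Butterworth filter applied in series, each run
#' forward and backward (`filtfilt`) so the output is zero-phase. Filter
#' orders are the smallest meeting `attenuation` dB at the stop-band edges in
#' a single pass; the forward-backward application then exceeds the target.
#'
#' @param ts numeric vector, or channels-by-time matrix (filtered per row).
#' @param lo,hi pass-band edges (Hz), `0 < lo < hi < fs/2`.
#' @param fs sampling rate (Hz).
#' @param attenuation stop-band attenuation (dB), default 20.
#' @param stop_lo,stop_hi stop-band edges (Hz); default `0.5 * lo` and
#'   `1.5 * hi`.
#' @return filtered series, same shape as the input.
#' @export
apply_bandpass <- function(ts, lo, hi, fs, attenuation = 20,
                           stop_lo = 0.5 * lo, stop_hi = 1.5 * hi) {
  if (!(0 < lo && lo < hi && hi < fs / 2))
    stop("band [", lo, ", ", hi, "] outside (0, Nyquist = ", fs / 2, ")")
  hp <- design_butter(lo, stop_lo, fs, attenuation, "high")
  lp <- design_butter(hi, stop_hi, fs, attenuation, "low")
  filt1 <- function(x) signal::filtfilt(lp, signal::filtfilt(hp, x))
  if (is.matrix(ts)) t(apply(ts, 1, filt1)) else filt1(as.numeric(ts))
}

#' Band-pass filter into a [band_spec()] band
#' @param ts numeric vector or channels-by-time matrix.
#' @param band a `band_spec`.
#' @param fs sampling rate (Hz).
#' @return filtered series, same shape.
#' @export
apply_band_spec <- function(ts, band, fs) {
  apply_bandpass(ts, band$pass_lo, band$pass_hi, fs,
                 attenuation = band$attenuation,
                 stop_lo = band$stop_lo, stop_hi = band$stop_hi)
}

#' Fourier resampling of a uniformly sampled series
#'
#' Exact (zero-phase, ripple-free) rate conversion for band-limited signals:
#' the spectrum is truncated (or zero-padded) to the new Nyquist band and
#' inverse-transformed at `round(n * fs_out / fs_in)` samples.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling rates (Hz).
#' @return resampled numeric vector.
#' @export
resample_fft <- function(x, fs_in, fs_out) {
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  keep <- min(n, n_out)
  half <- floor((keep - 1) / 2)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  }
  if (keep %% 2 == 0) {  # shared Nyquist bin, split evenly
    ny <- keep / 2 + 1
    if (n_out < n) Y[ny] <- X[ny] + X[n - keep / 2 + 1] else Y[ny] <- X[ny]
  }
  Re(stats::fft(Y, inverse = TRUE)) * n_out / n / n_out
}

#' Standard pre-processing to 100 Hz
#'
#' Zero-phase 0.15-45 Hz Butterworth band-pass, anti-aliased resampling to
#' 100 Hz, and re-referencing to the common average (per-sample channel mean
#' subtracted).
#'
#' @param ts channels-by-time numeric matrix.
#' @param fs_in input sampling rate (Hz), `>= 100`.
#' @param fs_out target rate (Hz), default 100.
#' @return channels-by-time matrix at `fs_out`.
#' @export
preprocess <- function(ts, fs_in, fs_out = 100) {
  if (!is.matrix(ts)) ts <- matrix(ts, nrow = 1)
  if (fs_in < fs_out) stop("fs_in must be >= ", fs_out)
  filtered <- apply_bandpass(ts, 0.15, 45, fs_in)
  if (fs_in != fs_out)
    filtered <- t(apply(filtered, 1, resample_fft, fs_in = fs_in,
                        fs_out = fs_out))
  sweep(filtered, 2, colMeans(filtered))
}

#' Instantaneous amplitude envelope (analytic signal)
#'
#' The magnitude of the analytic signal computed by the Fourier method
#' (positive frequencies doubled, negative frequencies zeroed).
#'
#' @param ts band-limited numeric vector.
#' @return non-negative envelope, same length.
#' @export
hilbert_envelope <- function(ts) {
  as.numeric(envelope_columns(matrix(as.numeric(ts), ncol = 1)))
}

# column-wise analytic-signal envelope restricted to a frequency band,
# evaluated at rate fs/fac: the analytic signal of a band-limited column is
# reconstructed by inverse-transforming only its positive-frequency passband
# bins (demodulated, so the envelope is unchanged) at reduced length. Real
# column pairs are packed into single complex FFTs. Numerically equal to the
# full-rate Hilbert envelope up to stop-band leakage of the preceding filter.
envelope_subband_columns <- function(X, fs, lo, hi, fac = 4L) {
  L <- nrow(X); K <- ncol(X)
  Ld <- L %/% fac
  stopifnot(Ld * fac == L)
  # widen the band to catch filter transition skirts
  b1 <- max(2L, 1L + floor(0.7 * lo * L / fs))
  b2 <- min(L %/% 2, 1L + ceiling(min(1.3 * hi, fs / 2) * L / fs))
  if (b2 - b1 + 1L > Ld) stop("decimation factor too large for the band")
  # packed FFT of real column pairs
  Kp <- ceiling(K / 2)
  odd <- seq(1L, by = 2L, length.out = Kp)
  even <- odd + 1L
  has_even <- even <= K
  imag_part <- matrix(0, L, Kp)
  imag_part[, has_even] <- X[, even[has_even], drop = FALSE]
  Zc <- matrix(complex(real = X[, odd, drop = FALSE],
                       imaginary = imag_part), L, Kp)
  Fz <- stats::mvfft(Zc)
  band <- b1:b2
  rev_band <- L - band + 2L  # band excludes DC, so no index-1 wraparound
  Fb <- Fz[band, , drop = FALSE]
  Fc <- Conj(Fz[rev_band, , drop = FALSE])
  Fx <- (Fb + Fc) / 2
  Fy <- (Fb - Fc) / (2i)
  out <- matrix(0, Ld, K)
  pack <- function(Fb) {
    Yd <- matrix(0i, Ld, ncol(Fb))
    Yd[seq_along(band), ] <- 2 * Fb
    Mod(stats::mvfft(Yd, inverse = TRUE)) / L
  }
  out[, odd] <- pack(Fx)
  if (any(has_even)) out[, even[has_even]] <- pack(Fy[, has_even,
                                                      drop = FALSE])
  out
}

# column-wise analytic-signal envelope of a time-by-channels matrix
envelope_columns <- function(X) {
  n <- nrow(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  A <- stats::mvfft(stats::mvfft(X) * h, inverse = TRUE) / n
  Mod(A)
}

#' Serialize a filter bank to JSON
#' @param bank list of [band_spec()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_bank <- function(bank, path) {
  jsonlite::write_json(lapply(bank, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a filter bank written by [write_filter_bank()]
#' @param path JSON path.
#' @return list of `band_spec` objects.
#' @export
read_filter_bank <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    band_spec(raw$center[i], attenuation = raw$attenuation[i]))
}
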