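#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward (zero group delay).
#' The default 6th-order design attenuates by more than 20 dB at
#' 1.25 x cutoff after the two passes while keeping the pass band flat.
#'
#' @param eeg A [continuous_eeg()].
#' @param cutoff Cutoff frequency in Hz. Must be below Nyquist.
#' @param order Butterworth order of a single pass.
#' @return A filtered [continuous_eeg()] with the same shape.
#' @export
lowpass_filter <- function(eeg, cutoff = 30, order = 6) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  nyq <- eeg$sampling_rate / 2
  if (cutoff >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  out <- eeg
  out$data <- t(apply(eeg$data, 1L, function(x) signal::filtfilt(bf, x)))
  out
}

#' Segment continuous data into overlapping epochs
#'
#' @param eeg A [continuous_eeg()].
#' @param length Epoch length in seconds.
#' @param overlap Fractional overlap between consecutive epochs.
#' @param keep Optional integer vector of epoch indices to retain
#'   (e.g. after an external quality screen); default keeps all.
#' @return An `epoch_set`: array `data` of epochs x channels x samples
#'   plus epoching metadata. Trailing samples that do not fill a full
#'   epoch are discarded. Epoch count is
#'   `floor((duration - length) / (length * (1 - overlap))) + 1`.
#' @export
segment_epochs <- function(eeg, length = 12, overlap = 0.5, keep = NULL) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  fs <- eeg$sampling_rate
  nsamp <- round(length * fs)
  dur <- eeg_duration(eeg)
  if (ncol(eeg$data) < nsamp) {
    stop(sprintf("recording (%.3f s) shorter than one epoch; need at least %g s",
                 dur, length), call. = FALSE)
  }
  step <- round(length * (1 - overlap) * fs)
  n_ep <- floor((ncol(eeg$data) - nsamp) / step) + 1L
  starts <- (seq_len(n_ep) - 1L) * step + 1L
  dat <- array(0, dim = c(n_ep, nrow(eeg$data), nsamp))
  for (e in seq_len(n_ep)) {
    dat[e, , ] <- eeg$data[, starts[e]:(starts[e] + nsamp - 1L), drop = FALSE]
  }
  if (!is.null(keep)) {
    keep <- sort(unique(as.integer(keep)))
    if (any(keep < 1L | keep > n_ep)) stop("`keep` indices out of range", call. = FALSE)
    dat <- dat[keep, , , drop = FALSE]
  }
  structure(
    list(data = dat, epoch_length = length, overlap = overlap,
         sampling_rate = fs, channel_labels = eeg$channel_labels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (%d channels, overlap %g)\n",
              dim(x$data)[1L], x$epoch_length, dim(x$data)[2L], x$overlap))
  invisible(x)
}

# Hanning-tapered one-sided Fourier coefficients per epoch and channel,
# normalised so that the mean auto-spectrum over bins of unit-variance
# white noise is ~1 (Parseval under the taper).
epoch_fft <- function(epochs, max_freq = 35) {
  dims <- dim(epochs$data)
  n_ep <- dims[1L]; n_ch <- dims[2L]; n <- dims[3L]
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  norm <- sqrt(sum(taper^2))
  freqs <- (seq_len(n) - 1L) / epochs$epoch_length
  sel <- which(freqs <= min(max_freq, epochs$sampling_rate / 2))
  coef <- array(complex(real = 0), dim = c(n_ep, n_ch, length(sel)))
  for (e in seq_len(n_ep)) {
    x <- epochs$data[e, , , drop = TRUE]
    if (n_ch == 1L) x <- matrix(x, nrow = 1L)
    ft <- stats::mvfft(t(x * rep(taper, each = n_ch))) / norm
    coef[e, , ] <- t(ft[sel, , drop = FALSE])
  }
  list(coef = coef, freqs = freqs[sel])
}

#' Per-epoch cross-spectral densities
#'
#' Computes Hanning-tapered Fourier coefficients for every epoch and
#' channel; cross-spectra between channels i and j at epoch e are
#' `coef[e, i, f] * Conj(coef[e, j, f])` and are materialised on demand
#' via [csd_matrix()]. The frequency resolution is `1 / epoch_length`
#' (1/12 Hz at the default epoching).
#'
#' @param epochs An `epoch_set` with at least 2 epochs (the dwPLI
#'   estimator needs multiple observations of the imaginary
#'   cross-spectrum).
#' @param max_freq Highest frequency (Hz) retained.
#' @return A `csd` object with `freqs`, complex `coef`
#'   (epochs x channels x freqs), `channel_labels`, `n_epochs`.
#' @export
compute_csd <- function(epochs, max_freq = 35) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- dim(epochs$data)[1L]
  if (n_ep < 2L) {
    stop("need at least 2 epochs: the debiased WPLI estimator requires ",
         "multiple epochs of the imaginary cross-spectrum", call. = FALSE)
  }
  ft <- epoch_fft(epochs, max_freq = max_freq)
  structure(
    list(freqs = ft$freqs, coef = ft$coef,
         channel_labels = epochs$channel_labels,
         n_epochs = n_ep, epoch_length = epochs$epoch_length,
         sampling_rate = epochs$sampling_rate),
    class = "csd"
  )
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("<csd> %d epochs, %d channels, %d frequency bins (%.3g-%.3g Hz)\n",
              x$n_epochs, dim(x$coef)[2L], length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Cross-spectral matrix of one epoch
#'
#' @param csd A `csd` object.
#' @param epoch Epoch index.
#' @return Complex array channels x channels x freqs; Hermitian in the
#'   channel pair at every frequency, with real nonnegative diagonal.
#' @export
csd_matrix <- function(csd, epoch) {
  stopifnot(inherits(csd, "csd"))
  a <- csd$coef[epoch, , , drop = FALSE]
  n_ch <- dim(csd$coef)[2L]; n_f <- dim(csd$coef)[3L]
  out <- array(complex(real = 0), dim = c(n_ch, n_ch, n_f))
  for (f in seq_len(n_f)) {
    v <- a[1L, , f]
    out[, , f] <- outer(v, Conj(v))
  }
  dimnames(out) <- list(csd$channel_labels, csd$channel_labels, NULL)
  out
}

#' Mean power spectral density per channel
#'
#' @param csd A `csd` object.
#' @return Tibble with columns `channel`, `freq`, `power` (auto-spectrum
#'   averaged over epochs).
#' @export
psd_from_csd <- function(csd) {
  stopifnot(inherits(csd, "csd"))
  pw <- apply(Mod(csd$coef)^2, c(2L, 3L), mean)
  tibble::tibble(
    channel = rep(csd$channel_labels, times = length(csd$freqs)),
    freq = rep(csd$freqs, each = length(csd$channel_labels)),
    power = as.vector(pw)
  )
}

#' Estimate the individual alpha peak frequency (IAPF)
#'
#' Per-channel power spectra (epoch-averaged) are smoothed with a
#' Savitzky-Golay filter; a channel contributes a peak when the smoothed
#' spectrum has a local maximum (negative curvature) strictly inside the
#' search window. The subject-level IAPF is the mean of contributing
#' channels' peak frequencies weighted by peak prominence.
#'
#' @param epochs An `epoch_set` (or a `csd` object).
#' @param search_window Two-element numeric, Hz; peaks are sought inside.
#' @param sg_window,sg_order Savitzky-Golay window length (bins, odd) and
#'   polynomial order used to smooth each channel's spectrum.
#' @param peak_ratio A candidate peak qualifies only if its smoothed
#'   height is at least this multiple of the median smoothed power in
#'   the search window; separates genuine alpha bumps from smoothing
#'   ripple on peakless spectra.
#' @return A list of class `iapf_estimate`: `iapf` (Hz, `NA` when no
#'   channel has a peak), `n_channels_contributing`, `quality_flag`
#'   (`"ok"` or `"no_peak"`), and the per-channel peak table.
#' @export
estimate_iapf <- function(epochs, search_window = c(7, 13),
                          sg_window = 11, sg_order = 5, peak_ratio = 2) {
  csd <- if (inherits(epochs, "csd")) epochs else {
    compute_csd(epochs, max_freq = max(search_window) + 5)
  }
  pw <- apply(Mod(csd$coef)^2, c(2L, 3L), mean)   # channels x freqs
  freqs <- csd$freqs
  peaks <- purrr::map_dfr(seq_len(nrow(pw)), function(ch) {
    sm <- tryCatch(signal::sgolayfilt(pw[ch, ], p = sg_order, n = sg_window),
                   error = function(e) pw[ch, ])
    pk <- pracma::findpeaks(sm, nups = 1, ndowns = 1)
    if (is.null(pk)) return(NULL)
    pk <- matrix(pk, ncol = 4L)
    f_pk <- freqs[pk[, 2L]]
    win <- freqs >= search_window[1L] & freqs <= search_window[2L]
    bg <- stats::median(sm[win])
    inside <- f_pk > search_window[1L] & f_pk < search_window[2L] &
      pk[, 1L] >= peak_ratio * bg
    if (!any(inside)) return(NULL)
    pk <- pk[inside, , drop = FALSE]
    f_pk <- f_pk[inside]
    prom <- pk[, 1L] - pmax(sm[pk[, 3L]], sm[pk[, 4L]])
    best <- which.max(pk[, 1L])
    tibble::tibble(channel = csd$channel_labels[ch],
                   peak_freq = f_pk[best],
                   prominence = max(prom[best], .Machine$double.eps))
  })
  if (nrow(peaks) == 0L) {
    out <- list(iapf = NA_real_, n_channels_contributing = 0L,
                quality_flag = "no_peak", channel_peaks = peaks,
                search_window = search_window)
  } else {
    out <- list(
      iapf = sum(peaks$peak_freq * peaks$prominence) / sum(peaks$prominence),
      n_channels_contributing = nrow(peaks),
      quality_flag = "ok", channel_peaks = peaks,
      search_window = search_window
    )
  }
  structure(out, class = "iapf_estimate")
}

#' @export
print.iapf_estimate <- function(x, ...) {
  if (x$quality_flag == "ok") {
    cat(sprintf("<iapf_estimate> IAPF = %.2f Hz (%d channels contributing)\n",
                x$iapf, x$n_channels_contributing))
  } else {
    cat("<iapf_estimate> no alpha peak detected\n")
  }
  invisible(x)
}

#' IAPF-anchored frequency band definitions
#'
#' Band edges are placed relative to the individual alpha peak
#' frequency: delta `[IAPF-8, IAPF-6)`, theta `[IAPF-6, IAPF-4)`, alpha
#' `[IAPF-4, IAPF+2)`, beta `[IAPF+2, 30]` (beta closed at 30 Hz). The
#' four bands tile `[IAPF-8, 30]` without gaps or overlap.
#'
#' @param iapf An `iapf_estimate` or a single numeric IAPF in Hz.
#' @param fallback If `TRUE` and no peak was detected, fall back to
#'   canonical bands anchored at 10 Hz instead of erroring.
#' @return Tibble with columns `band` (delta/theta/alpha/beta), `f_lo`,
#'   `f_hi`, `closed_hi` (whether the upper edge is included).
#' @export
derive_bands <- function(iapf, fallback = FALSE) {
  if (inherits(iapf, "iapf_estimate")) {
    if (iapf$quality_flag != "ok") {
      if (!fallback) {
        stop("no alpha peak detected; re-run with `fallback = TRUE` to use ",
             "canonical bands anchored at 10 Hz", call. = FALSE)
      }
      iapf <- 10
    } else {
      iapf <- iapf$iapf
    }
  }
  stopifnot(is.numeric(iapf), length(iapf) == 1L, is.finite(iapf))
  tibble::tibble(
    band = factor(c("delta", "theta", "alpha", "beta"),
                  levels = c("delta", "theta", "alpha", "beta")),
    f_lo = c(iapf - 8, iapf - 6, iapf - 4, iapf + 2),
    f_hi = c(iapf - 6, iapf - 4, iapf + 2, 30),
    closed_hi = c(FALSE, FALSE, FALSE, TRUE)
  )
}

# Indices of frequency bins whose centres fall in a band row.
band_bin_indices <- function(freqs, f_lo, f_hi, closed_hi = FALSE) {
  if (closed_hi) which(freqs >= f_lo & freqs <= f_hi)
  else which(freqs >= f_lo & freqs < f_hi)
}
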