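test_that("low-pass filter attenuates stop band and preserves pass band", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  tone <- function(f) sin(2 * pi * f * t)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))

  eeg40 <- continuous_eeg(matrix(tone(40), nrow = 1), "Cz", fs)
  out40 <- lowpass_filter(eeg40, cutoff = 30)
  expect_lt(max(abs(out40$data[1, mid])), 0.10)

  eeg10 <- continuous_eeg(matrix(tone(10), nrow = 1), "Cz", fs)
  out10 <- lowpass_filter(eeg10, cutoff = 30)
  expect_equal(max(abs(out10$data[1, mid])), 1, tolerance = 0.01)
  # zero phase: the filtered pass-band tone tracks the input sample by sample
  expect_lt(max(abs(out10$data[1, mid] - tone(10)[mid])), 0.02)

  expect_error(lowpass_filter(eeg10, cutoff = 500), "Nyquist")
})

test_that("filtered white-noise spectrum follows the analytic transfer function", {
  fs <- 250
  set.seed(11)
  x <- rnorm(fs * 240)
  eeg <- continuous_eeg(matrix(x, nrow = 1), "Cz", fs)
  out <- lowpass_filter(eeg, cutoff = 30, order = 6)
  csd_in <- compute_csd(segment_epochs(eeg), max_freq = 60)
  csd_out <- compute_csd(segment_epochs(out), max_freq = 60)
  p_in <- apply(Mod(csd_in$coef[, 1, ])^2, 2, mean)
  p_out <- apply(Mod(csd_out$coef[, 1, ])^2, 2, mean)
  # forward-backward Butterworth: |H|^2 per pass, squared magnitude overall
  h2 <- (1 / (1 + (csd_in$freqs / 30)^(2 * 6)))^2
  band <- csd_in$freqs > 1 & csd_in$freqs < 45
  ratio <- p_out[band] / p_in[band]
  # compare in dB above the taper-leakage floor (~-20 dB and up)
  keep <- h2[band] > 1e-2
  expect_lt(max(abs(10 * log10(ratio[keep]) - 10 * log10(h2[band][keep]))), 3)
})

test_that("epoch segmentation obeys the count formula and errors when short", {
  fs <- 250
  mk <- function(dur) continuous_eeg(matrix(rnorm(round(dur * fs)), nrow = 1), "Cz", fs)
  expect_equal(dim(segment_epochs(mk(60))$data)[1], 9)
  expect_equal(dim(segment_epochs(mk(12))$data)[1], 1)
  expect_error(segment_epochs(mk(11.9)), "12")

  set.seed(2)
  for (dur in runif(20, 12, 200)) {
    n_ep <- dim(segment_epochs(mk(dur))$data)[1]
    n_samp <- floor(round(dur * fs))
    expect_equal(n_ep, floor((n_samp - 12 * fs) / (6 * fs)) + 1)
  }
})

test_that("cross-spectra are Hermitian with real nonnegative diagonals", {
  set.seed(3)
  eeg <- continuous_eeg(matrix(rnorm(3 * 250 * 36), nrow = 3),
                        c("A", "B", "C"), 250)
  csd <- compute_csd(segment_epochs(eeg))
  for (e in c(1, dim(csd$coef)[1])) {
    m <- csd_matrix(csd, e)
    for (f in c(1, 50, dim(m)[3])) {
      expect_equal(m[, , f], Conj(t(m[, , f])))
      expect_true(all(Re(diag(m[, , f])) >= 0))
      expect_true(all(abs(Im(diag(m[, , f]))) < 1e-12))
    }
  }
  short <- continuous_eeg(matrix(rnorm(250 * 12), nrow = 1), "A", 250)
  expect_error(compute_csd(segment_epochs(short)), "2 epochs")
})

test_that("identical channels give purely real cross-spectra; a quarter-period lag shows in the imaginary part", {
  fs <- 250
  x <- rnorm(fs * 36)
  eeg <- continuous_eeg(rbind(x, x), c("A", "B"), fs)
  csd <- compute_csd(segment_epochs(eeg))
  m <- csd_matrix(csd, 1)
  expect_lt(max(abs(Im(m[1, 2, ]))), 1e-9)

  # channel B = A delayed by a quarter period of 10 Hz
  t <- seq_len(fs * 36) / fs
  a <- sin(2 * pi * 10 * t)
  b <- sin(2 * pi * 10 * (t - 1 / 40))
  csd2 <- compute_csd(segment_epochs(continuous_eeg(rbind(a, b), c("A", "B"), fs)))
  bin10 <- which.min(abs(csd2$freqs - 10))
  s_ab <- csd2$coef[1, 1, bin10] * Conj(csd2$coef[1, 2, bin10])
  # phase of the cross-spectrum equals the planted quarter-period lag
  expect_equal(Arg(s_ab), pi / 2, tolerance = 0.01)
  expect_gt(abs(Im(s_ab)), 10 * abs(Re(s_ab)))
  # direct DFT oracle on the tapered epoch reproduces the coefficient
  ep <- segment_epochs(continuous_eeg(rbind(a, b), c("A", "B"), fs))
  nsamp <- dim(ep$data)[3]
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, nsamp - 1) / (nsamp - 1)))
  k <- bin10 - 1
  basis <- exp(-2i * pi * k * seq(0, nsamp - 1) / nsamp)
  c_a <- sum(ep$data[1, 1, ] * taper * basis) / sqrt(sum(taper^2))
  expect_equal(c_a, csd2$coef[1, 1, bin10], tolerance = 1e-10)
})

test_that("auto-spectrum of unit white noise is flat at the taper normalisation", {
  set.seed(4)
  fs <- 250
  eeg <- continuous_eeg(matrix(rnorm(fs * 600), nrow = 1), "Cz", fs)
  csd <- compute_csd(segment_epochs(eeg), max_freq = 125)
  pw <- apply(Mod(csd$coef[, 1, ])^2, 2, mean)
  # mean power per bin ~ variance = 1 under the chosen normalisation
  expect_equal(mean(pw), 1, tolerance = 0.05)
  # and flat: halves of the spectrum agree
  h <- length(pw) %/% 2
  expect_equal(mean(pw[1:h]), mean(pw[(h + 1):(2 * h)]), tolerance = 0.1)
})

test_that("IAPF estimation finds planted peaks and flags flat spectra", {
  sub <- synthetic_subject("s", "younger", "female", iapf_true = 10,
                           n_channels = 3, duration = 180)
  csd <- compute_csd(segment_epochs(lowpass_filter(generate_subject_signals(sub, 5))))
  est <- estimate_iapf(csd)
  expect_identical(est$quality_flag, "ok")
  expect_equal(est$iapf, 10, tolerance = 0.2)
  expect_gte(est$n_channels_contributing, 1)

  set.seed(6)
  flat <- continuous_eeg(matrix(rnorm(250 * 120), nrow = 1), "Cz", 250)
  est_flat <- estimate_iapf(compute_csd(segment_epochs(flat)))
  expect_identical(est_flat$quality_flag, "no_peak")
  expect_true(is.na(est_flat$iapf))
})

test_that("with two alpha bumps the larger one wins", {
  # small bump at 9 Hz, large at 11 Hz, on 1/f-ish background
  fs <- 250
  set.seed(7)
  n <- fs * 240
  t <- seq_len(n) / fs
  mk_band <- function(f) {
    bf <- signal::butter(4, c(f - 0.7, f + 0.7) / (fs / 2), type = "pass")
    y <- signal::filtfilt(bf, rnorm(n))
    y / sd(y)
  }
  x <- 0.4 * mk_band(9) + 1.0 * mk_band(11) + rnorm(n) * 0.3
  est <- estimate_iapf(compute_csd(segment_epochs(continuous_eeg(matrix(x, 1), "Cz", fs))))
  expect_identical(est$quality_flag, "ok")
  expect_equal(est$iapf, 11, tolerance = 0.3)
})

test_that("band rule follows the IAPF-relative offsets and tiles [IAPF-8, 30]", {
  b10 <- derive_bands(10)
  expect_equal(b10$f_lo, c(2, 4, 6, 12))
  expect_equal(b10$f_hi, c(4, 6, 12, 30))
  b94 <- derive_bands(9.4)
  expect_equal(b94$f_lo[3], 5.4)
  expect_equal(b94$f_hi[3], 11.4)
  b13 <- derive_bands(13)
  expect_equal(c(b13$f_lo[1], b13$f_hi[1]), c(5, 7))

  for (iapf in seq(7, 13, by = 0.37)) {
    b <- derive_bands(iapf)
    expect_equal(b$f_lo[1], iapf - 8)
    expect_equal(b$f_hi[4], 30)
    # adjacent edges coincide: no gaps, no overlaps
    expect_equal(b$f_hi[1:3], b$f_lo[2:4])
  }

  flat_est <- structure(list(iapf = NA_real_, quality_flag = "no_peak"),
                        class = "iapf_estimate")
  expect_error(derive_bands(flat_est), "canonical")
  expect_equal(derive_bands(flat_est, fallback = TRUE)$f_lo[3], 6)
})
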