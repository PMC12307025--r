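#' @title Synthetic EEG cohorts with known ground truth
#'
#' @description
#' The generator emulates eyes-closed resting recordings: per channel a
#' band-limited stochastic alpha oscillator centred on the subject's
#' alpha peak, 1/f background noise, optional instantaneously shared
#' (zero-lag) common source, and cross-channel phase-lagged coupling
#' along planted module structure. Because coupling is implemented by
#' sharing a lagged copy of the source oscillator, the imaginary
#' cross-spectrum — the raw material of the dwPLI — is under direct
#' control, which makes every downstream stage verifiable.
#' @name synthetic_eeg
NULL

# run code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Standard 10-10 channel labels
#'
#' @param n Number of channels (<= 61 uses the standard eyes-closed
#'   61-channel montage order; larger n appends generic labels).
#' @return Character vector of `n` unique labels.
#' @export
ten_ten_labels <- function(n = 61) {
  base <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
            "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
            "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
            "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
            "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
            "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
            "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("X%02d", seq_len(n - length(base))))
}

#' Specify one phase-lagged coupling between two channels
#'
#' @param source_channel,target_channel Channel labels (must differ).
#' @param band Band name the coupling lives in (`"alpha"` etc.).
#' @param phase_lag Phase lag in radians, in (-pi, pi]. The default
#'   pi/2 maximises the imaginary cross-spectrum.
#' @param strength Coupling strength in `[0, 1]`: the fraction of the
#'   target's band oscillator replaced by a lagged copy of the source's.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(source_channel, target_channel, band = "alpha",
                          phase_lag = pi / 2, strength = 0.4) {
  if (identical(source_channel, target_channel)) {
    stop("source and target channel must differ", call. = FALSE)
  }
  if (phase_lag <= -pi || phase_lag > pi) {
    stop("`phase_lag` must be in (-pi, pi]", call. = FALSE)
  }
  if (strength < 0 || strength > 1) stop("`strength` must be in [0, 1]", call. = FALSE)
  structure(list(source_channel = source_channel,
                 target_channel = target_channel,
                 band = band, phase_lag = phase_lag, strength = strength),
            class = "coupling_spec")
}

#' Specify one synthetic subject
#'
#' @param subject_id Subject identifier.
#' @param age_group `"younger"` or `"older"`.
#' @param sex `"female"` or `"male"`.
#' @param iapf_true True alpha peak frequency in Hz, in `[7, 13]`.
#' @param couplings List of [coupling_spec()] objects.
#' @param n_channels Number of channels (10-10 labels assigned).
#' @param module_assignment Optional named integer vector channel ->
#'   community id (defaults to 4 contiguous modules).
#' @param noise_exponent 1/f background slope (power ~ 1/f^exponent).
#' @param zero_lag_mix Mixing coefficient in `[0, 1)` of an
#'   instantaneously shared broadband source (volume-conduction
#'   surrogate).
#' @param sampling_rate Hz, >= 250.
#' @param duration Seconds; must fit at least one 12 s analysis epoch,
#'   >= 60 s recommended for stable connectivity estimates.
#' @return A `synthetic_subject` list.
#' @export
synthetic_subject <- function(subject_id, age_group = c("younger", "older"),
                              sex = c("female", "male"), iapf_true = 10,
                              couplings = list(), n_channels = 61,
                              module_assignment = NULL,
                              noise_exponent = 1, zero_lag_mix = 0,
                              sampling_rate = 250, duration = 120) {
  age_group <- match.arg(age_group)
  sex <- match.arg(sex)
  if (iapf_true < 7 || iapf_true > 13) stop("`iapf_true` must be in [7, 13] Hz", call. = FALSE)
  if (sampling_rate < 250) stop("`sampling_rate` must be >= 250 Hz", call. = FALSE)
  if (duration < 12) {
    stop("`duration` too short: need at least 12 s to fit one analysis epoch",
         call. = FALSE)
  }
  if (zero_lag_mix < 0 || zero_lag_mix >= 1) {
    stop("`zero_lag_mix` must be in [0, 1)", call. = FALSE)
  }
  labels <- ten_ten_labels(n_channels)
  if (is.null(module_assignment)) {
    k <- min(4L, n_channels)
    module_assignment <- stats::setNames(
      sort(rep_len(seq_len(k), n_channels)), labels)
  }
  for (cp in couplings) {
    if (!all(c(cp$source_channel, cp$target_channel) %in% labels)) {
      stop("coupling references a channel not in the montage", call. = FALSE)
    }
  }
  structure(
    list(subject_id = subject_id, age_group = age_group, sex = sex,
         iapf_true = iapf_true, couplings = couplings,
         channel_labels = labels, module_assignment = module_assignment,
         noise_exponent = noise_exponent, zero_lag_mix = zero_lag_mix,
         sampling_rate = sampling_rate, duration = duration),
    class = "synthetic_subject"
  )
}

# 1/f^beta noise via spectral shaping, unit variance
pink_noise <- function(n, fs, beta = 1) {
  x <- stats::rnorm(n)
  if (beta == 0) return(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1)) * fs / n          # avoid DC blow-up
  f <- pmin(f, fs - f + fs / n)               # mirror for negative freqs
  X <- X * f^(-beta / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

# unit-variance band-limited noise oscillator
narrowband_noise <- function(n, fs, f_lo, f_hi) {
  nyq <- fs / 2
  bf <- signal::butter(4, c(max(f_lo, 0.1), min(f_hi, nyq * 0.99)) / nyq,
                       type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n))
  (y - mean(y)) / stats::sd(y)
}

#' Generate one subject's multichannel signals
#'
#' Each channel carries a unit-variance alpha-band oscillator centred on
#' the subject's true alpha peak plus 1/f noise. Each coupling replaces
#' a fraction `strength` of the target's band oscillator with a copy of
#' the source's oscillator delayed by `phase_lag` (converted to samples
#' at the band's centre frequency), inducing a nonzero imaginary
#' cross-spectrum in that band. `zero_lag_mix` blends in one shared
#' broadband source identically (zero lag) across all channels.
#'
#' @param subject A [synthetic_subject()].
#' @param seed Integer seed; the output is deterministic given
#'   `subject` and `seed`.
#' @return A [continuous_eeg()].
#' @export
generate_subject_signals <- function(subject, seed = 1) {
  stopifnot(inherits(subject, "synthetic_subject"))
  fs <- subject$sampling_rate
  n <- round(subject$duration * fs)
  if (subject$duration < 12) {
    stop("`duration` too short: need at least 12 s to fit one analysis epoch",
         call. = FALSE)
  }
  labels <- subject$channel_labels
  nc <- length(labels)
  bands <- derive_bands(subject$iapf_true)
  alpha_row <- bands[bands$band == "alpha", ]
  with_seed(seed, {
    # per-channel alpha oscillator: a sharp component at the true peak
    # (+-1 Hz) riding on a full-band alpha plateau, so the spectrum peaks
    # at iapf_true while alpha-band couplings cover every bin of the band
    osc <- list()
    for (ch in labels) {
      osc[[paste0(ch, ".alpha")]] <-
        (narrowband_noise(n, fs, subject$iapf_true - 1, subject$iapf_true + 1) +
         narrowband_noise(n, fs, alpha_row$f_lo, alpha_row$f_hi)) / sqrt(2)
    }
    # oscillators for non-alpha coupled bands, then apply couplings
    for (cp in subject$couplings) {
      brow <- bands[as.character(bands$band) == cp$band, ]
      if (nrow(brow) == 0L) stop("unknown coupling band: ", cp$band, call. = FALSE)
      for (ch in c(cp$source_channel, cp$target_channel)) {
        key <- paste0(ch, ".", cp$band)
        if (is.null(osc[[key]])) {
          osc[[key]] <- narrowband_noise(n, fs, brow$f_lo, brow$f_hi)
        }
      }
    }
    for (cp in subject$couplings) {
      brow <- bands[as.character(bands$band) == cp$band, ]
      f_c <- (brow$f_lo + brow$f_hi) / 2
      lag <- round(cp$phase_lag / (2 * pi * f_c) * fs)
      src <- osc[[paste0(cp$source_channel, ".", cp$band)]]
      lagged <- if (lag == 0) src else {
        lag <- ((lag %% n) + n) %% n
        c(src[(n - lag + 1L):n], src[seq_len(n - lag)])
      }
      key <- paste0(cp$target_channel, ".", cp$band)
      s <- cp$strength
      osc[[key]] <- sqrt(1 - s^2) * osc[[key]] + s * lagged
    }
    dat <- matrix(0, nrow = nc, ncol = n)
    for (i in seq_len(nc)) {
      parts <- osc[grepl(paste0("^", labels[i], "\\."), names(osc))]
      dat[i, ] <- Reduce(`+`, parts) + pink_noise(n, fs, subject$noise_exponent)
    }
    if (subject$zero_lag_mix > 0) {
      shared <- narrowband_noise(n, fs, subject$iapf_true - 1, subject$iapf_true + 1) +
        pink_noise(n, fs, subject$noise_exponent)
      rho <- subject$zero_lag_mix
      dat <- (1 - rho) * dat + rho * matrix(shared, nc, n, byrow = TRUE)
    }
    continuous_eeg(dat * 10, labels, fs)  # ~10 uV scale
  })
}

#' Specify a synthetic cohort
#'
#' @param n_per_group Subjects per age group (>= 2).
#' @param n_channels Channels per subject.
#' @param planted_betas Named numeric vector of regression coefficients
#'   generating semantic-fluency scores from a z-scaled graph metric:
#'   `intercept`, `metric`, `age` (older vs younger), `sex` (male vs
#'   female), `metric_age` (metric x older interaction). Defaults echo
#'   typical semantic-fluency group means (25 vs 22 words).
#' @param planted_betas_letter Same structure for letter fluency
#'   (defaults echo 15 vs 13 words).
#' @param residual_sd Gaussian residual SD of the planted score model.
#' @param iapf_mean_younger,iapf_mean_older,iapf_sd Group alpha-peak
#'   distributions in Hz (defaults 10.1 / 9.4, SD 0.9).
#' @param coupling_strength,coupling_band,phase_lag Planted within-module
#'   chain couplings.
#' @param sampling_rate,duration Per-subject recording parameters.
#' @param noise_exponent,zero_lag_mix Passed to each subject.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group, n_channels = 61,
                        planted_betas = c(intercept = 25, metric = 2,
                                          age = -3, sex = 0, metric_age = 0),
                        planted_betas_letter = c(intercept = 15, metric = 1,
                                                 age = -2, sex = 0, metric_age = 0),
                        residual_sd = 2,
                        iapf_mean_younger = 10.1, iapf_mean_older = 9.4,
                        iapf_sd = 0.9,
                        coupling_strength = 0.4, coupling_band = "alpha",
                        phase_lag = pi / 2,
                        sampling_rate = 250, duration = 120,
                        noise_exponent = 1, zero_lag_mix = 0, seed = 1) {
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  if (residual_sd < 0) stop("`residual_sd` must be >= 0", call. = FALSE)
  needed <- c("intercept", "metric", "age", "sex", "metric_age")
  for (b in list(planted_betas, planted_betas_letter)) {
    if (!all(needed %in% names(b))) {
      stop("planted beta vectors need names: ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group), n_channels = n_channels,
         planted_betas = planted_betas,
         planted_betas_letter = planted_betas_letter,
         residual_sd = residual_sd,
         iapf_mean_younger = iapf_mean_younger,
         iapf_mean_older = iapf_mean_older, iapf_sd = iapf_sd,
         coupling_strength = coupling_strength,
         coupling_band = coupling_band, phase_lag = phase_lag,
         sampling_rate = sampling_rate, duration = duration,
         noise_exponent = noise_exponent, zero_lag_mix = zero_lag_mix,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# deterministic per-subject seed below 2^31
subject_seed <- function(seed, index) {
  (as.numeric(seed) * 2654435761 + index * 97) %% 2147483647
}

# within-module couplings for one subject: a chain of first neighbours
# at full strength plus second-neighbour chords at half strength (so
# modules carry graded coherence with genuine triangles), and a weak
# ring linking module representatives so the graph has inter-module
# structure rather than a strict block pattern
module_chain_couplings <- function(labels, module_assignment, band,
                                   strength, phase_lag) {
  out <- list()
  mods <- unique(module_assignment)
  for (m in mods) {
    chs <- labels[module_assignment[labels] == m]
    if (length(chs) < 2L) next
    for (k in seq_len(length(chs) - 1L)) {
      out[[length(out) + 1L]] <-
        coupling_spec(chs[k], chs[k + 1L], band = band,
                      phase_lag = phase_lag, strength = strength)
    }
    if (length(chs) >= 3L) {
      for (k in seq_len(length(chs) - 2L)) {
        out[[length(out) + 1L]] <-
          coupling_spec(chs[k], chs[k + 2L], band = band,
                        phase_lag = phase_lag, strength = strength / 2)
      }
    }
  }
  if (length(mods) >= 2L) {
    reps <- labels[!duplicated(module_assignment[labels])]
    for (k in seq_along(reps)) {
      out[[length(out) + 1L]] <-
        coupling_spec(reps[k], reps[(k %% length(reps)) + 1L], band = band,
                      phase_lag = phase_lag, strength = strength * 0.375)
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws `2 * n_per_group` subjects (balanced age groups and sexes) with
#' group-specific alpha-peak distributions — older adults are drawn with
#' a lower mean IAPF than younger adults — and planted within-module
#' phase-lagged couplings.
#'
#' @param spec A [cohort_spec()].
#' @param materialise_signals If `TRUE`, also generate and return every
#'   subject's [continuous_eeg()] (memory-heavy for large cohorts; the
#'   pipeline instead generates signals per subject on the fly).
#' @return A list with `subjects` (tibble: subject_id, age_group, sex,
#'   iapf_true, seed, and a list-column `subject` of
#'   [synthetic_subject()] objects) and `signals` (named list of
#'   `continuous_eeg` or `NULL`).
#' @export
generate_cohort <- function(spec, materialise_signals = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_group
  ids <- sprintf("sub-%03d", seq_len(n))
  age <- rep(c("younger", "older"), each = spec$n_per_group)
  sex <- rep_len(c("female", "male"), n)
  labels <- ten_ten_labels(spec$n_channels)
  k <- min(4L, spec$n_channels)
  modules <- stats::setNames(sort(rep_len(seq_len(k), spec$n_channels)), labels)
  iapf <- with_seed(spec$seed, {
    mu <- ifelse(age == "older", spec$iapf_mean_older, spec$iapf_mean_younger)
    pmin(pmax(stats::rnorm(n, mu, spec$iapf_sd), 7), 13)
  })
  couplings <- module_chain_couplings(labels, modules, spec$coupling_band,
                                      spec$coupling_strength, spec$phase_lag)
  subjects <- purrr::map(seq_len(n), function(i) {
    synthetic_subject(
      subject_id = ids[i], age_group = age[i], sex = sex[i],
      iapf_true = iapf[i], couplings = couplings,
      n_channels = spec$n_channels, module_assignment = modules,
      noise_exponent = spec$noise_exponent,
      zero_lag_mix = spec$zero_lag_mix,
      sampling_rate = spec$sampling_rate, duration = spec$duration
    )
  })
  tab <- tibble::tibble(
    subject_id = ids, age_group = age, sex = sex, iapf_true = iapf,
    seed = subject_seed(spec$seed, seq_len(n)),
    subject = subjects
  )
  signals <- NULL
  if (materialise_signals) {
    signals <- purrr::map2(subjects, tab$seed, generate_subject_signals)
    names(signals) <- ids
  }
  list(subjects = tab, signals = signals)
}

#' Plant verbal-fluency scores on computed graph metrics
#'
#' Scores follow a linear model on one z-scaled graph metric with
#' treatment-coded age and sex and a metric x age interaction, plus
#' Gaussian noise, rounded to nonnegative integers (fluency scores are
#' word counts). Subjects whose metric is missing get a missing score —
#' nothing is imputed.
#'
#' @param metrics Tibble of per-subject metric records (long or wide;
#'   must contain `subject_id`, `band` and the chosen metric column).
#' @param subjects Subject table from [generate_cohort()] (needs
#'   `subject_id`, `age_group`, `sex`).
#' @param spec The [cohort_spec()] carrying `planted_betas`,
#'   `planted_betas_letter`, `residual_sd` and `seed`.
#' @param metric Metric column used as the planted predictor.
#' @param band Band whose metric drives the scores.
#' @return Tibble: `subject_id`, `age_group`, `sex`, `semantic_fluency`,
#'   `letter_fluency`.
#' @export
plant_fluency_scores <- function(metrics, subjects, spec,
                                 metric = "dwpli_mean", band = "alpha") {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!metric %in% names(metrics)) {
    stop("metric column not found in `metrics`: ", metric, call. = FALSE)
  }
  m <- metrics[as.character(metrics$band) == band,
               c("subject_id", metric)]
  names(m)[2L] <- ".metric"
  tab <- dplyr::left_join(
    subjects[, c("subject_id", "age_group", "sex")], m, by = "subject_id")
  ok <- !is.na(tab$.metric)
  z <- rep(NA_real_, nrow(tab))
  z[ok] <- as.numeric(scale(tab$.metric[ok]))
  older <- as.numeric(tab$age_group == "older")
  male <- as.numeric(tab$sex == "male")
  lp <- function(b) {
    b[["intercept"]] + b[["metric"]] * z + b[["age"]] * older +
      b[["sex"]] * male + b[["metric_age"]] * z * older
  }
  with_seed(spec$seed + 1L, {
    noise_s <- stats::rnorm(nrow(tab), 0, spec$residual_sd)
    noise_l <- stats::rnorm(nrow(tab), 0, spec$residual_sd)
    sem <- pmax(0, round(lp(spec$planted_betas) + noise_s))
    let <- pmax(0, round(lp(spec$planted_betas_letter) + noise_l))
  })
  sem[!ok] <- NA_real_
  let[!ok] <- NA_real_
  tibble::tibble(subject_id = tab$subject_id, age_group = tab$age_group,
                 sex = tab$sex, semantic_fluency = sem, letter_fluency = let)
}

#' Write a behavioural table as TSV
#'
#' @param scores Tibble from [plant_fluency_scores()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_behavioural <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
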