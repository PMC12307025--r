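#' Construct a continuous EEG recording
#'
#' The entry point of the pipeline: a cleaned multichannel time series.
#' Artifact removal is assumed to have happened upstream; the pipeline
#' operates on clean continuous data only.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector of unique channel names
#'   (10-10 system names for real recordings), one per row of `data`.
#' @param sampling_rate Sampling rate in Hz.
#'
#' @return An object of class `continuous_eeg` with elements `data`,
#'   `channel_labels`, `sampling_rate`.
#' @export
#' @examples
#' eeg <- continuous_eeg(matrix(rnorm(2 * 500), nrow = 2),
#'                       c("Cz", "Pz"), sampling_rate = 250)
#' eeg
continuous_eeg <- function(data, channel_labels, sampling_rate) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite samples in `data` (first at channel %d ['%s'], sample %d)",
      bad[1L], if (length(channel_labels) >= bad[1L]) channel_labels[bad[1L]] else "?",
      bad[2L]
    ), call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (nrow(data) < 1L) stop("need at least one channel", call. = FALSE)
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must have one entry per channel (row)", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(data = data, channel_labels = channel_labels,
         sampling_rate = as.numeric(sampling_rate)),
    class = "continuous_eeg"
  )
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param eeg A `continuous_eeg`.
#' @return Length in seconds.
#' @export
eeg_duration <- function(eeg) ncol(eeg$data) / eeg$sampling_rate

#' Read a continuous EEG recording from a matrix file with a JSON sidecar
#'
#' The on-disk format is a plain-text numeric matrix (one channel per row,
#' whitespace-separated samples, file `<stem>.dat`) plus a JSON sidecar
#' `<stem>.json` holding `channel_labels` and `sampling_rate`.
#'
#' @param path Path to the `.dat` matrix file (or its stem).
#' @return A [continuous_eeg()].
#' @export
read_eeg <- function(path) {
  stem <- sub("\\.dat$", "", path)
  dat_path <- paste0(stem, ".dat")
  side_path <- paste0(stem, ".json")
  if (!file.exists(dat_path)) stop("matrix file not found: ", dat_path, call. = FALSE)
  if (!file.exists(side_path)) {
    stop("sidecar with channel labels and sampling rate not found: ", side_path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (is.null(meta$channel_labels) || is.null(meta$sampling_rate)) {
    stop("sidecar must contain `channel_labels` and `sampling_rate`", call. = FALSE)
  }
  mat <- as.matrix(utils::read.table(dat_path, header = FALSE))
  dimnames(mat) <- NULL
  continuous_eeg(mat, meta$channel_labels, meta$sampling_rate)
}

#' Write a continuous EEG recording as matrix + JSON sidecar
#'
#' @param eeg A [continuous_eeg()].
#' @param path Output path stem (or `.dat` path); writes `<stem>.dat`
#'   and `<stem>.json`.
#' @param digits Significant digits kept in the text matrix.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(eeg, path, digits = 8) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  stem <- sub("\\.dat$", "", path)
  utils::write.table(signif(eeg$data, digits), paste0(stem, ".dat"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(channel_labels = eeg$channel_labels,
         sampling_rate = eeg$sampling_rate, units = "uV"),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
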