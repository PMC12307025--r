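#' @title Debiased weighted phase lag index (dwPLI)
#'
#' @description
#' The dwPLI quantifies consistent nonzero-lag phase synchronisation
#' between two signals from the imaginary parts of their cross-spectrum
#' across epochs, with a small-sample (debiasing) correction. With
#' `I_k = Im(S_xy)` at epoch `k`, the per-bin estimate is
#'
#'   \deqn{((\sum_k I_k)^2 - \sum_k I_k^2) /
#'         ((\sum_k |I_k|)^2 - \sum_k I_k^2)}
#'
#' The estimator is insensitive to instantaneous (zero-lag) mixing such
#' as volume conduction, whose cross-spectra are purely real. When all
#' `I_k` are exactly zero the denominator vanishes and the estimate is
#' defined as 0 (no measurable lagged coupling), flagged degenerate.
#' @name dwpli
NULL

# Signed per-bin dwPLI for all channel pairs over a set of frequency
# bins. Returns n_ch x n_ch x n_bins array (diagonal NaN-free: the
# diagonal has I_k = 0 so the degenerate rule puts 0 there).
dwpli_bin_array <- function(csd, bins) {
  stopifnot(inherits(csd, "csd"))
  n_ch <- dim(csd$coef)[2L]
  ii <- rep(seq_len(n_ch), times = n_ch)
  jj <- rep(seq_len(n_ch), each = n_ch)
  out <- array(0, dim = c(n_ch, n_ch, length(bins)))
  for (b in seq_along(bins)) {
    a <- csd$coef[, , bins[b], drop = FALSE]
    dim(a) <- dim(a)[1:2]                      # epochs x channels
    re <- Re(a); im <- Im(a)
    # Im(x_i * Conj(x_j)) = im_i * re_j - re_i * im_j, per epoch
    I <- im[, ii, drop = FALSE] * re[, jj, drop = FALSE] -
         re[, ii, drop = FALSE] * im[, jj, drop = FALSE]
    s1 <- colSums(I); s2 <- colSums(I^2); s3 <- colSums(abs(I))
    num <- s1^2 - s2
    den <- s3^2 - s2
    est <- ifelse(den == 0, 0, num / den)
    out[, , b] <- matrix(est, n_ch, n_ch)
  }
  out
}

#' Signed dwPLI estimate for one channel pair at one frequency bin
#'
#' @param csd A `csd` object (>= 2 epochs).
#' @param pair Length-2 vector of channel labels or indices.
#' @param bin Frequency bin index (into `csd$freqs`).
#' @return A single signed estimate in `[-1, 1]`, with attribute
#'   `degenerate = TRUE` when every epoch's imaginary cross-spectrum is
#'   zero (the estimate is then 0 by convention).
#' @export
#' @examples
#' # perfectly consistent lag sign across epochs gives 1; an
#' # alternating sign can drive the debiased estimate negative.
dwpli_per_bin <- function(csd, pair, bin) {
  stopifnot(inherits(csd, "csd"))
  if (csd$n_epochs < 2L) stop("dwPLI needs >= 2 epochs", call. = FALSE)
  idx <- pair
  if (is.character(pair)) idx <- match(pair, csd$channel_labels)
  if (anyNA(idx)) stop("unknown channel label in `pair`", call. = FALSE)
  x <- csd$coef[, idx[1L], bin]
  y <- csd$coef[, idx[2L], bin]
  I <- Im(x * Conj(y))
  s1 <- sum(I); s2 <- sum(I^2); s3 <- sum(abs(I))
  den <- s3^2 - s2
  if (den == 0) return(structure(0, degenerate = TRUE))
  structure((s1^2 - s2) / den, degenerate = FALSE)
}

#' Band-level dwPLI connectivity matrix
#'
#' Signed per-bin estimates are averaged over the band's frequency bins
#' and the absolute value of that band average is taken, giving the
#' strength of oscillatory synchronisation between channel pairs
#' irrespective of lag direction. The alternative order (absolute value
#' per bin, then average) is available via `abs_per_bin = TRUE` but
#' inflates the null and is not the default.
#'
#' @param csd A `csd` object.
#' @param band One row of [derive_bands()] (or a list with `band`,
#'   `f_lo`, `f_hi`, optional `closed_hi`).
#' @param abs_per_bin Take `|.|` before instead of after averaging bins.
#' @return A `connectivity_matrix`: symmetric `weights` in `[0, 1]` with
#'   zero diagonal, `band`, `labels`, `n_epochs_used`.
#' @export
band_dwpli <- function(csd, band, abs_per_bin = FALSE) {
  stopifnot(inherits(csd, "csd"))
  if (csd$n_epochs < 2L) stop("dwPLI needs >= 2 epochs", call. = FALSE)
  closed <- if (!is.null(band$closed_hi)) isTRUE(band$closed_hi) else FALSE
  bins <- band_bin_indices(csd$freqs, band$f_lo, band$f_hi, closed)
  if (length(bins) == 0L) {
    stop(sprintf("band '%s' [%g, %g%s contains no frequency bins at resolution %g Hz",
                 as.character(band$band), band$f_lo, band$f_hi,
                 if (closed) "]" else ")", 1 / csd$epoch_length), call. = FALSE)
  }
  est <- dwpli_bin_array(csd, bins)
  w <- if (abs_per_bin) apply(abs(est), c(1L, 2L), mean)
       else abs(apply(est, c(1L, 2L), mean))
  w <- (w + t(w)) / 2          # symmetric up to float noise already
  diag(w) <- 0
  dimnames(w) <- list(csd$channel_labels, csd$channel_labels)
  structure(
    list(band = as.character(band$band), labels = csd$channel_labels,
         weights = w, n_epochs_used = csd$n_epochs,
         f_lo = band$f_lo, f_hi = band$f_hi),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> band %s [%g, %g), %d channels, %d epochs, mean weight %.3f\n",
              x$band, x$f_lo, x$f_hi, length(x$labels), x$n_epochs_used,
              summarize_dwpli(x)))
  invisible(x)
}

#' Scalar connectivity strength of a matrix
#'
#' Mean of the off-diagonal upper-triangle weights: the per-subject,
#' per-band overall connectedness used as a predictor downstream.
#'
#' @param matrix A `connectivity_matrix` or a plain symmetric matrix.
#' @return A scalar in `[0, 1]`.
#' @export
summarize_dwpli <- function(matrix) {
  w <- if (inherits(matrix, "connectivity_matrix")) matrix$weights else matrix
  mean(w[upper.tri(w)])
}

#' Connectivity matrix as a tidy edge table
#'
#' @param matrix A `connectivity_matrix`.
#' @return Tibble with `from`, `to`, `weight` (upper triangle only).
#' @export
connectivity_edges <- function(matrix) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  ut <- which(upper.tri(matrix$weights), arr.ind = TRUE)
  tibble::tibble(
    from = matrix$labels[ut[, 1L]],
    to = matrix$labels[ut[, 2L]],
    weight = matrix$weights[ut]
  )
}

#' Write a connectivity matrix as CSV plus JSON metadata sidecar
#'
#' @param matrix A `connectivity_matrix`.
#' @param path Output CSV path; the sidecar replaces `.csv` with `.json`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(matrix, path) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  df <- as.data.frame(matrix$weights)
  utils::write.csv(cbind(channel = matrix$labels, df), path, row.names = FALSE)
  jsonlite::write_json(
    list(band = matrix$band, f_lo = matrix$f_lo, f_hi = matrix$f_hi,
         n_epochs_used = matrix$n_epochs_used),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
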