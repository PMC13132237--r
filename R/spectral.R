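#' Frequency band definition
#'
#' @param name Band label.
#' @param lo,hi Band edges in Hz, `lo < hi`.
#' @return A `band_definition`.
#' @export
band_definition <- function(name, lo, hi) {
  if (!(lo < hi)) stop("band '", name, "': lo must be < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' Canonical EEG bands
#'
#' Delta 1-4, theta 4-8, alpha 8-12 and beta 12-20 Hz. The four bands
#' partition 1-20 Hz, so their band powers sum to the total 1-20 Hz area.
#'
#' @return List of [band_definition()]s.
#' @export
default_bands <- function() {
  list(band_definition("delta", 1, 4), band_definition("theta", 4, 8),
       band_definition("alpha", 8, 12), band_definition("beta", 12, 20))
}

# Cache for Slepian tapers keyed by (n, nw, k).
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the DPSS. For series longer than `base_n` samples the
#' tapers are computed at `base_n` and spline-interpolated to length `n`,
#' then re-orthonormalised; this keeps the dense eigendecomposition at a
#' fixed modest size while preserving taper orthonormality.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @param base_n Maximum size of the exact eigenproblem.
#' @return `n x k` matrix of unit-energy tapers.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1, base_n = 1024L) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  n0 <- min(n, base_n)
  w <- nw / n0
  t <- seq_len(n0) - 1
  A <- matrix(0, n0, n0)
  diag(A) <- ((n0 - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n0 - t[-1]) / 2
  A[cbind(seq_len(n0 - 1), seq_len(n0 - 1) + 1)] <- off
  A[cbind(seq_len(n0 - 1) + 1, seq_len(n0 - 1))] <- off
  V <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  if (n > n0) {
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = n)
    V <- apply(V, 2, function(v) stats::spline(x0, v, xout = x1)$y)
    V <- qr.Q(qr(V))  # restore orthonormality after interpolation
  }
  # unit energy and deterministic sign (positive centre-of-mass lobe)
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (sum(v^3) < 0) -v else v
  })
  .taper_cache[[key]] <- V
  V
}

#' Multitaper power spectral density
#'
#' DPSS multitaper PSD of one epoch, per channel. Channels are demeaned,
#' tapered with `2 nw - 1` Slepian tapers and the one-sided eigenspectra
#' averaged. The density is Parseval-consistent: its integral over
#' `[0, fs/2]` approximates the signal variance.
#'
#' @param epoch Channels x samples matrix (rownames = channel names), or a
#'   single numeric vector.
#' @param fs Sampling rate (Hz).
#' @param nw Time-bandwidth product.
#' @return A `psd` object: `freqs` (Hz) and `power`
#'   (channels x frequencies, uV^2/Hz).
#' @export
multitaper_psd <- function(epoch, fs, nw = 4) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  if (anyNA(epoch) || any(!is.finite(epoch)))
    stop("epoch contains non-finite samples")
  n <- ncol(epoch)
  if (n < 2 * fs) stop("epoch too short: need at least 2 s of data")
  V <- dpss_tapers(n, nw = nw)
  k <- ncol(V)
  nfreq <- floor(n / 2) + 1
  freqs <- (seq_len(nfreq) - 1) * fs / n
  power <- matrix(0, nrow(epoch), nfreq,
                  dimnames = list(rownames(epoch), NULL))
  for (ch in seq_len(nrow(epoch))) {
    x <- epoch[ch, ] - mean(epoch[ch, ])
    s <- numeric(nfreq)
    for (j in seq_len(k)) {
      p <- Mod(stats::fft(x * V[, j]))^2 / fs
      one <- p[seq_len(nfreq)]
      mid <- seq(2, nfreq - if (n %% 2 == 0) 1 else 0)
      one[mid] <- one[mid] + p[n + 2 - mid]  # fold negative frequencies
      s <- s + one
    }
    power[ch, ] <- s / k
  }
  structure(list(freqs = freqs, power = power, fs = fs), class = "psd")
}

# Trapezoid integral of y(f) over [lo, hi] with linear interpolation at the
# band edges; exactly additive over abutting bands.
trapz_band <- function(freqs, y, lo, hi) {
  yl <- stats::approx(freqs, y, xout = lo)$y
  yh <- stats::approx(freqs, y, xout = hi)$y
  inside <- freqs > lo & freqs < hi
  f <- c(lo, freqs[inside], hi)
  v <- c(yl, y[inside], yh)
  sum(diff(f) * (v[-1] + v[-length(v)]) / 2)
}

#' Band powers from a PSD
#'
#' Area under the spectral density over each band, per channel (trapezoid
#' rule on the native frequency grid, edges interpolated).
#'
#' @param psd A `psd` from [multitaper_psd()].
#' @param bands List of [band_definition()]s.
#' @return Matrix channels x bands (uV^2).
#' @export
band_powers <- function(psd, bands = default_bands()) {
  stopifnot(inherits(psd, "psd"))
  rng <- range(psd$freqs)
  out <- sapply(bands, function(b) {
    if (b$lo < rng[1] || b$hi > rng[2])
      stop("band '", b$name, "' (", b$lo, "-", b$hi,
           " Hz) outside the PSD frequency grid")
    apply(psd$power, 1, function(y) trapz_band(psd$freqs, y, b$lo, b$hi))
  })
  out <- matrix(out, nrow = nrow(psd$power),
                dimnames = list(rownames(psd$power),
                                vapply(bands, `[[`, character(1), "name")))
  out
}

#' Spectral band-power features of one session
#'
#' Multitaper band powers of every 10-s resting-state epoch, averaged
#' arithmetically across epochs for each channel.
#'
#' @param session A `session_record`.
#' @param bands List of [band_definition()]s.
#' @param nw Multitaper time-bandwidth product.
#' @return Long data frame `session_id, channel, feature, value` with
#'   feature names `bp_<band>`.
#' @export
session_band_powers <- function(session, bands = default_bands(), nw = 4) {
  stopifnot(inherits(session, "session_record"))
  eeg <- session$rs_eeg
  n_ep <- dim(eeg)[1]
  if (n_ep < 1) stop("session has no rsEEG epochs")
  acc <- 0
  for (e in seq_len(n_ep)) {
    psd <- multitaper_psd(eeg[e, , ], fs = session$fs, nw = nw)
    rownames(psd$power) <- dimnames(eeg)[[2]]
    acc <- acc + band_powers(psd, bands)
  }
  bp <- acc / n_ep
  data.frame(
    session_id = session$session_id,
    channel = rep(rownames(bp), times = ncol(bp)),
    feature = paste0("bp_", rep(colnames(bp), each = nrow(bp))),
    value = as.vector(bp), row.names = NULL)
}
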