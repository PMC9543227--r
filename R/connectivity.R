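#' Band filtering, instantaneous phase, and PLV connectivity
#'
#' Connectivity is estimated in canonical EEG rhythms on the region time
#' series: zero-phase band-pass filtering, instantaneous phase by the
#' analytic (Hilbert) signal, then the phase-locking value
#' `PLV_ij = |mean_t exp(i (phi_i(t) - phi_j(t)))|` per sliding window.
#' Window-level (dynamic) matrices are averaged across windows and epochs
#' into one static matrix per band.
#'
#' @name spectral_connectivity
NULL

#' Canonical EEG frequency bands
#'
#' theta (4-8 Hz), alpha1 (8-10), alpha2 (10-13), beta (13-30).
#'
#' @param name optional band name; if given, returns the `c(lo, hi)` pair.
#' @return Named list of `c(lo, hi)` pairs, or one pair.
#' @export
eeg_bands <- function(name = NULL) {
  bands <- list(theta = c(4, 8), alpha1 = c(8, 10),
                alpha2 = c(10, 13), beta = c(13, 30))
  if (is.null(name)) return(bands)
  if (!name %in% names(bands)) {
    stop_input("unknown band '%s' (known: %s)", name,
               paste(names(bands), collapse = ", "))
  }
  bands[[name]]
}

# Zero-phase FIR band-pass. Cutoffs are placed at 0.75*lo and 1.5*hi with a
# Hamming-window length sized so the transition bands fit inside
# (lo/2, lo) and (hi, 2*hi): unit gain across [lo, hi], >= 40 dB rejection
# one octave outside. filtfilt doubles the attenuation and cancels the
# group delay.
band_fir <- function(band, sfreq) {
  lo <- band[1]; hi <- band[2]
  nyq <- sfreq / 2
  ntaps <- ceiling(3.3 * sfreq / (lo / 2))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  as.numeric(signal::fir1(ntaps - 1,
                          c(0.75 * lo, min(1.5 * hi, 0.99 * nyq)) / nyq,
                          type = "pass"))
}

#' Zero-phase band-pass filter an epoch
#'
#' @param epoch a [signal_epoch].
#' @param band `c(lo, hi)` in Hz or a band name from [eeg_bands()].
#' @return Filtered [signal_epoch]; no group delay, in-band amplitude
#'   preserved within 5%, at least 40 dB attenuation one octave outside
#'   the band.
#' @export
bandpass <- function(epoch, band) {
  stopifnot(inherits(epoch, "signal_epoch"))
  if (is.character(band)) band <- eeg_bands(band)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    stop_input("band must be c(lo, hi) with 0 < lo < hi")
  }
  if (band[2] >= epoch$sfreq / 2) {
    stop_input("band upper edge %g Hz is at/above Nyquist (%g Hz)",
               band[2], epoch$sfreq / 2)
  }
  b <- band_fir(band, epoch$sfreq)
  out <- t(apply(epoch$data, 1, function(x) signal::filtfilt(b, 1, x)))
  if (nrow(epoch$data) == 1) out <- matrix(out, nrow = 1)
  signal_epoch(out, epoch$sfreq)
}

# Analytic signal by the FFT method (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of narrowband signals
#'
#' Phase of the analytic signal, per channel. The narrowband contract is
#' documented, not enforced: broadband input yields phases without a
#' meaningful interpretation.
#'
#' @param epoch a [signal_epoch] (band-limited).
#' @param unwrap if `TRUE`, cumulatively unwrap each channel's phase.
#' @return `channels x samples` matrix of phases in radians.
#' @export
instantaneous_phase <- function(epoch, unwrap = FALSE) {
  stopifnot(inherits(epoch, "signal_epoch"))
  ph <- t(apply(epoch$data, 1, function(x) Arg(analytic_signal(x))))
  if (nrow(epoch$data) == 1) ph <- matrix(ph, nrow = 1)
  if (unwrap) {
    ph <- t(apply(ph, 1, function(p) {
      d <- diff(p)
      d <- d - 2 * pi * round(d / (2 * pi))
      cumsum(c(p[1], d))
    }))
    if (nrow(epoch$data) == 1) ph <- matrix(ph, nrow = 1)
  }
  ph
}

# PLV of a block of phases (regions x samples): |Z Z^H| / T with
# Z = exp(i phi). Diagonal is zeroed to satisfy the connectivity-matrix
# convention (mathematically PLV(x,x) = 1).
plv_matrix <- function(phases) {
  z <- exp(1i * phases)
  p <- Mod(z %*% Conj(t(z))) / ncol(phases)
  p <- pmin(p, 1)
  diag(p) <- 0
  (p + t(p)) / 2
}

#' Dynamic (windowed) PLV matrices for one epoch
#'
#' @param phases `regions x samples` phase matrix (radians).
#' @param sfreq sampling frequency in Hz.
#' @param window_length_s window length in seconds; `NULL` (default)
#'   takes one window spanning the whole usable epoch (one dynamic
#'   matrix per epoch). Short windows estimate PLV from few effectively
#'   independent phase samples and are biased upward under weak
#'   coupling; epoch-length windows keep the static average close to the
#'   long-run PLV.
#' @param window_step_s step between window starts (default: non-
#'   overlapping windows).
#' @param edge_trim_s seconds discarded at each end before windowing, to
#'   drop filter/analytic-transform transients (default 1 s; 0 to keep
#'   everything).
#' @return List of symmetric zero-diagonal PLV matrices, one per window.
#' @export
plv_dynamic <- function(phases, sfreq, window_length_s = NULL,
                        window_step_s = window_length_s, edge_trim_s = 1) {
  if (!is.matrix(phases)) stop_input("phases must be a regions x samples matrix")
  trim <- round(edge_trim_s * sfreq)
  if (2 * trim >= ncol(phases)) stop_input("edge trim leaves no samples")
  if (trim > 0) phases <- phases[, (trim + 1):(ncol(phases) - trim), drop = FALSE]
  if (is.null(window_length_s)) {
    window_length_s <- ncol(phases) / sfreq
    window_step_s <- window_length_s
  }
  if (is.null(window_step_s)) window_step_s <- window_length_s
  wl <- round(window_length_s * sfreq)
  ws <- max(1L, round(window_step_s * sfreq))
  if (wl > ncol(phases)) {
    stop_input("window (%g s) longer than usable epoch (%g s)",
               window_length_s, ncol(phases) / sfreq)
  }
  starts <- seq(1L, ncol(phases) - wl + 1L, by = ws)
  lapply(starts, function(s) plv_matrix(phases[, s:(s + wl - 1L), drop = FALSE]))
}

#' Average dynamic matrices into one static connectivity matrix
#'
#' Arithmetic mean over all windows of all epochs. With equal-length
#' windows this equals per-epoch averaging followed by cross-epoch
#' averaging.
#'
#' @param epochs list of per-epoch dynamic-matrix lists (as returned by
#'   [plv_dynamic()]), or a flat list of matrices.
#' @return One symmetric zero-diagonal matrix in `[0, 1]`.
#' @export
assemble_static <- function(epochs) {
  mats <- if (length(epochs) && is.list(epochs[[1]])) {
    unlist(epochs, recursive = FALSE)
  } else epochs
  if (!length(mats)) stop_input("no matrices to average")
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    stop_input("mismatched region counts across matrices: %s",
               paste(unique(dims), collapse = ", "))
  }
  out <- Reduce(`+`, mats) / length(mats)
  validate_connectivity(out, what = "static connectivity matrix")
  out
}

#' Full epoch-to-static-connectivity chain for one subject
#'
#' Convenience wrapper: band-pass each source epoch, extract phases,
#' compute windowed PLV, and average everything into the static matrix.
#' By default each epoch contributes one dynamic matrix (epoch-length
#' window); pass `window_length_s` for finer within-epoch dynamics.
#'
#' @param epochs list of [signal_epoch] region time series.
#' @param band band name or `c(lo, hi)` Hz.
#' @param window_length_s window length in seconds; `NULL` = one window
#'   per epoch.
#' @param edge_trim_s transient trim per epoch edge (seconds).
#' @return Static PLV connectivity matrix.
#' @export
static_plv <- function(epochs, band, window_length_s = NULL, edge_trim_s = 1) {
  if (is.character(band)) band <- eeg_bands(band)
  per_epoch <- lapply(epochs, function(ep) {
    ph <- instantaneous_phase(bandpass(ep, band))
    plv_dynamic(ph, ep$sfreq, window_length_s, edge_trim_s = edge_trim_s)
  })
  assemble_static(per_epoch)
}
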