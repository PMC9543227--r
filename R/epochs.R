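#' Signal epochs
#'
#' A `signal_epoch` holds one multichannel (or multi-region) segment of
#' band-limited time series: a `channels x samples` matrix plus its
#' sampling frequency. Recording convention mirrors the resting-state
#' protocol the pipeline targets: 40-s epochs, six retained per subject.
#'
#' @param data numeric matrix, channels/regions in rows, samples in columns.
#' @param sfreq sampling frequency in Hz.
#' @return An object of class `signal_epoch` with fields `data`, `sfreq`,
#'   `duration` (seconds).
#' @export
signal_epoch <- function(data, sfreq) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_input("epoch data must be a numeric matrix (channels x samples)")
  }
  if (any(!is.finite(data))) stop_input("epoch data contains non-finite values")
  if (!is.numeric(sfreq) || sfreq <= 0) stop_input("sfreq must be positive")
  structure(list(data = data, sfreq = sfreq,
                 duration = ncol(data) / sfreq),
            class = "signal_epoch")
}

#' @export
print.signal_epoch <- function(x, ...) {
  cat(sprintf("<signal_epoch> %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, x$duration))
  invisible(x)
}

#' Generate a random leadfield (gain) matrix
#'
#' Stand-in forward model for simulation studies: a dense random gain with
#' a capped condition number, so the inverse problem is well posed by
#' construction. Singular values below `s_max / condition_cap` are raised
#' to that floor.
#'
#' @param n_channels number of sensors (>= 2).
#' @param n_sources number of sources (>= 2).
#' @param condition_cap maximum allowed condition number (>= 1).
#' @param seed integer seed; the matrix is deterministic given all
#'   arguments.
#' @param identity if `TRUE` (requires `n_channels == n_sources`), return
#'   the identity gain.
#' @return `n_channels x n_sources` numeric matrix with strictly positive
#'   column norms.
#' @export
generate_leadfield <- function(n_channels, n_sources, condition_cap = 1e3,
                               seed = 1, identity = FALSE) {
  if (!is_count(n_channels, 2) || !is_count(n_sources, 2)) {
    stop_input("n_channels and n_sources must be integers >= 2")
  }
  if (condition_cap < 1) stop_input("condition_cap must be >= 1")
  if (identity) {
    if (n_channels != n_sources) {
      stop_input("identity gain requires n_channels == n_sources")
    }
    return(diag(n_channels))
  }
  with_seed(seed, {
    g <- matrix(rnorm(n_channels * n_sources), n_channels, n_sources)
    sv <- svd(g)
    d <- pmax(sv$d, max(sv$d) / condition_cap)
    g <- sv$u %*% (d * t(sv$v))
    if (any(sqrt(colSums(g^2)) <= 0)) {
      # cannot occur with the floor above, but keep the contract explicit
      stop_input("generated gain has a zero column")
    }
    g
  })
}
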