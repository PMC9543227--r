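#' Phase-coupled narrowband source simulation
#'
#' Ground-truth generator for the connectivity pipeline. Each region's
#' signal is band-limited Gaussian noise; coupling between regions is
#' produced by shared-component mixing:
#' `x_i = sqrt(a_i) * s_common + sqrt(1 - a_i) * s_private_i`, all
#' components band-filtered white noise with unit variance, so the linear
#' correlation of a coupled pair is `sqrt(a_i * a_j)`. The requested
#' coupling matrix entry `c_ij` is interpreted as that target correlation;
#' the induced long-run PLV is a monotone function of `c_ij` obtainable
#' from the simulation oracle [plv_oracle()].
#'
#' Coupling matrices must decompose, on their nonzero support, into
#' connected blocks with rank-one structure `c_ij = sqrt(a_i a_j)`
#' (uniform blocks and disjoint pairs always qualify); anything else is
#' rejected rather than silently approximated.
#'
#' @name coupled_sources
NULL

narrowband_noise <- function(n_signals, n_samples, sfreq, band) {
  ep <- signal_epoch(matrix(rnorm(n_signals * n_samples), n_signals), sfreq)
  out <- bandpass(ep, band)$data
  out / pmax(apply(out, 1, sd), .Machine$double.eps)
}

# Solve per-region mixing weights a_i on one coupling block so that
# sqrt(a_i a_j) = c_ij for every coupled pair; least squares in logs, with
# a consistency check.
solve_block_weights <- function(members, pairs, cvals) {
  if (nrow(pairs) == 1) {
    a <- setNames(rep(cvals, 2), members)
    return(a)
  }
  ridx <- match(pairs[, 1], members)
  cidx <- match(pairs[, 2], members)
  amat <- matrix(0, nrow(pairs), length(members))
  amat[cbind(seq_len(nrow(pairs)), ridx)] <- 0.5
  amat[cbind(seq_len(nrow(pairs)), cidx)] <- 0.5
  # minimum-norm least squares (the system may be singular; consistency
  # is judged from the residual, not from solvability)
  sv <- svd(amat)
  dinv <- ifelse(sv$d > max(sv$d) * 1e-10, 1 / sv$d, 0)
  fit <- sv$v %*% (dinv * crossprod(sv$u, log(cvals)))
  resid <- amat %*% fit - log(cvals)
  if (max(abs(resid)) > 1e-6) {
    stop_input(paste0("coupling block {%s} lacks rank-one structure ",
                      "c_ij = sqrt(a_i a_j); use uniform blocks or ",
                      "disjoint pairs"), paste(members, collapse = ","))
  }
  a <- exp(fit)
  if (any(a > 1 + 1e-9)) {
    stop_input("coupling block {%s} implies mixing weight > 1",
               paste(members, collapse = ","))
  }
  setNames(pmin(a, 1), members)
}

#' Simulate phase-coupled narrowband region signals
#'
#' @param n_regions number of regions (or a [region_atlas]).
#' @param band `c(lo, hi)` Hz or band name.
#' @param sfreq sampling frequency (Hz).
#' @param duration epoch length (seconds).
#' @param coupling symmetric zero-diagonal matrix in `[0, 1]`: target
#'   linear correlation per pair (0 = independent, 1 = identical
#'   narrowband component).
#' @param seed integer seed; output is deterministic given all arguments.
#' @return A [signal_epoch] (`regions x samples`).
#' @export
simulate_coupled_sources <- function(n_regions, band, sfreq, duration,
                                     coupling = NULL, seed = 1) {
  if (inherits(n_regions, "region_atlas")) n_regions <- n_regions$n_regions
  if (is.character(band)) band <- eeg_bands(band)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= sfreq / 2) {
    stop_input("invalid band: need 0 < lo < hi < sfreq/2")
  }
  n_samples <- round(sfreq * duration)
  if (is.null(coupling)) coupling <- matrix(0, n_regions, n_regions)
  if (!is.matrix(coupling) || nrow(coupling) != n_regions ||
      max(abs(coupling - t(coupling))) > 1e-10 || any(diag(coupling) != 0) ||
      any(coupling < 0) || any(coupling > 1)) {
    stop_input("coupling must be a symmetric zero-diagonal %d x %d matrix in [0,1]",
               n_regions, n_regions)
  }
  with_seed(seed, {
    x <- narrowband_noise(n_regions, n_samples, sfreq, band)
    g <- igraph::graph_from_adjacency_matrix(coupling > 0, mode = "undirected")
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      members <- which(comp$membership == k)
      if (length(members) < 2) next
      sub <- coupling[members, members, drop = FALSE]
      idx <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
      pairs <- cbind(members[idx[, 1]], members[idx[, 2]])
      a <- solve_block_weights(members, pairs, sub[idx])
      s_common <- narrowband_noise(1, n_samples, sfreq, band)
      for (m in members) {
        am <- a[[as.character(m)]]
        x[m, ] <- sqrt(am) * s_common + sqrt(1 - am) * x[m, ]
      }
    }
    signal_epoch(x, sfreq)
  })
}

#' Long-run PLV oracle for the shared-component mixing model
#'
#' Estimates the asymptotic PLV induced by a given coupling (target
#' correlation) by simulating a long record at that mixing weight and
#' computing the PLV directly from the full-length phase difference - the
#' reference against which the windowed pipeline estimate is compared.
#' Results are cached per (coupling, band, sfreq) within the session.
#'
#' @param coupling scalar target correlation in `[0, 1]`.
#' @param band `c(lo, hi)` Hz or band name.
#' @param sfreq sampling frequency.
#' @param duration oracle record length in seconds (default 600).
#' @param seed oracle seed.
#' @return Scalar PLV in `[0, 1]`.
#' @export
plv_oracle <- local({
  cache <- new.env(parent = emptyenv())
  function(coupling, band, sfreq = 250, duration = 600, seed = 99) {
    if (is.character(band)) band <- eeg_bands(band)
    key <- paste(signif(coupling, 8), band[1], band[2], sfreq, duration, seed,
                 sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cm <- matrix(0, 2, 2); cm[1, 2] <- cm[2, 1] <- coupling
    ep <- simulate_coupled_sources(2, band, sfreq, duration, cm, seed = seed)
    ph <- instantaneous_phase(ep)
    trim <- round(sfreq)
    keep <- (trim + 1):(ncol(ph) - trim)
    val <- Mod(mean(exp(1i * (ph[1, keep] - ph[2, keep]))))
    cache[[key]] <- val
    val
  }
})
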