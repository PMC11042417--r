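# Synthetic-study forward generator: drive the tissue wave equation with
# localized oscillatory sources, take the periodic steady state, and
# sample it at scalp electrodes.  Because the medium's damping rates
# (75-115 1/s in brain tissue, far more in CSF) greatly exceed EEG
# frequencies, transients die out within tens of milliseconds and the
# driven solution is the frequency-domain steady state; it is computed
# directly per source frequency with a matrix-free Krylov solve of the
# same operator equation the inverse solver iterates on.  Equivalence
# with long-time RK4 integration is established in the test suite on a
# non-stiff medium.

#' Steady-state harmonic response of the head model
#'
#' Solves the driven frequency-domain wave equation
#' \eqn{(L - R)\,\phi_\omega = s_\omega} for a complex source volume
#' `s`, where `L` is the Laplacian and `R` the tissue relaxation
#' operator of [apply_R()], using matrix-free BiCGSTAB on the
#' Laplacian-preconditioned form \eqn{(I - L^{-1}R)\phi = L^{-1}s}.
#'
#' @param fields A [property_fields()].
#' @param s Complex source volume (the rate of change of
#'   \eqn{\nabla^2\phi} injected per unit time, divided by
#'   \eqn{\bar\sigma_{scaled} - i\omega}; see [synthesize_study()]).
#' @param freq Source frequency in Hz (> 0).
#' @param tol Relative residual tolerance of the Krylov solve.
#' @param maxit Maximum BiCGSTAB iterations.
#' @return Complex volume `phi` with attributes `iterations` and
#'   `relres`.
#' @export
harmonic_response <- function(fields, s, freq, tol = 1e-8, maxit = 400L) {
  stopifnot(inherits(fields, "property_fields"))
  if (freq <= 0) stop("`freq` must be positive")
  plan <- fields$plan
  omega <- 2 * pi * freq
  shape <- plan$shape
  amul <- .amul_forward(fields, omega)
  b <- as.vector(.sinvlap(array(s, shape), plan))
  sol <- .bicgstab(amul, b, tol = tol, maxit = maxit)
  if (!sol$converged)
    warning("harmonic solve reached ", sol$iter,
            " iterations with relative residual ", signif(sol$relres, 3))
  structure(array(sol$x, shape), iterations = sol$iter, relres = sol$relres)
}

#' @noRd
.gauss_blob <- function(shape, center_vox, fwhm_vox) {
  sdv <- fwhm_vox / (2 * sqrt(2 * log(2)))
  ax <- lapply(1:3, function(d) (seq_len(shape[d]) - center_vox[d])^2)
  g <- exp(-outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`) / (2 * sdv^2))
  g / max(g)
}

#' Synthesize a forward EEG study
#'
#' Builds the complete forward fixture for inverse-problem work: places
#' Gaussian oscillatory sources inside the brain, computes the driven
#' steady-state potential field per source frequency with
#' [harmonic_response()], synthesises the time-domain 4D field over the
#' requested duration, and samples it at the electrodes.
#'
#' @param grid A [tissue_grid()].
#' @param fields Matching [property_fields()].
#' @param sources Data frame (or list coercible to one) with columns
#'   `x`, `y`, `z` (world mm, inside gray/white matter), `freq` (Hz)
#'   and `amplitude`.
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz (sources must satisfy `freq < fs/2`).
#' @param sensors A [sensor_array()] (e.g. from [place_electrodes()]).
#' @param snr_db Optional sensor noise level (empirical SNR in dB).
#' @param seed Seed for the noise draw.
#' @param source_fwhm Source blob full width at half maximum in voxels.
#' @return List with `field` (ground-truth `wave_field`), `recording`
#'   (an [eeg_recording()]), `phi_hat` (complex steady-state volume per
#'   distinct frequency) and `freqs`.
#' @export
synthesize_study <- function(grid, fields, sources, duration, fs, sensors,
                             snr_db = NULL, seed = 1, source_fwhm = 3) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(fields, "property_fields"))
  sources <- as.data.frame(sources)
  need <- c("x", "y", "z", "freq", "amplitude")
  if (!all(need %in% names(sources)))
    stop("`sources` needs columns ", paste(need, collapse = ", "))
  if (any(sources$freq >= fs / 2))
    stop("source frequency at or above Nyquist (fs/2); raise fs")
  vox <- world_to_voxel(grid, as.matrix(sources[, c("x", "y", "z")]))
  shape <- grid$shape
  if (any(vox < 0.5) || any(vox > rep(shape, each = nrow(vox)) + 0.5))
    stop("source center outside the volume")
  lab <- grid$labels[round(vox)]
  if (any(!lab %in% .TISSUES[c("gm", "wm")]))
    stop("all source centers must lie in gray or white matter")

  n <- round(duration * fs)
  if (n < 2) stop("duration too short for the requested sampling rate")
  tt <- (seq_len(n) - 1) / fs
  shape <- grid$shape

  freqs <- sort(unique(sources$freq[sources$amplitude != 0]))
  phi_hat <- vector("list", length(freqs))
  names(phi_hat) <- as.character(freqs)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    rows <- which(sources$freq == f & sources$amplitude != 0)
    forcing <- array(0, shape)
    for (r in rows)
      forcing <- forcing +
        sources$amplitude[r] * .gauss_blob(shape, vox[r, ], source_fwhm)
    # time-domain forcing f(x) cos(wt) on d/dt lap(phi) corresponds to
    # the frequency-domain source forcing/(sigbar_scaled - i w)
    s <- forcing / (fields$sigma_bar_scaled - 2i * pi * f)
    phi_hat[[fi]] <- harmonic_response(fields, s, f)
  }

  out <- array(0, c(shape, n))
  nvox <- prod(shape)
  for (fi in seq_along(freqs)) {
    osc <- exp(-2i * pi * freqs[fi] * tt)
    re <- Re(phi_hat[[fi]]); im <- Im(phi_hat[[fi]])
    for (ti in seq_len(n)) {
      rng <- ((ti - 1) * nvox + 1):(ti * nvox)
      out[rng] <- out[rng] + re * Re(osc[ti]) - im * Im(osc[ti])
    }
  }
  field <- structure(list(phi = out, dt = 1 / fs, times = tt,
                          spacing = grid$voxel_size * 1e-3, grid = grid),
                     class = "wave_field")
  rec <- if (length(freqs))
    sample_sensors(field, sensors, snr_db = snr_db, seed = seed)
  else
    eeg_recording(matrix(0, nrow(sensors), n), fs, sensors)
  list(field = field, recording = rec, phi_hat = phi_hat, freqs = freqs)
}
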