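# Time-domain pseudo-spectral integration of the tissue wave equation
#   d/dt lap(phi) = -div(Sigma grad(phi)) [+ forcing],
# advanced with classical RK4 on the state u = lap(phi); phi is recovered
# at every stage by spectral Laplacian inversion.  The domain is periodic.

#' Idealized wave medium
#'
#' A bare scaled-conductivity field on a periodic grid, for simulations
#' that do not need a segmented head (dispersion checks, idealized
#' gradients).  `sigma_scaled` may be 1D, 2D or 3D.
#'
#' @param sigma_scaled Array of scaled conductivity (1/s).
#' @param spacing Grid spacing per axis (meters; recycled).
#' @return Object of class `wave_medium`.
#' @export
medium <- function(sigma_scaled, spacing = 1) {
  dims <- if (is.null(dim(sigma_scaled))) length(sigma_scaled)
          else dim(sigma_scaled)
  structure(list(sigma_scaled = array(sigma_scaled, dims),
                 spacing = rep_len(spacing, length(dims)),
                 plan = .spec_plan(dims, spacing)),
            class = "wave_medium")
}

#' @noRd
.sim_medium <- function(fields, apodize) {
  if (inherits(fields, "wave_medium")) {
    list(sig = fields$sigma_scaled, tensor = NULL, plan = fields$plan)
  } else if (inherits(fields, "property_fields")) {
    sig <- fields$sigma_scaled
    tensor <- fields$tensor_scaled
    if (apodize) {
      tap <- .edge_taper(dim(sig), width = 3)
      sig <- sig * tap
      if (!is.null(tensor)) tensor <- lapply(tensor, `*`, tap)
    }
    list(sig = sig, tensor = tensor, plan = fields$plan)
  } else stop("`fields` must be property_fields or wave_medium")
}

# Cosine taper to ~0 within `width` voxels of every box edge; used to
# suppress periodic wrap-around of the inherently periodic spectral
# operators when simulating a head in a box.
#' @noRd
.edge_taper <- function(shape, width = 3) {
  tap <- array(1, shape)
  for (d in seq_along(shape)) {
    n <- shape[d]
    prof <- rep(1, n)
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(width) - 0.5) / width)
    prof[seq_len(width)] <- ramp
    prof[n + 1 - seq_len(width)] <- ramp
    tap <- tap * array(prof[slice.index(tap, d)], shape)
  }
  tap
}

#' Simulate the tissue wave equation
#'
#' Integrates \eqn{\partial_t \nabla^2\phi = -\nabla\cdot(\Sigma\nabla\phi)}
#' (plus an optional oscillatory forcing on \eqn{\nabla^2\phi}) with RK4
#' and spectral derivatives on a periodic grid.  The time step must obey
#' the explicit stability guard `dt <= 0.1 / max(Sigma)`.
#'
#' @param fields A [property_fields()] (its scaled tensor is used, with a
#'   3-voxel cosine edge taper unless `apodize = FALSE`) or a [medium()].
#' @param phi0 Initial potential (array matching the grid); its spatial
#'   mean is removed (the potential gauge).  May be complex, in which
#'   case the complex field is evolved componentwise (the equation has
#'   real coefficients); useful to isolate a single wave branch.
#' @param dt Time step (s).
#' @param n_steps Number of RK4 steps.
#' @param forcing Optional list(`amplitude` = array, `freq` = Hz,
#'   `phase` = 0): adds `amplitude * cos(2 pi freq t + phase)` to the
#'   rate of change of \eqn{\nabla^2\phi}.
#' @param save_every Store every `save_every`-th frame (plus t = 0).
#' @param apodize Taper the conductivity near box edges (head grids).
#' @return Object of class `wave_field`: list with `phi` (array with one
#'   trailing time dimension), `dt` (frame interval), `times`, `spacing`.
#' @export
simulate_wave_field <- function(fields, phi0, dt, n_steps, forcing = NULL,
                                save_every = 1L, apodize = TRUE) {
  med <- .sim_medium(fields, apodize)
  plan <- med$plan
  shape <- plan$shape
  if (dt <= 0 || n_steps < 1) stop("`dt` and `n_steps` must be positive")
  phi0 <- array(phi0, shape)
  phi0 <- phi0 - mean(phi0)

  max_sig <- if (is.null(med$tensor)) max(abs(med$sig)) else
    max(abs(med$tensor$xx) + abs(med$tensor$xy) + abs(med$tensor$xz),
        abs(med$tensor$xy) + abs(med$tensor$yy) + abs(med$tensor$yz),
        abs(med$tensor$xz) + abs(med$tensor$yz) + abs(med$tensor$zz))
  if (dt * max_sig > 0.1 + 1e-12)
    stop("unstable step: dt * max(Sigma) = ", signif(dt * max_sig, 4),
         " exceeds the stability guard 0.1; reduce dt below ",
         signif(0.1 / max_sig, 4), " s")

  tens <- med$tensor
  flux <- function(dphi) {
    if (is.null(tens)) lapply(dphi, `*`, med$sig)
    else list(tens$xx * dphi[[1]] + tens$xy * dphi[[2]] + tens$xz * dphi[[3]],
              tens$xy * dphi[[1]] + tens$yy * dphi[[2]] + tens$yz * dphi[[3]],
              tens$xz * dphi[[1]] + tens$yz * dphi[[2]] + tens$zz * dphi[[3]])
  }
  cplx <- is.complex(phi0)
  keep <- if (cplx) identity else Re
  rhs <- function(u, t) {
    phihat <- plan$ilap * .fftn(u)
    dphi <- lapply(seq_len(plan$nd),
                   function(d) keep(.ifftn(1i * plan$k[[d]] * phihat)))
    fl <- flux(dphi)
    div <- array(if (cplx) 0i else 0, shape)
    for (d in seq_len(plan$nd))
      div <- div + keep(.ifftn(1i * plan$k[[d]] * .fftn(fl[[d]])))
    out <- -div
    if (!is.null(forcing)) {
      ph <- if (is.null(forcing$phase)) 0 else forcing$phase
      out <- out + forcing$amplitude * cos(2 * pi * forcing$freq * t + ph)
    }
    out
  }

  u <- .slaplacian(phi0, plan)
  n_frames <- floor(n_steps / save_every) + 1L
  out <- array(if (cplx) NA_complex_ else NA_real_, c(shape, n_frames))
  nvox <- prod(shape)
  fslice <- function(fi) ((fi - 1) * nvox + 1):(fi * nvox)
  out[fslice(1L)] <- phi0
  fi <- 2L
  times <- numeric(n_frames); times[1] <- 0
  t <- 0
  for (s in seq_len(n_steps)) {
    k1 <- rhs(u, t)
    k2 <- rhs(u + dt / 2 * k1, t + dt / 2)
    k3 <- rhs(u + dt / 2 * k2, t + dt / 2)
    k4 <- rhs(u + dt * k3, t + dt)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (s %% save_every == 0L) {
      if (!all(is.finite(Re(u))) || (cplx && !all(is.finite(Im(u)))))
        stop("instability: non-finite field at step ", s,
             "; dt * max(Sigma) = ", signif(dt * max_sig, 4),
             " exceeded what this medium tolerates")
      out[fslice(fi)] <- .sinvlap(u, plan)
      times[fi] <- t
      fi <- fi + 1L
    }
  }
  structure(list(phi = out, dt = dt * save_every, times = times,
                 spacing = plan$spacing,
                 grid = if (inherits(fields, "property_fields"))
                   fields$grid else NULL),
            class = "wave_field")
}

#' @export
print.wave_field <- function(x, ...) {
  d <- dim(x$phi)
  nd <- length(d)
  cat("Wave field:", paste(d[-nd], collapse = " x "), "voxels,",
      d[nd], "frames @ dt =", signif(x$dt, 4), "s\n")
  invisible(x)
}

#' Simulate the idealized 1D boundary-layer equations
#'
#' Pseudo-spectral RK4 integration of the two thin-layer modes described
#' by [boundary_layer_modes()]: the along-fiber damped-oscillator
#' equation \eqn{\partial_t\phi = -a\,\partial_z^2\phi - b\,\partial_z\phi}
#' ("parallel") or the cross-fiber wave equation
#' \eqn{\partial_t\partial_y^2\phi = -b\,\partial_y\phi} ("transverse",
#' integrated on \eqn{u = \partial_y^2 \phi} like the volumetric
#' simulator).  The zero-mean gauge is enforced.
#'
#' @inheritParams boundary_layer_modes
#' @param phi0 Initial 1D profile (length n, periodic).
#' @param length_domain Domain length (same length unit as 1/k).
#' @param dt,n_steps,save_every Time stepping controls.
#' @return A `wave_field` whose `phi` is n x frames.
#' @export
simulate_boundary_layer <- function(a, b, branch = c("transverse", "parallel"),
                                    phi0, length_domain = 2 * pi, dt, n_steps,
                                    save_every = 1L) {
  branch <- match.arg(branch)
  n <- length(phi0)
  h <- length_domain / n
  k <- .kaxis(n, h)
  # Fourier symbols of d(phi_hat)/dt = -i Omega(k) phi_hat:
  # parallel Omega = b k + i a k^2; transverse Omega = -b/k.
  sym <- if (branch == "parallel") a * k^2 - 1i * b * k
         else { s <- 1i * b / k; s[k == 0] <- 0; s }
  phi <- phi0 - mean(phi0)
  rhs <- function(p) Re(stats::fft(sym * stats::fft(p), inverse = TRUE) / n)
  n_frames <- floor(n_steps / save_every) + 1L
  out <- matrix(NA_real_, n, n_frames)
  out[, 1] <- phi
  times <- numeric(n_frames)
  fi <- 2L
  t <- 0
  for (s in seq_len(n_steps)) {
    k1 <- rhs(phi)
    k2 <- rhs(phi + dt / 2 * k1)
    k3 <- rhs(phi + dt / 2 * k2)
    k4 <- rhs(phi + dt * k3)
    phi <- phi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (s %% save_every == 0L) {
      if (!all(is.finite(phi))) stop("instability in boundary-layer simulation")
      out[, fi] <- phi
      times[fi] <- t
      fi <- fi + 1L
    }
  }
  structure(list(phi = out, dt = dt * save_every, times = times,
                 spacing = h, grid = NULL),
            class = "wave_field")
}
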