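# Dispersion-relation analytics for potential waves in conductive tissue.
#
# Plane-wave convention: phi ~ exp[-i(k.x - Omega t)] with complex
# Omega = omega + i*gamma, so positive gamma means decay exp(-gamma t).
# Substituted into the wave equation
# d/dt lap(phi) = -div(Sigma grad(phi)) this gives
#   gamma = (k' Sigma k)/|k|^2        (decay rate, k-independent scale)
#   omega = -(div(Sigma) . k)/|k|^2   (oscillation, ~ 1/|k|)
# so long waves oscillate fastest - the opposite of electromagnetic
# dispersion - and the decay rate is set purely by the local tensor.

#' Dispersion relation for tissue potential waves
#'
#' Evaluates the complex frequency of a plane wave with wavevector `k`
#' in a medium with local scaled conductivity tensor `Sigma` (1/s) and
#' divergence vector `div_Sigma` (\eqn{\partial_i \Sigma_{ij}}, 1/(s m)).
#'
#' @param k Wavevector (1/m); any nonzero numeric vector.
#' @param Sigma Scaled conductivity tensor: scalar (isotropic), or a
#'   square matrix matching `length(k)`.
#' @param div_Sigma Divergence vector of the tensor (same length as `k`);
#'   defaults to zero (homogeneous medium).
#' @return List with `omega` (oscillation rate, 1/s), `gamma` (decay
#'   rate, 1/s) and `Omega = omega + 1i * gamma`.
#' @examples
#' dispersion(c(100, 0, 0), Sigma = 80)           # pure decay at 80 1/s
#' dispersion(c(100, 0, 0), 80, c(5000, 0, 0))    # omega = -50 1/s
#' @export
dispersion <- function(k, Sigma, div_Sigma = NULL) {
  k <- as.numeric(k)
  k2 <- sum(k^2)
  if (k2 == 0) stop("`k` must be nonzero")
  n <- length(k)
  if (is.null(div_Sigma)) div_Sigma <- numeric(n)
  if (length(div_Sigma) != n) stop("`div_Sigma` must match length(k)")
  S <- if (length(Sigma) == 1L) diag(as.numeric(Sigma), n) else as.matrix(Sigma)
  if (!all(dim(S) == n)) stop("`Sigma` must be scalar or ", n, "x", n)
  gamma <- drop(t(k) %*% S %*% k) / k2
  omega <- -sum(div_Sigma * k) / k2
  list(omega = omega, gamma = gamma, Omega = complex(real = omega,
                                                     imaginary = gamma))
}

#' Electromagnetic wavelength in a dielectric
#'
#' The textbook estimate used to argue that electromagnetic propagation
#' effects are negligible in the head: a wave at `freq` Hz in a medium
#' of relative permittivity `eps_rel` travels at \eqn{v = c/\sqrt{\epsilon_{rel}}}
#' and has wavelength \eqn{\lambda = v/\nu}.  At 10 Hz and
#' \eqn{\epsilon_{rel} = 100} this gives 3e7 m/s and 3e6 m (3000 km) -
#' vastly larger than a head, which is why slow observed brain waves
#' cannot be electromagnetic waves.
#'
#' @param freq Frequency in Hz (> 0).
#' @param eps_rel Relative permittivity (>= 1).
#' @return List with `velocity` (m/s) and `wavelength` (m).
#' @export
em_wavelength <- function(freq, eps_rel) {
  if (any(freq <= 0)) stop("`freq` must be positive")
  if (any(eps_rel < 1)) stop("`eps_rel` must be >= 1")
  v <- .C0 / sqrt(eps_rel)
  list(velocity = v, wavelength = v / freq)
}

#' Wave persistence ratio
#'
#' Ratio of decay rate to oscillation rate, \eqn{\gamma/|\omega|}, from
#' the dispersion relation: small values mean waves persist for many
#' cycles before damping out.
#'
#' @inheritParams dispersion
#' @return Dimensionless ratio \eqn{\gamma/|\omega|}.
#' @export
persistence_ratio <- function(k, Sigma, div_Sigma) {
  d <- dispersion(k, Sigma, div_Sigma)
  if (d$omega == 0) stop("omega is zero at this k; persistence undefined")
  d$gamma / abs(d$omega)
}

#' Boundary-layer wave branches
#'
#' Complex frequencies of the two idealized thin-boundary-layer modes in
#' a medium with fibers along z and a conductivity profile v(x) varying
#' across a thin layer: with `a = v(x0)` and `b = dv/dx(x0)`,
#' the along-fiber ("parallel") potential obeys a damped-oscillator
#' equation \eqn{(\partial_t + a\partial_z^2 + b\partial_z)\phi = 0} and
#' the cross-fiber ("transverse") potential a pure wave equation
#' \eqn{(\partial_t \partial_y^2 + b\partial_y)\phi = 0}.  Under the
#' plane-wave ansatz \eqn{\exp[i(k y - \Omega t)]}:
#' * transverse: \eqn{\Omega = -b/k}, exactly real - no damping term
#'   exists, the mode conserves energy;
#' * parallel: \eqn{\Omega = b k + i a k^2}; with this sign convention a
#'   negative `a` damps the mode at rate \eqn{|a| k^2}.
#'
#' @param a Layer coefficient v(x0) (damping scale of the parallel mode).
#' @param b Layer gradient dv/dx at x0 (must be nonzero for transverse
#'   propagation).
#' @param k Wavenumber(s), nonzero.
#' @param branch `"transverse"` or `"parallel"`.
#' @return List with vectors `omega`, `gamma`, `Omega`.
#' @examples
#' boundary_layer_modes(a = 0, b = 1, k = 2, branch = "transverse")$Omega # -0.5
#' @export
boundary_layer_modes <- function(a, b, k, branch = c("transverse", "parallel")) {
  branch <- match.arg(branch)
  if (any(k == 0)) stop("`k` must be nonzero")
  if (branch == "transverse") {
    if (b == 0) stop("`b` must be nonzero for the transverse branch")
    omega <- -b / k
    gamma <- rep(0, length(k))
  } else {
    omega <- b * k
    gamma <- a * k^2
  }
  list(omega = omega, gamma = gamma,
       Omega = complex(real = omega, imaginary = gamma))
}
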