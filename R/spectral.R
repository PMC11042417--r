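# Pseudo-spectral machinery shared by the simulator and the inverse solver.
# All operators assume a periodic domain; derivatives are evaluated in
# Fourier space.  Spacings are in meters so that wavenumbers are rad/m and
# spatial gradients of the property fields carry 1/m.

.EPS0 <- 8.854187817e-12 # vacuum permittivity, F/m
.C0 <- 3e8               # speed of light, m/s (conventional rounded value)

#' @noRd
.kaxis <- function(n, h) {
  i <- 0:(n - 1L)
  i[i > n / 2] <- i[i > n / 2] - n
  2 * pi * i / (n * h)
}

# A spectral "plan": full-size wavenumber arrays for each axis plus |k|^2
# and the inverse-Laplacian symbol (zero at DC: the potential gauge).
#' @noRd
.spec_plan <- function(shape, spacing) {
  shape <- as.integer(shape)
  nd <- length(shape)
  spacing <- rep_len(spacing, nd)
  tmpl <- array(0, dim = shape)
  k <- vector("list", nd)
  k2 <- array(0, dim = shape)
  for (d in seq_len(nd)) {
    kv <- .kaxis(shape[d], spacing[d])
    kd <- array(kv[slice.index(tmpl, d)], dim = shape)
    k[[d]] <- kd
    k2 <- k2 + kd^2
  }
  ilap <- -1 / k2
  ilap[k2 == 0] <- 0
  list(shape = shape, spacing = spacing, nd = nd, k = k, k2 = k2, ilap = ilap)
}

#' @noRd
.fftn <- function(x) stats::fft(x)

#' @noRd
.ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Derivative of f along axis d; keeps complex input complex.
#' @noRd
.sderiv <- function(f, plan, d) {
  out <- .ifftn(1i * plan$k[[d]] * .fftn(f))
  if (is.complex(f)) out else Re(out)
}

#' @noRd
.sgrad_hat <- function(fhat, plan, complex_out = TRUE) {
  lapply(seq_len(plan$nd), function(d) {
    g <- .ifftn(1i * plan$k[[d]] * fhat)
    if (complex_out) g else Re(g)
  })
}

#' @noRd
.slaplacian <- function(f, plan) {
  out <- .ifftn(-plan$k2 * .fftn(f))
  if (is.complex(f)) out else Re(out)
}

#' @noRd
.sinvlap <- function(f, plan) {
  out <- .ifftn(plan$ilap * .fftn(f))
  if (is.complex(f)) out else Re(out)
}

# Isotropic Gaussian filter with standard deviation `width` (same length
# unit as the plan spacings); width 0 is the identity.
#' @noRd
.sgauss <- function(f, plan, width) {
  if (width <= 0) return(f)
  out <- .ifftn(exp(-0.5 * plan$k2 * width^2) * .fftn(f))
  if (is.complex(f)) out else Re(out)
}

#' Invert the Laplacian on a periodic grid
#'
#' Solves \eqn{\nabla^2 u = f} spectrally by dividing the Fourier transform
#' of `f` by \eqn{-|k|^2}.  The zero-wavenumber (mean) component is set to
#' zero: a potential is only defined up to an additive constant, and this
#' fixes the gauge so that the result has zero spatial mean.
#'
#' @param f Real or complex array (any dimensionality) on a periodic grid.
#' @param spacing Grid spacing per axis, in the length unit of interest
#'   (recycled across axes).  Wavelengths and amplitudes scale accordingly.
#' @return Array of the same shape as `f` with zero mean, such that
#'   `laplacian(invert_laplacian(f)) == f - mean(f)` to spectral accuracy.
#' @examples
#' x <- seq(0, 1, length.out = 33)[-33]
#' f <- sin(2 * pi * x)
#' u <- invert_laplacian(f, spacing = 1 / 32)
#' max(abs(u - (-(1 / (2 * pi))^2 * f))) < 1e-10
#' @export
invert_laplacian <- function(f, spacing = 1) {
  plan <- .spec_plan(if (is.null(dim(f))) length(f) else dim(f), spacing)
  out <- .sinvlap(if (is.null(dim(f))) array(f, length(f)) else f, plan)
  if (is.null(dim(f))) as.vector(out) else out
}

#' Laplacian on a periodic grid
#'
#' Spectral counterpart of [invert_laplacian()].
#'
#' @inheritParams invert_laplacian
#' @return Array of the same shape as `f`.
#' @export
laplacian <- function(f, spacing = 1) {
  plan <- .spec_plan(if (is.null(dim(f))) length(f) else dim(f), spacing)
  out <- .slaplacian(if (is.null(dim(f))) array(f, length(f)) else f, plan)
  if (is.null(dim(f))) as.vector(out) else out
}

# Matrix-free BiCGSTAB for complex linear operators.  Used to solve the
# driven frequency-domain wave equation; no installed package provides a
# matrix-free complex Krylov solver.
#' @noRd
.bicgstab <- function(amul, b, tol = 1e-8, maxit = 400L) {
  cdot <- function(a, b) sum(Conj(a) * b)
  nb <- sqrt(Re(cdot(b, b)))
  if (nb == 0) return(list(x = b * 0, iter = 0L, relres = 0, converged = TRUE))
  x <- b * 0
  r <- b
  rhat <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- r * 0
  for (it in seq_len(maxit)) {
    rho1 <- cdot(rhat, r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    v <- amul(p)
    alpha <- rho / cdot(rhat, v)
    s <- r - alpha * v
    if (sqrt(Re(cdot(s, s))) / nb < tol) {
      x <- x + alpha * p
      return(list(x = x, iter = it, relres = sqrt(Re(cdot(s, s))) / nb,
                  converged = TRUE))
    }
    t <- amul(s)
    omega <- cdot(t, s) / cdot(t, t)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    relres <- sqrt(Re(cdot(r, r))) / nb
    if (relres < tol)
      return(list(x = x, iter = it, relres = relres, converged = TRUE))
  }
  list(x = x, iter = maxit, relres = sqrt(Re(cdot(r, r))) / nb,
       converged = FALSE)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
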