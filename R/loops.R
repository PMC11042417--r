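# Detection of closed wave loops: stable rotating-wave patterns whose
# instantaneous-phase streamlines close on themselves in a plane.

# Analytic signal along the last (time) dimension via the FFT Hilbert
# transform; rows are pixels.
#' @noRd
.analytic_signal <- function(xmat) {
  n <- ncol(xmat)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(xmat)))
  t(stats::mvfft(t(X * rep(h, each = nrow(xmat))), inverse = TRUE)) / n
}

#' Detect closed phase-streamline loops in a wave field
#'
#' Computes the per-voxel instantaneous phase of `field` over time (FFT
#' analytic signal), extracts the requested plane, and integrates
#' streamlines of the in-plane phase gradient from a grid of seed
#' points.  A streamline that returns within `closure_tol` voxels of its
#' starting point (after at least one full step away) is reported as a
#' loop; loops are deduplicated by centroid distance.  Rotating spiral
#' waves produce one loop around each phase singularity; traveling
#' plane waves produce none.
#'
#' @param field A `wave_field` with at least 8 time frames.
#' @param plane_axis Axis (1-3) normal to the inspection plane; for 2D
#'   fields the (only) plane is used as is.
#' @param plane_index Slice index along `plane_axis`.
#' @param closure_tol Closure tolerance in voxels (default 1).
#' @param seed_stride Spacing of streamline seed points in voxels.
#' @param dedupe_dist Minimum centroid separation between distinct
#'   loops, in voxels.
#' @return Data frame with one row per loop: `id`, centroid (voxels,
#'   plane coordinates), path length (voxels) and step count.
#' @export
detect_wave_loops <- function(field, plane_axis = 3, plane_index = NULL,
                              closure_tol = 1, seed_stride = 4,
                              dedupe_dist = 5) {
  stopifnot(inherits(field, "wave_field"))
  d <- dim(field$phi)
  nd <- length(d) - 1L
  nt <- d[length(d)]
  if (nt < 8) stop("need at least 8 time frames for analytic-signal phase")
  if (nd == 2) {
    sl <- field$phi
  } else {
    if (is.null(plane_index)) plane_index <- ceiling(d[plane_axis] / 2)
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[plane_axis]] <- plane_index
    sl <- do.call(`[`, c(list(field$phi), idx, list(quote(expr =)),
                         list(drop = FALSE)))
    sl <- array(sl, dim(sl)[-plane_axis])
  }
  if (max(abs(sweep(sl, 1:2, sl[, , 1]))) < 1e-14 * max(1, max(abs(sl))))
    stop("field is constant in time; instantaneous phase is undefined")
  nx <- dim(sl)[1]; ny <- dim(sl)[2]
  z <- .analytic_signal(matrix(sl, nx * ny, nt))
  zmid <- matrix(z[, ceiling(nt / 2)], nx, ny)

  # Wrap-safe phase gradient: grad(arg z) = Im(Conj(z) grad z)/|z|^2.
  cdiff <- function(m, d) {
    n <- dim(m)[d]
    ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
    if (d == 1) (m[ip, , drop = FALSE] - m[im, , drop = FALSE]) / 2
    else (m[, ip, drop = FALSE] - m[, im, drop = FALSE]) / 2
  }
  mod2 <- pmax(Mod(zmid)^2, 1e-300)
  gx <- Im(Conj(zmid) * cdiff(zmid, 1)) / mod2
  gy <- Im(Conj(zmid) * cdiff(zmid, 2)) / mod2

  interp2 <- function(m, p) {
    i <- floor(p[1]); j <- floor(p[2])
    fi <- p[1] - i; fj <- p[2] - j
    i <- max(1, min(nx - 1, i)); j <- max(1, min(ny - 1, j))
    m[i, j] * (1 - fi) * (1 - fj) + m[i + 1, j] * fi * (1 - fj) +
      m[i, j + 1] * (1 - fi) * fj + m[i + 1, j + 1] * fi * fj
  }

  # Streamlines are meaningless where the oscillation amplitude is
  # negligible (the phase is noise there); mask those pixels out.
  amp <- Mod(zmid)
  amp_tol <- 0.05 * max(amp)

  # Unit tangent of the phase-gradient field, RK4-integrated (forward
  # Euler drifts off closed orbits and misses closures).
  tangent <- function(p) {
    if (interp2(amp, p) < amp_tol) return(c(NA_real_, NA_real_))
    v <- c(interp2(gx, p), interp2(gy, p))
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv < 1e-12) return(c(NA_real_, NA_real_))
    v / nv
  }
  step <- 0.5
  max_steps <- ceiling(10 * 2 * (nx + ny) / step)
  min_travel <- max(2 * pi * closure_tol, 4)
  seeds <- expand.grid(x = seq(2, nx - 1, by = seed_stride),
                       y = seq(2, ny - 1, by = seed_stride))
  loops <- list()
  for (s in seq_len(nrow(seeds))) {
    p <- c(seeds$x[s], seeds$y[s])
    start <- p
    path <- matrix(NA_real_, max_steps + 1L, 2L)
    path[1, ] <- p
    n_pts <- 1L
    travelled <- 0
    closed <- FALSE
    for (it in seq_len(max_steps)) {
      v1 <- tangent(p)
      if (anyNA(v1)) break
      v2 <- tangent(p + step / 2 * v1)
      v3 <- if (anyNA(v2)) v2 else tangent(p + step / 2 * v2)
      v4 <- if (anyNA(v3)) v3 else tangent(p + step * v3)
      if (anyNA(v2) || anyNA(v3) || anyNA(v4)) break
      p <- p + step / 6 * (v1 + 2 * v2 + 2 * v3 + v4)
      if (p[1] < 1.5 || p[1] > nx - 0.5 || p[2] < 1.5 || p[2] > ny - 0.5)
        break
      travelled <- travelled + step
      n_pts <- n_pts + 1L
      path[n_pts, ] <- p
      if (travelled > min_travel &&
          sqrt(sum((p - start)^2)) <= closure_tol) {
        closed <- TRUE
        break
      }
    }
    if (closed) {
      ctr <- colMeans(path[seq_len(n_pts), , drop = FALSE])
      loops[[length(loops) + 1L]] <- c(ctr, travelled, n_pts)
    }
  }
  if (!length(loops))
    return(data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      length = numeric(), n_steps = integer()))
  lm <- do.call(rbind, loops)
  keep <- rep(TRUE, nrow(lm))
  for (i in seq_len(nrow(lm))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(lm))) {
      if (j <= i || !keep[j]) next
      if (sqrt(sum((lm[i, 1:2] - lm[j, 1:2])^2)) < dedupe_dist)
        keep[j] <- FALSE
    }
  }
  lm <- lm[keep, , drop = FALSE]
  data.frame(id = seq_len(nrow(lm)), cx = lm[, 1], cy = lm[, 2],
             length = lm[, 3], n_steps = as.integer(lm[, 4]))
}
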