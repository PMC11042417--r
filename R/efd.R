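# Entropy-based spatiotemporal mode decomposition and map-comparison
# statistics.
#
# The decomposition implemented here is a documented simplification of
# the full field-theoretic entropy field decomposition: the space-time
# coupling is summarized by the matrix of absolute temporal correlations
# between voxel time courses; its eigendecomposition yields orthonormal
# spatial modes, the squared leading eigenvector (normalized to sum 1)
# is the maximum-path-entropy equilibrium distribution over voxels, and
# per-mode time courses/power maps follow by projection.  It retains
# the operational ingredients - single-dataset space-time correlations,
# an equilibrium distribution, a small number of summed power modes -
# without claiming equivalence to the full hierarchy of field
# interactions.

#' Voxel-voxel temporal coupling matrix
#'
#' Absolute Pearson correlation between the time courses of masked
#' voxels.  If the mask exceeds `max_voxels`, a deterministic
#' stratified subsample (every k-th masked voxel after a seeded random
#' start) is used.  Voxels with constant time courses are dropped with
#' a warning.
#'
#' @param field A `wave_field`, or a plain array whose last dimension
#'   is time.
#' @param mask Logical/integer array matching the spatial dimensions
#'   (nonzero = included); `NULL` includes everything.
#' @param max_voxels Upper bound on the number of coupled voxels.
#' @param seed Seed for the subsample start.
#' @return List of class `coupling_matrix`: `Q` (symmetric, unit
#'   diagonal, entries in [0,1]), `voxels` (linear indices into the
#'   spatial grid), `dims` (spatial dimensions).
#' @export
coupling_matrix <- function(field, mask = NULL, max_voxels = 2000, seed = 1) {
  X <- .mask_timecourses(field, mask)
  vox <- attr(X, "voxels", exact = TRUE)
  dims <- attr(X, "dims", exact = TRUE)
  keep <- which(apply(X, 1, stats::sd) > 0)
  if (length(keep) < nrow(X))
    warning(nrow(X) - length(keep),
            " constant voxel time course(s) dropped from the coupling")
  X <- X[keep, , drop = FALSE]
  vox <- vox[keep]
  if (nrow(X) < 2) stop("need at least 2 non-constant masked voxels")
  if (ncol(X) < 8) stop("need at least 8 time points")
  if (nrow(X) > max_voxels) {
    stride <- ceiling(nrow(X) / max_voxels)
    start <- .with_seed(seed, sample.int(stride, 1))
    sel <- seq(start, nrow(X), by = stride)
    X <- X[sel, , drop = FALSE]
    vox <- vox[sel]
  }
  Q <- abs(stats::cor(t(X)))
  diag(Q) <- 1
  structure(list(Q = Q, voxels = vox, dims = dims),
            class = "coupling_matrix")
}

# Masked voxel x time matrix from a wave field or array.
#' @noRd
.mask_timecourses <- function(field, mask = NULL) {
  arr <- if (inherits(field, "wave_field")) field$phi else field
  d <- dim(arr)
  nd <- length(d)
  if (nd < 2) stop("field must have a trailing time dimension")
  sdim <- d[-nd]; nt <- d[nd]
  X <- matrix(arr, prod(sdim), nt)
  vox <- if (is.null(mask)) seq_len(prod(sdim)) else {
    if (!isTRUE(all.equal(dim(mask), sdim, check.attributes = FALSE)))
      stop("mask dimensions must match the field's spatial dimensions")
    which(as.vector(mask != 0))
  }
  if (!length(vox)) stop("empty mask")
  out <- X[vox, , drop = FALSE]
  attr(out, "voxels") <- vox
  attr(out, "dims") <- sdim
  out
}

#' Equilibrium distribution of the coupling spectrum
#'
#' Eigendecomposition of the coupling matrix.  The equilibrium (long
#' time) distribution over voxels is the squared leading eigenvector,
#' normalized to sum to one - the stationary visiting distribution of
#' the maximum-entropy path ensemble defined by the nonnegative
#' couplings.
#'
#' @param Q A [coupling_matrix()] (or bare symmetric matrix).
#' @return List with `values` (descending eigenvalues), `vectors`
#'   (orthonormal columns), `mu_star` (nonnegative, sums to 1).
#' @export
esp_equilibrium <- function(Q) {
  M <- if (inherits(Q, "coupling_matrix")) Q$Q else as.matrix(Q)
  if (!all(is.finite(M))) stop("coupling matrix contains non-finite values")
  e <- eigen(M, symmetric = TRUE)
  mu <- e$vectors[, 1]^2
  list(values = e$values, vectors = e$vectors, mu_star = mu / sum(mu))
}

#' Spatiotemporal mode decomposition of a 4D field
#'
#' Fits the simplified entropy-mode model described above: builds the
#' voxel coupling matrix, eigendecomposes it, and returns the top `n`
#' orthonormal spatial modes with their projected time courses and
#' power maps.  The power map of mode k is
#' \eqn{\psi_k^2 \cdot \mathrm{var}(\tau_k)}; the displayed summed map
#' weights modes by their eigenvalues, while the unweighted sum over
#' all modes reproduces the total masked variance exactly (orthonormal
#' completeness).
#'
#' @inheritParams coupling_matrix
#' @param n Number of modes to keep (default 10).
#' @return Object of class `efd`: `values`, `maps` (voxels x n),
#'   `timecourses` (n x time), `mu_star`, `power` (per-mode power
#'   maps, voxels x n), `voxels`, `dims`, `n`.
#' @export
efd <- function(field, mask = NULL, n = 10, max_voxels = 2000, seed = 1) {
  cm <- coupling_matrix(field, mask, max_voxels = max_voxels, seed = seed)
  X <- .mask_timecourses(field, mask)
  X <- X[match(cm$voxels, attr(X, "voxels")), , drop = FALSE]
  nv <- nrow(X)
  if (n > nv) stop("`n` exceeds the number of coupled voxels (", nv, ")")
  es <- esp_equilibrium(cm)
  rank_ok <- sum(es$values > max(es$values) * 1e-12)
  if (n > rank_ok) stop("`n` exceeds the numerical rank (", rank_ok,
                        ") of the coupling matrix")
  Xc <- X - rowMeans(X)
  psi <- es$vectors[, seq_len(n), drop = FALSE]
  tau <- crossprod(psi, Xc)                       # n x time
  vt <- rowSums(tau^2) / ncol(tau)                # population variance
  power <- sweep(psi^2, 2, vt, `*`)
  structure(list(values = es$values[seq_len(n)], maps = psi,
                 timecourses = tau, mu_star = es$mu_star, power = power,
                 voxels = cm$voxels, dims = cm$dims, n = n,
                 total_variance = sum(Xc^2) / ncol(Xc),
                 all_values = es$values, call = match.call()),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat("Entropy-mode decomposition:", x$n, "modes over",
      length(x$voxels), "voxels\n")
  ev <- x$values / sum(x$all_values)
  cat("  coupling-spectrum share of kept modes:",
      paste(signif(ev, 3), collapse = " "), "\n")
  cat("  variance explained:",
      signif(sum(rowSums(x$timecourses^2) / ncol(x$timecourses)) /
               x$total_variance, 4), "\n")
  invisible(x)
}

#' @export
summary.efd <- function(object, ...) {
  vt <- rowSums(object$timecourses^2) / ncol(object$timecourses)
  data.frame(mode = seq_len(object$n), eigenvalue = object$values,
             variance = vt, variance_share = vt / object$total_variance)
}

#' @export
plot.efd <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$all_values, type = "h", xlab = "mode",
                 ylab = "coupling eigenvalue", main = "spectrum", ...)
  graphics::matplot(t(x$timecourses), type = "l", lty = 1,
                    xlab = "time index", ylab = "mode time course",
                    main = paste("top", x$n, "modes"))
  invisible(x)
}

#' Summed mode power map
#'
#' @param x An [efd()] fit.
#' @param weights `"eigen"` (eigenvalue-weighted, the display default)
#'   or `"unit"` (plain sum; with `n` = all modes this equals the
#'   voxelwise variance of the masked data).
#' @return Array of the decomposition's spatial dimensions (zero
#'   outside the mask).
#' @export
mode_power_map <- function(x, weights = c("eigen", "unit")) {
  stopifnot(inherits(x, "efd"))
  weights <- match.arg(weights)
  w <- if (weights == "eigen") x$values / max(x$values) else rep(1, x$n)
  out <- array(0, x$dims)
  out[x$voxels] <- as.vector(x$power %*% w)
  out
}

#' Signed difference of two power maps
#'
#' @param a,b Arrays on the same grid (e.g. from [mode_power_map()] or
#'   [band_power()]).
#' @return `a - b`, voxelwise.
#' @export
contrast_power <- function(a, b) {
  if (!isTRUE(all.equal(dim(a), dim(b)))) stop("maps are on different grids")
  a - b
}

#' Mean power per atlas region
#'
#' @param power_map Real array.
#' @param atlas Integer label array on the same grid (0 = outside).
#' @return Data frame with `region`, `n_voxels`, `mean_power`, sorted
#'   by decreasing mean; empty regions are kept with `n_voxels = 0`
#'   and `NA` mean.
#' @export
roi_power_table <- function(power_map, atlas) {
  if (!isTRUE(all.equal(dim(power_map), dim(atlas))))
    stop("atlas and map are on different grids")
  regions <- sort(setdiff(unique(as.vector(atlas)), 0))
  rows <- lapply(regions, function(r) {
    v <- power_map[atlas == r]
    data.frame(region = r, n_voxels = length(v),
               mean_power = if (length(v)) mean(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_power, na.last = TRUE), , drop = FALSE]
}

#' Thresholded correlation between two activation maps
#'
#' Pearson correlation over the voxels where **both** maps exceed the
#' activation threshold in absolute value (optionally within a region
#' of interest) - the conservative comparison used when two imaging
#' modalities only agree where both actually detect activity.
#'
#' @param a,b Real arrays on the same grid.
#' @param roi Optional logical/integer mask.
#' @param threshold Activation level (default 0.1); a length-2 vector
#'   applies separate levels to `a` and `b` (so a rescaled map keeps
#'   the same surviving voxels when its threshold is rescaled with it).
#' @return Pearson r.
#' @export
map_correlation <- function(a, b, roi = NULL, threshold = 0.1) {
  if (!isTRUE(all.equal(dim(a), dim(b)))) stop("maps are on different grids")
  threshold <- rep_len(threshold, 2)
  sel <- abs(a) > threshold[1] & abs(b) > threshold[2]
  if (!is.null(roi)) sel <- sel & (roi != 0)
  if (sum(sel) < 3)
    stop("fewer than 3 voxels exceed the threshold in both maps")
  stats::cor(a[sel], b[sel])
}

#' Slice-wise correlation profile
#'
#' Pearson correlation between two volumes within each slice along an
#' axis; slices where either volume is constant (or empty) give `NA`.
#'
#' @param a,b Real 3D arrays on the same grid.
#' @param axis Slicing axis (1, 2 or 3).
#' @return Numeric vector, one r per slice.
#' @export
slicewise_correlation <- function(a, b, axis = 3) {
  if (!isTRUE(all.equal(dim(a), dim(b)))) stop("maps are on different grids")
  n <- dim(a)[axis]
  vapply(seq_len(n), function(i) {
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[axis]] <- i
    x <- as.vector(do.call(`[`, c(list(a), idx)))
    y <- as.vector(do.call(`[`, c(list(b), idx)))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }, 0)
}

#' Fisher z-transform of a correlation
#'
#' \eqn{z = \mathrm{artanh}(r)}, the variance-stabilizing transform
#' used before t-tests on correlation values.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}
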