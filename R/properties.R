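# Voxelwise bioelectric property fields.
#
# Two views of the conductivity are kept side by side:
#   * raw conductivity sigma (S/m) and absolute permittivity eps_rel*eps0
#     (F/m), the coefficients of the frequency-domain operator used by the
#     inverse solver, where sigma and omega*eps are comparable at EEG
#     frequencies;
#   * the scaled tensor Sigma = sigma/(eps_rel*eps0) (units 1/s), the
#     coefficient field of the time-domain wave equation
#     d/dt lap(phi) = -div(Sigma grad(phi)), whose trace/3 is the isotropic
#     damping rate.

#' Default per-tissue bioelectric property table
#'
#' Conductivity (S/m), relative permittivity (multiplies the vacuum
#' permittivity 8.854187817e-12 F/m) and transverse/longitudinal
#' anisotropy ratio per tissue label.  Gray- and white-matter values are
#' standard literature averages for low frequency (sigma_GM = 2.75e-2,
#' sigma_WM = 2.77e-2 S/m; eps_rel_GM = 4.07e7, eps_rel_WM = 2.76e7),
#' which put the isotropic damping rate sigma/(eps_rel eps0) in the
#' 75-115 1/s range.  Scalp, skull and CSF conductivities are common
#' modeling placeholders and, like everything here, are configurable;
#' their relative permittivity defaults to 1e7.  The background gets a
#' tiny conductivity floor so spectral operators stay finite.
#'
#' @param sigma Named numeric vector of conductivities (S/m) for
#'   `background`, `scalp`, `skull`, `csf`, `gm`, `wm`.
#' @param eps_rel Named numeric vector of relative permittivities.
#' @param anisotropy_ratio Transverse/longitudinal conductivity ratio in
#'   (0, 1]; scalar or named per-tissue vector.  Only used when fiber
#'   directions are supplied to [property_fields()].
#' @return A data frame with columns `label`, `tissue`, `sigma`,
#'   `eps_rel`, `anisotropy_ratio`.
#' @export
tissue_properties <- function(sigma = c(background = 1e-6, scalp = 0.43,
                                        skull = 0.01, csf = 1.79,
                                        gm = 2.75e-2, wm = 2.77e-2),
                              eps_rel = c(background = 1e7, scalp = 1e7,
                                          skull = 1e7, csf = 1e7,
                                          gm = 4.07e7, wm = 2.76e7),
                              anisotropy_ratio = 1) {
  tiss <- names(.TISSUES)
  sg <- sigma[tiss]; ep <- eps_rel[tiss]
  if (anyNA(sg) || anyNA(ep))
    stop("`sigma` and `eps_rel` must be named for all six tissues")
  ar <- if (length(anisotropy_ratio) == 1L)
    rep(anisotropy_ratio, 6) else anisotropy_ratio[tiss]
  if (any(sg < 0)) stop("conductivities must be >= 0")
  if (any(ep <= 0)) stop("relative permittivities must be > 0")
  if (any(ar <= 0 | ar > 1)) stop("anisotropy ratios must be in (0, 1]")
  data.frame(label = unname(.TISSUES), tissue = tiss, sigma = unname(sg),
             eps_rel = unname(ep), anisotropy_ratio = unname(ar))
}

#' Isotropic wave damping rate
#'
#' The decay rate of potential waves in a homogeneous isotropic medium:
#' \eqn{\gamma = \sigma / (\epsilon_{rel}\,\epsilon_0)}, independent of
#' wavevector.  For average gray/white matter properties this falls in
#' the 75-115 1/s range, strong damping that only tissue anisotropy and
#' boundary-layer geometry can circumvent.
#'
#' @param sigma Conductivity in S/m (vectorised).
#' @param eps_rel Relative permittivity (> 0, vectorised).
#' @return Damping rate in 1/s.
#' @examples
#' damping_rate(2.75e-2, 4.07e7)  # ~76.3 1/s (gray matter)
#' damping_rate(2.77e-2, 2.76e7)  # ~113.3 1/s (white matter)
#' @export
damping_rate <- function(sigma, eps_rel) {
  if (any(eps_rel <= 0)) stop("`eps_rel` must be > 0")
  sigma / (eps_rel * .EPS0)
}

#' Build voxelwise property fields from a labelled grid
#'
#' Assigns per-voxel conductivity and permittivity by tissue label,
#' Gaussian-smooths the scalar maps (spectral differentiation of
#' discontinuous fields rings, so interfaces are softened before any
#' derivative is taken), and precomputes the spectral gradient and
#' divergence fields that the wave operators need.  With `fiber_dir`
#' supplied, the conductivity becomes a rank-1 anisotropic tensor
#' \eqn{\Sigma = v v^T \Sigma_\parallel + (I - v v^T) \Sigma_\perp} with
#' \eqn{\Sigma_\perp/\Sigma_\parallel} given by the table's anisotropy
#' ratio; otherwise all voxels are isotropic.
#'
#' @param grid A [tissue_grid()].
#' @param table Property table as from [tissue_properties()].
#' @param smooth_width Gaussian smoothing standard deviation in mm
#'   (default: one voxel).  Must be non-negative and smaller than a
#'   quarter of the smallest domain extent.
#' @param fiber_dir Optional 4D array (shape x 3) of unit fiber
#'   direction vectors enabling anisotropy.
#' @return An object of class `property_fields` with elements `sigma`
#'   (S/m), `eps_rel`, `sigma_scaled` (1/s), gradient/divergence fields,
#'   and (if anisotropic) the 6 unique tensor components.
#' @export
property_fields <- function(grid, table = tissue_properties(),
                            smooth_width = NULL, fiber_dir = NULL) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (is.null(smooth_width)) smooth_width <- min(grid$voxel_size)
  if (smooth_width < 0) stop("`smooth_width` must be >= 0")
  extent_mm <- grid$shape * grid$voxel_size
  if (smooth_width > min(extent_mm) / 4)
    stop("`smooth_width` (", smooth_width, " mm) exceeds a quarter of the ",
         "domain extent (", min(extent_mm), " mm)")
  labs <- grid$labels
  miss <- setdiff(unique(as.vector(labs)), table$label)
  if (length(miss))
    stop("grid contains labels with no property-table entry: ",
         paste(miss, collapse = ", "))

  idx <- match(as.vector(labs), table$label)
  shape <- grid$shape
  spacing <- grid$voxel_size * 1e-3      # meters
  plan <- .spec_plan(shape, spacing)
  sw <- smooth_width * 1e-3

  sigma <- .sgauss(array(table$sigma[idx], shape), plan, sw)
  sigma[sigma < 0] <- 0
  eps_rel <- .sgauss(array(table$eps_rel[idx], shape), plan, sw)
  eps_rel[eps_rel < min(table$eps_rel)] <- min(table$eps_rel)

  out <- list(grid = grid, table = table, smooth_width = smooth_width,
              spacing = spacing, plan = plan,
              sigma = sigma, eps_rel = eps_rel)

  if (is.null(fiber_dir)) {
    out$tensor <- NULL
    out$sigma_bar <- sigma
    # isotropic: div_j Sigma_ij = d_j sigma
    shat <- .fftn(sigma)
    out$div_sigma <- .sgrad_hat(shat, plan, complex_out = FALSE)
  } else {
    if (!all(dim(fiber_dir) == c(shape, 3L)))
      stop("`fiber_dir` must have shape c(dim(labels), 3)")
    ratio <- .sgauss(array(table$anisotropy_ratio[idx], shape), plan, sw)
    ratio[ratio < 0] <- 0; ratio[ratio > 1] <- 1
    v <- list(fiber_dir[, , , 1], fiber_dir[, , , 2], fiber_dir[, , , 3])
    nrm <- sqrt(v[[1]]^2 + v[[2]]^2 + v[[3]]^2)
    nrm[nrm == 0] <- 1
    v <- lapply(v, function(a) a / nrm)
    s_par <- sigma; s_per <- ratio * sigma
    comp <- list()
    pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
    for (p in seq_along(pairs)) {
      i <- pairs[[p]][1]; j <- pairs[[p]][2]
      comp[[p]] <- (s_par - s_per) * v[[i]] * v[[j]] +
        if (i == j) s_per else 0
    }
    names(comp) <- c("xx", "yy", "zz", "xy", "xz", "yz")
    out$tensor <- comp
    out$sigma_bar <- (comp$xx + comp$yy + comp$zz) / 3
    tens <- function(i, j) {
      nm <- paste0(sort(c("x", "y", "z")[c(i, j)]), collapse = "")
      comp[[nm]]
    }
    out$div_sigma <- lapply(1:3, function(j) {
      acc <- array(0, shape)
      for (i in 1:3) acc <- acc + .sderiv(tens(i, j), plan, i)
      acc
    })
  }

  eps_abs <- eps_rel * .EPS0
  out$eps_abs <- eps_abs
  ehat <- .fftn(eps_abs)
  out$grad_eps <- .sgrad_hat(ehat, plan, complex_out = FALSE)

  # Scaled view for the time-domain wave equation (1/s).
  out$sigma_scaled <- sigma / eps_abs
  if (!is.null(out$tensor)) {
    out$tensor_scaled <- lapply(out$tensor, function(a) a / eps_abs)
    out$sigma_bar_scaled <- out$sigma_bar / eps_abs
    tens_s <- function(i, j) {
      nm <- paste0(sort(c("x", "y", "z")[c(i, j)]), collapse = "")
      out$tensor_scaled[[nm]]
    }
    out$div_sigma_scaled <- lapply(1:3, function(j) {
      acc <- array(0, shape)
      for (i in 1:3) acc <- acc + .sderiv(tens_s(i, j), plan, i)
      acc
    })
  } else {
    out$sigma_bar_scaled <- out$sigma_scaled
    shat_s <- .fftn(out$sigma_scaled)
    out$div_sigma_scaled <- .sgrad_hat(shat_s, plan, complex_out = FALSE)
  }
  structure(out, class = "property_fields")
}

#' @export
print.property_fields <- function(x, ...) {
  cat("Property fields on", paste(x$grid$shape, collapse = " x "),
      "grid;", if (is.null(x$tensor)) "isotropic" else "anisotropic",
      "; smoothing", x$smooth_width, "mm\n")
  cat("  sigma range [S/m]:", signif(range(x$sigma), 4), "\n")
  cat("  damping-rate range [1/s]:", signif(range(x$sigma_scaled), 4), "\n")
  invisible(x)
}
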