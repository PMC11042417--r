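# Head-model grids: tissue label volumes with voxel geometry, a synthetic
# phantom generator, and the standard template grid dimensions.

.TISSUES <- c(background = 0L, scalp = 1L, skull = 2L, csf = 3L,
              gm = 4L, wm = 5L)

#' Tissue label grid
#'
#' A segmented head volume: an integer label array (0 = background,
#' 1 = scalp, 2 = skull, 3 = CSF, 4 = gray matter, 5 = white matter)
#' together with its voxel size (mm) and a voxel-to-world affine.
#' World coordinates are in mm; voxel indices are 1-based in R, and the
#' affine maps the 0-based index convention used on disk, so voxel
#' `(i,j,k)` sits at `affine %*% c(i-1, j-1, k-1, 1)`.
#'
#' @param labels 3D integer array with values in 0..5.
#' @param voxel_size Voxel edge length(s) in mm (scalar or length 3).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a
#'   world frame centred on the volume with axes scaled by `voxel_size`.
#' @return An object of class `tissue_grid`.
#' @export
tissue_grid <- function(labels, voxel_size = 1, affine = NULL) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (anyNA(labels) || !all(labels %in% 0:5))
    stop("tissue labels must be integers in 0..5")
  shape <- dim(labels)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
    affine[1:3, 4] <- -(shape - 1) / 2 * voxel_size
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix")
  structure(list(labels = array(as.integer(labels), shape),
                 shape = shape, voxel_size = voxel_size, affine = affine),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("Tissue grid:", paste(x$shape, collapse = " x "),
      "voxels @", paste(signif(x$voxel_size, 3), collapse = " x "), "mm\n")
  tab <- table(factor(x$labels, levels = 0:5,
                      labels = names(.TISSUES)))
  print(tab)
  invisible(x)
}

#' Convert between world (mm) and voxel coordinates
#'
#' `voxel_to_world()` maps 1-based voxel indices to world mm through the
#' grid affine; `world_to_voxel()` is its inverse.  Both accept a vector
#' of length 3 or an n x 3 matrix.
#'
#' @param grid A [tissue_grid()].
#' @param x Coordinates (length-3 vector or n x 3 matrix).
#' @return Matrix (n x 3) of transformed coordinates.
#' @export
voxel_to_world <- function(grid, x) {
  x <- rbind2_coords(x)
  t(grid$affine %*% rbind(t(x) - 1, 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, x) {
  x <- rbind2_coords(x)
  t(solve(grid$affine) %*% rbind(t(x), 1))[, 1:3, drop = FALSE] + 1
}

#' @noRd
rbind2_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3) stop("coordinates must have 3 columns")
  x
}

#' Synthetic head phantom
#'
#' Builds a nested-ellipsoid head: scalp, skull, CSF, gray matter and
#' white matter shells around the volume centre.  `fold_amplitude`
#' superimposes a smooth sinusoidal radial perturbation on the GM/WM
#' interface, imitating cortical folding; 0 leaves the interface a
#' smooth ellipsoid.  The perturbation phases are drawn from `seed`, so
#' the phantom is fully deterministic.
#'
#' @param shape Integer 3-vector of volume dimensions (each >= 16).
#' @param voxel_size Voxel size in mm.
#' @param fold_amplitude Dimensionless relative amplitude of the GM/WM
#'   interface perturbation (default 0.1; 0 disables folding).
#' @param seed Integer seed fixing the fold phases.
#' @return A [tissue_grid()].
#' @examples
#' g <- phantom_head(c(24, 24, 24), voxel_size = 4)
#' table(g$labels)
#' @export
phantom_head <- function(shape = c(48, 48, 48), voxel_size = 2,
                         fold_amplitude = 0.1, seed = 1) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < 16L))
    stop("phantom shape must be at least 16 voxels per axis; ",
         "smaller volumes give degenerate shells")
  if (fold_amplitude < 0 || fold_amplitude > 0.3)
    stop("`fold_amplitude` must be in [0, 0.3]")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  ph <- .with_seed(seed, stats::runif(4, 0, 2 * pi))

  ctr <- (shape - 1) / 2
  semi <- 0.44 * shape * voxel_size   # leave a margin inside the box
  x <- (seq_len(shape[1]) - 1 - ctr[1]) * voxel_size[1] / semi[1]
  y <- (seq_len(shape[2]) - 1 - ctr[2]) * voxel_size[2] / semi[2]
  z <- (seq_len(shape[3]) - 1 - ctr[3]) * voxel_size[3] / semi[3]
  X <- array(x[slice.index(array(0, shape), 1)], shape)
  Y <- array(y[slice.index(array(0, shape), 2)], shape)
  Z <- array(z[slice.index(array(0, shape), 3)], shape)
  r <- sqrt(X^2 + Y^2 + Z^2)

  # Normalised shell radii (fractions of the scalp surface).
  r_scalp <- 1; r_skull <- 0.92; r_csf <- 0.85; r_gm <- 0.78; r_wm <- 0.62
  theta <- atan2(Y, X)
  cphi <- ifelse(r > 0, Z / pmax(r, 1e-12), 0)
  fold <- 1 + fold_amplitude *
    sin(6 * theta + ph[1]) * sin(4 * acos(pmin(pmax(cphi, -1), 1)) + ph[2])
  r_wm_local <- r_wm * fold

  labels <- array(0L, shape)
  labels[r <= r_scalp] <- .TISSUES[["scalp"]]
  labels[r <= r_skull] <- .TISSUES[["skull"]]
  labels[r <= r_csf] <- .TISSUES[["csf"]]
  labels[r <= r_gm] <- .TISSUES[["gm"]]
  labels[r <= r_wm_local] <- .TISSUES[["wm"]]
  if (!all(1:5 %in% labels))
    stop("degenerate phantom: some tissue shells are empty at this shape")
  tissue_grid(labels, voxel_size)
}

#' Standard template grid dimensions
#'
#' Voxel dimensions of the standard MNI template volume at the supported
#' working resolutions: 2 mm (91 x 109 x 91), 1 mm (182 x 218 x 182) and
#' 0.7 mm (207 x 256 x 215).
#'
#' @param resolution_mm One of 2, 1 or 0.7.
#' @return Integer 3-vector of grid dimensions.
#' @examples
#' prod(template_grid_dim(2))  # 902629 voxels
#' @export
template_grid_dim <- function(resolution_mm) {
  key <- as.character(resolution_mm)
  dims <- list(`2` = c(91L, 109L, 91L),
               `1` = c(182L, 218L, 182L),
               `0.7` = c(207L, 256L, 215L))
  if (!key %in% names(dims))
    stop("supported template resolutions: 2, 1, 0.7 mm")
  dims[[key]]
}
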