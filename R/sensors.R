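# Electrode arrays and synthetic sensor sampling.

#' Sensor array constructor
#'
#' @param names Channel labels (unique).
#' @param positions n x 3 matrix of world coordinates (mm).
#' @param reference `"average"` or the name of a reference channel.
#' @return Object of class `sensor_array` (a data frame with columns
#'   `name`, `x`, `y`, `z` plus a `reference` attribute).
#' @export
sensor_array <- function(names, positions, reference = "average") {
  positions <- rbind2_coords(positions)
  if (length(names) != nrow(positions)) stop("one name per position needed")
  if (anyDuplicated(names)) stop("duplicate channel names")
  if (anyDuplicated(positions)) stop("electrode positions must be distinct")
  if (!identical(reference, "average") && !reference %in% names)
    stop("`reference` must be \"average\" or a channel name")
  out <- data.frame(name = as.character(names), x = positions[, 1],
                    y = positions[, 2], z = positions[, 3])
  attr(out, "reference") <- reference
  class(out) <- c("sensor_array", "data.frame")
  out
}

#' Place electrodes on the scalp of a head model
#'
#' Selects `n` quasi-uniform points on the outer scalp surface by
#' farthest-point sampling over the scalp boundary voxels (scalp voxels
#' with at least one background face-neighbour).  The first point is
#' drawn from `seed`, so the montage is deterministic.
#'
#' @param grid A [tissue_grid()] with a nonempty scalp shell.
#' @param n Number of electrodes (>= 4 for a usable montage; >= 2
#'   accepted for diagnostics).
#' @param seed Integer seed.
#' @return A [sensor_array()] in world mm with average reference.
#' @export
place_electrodes <- function(grid, n = 64, seed = 1) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (n < 2) stop("`n` must be at least 2")
  labs <- grid$labels
  scalp <- which(labs == .TISSUES[["scalp"]])
  if (!length(scalp)) stop("grid has no scalp voxels")
  shape <- grid$shape
  idx <- arrayInd(scalp, shape)
  # boundary: any 6-neighbour outside the volume or labelled background
  is_bg <- function(i, j, k) {
    out <- i < 1 | i > shape[1] | j < 1 | j > shape[2] | k < 1 | k > shape[3]
    v <- rep(TRUE, length(i))
    v[!out] <- labs[cbind(i[!out], j[!out], k[!out])] == 0L
    v
  }
  b <- is_bg(idx[, 1] - 1, idx[, 2], idx[, 3]) |
    is_bg(idx[, 1] + 1, idx[, 2], idx[, 3]) |
    is_bg(idx[, 1], idx[, 2] - 1, idx[, 3]) |
    is_bg(idx[, 1], idx[, 2] + 1, idx[, 3]) |
    is_bg(idx[, 1], idx[, 2], idx[, 3] - 1) |
    is_bg(idx[, 1], idx[, 2], idx[, 3] + 1)
  surf <- idx[b, , drop = FALSE]
  if (n > nrow(surf))
    stop("requested ", n, " electrodes but the scalp surface has only ",
         nrow(surf), " voxels")
  pos <- voxel_to_world(grid, surf)
  chosen <- integer(n)
  chosen[1] <- .with_seed(seed, sample.int(nrow(pos), 1))
  d2 <- colSums((t(pos) - pos[chosen[1], ])^2)
  if (n > 1) {
    for (i in 2:n) {
      chosen[i] <- which.max(d2)
      d2 <- pmin(d2, colSums((t(pos) - pos[chosen[i], ])^2))
    }
  }
  sensor_array(sprintf("E%03d", seq_len(n)), pos[chosen, , drop = FALSE])
}

#' EEG recording constructor
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz (> 0).
#' @param sensors Optional [sensor_array()] (row order matches channels).
#' @param reference Reference that has been applied to `data`.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, sensors = NULL, reference = "average") {
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be a positive sampling rate")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (!is.null(sensors)) {
    stopifnot(inherits(sensors, "sensor_array"))
    if (nrow(sensors) != nrow(data))
      stop("channel count mismatch between data and sensors")
    rownames(data) <- sensors$name
  }
  structure(list(data = data, fs = fs, sensors = sensors,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz;", x$reference, "reference\n")
  invisible(x)
}

# Trilinear interpolation of a (possibly complex) volume at continuous
# 1-based voxel coordinates (n x 3 matrix).
#' @noRd
.trilinear <- function(vol, vox) {
  shape <- dim(vol)
  p <- pmin(pmax(vox, 1), rep(shape, each = nrow(vox)) - 1e-9)
  i0 <- pmin(floor(p), rep(shape, each = nrow(vox)) - 1)
  f <- p - i0
  acc <- if (is.complex(vol)) complex(nrow(vox)) else numeric(nrow(vox))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    acc <- acc + w * vol[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  acc
}

#' Sample a wave field at electrode positions
#'
#' Trilinear interpolation of the volumetric potential at each sensor
#' for every time frame, followed by referencing (average reference
#' subtracts the channel mean at every sample) and optional additive
#' white Gaussian noise at a prescribed empirical signal-to-noise ratio.
#' Noise is injected before referencing so the reference identity holds
#' exactly on the returned data.
#'
#' @param field A 3D + time `wave_field` whose grid geometry is known.
#' @param sensors A [sensor_array()]; positions must fall inside the
#'   field volume.
#' @param snr_db Signal-to-noise ratio in dB, or `NULL` for noise-free.
#' @param seed Seed for the noise draw.
#' @param reference Overrides the sensors' reference if given;
#'   `"none"` returns raw (unreferenced) potentials.
#' @return An [eeg_recording()] with `fs = 1/field$dt`.
#' @export
sample_sensors <- function(field, sensors, snr_db = NULL, seed = 1,
                           reference = NULL) {
  stopifnot(inherits(field, "wave_field"), inherits(sensors, "sensor_array"))
  if (is.null(field$grid))
    stop("field has no grid geometry; cannot place world-mm electrodes")
  if (is.null(reference)) reference <- attr(sensors, "reference")
  vox <- world_to_voxel(field$grid, as.matrix(sensors[, c("x", "y", "z")]))
  shape <- field$grid$shape
  if (any(vox < 0.5) || any(vox > rep(shape, each = nrow(vox)) + 0.5))
    stop("electrode position outside the field volume")
  nt <- dim(field$phi)[4]
  dat <- matrix(0, nrow(sensors), nt)
  for (ti in seq_len(nt))
    dat[, ti] <- Re(.trilinear(field$phi[, , , ti], vox))
  if (!is.null(snr_db)) {
    psig <- mean(dat^2)
    nsd <- sqrt(psig / 10^(snr_db / 10))
    dat <- dat + .with_seed(seed, matrix(stats::rnorm(length(dat), sd = nsd),
                                         nrow(dat), ncol(dat)))
  }
  if (identical(reference, "average")) {
    dat <- sweep(dat, 2, colMeans(dat))
  } else if (identical(reference, "none")) {
    # raw potentials, no referencing
  } else if (reference %in% sensors$name) {
    dat <- sweep(dat, 2, dat[match(reference, sensors$name), ])
  } else stop("unknown reference: ", reference)
  eeg_recording(dat, fs = 1 / field$dt, sensors = sensors,
                reference = reference)
}
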