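# File formats: NIfTI volumes (via RNifti), TSV electrode tables and
# recordings with JSON sidecars, YAML configuration, and a minimal EDF
# reader for continuous single-session recordings.

#' Read and write volumes as NIfTI-1
#'
#' `write_volume()` stores a 3D or 4D array with its voxel-to-world
#' affine (sform, code 2).  For 4D fields the frame interval `dt` is
#' recorded in the NIfTI time pixdim and, together with any extra
#' metadata, in a JSON sidecar `<path>.json`.  `read_volume()` returns
#' the array with attributes `affine`, `voxel_size` and (if present)
#' `dt`.
#'
#' @param x Numeric array (3D or 4D).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param grid Optional [tissue_grid()] supplying affine and voxel
#'   size; alternatively give `affine` directly.
#' @param affine Optional 4x4 voxel-to-world matrix (mm).
#' @param dt Optional frame interval in seconds for 4D data.
#' @return `write_volume()` the path, invisibly; `read_volume()` the
#'   array with geometry attributes.
#' @export
write_volume <- function(x, path, grid = NULL, affine = NULL, dt = NULL) {
  if (!is.null(grid)) affine <- grid$affine
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 4] <- -(dim(x)[1:3] - 1) / 2
  }
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- if (length(dim(x)) == 4) c(vs, if (is.null(dt)) 1 else dt) else vs
  img <- RNifti::asNifti(x, pixdim = pd)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  side <- list()
  if (!is.null(dt)) side$dt <- dt
  if (length(side))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  attr(out, "affine") <- aff
  attr(out, "voxel_size") <- sqrt(colSums(aff[1:3, 1:3]^2))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$dt)) attr(out, "dt") <- meta$dt
  }
  out
}

#' Read a label volume as a tissue grid
#'
#' @param path NIfTI file holding integer tissue labels (0..5).
#' @return A [tissue_grid()] with the file's affine.
#' @export
read_tissue_grid <- function(path) {
  v <- read_volume(path)
  tissue_grid(round(v), voxel_size = attr(v, "voxel_size"),
              affine = attr(v, "affine"))
}

#' Read and write electrode tables
#'
#' Tab-separated table with columns `name`, `x`, `y`, `z` (world mm).
#'
#' @param sensors A [sensor_array()].
#' @param path File path.
#' @return `read_electrodes()` a [sensor_array()]; `write_electrodes()`
#'   the path, invisibly.
#' @export
write_electrodes <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  utils::write.table(as.data.frame(sensors), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrodes
#' @export
read_electrodes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("electrode table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate electrode names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  sensor_array(tab$name, as.matrix(tab[, c("x", "y", "z")]))
}

#' Read and write EEG recordings as TSV + sidecar
#'
#' The data file is tab-separated with a `time` column (seconds) and
#' one column per channel; the sampling rate and reference live in a
#' JSON sidecar `<path>.json`.  `read_recording()` refuses files
#' without a sampling rate, and checks channel consistency against an
#' electrode table when one is supplied.
#'
#' @param rec An [eeg_recording()].
#' @param path File path (`.tsv`).
#' @param electrodes Optional [sensor_array()] or path to one; channel
#'   names must match the recording exactly.
#' @return `read_recording()` an [eeg_recording()];
#'   `write_recording()` the path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ch <- rownames(rec$data)
  if (is.null(ch)) ch <- sprintf("E%03d", seq_len(nrow(rec$data)))
  tab <- data.frame((seq_len(ncol(rec$data)) - 1) / rec$fs, t(rec$data))
  names(tab) <- c("time", ch)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, reference = rec$reference,
                            channels = ch),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, electrodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar ", side, ": the sampling rate is required")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar has no `fs` (sampling rate)")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!"time" %in% names(tab)) stop("recording needs a `time` column")
  dat <- t(as.matrix(tab[, setdiff(names(tab), "time"), drop = FALSE]))
  sensors <- NULL
  if (!is.null(electrodes)) {
    sensors <- if (inherits(electrodes, "sensor_array")) electrodes
               else read_electrodes(electrodes)
    d1 <- setdiff(rownames(dat), sensors$name)
    d2 <- setdiff(sensors$name, rownames(dat))
    if (length(d1) || length(d2))
      stop("channel mismatch between recording and electrodes; ",
           "only in recording: [", paste(d1, collapse = ", "),
           "]; only in electrodes: [", paste(d2, collapse = ", "), "]")
    dat <- dat[match(sensors$name, rownames(dat)), , drop = FALSE]
  }
  eeg_recording(dat, fs = meta$fs, sensors = sensors,
                reference = if (is.null(meta$reference)) "average"
                            else meta$reference)
}

#' Minimal EDF reader
#'
#' Reads the subset of the European Data Format sufficient for
#' continuous single-session recordings: the fixed-width ASCII header,
#' per-signal headers, and contiguous 2-byte little-endian data
#' records, rescaled to physical units.  All signals must share one
#' sampling rate.  Annotations and discontinuous files are not
#' supported.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] (without sensor positions).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  a <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  a(8)                     # version
  a(80); a(80)             # patient, recording id
  a(8); a(8)               # start date, time
  header_bytes <- as.integer(a(8))
  a(44)                    # reserved
  n_rec <- as.integer(a(8))
  rec_dur <- as.numeric(a(8))
  ns <- as.integer(a(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: signal count")
  labels <- vapply(seq_len(ns), function(i) a(16), "")
  for (i in seq_len(ns)) a(80)   # transducer
  for (i in seq_len(ns)) a(8)    # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) a(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) a(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) a(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) a(8), ""))
  for (i in seq_len(ns)) a(80)   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) a(8), ""))
  for (i in seq_len(ns)) a(32)   # reserved
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr)))
    stop("malformed EDF header: signal scaling fields")
  if (length(unique(spr)) != 1)
    stop("signals with mixed sampling rates are not supported")
  seek(con, header_bytes)
  dat <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      dat[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        pmin_[s] + (raw - dmin_[s]) * scale[s]
    }
  }
  rownames(dat) <- labels
  eeg_recording(dat, fs = spr[1] / rec_dur, reference = "unknown")
}

#' Read a run configuration
#'
#' YAML file with optional sections `paths` (labels, electrodes,
#' recording, out), `band` (two numbers), `reconstruction` (lambda,
#' depth, max_iter, tol, splat_fwhm, smooth_width), `properties`
#' (per-tissue sigma / eps_rel / anisotropy_ratio) and `seed`.
#' Referenced input paths must exist.
#'
#' @param path YAML file.
#' @return Nested list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  for (p in unlist(cfg$paths[c("labels", "electrodes", "recording")]))
    if (!is.null(p) && !file.exists(p))
      stop("config references a missing path: ", p)
  if (!is.null(cfg$band) && (length(cfg$band) != 2 ||
                             cfg$band[1] >= cfg$band[2]))
    stop("config `band` must be two increasing frequencies")
  cfg
}

#' @noRd
.table_from_config <- function(props) {
  if (is.null(props)) return(tissue_properties())
  base <- tissue_properties()
  for (tn in names(props)) {
    i <- match(tn, base$tissue)
    if (is.na(i)) stop("unknown tissue in config: ", tn)
    for (f in intersect(names(props[[tn]]),
                        c("sigma", "eps_rel", "anisotropy_ratio")))
      base[[f]][i] <- props[[tn]][[f]]
  }
  tissue_properties(sigma = stats::setNames(base$sigma, base$tissue),
                    eps_rel = stats::setNames(base$eps_rel, base$tissue),
                    anisotropy_ratio = stats::setNames(base$anisotropy_ratio,
                                                       base$tissue))
}
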