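#' Toy leadfield on a regular voxel grid
#'
#' A fixed-orientation forward model for testing source reconstruction
#' without any head geometry: voxels on an even 3-D grid, sensors on a
#' plane above the grid, and gains decaying with the inverse square of the
#' voxel-sensor distance. Gains carry no physical units; they only need to
#' be full-rank enough for beamforming round trips.
#'
#' @param dims integer length-3 vector of grid extents (voxels per axis).
#' @param spacing grid spacing in cm (equal along the three axes).
#' @param n_sensors number of sensors; laid out on a jittered plane 2 grid
#'   units above the top of the grid.
#' @param seed integer seed for the sensor jitter.
#' @return object of class `toy_leadfield`: `voxel_positions` (V x 3, cm),
#'   `grid_spacing`, `gain` (V x S), `sensor_names`, `dims`.
#' @export
make_toy_leadfield <- function(dims = c(5, 5, 3), spacing = 0.5,
                               n_sensors = 24, seed = 1) {
  stopifnot(length(dims) == 3, all(dims >= 1), spacing > 0, n_sensors >= 2)
  pos <- as.matrix(expand.grid(
    x = (seq_len(dims[1]) - 1) * spacing,
    y = (seq_len(dims[2]) - 1) * spacing,
    z = (seq_len(dims[3]) - 1) * spacing))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nx <- ceiling(sqrt(n_sensors))
  sx <- seq(min(pos[, 1]), max(pos[, 1]) + spacing, length.out = nx)
  sy <- seq(min(pos[, 2]), max(pos[, 2]) + spacing, length.out = nx)
  sens <- as.matrix(expand.grid(x = sx, y = sy))[seq_len(n_sensors), , drop = FALSE]
  sens <- cbind(sens, max(pos[, 3]) + 2 * spacing)
  sens <- sens + matrix(stats::runif(length(sens), -0.05, 0.05) * spacing,
                        nrow(sens), 3)
  V <- nrow(pos); S <- n_sensors
  gain <- matrix(0, V, S)
  for (s in seq_len(S)) {
    d2 <- rowSums(sweep(pos, 2, sens[s, ])^2)
    gain[, s] <- 1 / d2
  }
  structure(
    list(voxel_positions = pos, grid_spacing = spacing, gain = gain,
         sensor_names = sprintf("S%02d", seq_len(S)), dims = dims),
    class = "toy_leadfield")
}

#' @export
print.toy_leadfield <- function(x, ...) {
  cat(sprintf("<toy_leadfield> %d voxels (%s grid, %.2g cm), %d sensors\n",
              nrow(x$voxel_positions), paste(x$dims, collapse = "x"),
              x$grid_spacing, length(x$sensor_names)))
  invisible(x)
}

#' Project source time series to sensors through a toy leadfield
#'
#' Sensor series are the gain-weighted sum of the active-voxel sources
#' plus white Gaussian noise scaled so that the ratio of total signal
#' power to total noise power across sensors equals `snr`.
#'
#' @param sources a [ts_set()] with one channel per active voxel.
#' @param lf a [make_toy_leadfield()] object.
#' @param active_voxels integer voxel indices, one per source channel.
#' @param snr sensor-level signal-to-noise power ratio; `Inf` disables
#'   noise.
#' @param seed integer seed for the noise.
#' @return a [ts_set()] with one channel per sensor.
#' @export
project_to_sensors <- function(sources, lf, active_voxels, snr = Inf,
                               seed = 1) {
  stopifnot(inherits(sources, "ts_set"), inherits(lf, "toy_leadfield"))
  V <- nrow(lf$gain)
  if (any(active_voxels < 1 | active_voxels > V))
    stop("active voxel index out of range")
  if (length(active_voxels) != n_channels(sources))
    stop("need exactly one source channel per active voxel")
  G <- t(lf$gain[active_voxels, , drop = FALSE])   # S x nsrc
  sig <- G %*% sources$data                         # S x T
  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive or Inf")
    sig_pow <- mean(sig^2)
    noise_sd <- sqrt(sig_pow / snr)
    if (sig_pow == 0) noise_sd <- 1   # pure-noise case: unit variance
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sig <- sig + matrix(stats::rnorm(length(sig), sd = noise_sd),
                        nrow(sig), ncol(sig))
  }
  ts_set(sig, sampling_rate = sources$sampling_rate,
         channels = lf$sensor_names)
}
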