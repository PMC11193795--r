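#' Band-averaged cross-spectral density of epoched sensor data
#'
#' Per trial, channels are Hann-tapered and Fourier-transformed; the
#' cross-spectral density is averaged over all FFT bins inside the band
#' and over trials.
#'
#' @param epochs an `epoch_set`.
#' @param band numeric `c(low, high)` in Hz (within 3-30 Hz in the
#'   pipeline; any band below Nyquist is accepted).
#' @return object of class `csd_matrix`: complex conjugate-symmetric
#'   `csd` (channels x channels), `band`, `n_trials`, `freq_bins`.
#' @export
band_csd <- function(epochs, band) {
  stopifnot(inherits(epochs, "epoch_set"), length(band) == 2)
  sf <- epochs$sampling_rate
  if (band[2] > sf / 2) stop("band extends beyond the Nyquist frequency")
  dat <- epochs$data
  n_tr <- dim(dat)[1]; C <- dim(dat)[2]; L <- dim(dat)[3]
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  freqs <- (seq_len(L) - 1) * sf / L
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bins)) stop("band contains no FFT bin at this epoch length")
  csd <- matrix(0 + 0i, C, C)
  for (tr in seq_len(n_tr)) {
    X <- t(apply(dat[tr, , , drop = FALSE][1, , ], 1,
                 function(v) stats::fft(v * taper)))
    Xb <- X[, bins, drop = FALSE]
    csd <- csd + (Xb %*% Conj(t(Xb))) / length(bins)
  }
  csd <- csd / n_tr
  dimnames(csd) <- list(epochs$channels, epochs$channels)
  structure(list(csd = csd, band = band, n_trials = n_tr,
                 freq_bins = freqs[bins]),
            class = "csd_matrix")
}

#' DICS beamformer with Neural Activity Index
#'
#' Computes, per voxel v with gain column l, the unit-gain spatial filter
#' `w = (l' Cr^-1 l)^-1 l' Cr^-1` on the regularized cross-spectral
#' density `Cr = C + lambda * (trace(C)/S) * I`. Source power is
#' `Re(w C w^H)`. The Neural Activity Index divides the power by the
#' noise projected through the same filter, `Re(w N w^H)`, correcting the
#' depth bias; the noise CSD `N` defaults to white noise `sigma^2 I` with
#' `sigma^2` the smallest eigenvalue of the band CSD. The dB map is
#' `10 log10(NAI)`.
#'
#' @param csd a [band_csd()] result.
#' @param lf a [make_toy_leadfield()] object.
#' @param noise_csd noise cross-spectral density: scalar variance, full
#'   matrix, or `NULL` for the smallest-eigenvalue default.
#' @param reg_lambda regularization as a fraction of mean sensor power
#'   (default 0.05).
#' @return object of class `source_model`: `filters` (voxels x sensors,
#'   complex), `power`, `nai`, `db` per voxel, plus `leadfield`, `band`,
#'   `reg_lambda`, `noise_var`.
#' @export
dics <- function(csd, lf, noise_csd = NULL, reg_lambda = 0.05) {
  stopifnot(inherits(csd, "csd_matrix"), inherits(lf, "toy_leadfield"))
  C <- csd$csd
  S <- nrow(C)
  if (ncol(lf$gain) != S) stop("leadfield sensor count does not match CSD")
  Cr <- C + reg_lambda * (sum(Re(diag(C))) / S) * diag(S)
  Ci <- tryCatch(solve(Cr), error = function(e)
    stop(sprintf("regularized CSD is singular at lambda = %g", reg_lambda)))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  noise_var <- NULL
  if (is.null(noise_csd)) {
    noise_var <- max(Re(ev[length(ev)]), .Machine$double.eps)
    N <- noise_var * diag(S)
  } else if (length(noise_csd) == 1) {
    noise_var <- noise_csd
    N <- noise_csd * diag(S)
  } else {
    N <- if (inherits(noise_csd, "csd_matrix")) noise_csd$csd else noise_csd
  }
  V <- nrow(lf$gain)
  W <- matrix(0 + 0i, V, S)
  pow <- nai <- numeric(V)
  for (v in seq_len(V)) {
    l <- lf$gain[v, ]
    Cil <- Ci %*% l
    w <- Conj(t(Cil)) / drop(Re(crossprod(l, Cil)))
    W[v, ] <- w
    pow[v] <- Re(w %*% C %*% Conj(t(w)))
    nai[v] <- pow[v] / Re(w %*% N %*% Conj(t(w)))
  }
  structure(
    list(filters = W, power = pow, nai = nai,
         db = 10 * log10(pmax(nai, .Machine$double.xmin)),
         leadfield = lf, band = csd$band, reg_lambda = reg_lambda,
         noise_var = noise_var),
    class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d voxels, band %g-%g Hz, peak NAI %.3g at voxel %d\n",
              length(x$nai), x$band[1], x$band[2], max(x$nai),
              which.max(x$nai)))
  invisible(x)
}

# Classic DBSCAN over a point set. minPts counts the point itself.
dbscan_points <- function(points, eps, min_pts) {
  n <- nrow(points)
  if (!n) return(integer(0))
  D <- as.matrix(stats::dist(points))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)            # 0 = noise / unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, nbrs[[j]][labels[nbrs[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Extract top-activity voxel clusters by DBSCAN
#'
#' Thresholds the NAI map at the `100 - top_pct` percentile (voxels at or
#' above the threshold are kept — relevant when ties sit exactly on it)
#' and runs DBSCAN over the suprathreshold voxel coordinates with
#' `eps` of one grid edge length and a minimum of `min_size` voxels, so
#' isolated voxels are discarded as noise. An optional integer label mask
#' restricts both the percentile computation and the clustering to
#' labeled (non-zero) voxels.
#'
#' @param source a [dics()] result.
#' @param top_pct percentage of the NAI distribution to keep (default 3).
#' @param eps DBSCAN radius; defaults to one grid spacing.
#' @param min_size minimum cluster size in voxels (default 2).
#' @param label_mask optional integer vector per voxel; 0/NA voxels are
#'   excluded.
#' @return object of class `voxel_cluster_set`: `clusters` (list of
#'   global voxel index vectors), `threshold`, `eps`, `min_size`,
#'   `noise_voxels`.
#' @export
dbscan_top <- function(source, top_pct = 3, eps = NULL, min_size = 2,
                       label_mask = NULL) {
  stopifnot(inherits(source, "source_model"))
  lf <- source$leadfield
  if (is.null(eps)) eps <- lf$grid_spacing
  nai <- source$nai
  idx_pool <- seq_along(nai)
  if (!is.null(label_mask))
    idx_pool <- idx_pool[!is.na(label_mask) & label_mask != 0]
  if (!length(idx_pool)) stop("label mask excludes every voxel")
  thr <- stats::quantile(nai[idx_pool], 1 - top_pct / 100, names = FALSE)
  supra <- idx_pool[nai[idx_pool] >= thr]
  if (!length(supra))
    return(structure(list(clusters = list(), threshold = thr, eps = eps,
                          min_size = min_size, noise_voxels = integer(0)),
                     class = "voxel_cluster_set"))
  labels <- dbscan_points(lf$voxel_positions[supra, , drop = FALSE],
                          eps = eps, min_pts = min_size)
  clusters <- lapply(seq_len(max(labels, 0L)), function(k) supra[labels == k])
  clusters <- clusters[vapply(clusters, length, integer(1)) >= min_size]
  structure(
    list(clusters = clusters, threshold = thr, eps = eps,
         min_size = min_size, noise_voxels = supra[labels == 0L]),
    class = "voxel_cluster_set")
}

#' @export
print.voxel_cluster_set <- function(x, ...) {
  cat(sprintf("<voxel_cluster_set> %d cluster(s), threshold %.4g, eps %.3g\n",
              length(x$clusters), x$threshold, x$eps))
  invisible(x)
}

#' LCMV reconstruction of a cluster's source time series
#'
#' Band-pass filters the epochs (zero-phase FIR, see Details), estimates
#' the broadband sensor covariance of the filtered data over the
#' -500..+500 ms window of every trial, computes the unit-gain LCMV
#' filter at the cluster's peak-NAI voxel, applies it to the
#' -500..+500 ms window of each trial and concatenates the trials into a
#' single series.
#'
#' @details The band-pass is a linear-phase FIR (window method,
#'   [signal::fir1()]) applied forward and backward ([signal::filtfilt()])
#'   for zero phase; the default order is one sampling-rate's worth of
#'   taps (1 s kernel), shortened when the epoch is short. Filtering runs
#'   on the padded window when present, so filter edges stay outside the
#'   analysis window. The reconstructed series has an arbitrary sign.
#'
#' @param epochs an `epoch_set` of sensor data.
#' @param lf the [make_toy_leadfield()] used for the forward model.
#' @param cluster integer vector of voxel indices (one entry of a
#'   [dbscan_top()] result).
#' @param band numeric `c(low, high)` Hz.
#' @param nai optional per-voxel NAI (from [dics()]) used to pick the
#'   peak voxel; defaults to the first cluster voxel.
#' @param reg_lambda covariance regularization fraction (default 0.05).
#' @param filter_order FIR order override.
#' @return a [ts_set()] with one channel of length
#'   `n_trials * (2 * round(0.5 * sampling_rate) + 1)`.
#' @export
lcmv_timeseries <- function(epochs, lf, cluster, band, nai = NULL,
                            reg_lambda = 0.05, filter_order = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(lf, "toy_leadfield"))
  if (!length(cluster)) stop("cluster is empty")
  sf <- epochs$sampling_rate
  pad <- epochs$pad_data
  n_tr <- dim(pad)[1]; C <- dim(pad)[2]; L <- dim(pad)[3]
  if (is.null(filter_order))
    filter_order <- min(round(sf), floor((L - 1) / 4))
  filter_order <- max(2 * (filter_order %/% 2), 4)
  b <- signal::fir1(filter_order, band / (sf / 2), type = "pass")
  filt <- array(0, dim(pad))
  for (tr in seq_len(n_tr))
    for (ch in seq_len(C))
      filt[tr, ch, ] <- signal::filtfilt(b, pad[tr, ch, ])
  half <- round(0.5 * sf)
  center <- which.min(abs(epochs$pad_times))
  win <- (center - half):(center + half)
  if (win[1] < 1 || win[length(win)] > L)
    stop("epochs are shorter than the -500..+500 ms analysis window")
  seg <- filt[, , win, drop = FALSE]
  flat <- matrix(aperm(seg, c(2, 3, 1)), nrow = C)   # C x (len * trials)
  flat_c <- flat - rowMeans(flat)
  Cov <- tcrossprod(flat_c) / ncol(flat_c)
  Cr <- Cov + reg_lambda * (sum(diag(Cov)) / C) * diag(C)
  Ci <- tryCatch(solve(Cr), error = function(e)
    stop(sprintf("regularized covariance singular at lambda = %g", reg_lambda)))
  peak <- if (is.null(nai)) cluster[1] else cluster[which.max(nai[cluster])]
  l <- lf$gain[peak, ]
  w <- drop(crossprod(l, Ci)) / drop(crossprod(l, Ci %*% l))
  src <- drop(w %*% flat)
  ts_set(matrix(src, 1), sampling_rate = sf,
         channels = sprintf("cluster_v%d", peak))
}

#' Write a voxel cluster set to JSON
#' @param x a `voxel_cluster_set`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_voxel_clusters <- function(x, path) {
  jsonlite::write_json(
    list(clusters = x$clusters, threshold = x$threshold, eps = x$eps,
         min_size = x$min_size, noise_voxels = x$noise_voxels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
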